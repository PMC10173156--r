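#' Construct and validate a dosage matrix
#'
#' A dosage matrix stores biallelic SNP genotype calls for a (possibly
#' mixed-ploidy) panel on the tetraploid scale: each call counts the copies
#' of the alternate allele, so AAAA, AAAB, AABB, ABBB and BBBB are coded
#' 0, 1, 2, 3 and 4. Rows are samples (accessions), columns are markers;
#' missing calls are `NA`.
#'
#' @param calls integer matrix, samples x markers; entries in `0:4` or `NA`.
#' @param sample_ids,marker_ids optional character vectors overriding the
#'   dimnames of `calls`. Must be unique.
#' @return An integer matrix of class `dosage_matrix` with sample ids as
#'   rownames and marker ids as colnames.
#' @examples
#' m <- dosage_matrix(rbind(a = c(0, 2, 4), b = c(1, 3, NA)),
#'                    marker_ids = c("m1", "m2", "m3"))
#' dim(m)
#' @export
dosage_matrix <- function(calls, sample_ids = rownames(calls),
                          marker_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(nrow(calls)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- sprintf("M%05d", seq_len(ncol(calls)))
  }
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(calls)) {
    stop("length(sample_ids) does not match nrow(calls)", call. = FALSE)
  }
  if (length(marker_ids) != ncol(calls)) {
    stop("length(marker_ids) does not match ncol(calls)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  bad <- which(!is.na(calls) & (calls < 0L | calls > 4L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("dosage call out of range 0..4 at sample '%s', marker '%s'",
                 sample_ids[bad[1L, 1L]], marker_ids[bad[1L, 2L]]),
         call. = FALSE)
  }
  dimnames(calls) <- list(sample_ids, marker_ids)
  class(calls) <- c("dosage_matrix", class(calls))
  calls
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d markers (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.dosage_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("dosage_matrix", class(out))
  out
}

assert_dosage <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x)) stop(arg, " must be a dosage matrix", call. = FALSE)
  x
}

#' Read a dosage matrix from TSV
#'
#' Expects a header row `sample_id<TAB>marker1<TAB>...`, one row per sample,
#' cells `0`-`4` or `NA` for missing.
#'
#' @param path file path.
#' @return A [dosage_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = "NA",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("TSV must have a sample_id column and >=1 marker")
  sample_ids <- df[[1L]]
  marker_ids <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which((!is.na(cells) & is.na(num)) |
                 (!is.na(num) & (num != round(num) | num < 0 | num > 4)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid dosage cell '%s' at sample '%s', marker '%s' (expect 0-4 or NA)",
      cells[bad[1L, 1L], bad[1L, 2L]], sample_ids[bad[1L, 1L]],
      marker_ids[bad[1L, 2L]]), call. = FALSE)
  }
  m <- dosage_matrix(num, sample_ids = sample_ids, marker_ids = marker_ids)
  message(sprintf("read %d samples x %d markers from %s",
                  nrow(m), ncol(m), path))
  m
}

#' Write a dosage matrix to TSV
#'
#' Inverse of [read_dosage_tsv()]; missing calls are written as `NA`.
#'
#' @param m a [dosage_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(m, path) {
  assert_dosage(m)
  df <- data.frame(sample_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a dosage matrix from a VCF
#'
#' Converts genotype (GT) calls of biallelic sites to alternate-allele
#' dosages: the dosage is the count of ALT alleles among the (up to four)
#' alleles of the call. Genotypes containing any missing allele (`.`) become
#' `NA`. Multiallelic sites are skipped with a warning.
#'
#' @param path a VCF file (v4.2, plain or bgzipped).
#' @return A [dosage_matrix()] (samples x markers).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_dosage_vcf() requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1L
  if (any(multi)) {
    warning(sprintf("skipped %d multiallelic site(s)", sum(multi)))
    vcf <- vcf[!multi, ]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  dosage_from_gt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  d <- vapply(gt, dosage_from_gt, integer(1L))
  d <- matrix(d, nrow = nrow(gt), ncol = ncol(gt))
  dosage_matrix(t(d), sample_ids = colnames(gt), marker_ids = rownames(gt))
}

#' Alternate-allele frequencies from dosages
#'
#' Per-marker frequency of the alternate allele, `p = sum(d) / (4 * n)` over
#' non-missing calls `d`; all calls are on the tetraploid scale so the
#' denominator is 4 per call regardless of a sample's true ploidy.
#'
#' @param m a [dosage_matrix()].
#' @param marker optional marker id or index; if given, a single frequency is
#'   returned.
#' @return Named numeric vector of frequencies in `[0, 1]` (or a scalar).
#' @seealso [minor_allele_freq()]
#' @export
allele_freq <- function(m, marker = NULL) {
  assert_dosage(m)
  if (!is.null(marker)) m <- m[, marker, drop = FALSE]
  n <- colSums(!is.na(m))
  if (any(n == 0L)) {
    stop("allele frequency undefined for all-missing marker(s): ",
         paste(colnames(m)[n == 0L], collapse = ", "), call. = FALSE)
  }
  p <- colSums(m, na.rm = TRUE) / (4 * n)
  if (!is.null(marker) && length(p) == 1L) p <- unname(p)
  p
}

#' @rdname allele_freq
#' @export
minor_allele_freq <- function(m, marker = NULL) {
  p <- allele_freq(m, marker)
  pmin(p, 1 - p)
}

#' Filter a dosage matrix by MAF and missingness
#'
#' Standard array-QC filter. Each pass removes markers with minor allele
#' frequency below `maf_min` or a missing-call fraction above
#' `missing_max`, then samples whose missing fraction (over the retained
#' markers) exceeds `missing_max`. Because removing samples can change
#' marker-level MAF and missingness (and vice versa), passes repeat until
#' nothing more is removed, which makes the operation idempotent; on
#' typical array data the first pass is the only one that removes
#' anything.
#'
#' @param m a [dosage_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.03).
#' @param missing_max maximum missing fraction per marker and per sample
#'   (default 0.05).
#' @return A list of class `filter_result` with elements `matrix` (the
#'   filtered [dosage_matrix()]) and `report` (a `filter_report` list:
#'   in/out counts, removed ids with reasons, thresholds).
#' @export
filter_dosage <- function(m, maf_min = 0.03, missing_max = 0.05) {
  assert_dosage(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty dosage matrix")
  removed_markers <- character(0); marker_reason <- character(0)
  removed_samples <- character(0)
  n_in <- dim(m)
  cur <- m
  repeat {
    n_nm <- colSums(!is.na(cur))
    miss_frac <- 1 - n_nm / nrow(cur)
    p <- ifelse(n_nm > 0,
                colSums(cur, na.rm = TRUE) / (4 * pmax(n_nm, 1L)), NA)
    maf <- pmin(p, 1 - p)
    low_maf <- is.na(maf) | maf < maf_min
    high_miss <- miss_frac > missing_max
    drop_marker <- low_maf | high_miss
    if (any(drop_marker)) {
      # a marker failing both filters is reported under high_missing
      marker_reason <- c(marker_reason,
                         ifelse(high_miss, "high_missing",
                                "low_maf")[drop_marker])
      removed_markers <- c(removed_markers, colnames(cur)[drop_marker])
      cur <- cur[, !drop_marker, drop = FALSE]
      if (ncol(cur) == 0L) stop("all markers removed by filters")
    }
    drop_sample <- rowMeans(is.na(cur)) > missing_max
    if (any(drop_sample)) {
      removed_samples <- c(removed_samples, rownames(cur)[drop_sample])
      cur <- cur[!drop_sample, , drop = FALSE]
      if (nrow(cur) == 0L) stop("all samples removed by filters")
    }
    if (!any(drop_marker) && !any(drop_sample)) break
  }
  report <- list(
    n_markers_in = n_in[2L], n_markers_out = ncol(cur),
    n_samples_in = n_in[1L], n_samples_out = nrow(cur),
    removed_markers = data.frame(marker_id = removed_markers,
                                 reason = marker_reason,
                                 stringsAsFactors = FALSE),
    removed_samples = data.frame(sample_id = removed_samples,
                                 reason = rep("high_missing",
                                              length(removed_samples)),
                                 stringsAsFactors = FALSE),
    maf_threshold = maf_min, missing_threshold = missing_max)
  class(report) <- "filter_report"
  structure(list(matrix = cur, report = report), class = "filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter: markers %d -> %d, samples %d -> %d (MAF >= %g, missing <= %g)\n",
              x$n_markers_in, x$n_markers_out, x$n_samples_in,
              x$n_samples_out, x$maf_threshold, x$missing_threshold))
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report a `filter_report` from [filter_dosage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
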