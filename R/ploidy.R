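#' Simplex/triplex call frequency per sample
#'
#' The fraction of a sample's non-missing dosage calls that are simplex
#' (AAAB, dosage 1) or triplex (ABBB, dosage 3). True diploids genotyped on
#' the tetraploid scale produce essentially only dosages 0, 2 and 4, so this
#' frequency is near zero for diploids and substantial for tetraploids —
#' the basis of dosage-based ploidy inference.
#'
#' @param m a [dosage_matrix()], or a vector of dosage calls for one sample.
#' @return Named numeric vector (one value per sample) in `[0, 1]`.
#' @export
simplex_triplex_freq <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L, dimnames = list("sample", NULL))
  n <- rowSums(!is.na(m))
  if (any(n == 0L)) {
    stop("simplex/triplex frequency undefined for all-missing sample(s): ",
         paste(rownames(m)[n == 0L], collapse = ", "), call. = FALSE)
  }
  st <- rowSums(m == 1L | m == 3L, na.rm = TRUE) / n
  stats::setNames(as.numeric(st), rownames(m))
}

#' Classify ploidy from simplex/triplex frequency
#'
#' Samples with `st_freq <= dip_max` are called diploid, samples with
#' `st_freq > tet_min` tetraploid, and the grey area in between `unknown`.
#' The defaults encode the 0-15% diploid window and the >20% tetraploid
#' rule, with 15-20% left unknown. Boundary convention: a frequency exactly
#' at `dip_max` is diploid; exactly at `tet_min` is unknown. Triploids are
#' never emitted — this method cannot discriminate them.
#'
#' @param st_freq numeric vector of simplex+triplex frequencies in `[0, 1]`.
#' @param dip_max upper frequency bound (inclusive) for a diploid call.
#' @param tet_min lower frequency bound (exclusive) for a tetraploid call.
#' @return factor with levels `diploid`, `unknown`, `tetraploid`.
#' @export
classify_ploidy <- function(st_freq, dip_max = 0.15, tet_min = 0.20) {
  if (dip_max >= tet_min) stop("dip_max must be < tet_min")
  if (any(st_freq < 0 | st_freq > 1, na.rm = TRUE)) {
    stop("st_freq must be in [0, 1]")
  }
  call <- ifelse(st_freq <= dip_max, "diploid",
                 ifelse(st_freq > tet_min, "tetraploid", "unknown"))
  factor(call, levels = c("diploid", "unknown", "tetraploid"))
}

#' Per-sample ploidy calls for a panel
#'
#' Convenience wrapper combining [simplex_triplex_freq()] and
#' [classify_ploidy()].
#'
#' @inheritParams classify_ploidy
#' @param m a [dosage_matrix()].
#' @return data.frame with columns `sample_id`, `st_freq`, `call`, and the
#'   thresholds used as attributes `dip_max` / `tet_min`.
#' @export
ploidy_calls <- function(m, dip_max = 0.15, tet_min = 0.20) {
  st <- simplex_triplex_freq(m)
  out <- data.frame(sample_id = names(st), st_freq = as.numeric(st),
                    call = classify_ploidy(st, dip_max, tet_min),
                    stringsAsFactors = FALSE)
  attr(out, "dip_max") <- dip_max
  attr(out, "tet_min") <- tet_min
  out
}

reference_ploidy_from_chromosomes <- function(chromosome_count) {
  # Solanum base number x = 12: 24 -> diploid, 36 -> triploid, 48 -> tetraploid
  cls <- rep(NA_character_, length(chromosome_count))
  cls[chromosome_count == 24] <- "diploid"
  cls[chromosome_count == 36] <- "triploid"
  cls[chromosome_count == 48] <- "tetraploid"
  cls
}

#' Concordance of ploidy calls with a chromosome-count reference panel
#'
#' Reference ploidy is derived from root-cell chromosome counts (24 =
#' diploid, 36 = triploid, 48 = tetraploid). Per reference class the number
#' of concordant calls and the accuracy (percent, one decimal) are reported;
#' triploids cannot be discriminated by the simplex/triplex method and are
#' reported as unclassifiable, outside the diploid/tetraploid accuracy
#' denominators. A one-way ANOVA of st_freq across reference classes is
#' included.
#'
#' @param calls a data.frame from [ploidy_calls()].
#' @param metadata a [sample_metadata()] data.frame with `chromosome_count`
#'   for the reference samples.
#' @return list of class `concordance_report`: `by_class` data.frame
#'   (`class`, `n_reference`, `n_correct`, `n_offtype`, `accuracy_pct`,
#'   `st_mean`, `st_sd`), `n_reference_total`, `n_unclassifiable`, and
#'   `anova` (`F`, `p`, dfs).
#' @export
concordance <- function(calls, metadata) {
  metadata <- sample_metadata(metadata)
  ref <- metadata[!is.na(metadata$chromosome_count), , drop = FALSE]
  if (nrow(ref) == 0L) stop("no reference samples with chromosome counts")
  ref$ref_class <- reference_ploidy_from_chromosomes(ref$chromosome_count)
  if (any(is.na(ref$ref_class))) {
    stop("chromosome counts other than 24/36/48 in reference panel")
  }
  idx <- match(ref$sample_id, calls$sample_id)
  if (any(is.na(idx))) stop("reference sample(s) missing from ploidy calls")
  ref$call <- as.character(calls$call[idx])
  ref$st_freq <- calls$st_freq[idx]

  classes <- c("diploid", "triploid", "tetraploid")
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    sub <- ref[ref$ref_class == cl, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    n_correct <- if (cl == "triploid") NA_integer_ else sum(sub$call == cl)
    acc <- if (cl == "triploid") NA_real_ else
      round(100 * n_correct / nrow(sub), 1)
    data.frame(class = cl, n_reference = nrow(sub), n_correct = n_correct,
               n_offtype = nrow(sub) - ifelse(is.na(n_correct), 0L, n_correct),
               accuracy_pct = acc,
               st_mean = mean(sub$st_freq),
               st_sd = stats::sd(sub$st_freq),
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  groups <- split(ref$st_freq, ref$ref_class)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  aov_res <- if (length(groups) >= 2L) anova_oneway(groups) else
    list(F = NA_real_, p = NA_real_)
  out <- list(by_class = by_class,
              n_reference_total = nrow(ref),
              n_unclassifiable = sum(ref$ref_class == "triploid"),
              anova = aov_res)
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("reference panel: %d samples (%d triploid, unclassifiable)\n",
              x$n_reference_total, x$n_unclassifiable))
  print(x$by_class, row.names = FALSE)
  if (!is.na(x$anova$F)) {
    cat(sprintf("one-way ANOVA of st_freq across classes: F = %.3g, p = %.3g\n",
                x$anova$F, x$anova$p))
  }
  invisible(x)
}

#' Proportion of reference samples inside a chloroplast-count window
#'
#' Guard-cell chloroplast counts offer an independent, indirect ploidy
#' check: diploid accessions typically average 7-8 chloroplasts per guard
#' cell and tetraploids 12-14. This reports the percentage of a reference
#' class whose (rounded) mean count falls inside the expected window.
#'
#' @param metadata a [sample_metadata()] data.frame with
#'   `chromosome_count` (defining the reference class) and
#'   `chloroplast_count`.
#' @param ref_class reference class to evaluate (`"diploid"` default).
#' @param window inclusive integer window of rounded mean counts
#'   (default `c(7, 8)`, the diploid window).
#' @return list: `n_reference`, `n_in_window`, `percent` (one decimal).
#' @export
chloroplast_window <- function(metadata, ref_class = "diploid",
                               window = c(7, 8)) {
  metadata <- sample_metadata(metadata)
  cls <- reference_ploidy_from_chromosomes(metadata$chromosome_count)
  keep <- !is.na(cls) & cls == ref_class & !is.na(metadata$chloroplast_count)
  if (!any(keep)) stop("no reference samples of class ", ref_class)
  cnt <- round(metadata$chloroplast_count[keep])
  n_in <- sum(cnt >= window[1L] & cnt <= window[2L])
  list(n_reference = sum(keep), n_in_window = n_in,
       percent = round(100 * n_in / sum(keep), 1))
}

#' Calibrate ploidy thresholds from a reference panel
#'
#' Proposes `(dip_max, tet_min)` from reference simplex/triplex frequencies:
#' `dip_max` is the diploid maximum after trimming the top 5% of diploid
#' values as off-types, `tet_min` the tetraploid minimum after trimming the
#' bottom 5%. If the trimmed ranges overlap (no gap), the defaults
#' `(0.15, 0.20)` are returned with a warning. Class-conditional summaries
#' are always reported so a curator can override.
#'
#' @param st_freq numeric vector of reference frequencies.
#' @param classes character/factor vector, `diploid` / `tetraploid` per
#'   reference sample (other labels ignored).
#' @param trim fraction trimmed from the off-type tail of each class (0.05).
#' @return list: `dip_max`, `tet_min`, `calibrated` (FALSE when defaults
#'   were returned), `class_summary` data.frame (min/max/mean/sd per class).
#' @export
calibrate_thresholds <- function(st_freq, classes, trim = 0.05) {
  classes <- as.character(classes)
  keep <- classes %in% c("diploid", "tetraploid")
  st_freq <- st_freq[keep]; classes <- classes[keep]
  tab <- table(classes)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("calibration needs >=2 diploid and >=2 tetraploid reference samples")
  }
  dip <- sort(st_freq[classes == "diploid"])
  tet <- sort(st_freq[classes == "tetraploid"])
  class_summary <- data.frame(
    class = c("diploid", "tetraploid"),
    n = c(length(dip), length(tet)),
    min = c(min(dip), min(tet)), max = c(max(dip), max(tet)),
    mean = c(mean(dip), mean(tet)), sd = c(stats::sd(dip), stats::sd(tet)))
  dip_trim <- dip[seq_len(length(dip) - floor(trim * length(dip)))]
  tet_trim <- tet[(1L + floor(trim * length(tet))):length(tet)]
  dip_max <- max(dip_trim)
  tet_min <- min(tet_trim)
  if (dip_max >= tet_min) {
    warning("diploid and tetraploid st_freq distributions overlap after ",
            "trimming; returning default thresholds (0.15, 0.20)")
    return(list(dip_max = 0.15, tet_min = 0.20, calibrated = FALSE,
                class_summary = class_summary))
  }
  list(dip_max = dip_max, tet_min = tet_min, calibrated = TRUE,
       class_summary = class_summary)
}

#' Classic one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance with the F-distribution
#' p-value. When every group has zero internal variance but group means
#' differ, F is infinite and p is reported as 0 with `degenerate = TRUE`.
#'
#' @param groups a list of numeric vectors (>=2 groups, each n >= 2), or a
#'   numeric vector when `labels` is given.
#' @param labels optional grouping vector parallel to `groups`.
#' @return list: `F`, `p`, `df_between`, `df_within`, `degenerate`.
#' @export
anova_oneway <- function(groups, labels = NULL) {
  if (!is.null(labels)) groups <- split(groups, labels)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs n >= 2")
  n <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  grand <- sum(n * means) / sum(n)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1L
  dfw <- sum(n) - length(groups)
  if (ssw == 0) {
    degenerate <- TRUE
    if (ssb == 0) {
      return(list(F = 0, p = 1, df_between = dfb, df_within = dfw,
                  degenerate = degenerate))
    }
    return(list(F = Inf, p = 0, df_between = dfb, df_within = dfw,
                degenerate = degenerate))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw, degenerate = FALSE)
}

#' Ploidy-call consistency within replicate groups
#'
#' Biological replicates of one accession should receive the same ploidy
#' call. A replicate group is consistent when all its non-`unknown` calls
#' agree (`unknown` calls are ignored; a group of only unknowns is
#' consistent by convention).
#'
#' @param calls data.frame from [ploidy_calls()].
#' @param metadata a [sample_metadata()] data.frame with `replicate_group`.
#' @return data.frame: `replicate_group`, `n_members`, `calls`
#'   (comma-separated), `consistent`. Zero rows when no groups of size >= 2
#'   exist.
#' @export
replicate_consistency <- function(calls, metadata) {
  metadata <- sample_metadata(metadata)
  meta <- metadata[!is.na(metadata$replicate_group), , drop = FALSE]
  # members absent from the calls (e.g. removed by QC) are ignored
  meta <- meta[meta$sample_id %in% calls$sample_id, , drop = FALSE]
  grp <- split(meta$sample_id, meta$replicate_group)
  grp <- grp[vapply(grp, length, 1L) >= 2L]
  if (length(grp) == 0L) {
    return(data.frame(replicate_group = character(), n_members = integer(),
                      calls = character(), consistent = logical()))
  }
  rows <- lapply(names(grp), function(g) {
    idx <- match(grp[[g]], calls$sample_id)
    if (any(is.na(idx))) stop("replicate member(s) missing from ploidy calls")
    cl <- as.character(calls$call[idx])
    known <- cl[cl != "unknown"]
    data.frame(replicate_group = g, n_members = length(cl),
               calls = paste(cl, collapse = ","),
               consistent = length(unique(known)) <= 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$replicate_group), , drop = FALSE]
}
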