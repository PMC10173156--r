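#' Gower distance between phenotyped accessions
#'
#' Range-normalized mean absolute difference over the traits non-missing in
#' both accessions: \eqn{d_{ij} = \mathrm{mean}_t |x_{it} - x_{jt}| / R_t},
#' with each trait range \eqn{R_t} computed over the whole table so that
#' distances are comparable across sub-collections. All three tuber traits
#' are numeric, so this is the numeric special case of Gower's coefficient
#' (computed via `cluster::daisy`). Zero-range traits are dropped with a
#' warning; a pair sharing no non-missing trait is an error.
#'
#' @param pheno a [phenotype_table()] data.frame.
#' @param traits trait columns to use.
#' @return a `dist_matrix` with `metric = "Gower"`, entries in `[0, 1]`.
#' @export
gower_distance <- function(pheno, traits = c("ATW", "NTP", "TTY")) {
  pheno <- phenotype_table(pheno, traits)
  if (nrow(pheno) < 2L) stop("need >= 2 accessions")
  x <- pheno[, traits, drop = FALSE]
  rng <- vapply(x, function(v) diff(range(v, na.rm = TRUE)), 1)
  if (any(rng == 0)) {
    warning("dropping zero-range trait(s): ",
            paste(traits[rng == 0], collapse = ", "))
    x <- x[, rng > 0, drop = FALSE]
    if (ncol(x) == 0L) stop("no trait with nonzero range")
  }
  rownames(x) <- pheno$accession_id
  d <- as.matrix(cluster::daisy(x, metric = "gower"))
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("accessions '%s' and '%s' share no non-missing trait",
                 rownames(d)[bad[1L]], rownames(d)[bad[2L]]), call. = FALSE)
  }
  dist_matrix(d, metric = "Gower")
}

#' Summary statistics of traits per collection
#'
#' Central-tendency and dispersion statistics for each trait within each
#' collection (entry set): n with data, mean, median, sample sd, CV (%),
#' min and max. Entry sets are intersected with the phenotyped accessions.
#'
#' @param pheno a [phenotype_table()] data.frame.
#' @param collections named list of accession-id vectors (e.g. the whole
#'   collection and each core).
#' @param traits trait columns.
#' @return data.frame: `collection`, `trait`, `n`, `mean`, `median`, `sd`,
#'   `cv_pct`, `min`, `max`.
#' @export
summary_stats <- function(pheno, collections,
                          traits = c("ATW", "NTP", "TTY")) {
  pheno <- phenotype_table(pheno, traits)
  rows <- list()
  for (nm in names(collections)) {
    ids <- intersect(collections[[nm]], pheno$accession_id)
    if (length(ids) == 0L) {
      stop("collection '", nm, "' has no phenotyped accessions")
    }
    sub <- pheno[match(ids, pheno$accession_id), , drop = FALSE]
    for (tr in traits) {
      v <- sub[[tr]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      mu <- mean(v); s <- stats::sd(v)
      rows[[length(rows) + 1L]] <- data.frame(
        collection = nm, trait = tr, n = length(v), mean = mu,
        median = stats::median(v),
        sd = if (length(v) > 1L) s else 0,
        cv_pct = if (mu != 0 && length(v) > 1L) 100 * s / mu else 0,
        min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate genotype-selected cores on phenotypic distances
#'
#' Computes A-NE / E-NE / E-E on a Gower phenotype distance matrix using
#' the entries of genotype-selected core collections, after intersecting
#' each selection with the phenotyped accessions. Selections with fewer
#' than two phenotyped entries are skipped with a warning.
#'
#' @param gower_dist a `dist_matrix` from [gower_distance()].
#' @param selections named list of `core_selection` objects or id vectors.
#' @return data.frame like [evaluate_cores()], plus `n_phenotyped`.
#' @export
evaluate_cores_pheno <- function(gower_dist, selections) {
  d <- as.matrix(gower_dist)
  ids <- rownames(d)
  kept <- list()
  for (nm in names(selections)) {
    sel <- selections[[nm]]
    entries <- if (inherits(sel, "core_selection")) sel$entry_ids else sel
    frac <- if (inherits(sel, "core_selection")) sel$fraction else NA_real_
    ph <- intersect(entries, ids)
    if (length(ph) < 2L) {
      warning("selection '", nm, "' has < 2 phenotyped entries; skipped")
      next
    }
    kept[[nm]] <- list(entries = ph, fraction = frac)
  }
  rows <- lapply(names(kept), function(nm) {
    e <- kept[[nm]]$entries
    data.frame(selection = nm, fraction = kept[[nm]]$fraction,
               n_phenotyped = length(e),
               A_NE = ane_objective(d, e),
               E_NE = ene_objective(d, e),
               E_E = ee_objective(d, e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
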