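#' Observed heterozygosity per sample
#'
#' For tetraploid-scale dosage calls a sample is heterozygous at a marker
#' when its dosage is 1, 2 or 3 (at least one copy of each allele). Ho is
#' the fraction of heterozygous calls among a sample's non-missing calls.
#'
#' @param m a [dosage_matrix()].
#' @param groups optional grouping vector (length = samples) for per-group
#'   mean +/- sd summaries.
#' @return list of class `ho_result`: `per_sample` named numeric vector,
#'   and if `groups` was given, `by_group` data.frame
#'   (`group`, `n`, `mean`, `sd`).
#' @export
observed_heterozygosity <- function(m, groups = NULL) {
  assert_dosage(m)
  n <- rowSums(!is.na(m))
  if (any(n == 0L)) {
    stop("Ho undefined for all-missing sample(s): ",
         paste(rownames(m)[n == 0L], collapse = ", "), call. = FALSE)
  }
  ho <- rowSums(m >= 1L & m <= 3L, na.rm = TRUE) / n
  ho <- stats::setNames(as.numeric(ho), rownames(m))
  out <- list(per_sample = ho)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(m))
    sp <- split(ho, groups)
    out$by_group <- data.frame(
      group = names(sp),
      n = vapply(sp, length, 1L),
      mean = vapply(sp, mean, 1),
      sd = vapply(sp, stats::sd, 1),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  class(out) <- "ho_result"
  out
}

#' @export
print.ho_result <- function(x, ...) {
  cat(sprintf("Ho: mean %.3f (sd %.3f) over %d samples\n",
              mean(x$per_sample), stats::sd(x$per_sample),
              length(x$per_sample)))
  if (!is.null(x$by_group)) print(x$by_group, row.names = FALSE)
  invisible(x)
}

#' Modified Rogers distance matrix
#'
#' Pairwise Modified Rogers distances between samples from tetraploid-scale
#' dosages. Each call is converted to a within-individual allele frequency
#' p = d/4 and, for samples i and j,
#' \deqn{MRD(i,j) = \sqrt{ \sum_l (p_{il} - p_{jl})^2 / L_{ij} }}
#' where the sum runs over the \eqn{L_{ij}} markers non-missing in both
#' samples (pairwise-complete, per-pair normalization). For biallelic loci
#' this equals the classical \eqn{(1/\sqrt{2L}) \sqrt{\sum_l \sum_a
#' \Delta p_a^2}} form, is bounded in `[0, 1]`, and is Euclidean when there
#' is no missing data.
#'
#' @param m a [dosage_matrix()] with >= 2 samples.
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal,
#'   dimnames = sample ids, attribute `metric = "MRD"`.
#' @export
mrd_matrix <- function(m) {
  assert_dosage(m)
  if (nrow(m) < 2L) stop("need >= 2 samples")
  x <- unclass(m) / 4
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0)
  mode(obs) <- "numeric"
  L <- obs %*% t(obs)                       # shared non-missing markers
  if (any(L[upper.tri(L)] == 0)) {
    bad <- which(L == 0 & upper.tri(L), arr.ind = TRUE)[1L, ]
    stop(sprintf("samples '%s' and '%s' share no non-missing marker",
                 rownames(m)[bad[1L]], rownames(m)[bad[2L]]), call. = FALSE)
  }
  sq <- (x0^2) %*% t(obs)                   # sum over shared l of x_i^2
  d2 <- (sq + t(sq) - 2 * x0 %*% t(x0)) / L
  d2[d2 < 0] <- 0                           # numeric guard
  d <- sqrt(d2)
  diag(d) <- 0
  dist_matrix(d, metric = "MRD")
}

#' Construct a labelled symmetric distance matrix
#'
#' @param d symmetric numeric matrix, zero diagonal, dimnames = ids.
#' @param metric metric name, e.g. `"MRD"` or `"Gower"`.
#' @return matrix of class `dist_matrix` with a `metric` attribute.
#' @export
dist_matrix <- function(d, metric = "custom") {
  d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("S%03d", seq_len(nrow(d)))
  }
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  attr(d, "metric") <- metric
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Write / read a square distance matrix as TSV
#' @param d a `dist_matrix`.
#' @param path file path.
#' @return `path` (write) or a `dist_matrix` (read).
#' @export
write_dist_tsv <- function(d, path) {
  df <- data.frame(id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @param metric metric label to attach on read.
#' @export
read_dist_tsv <- function(path, metric = "custom") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  dist_matrix(m, metric = metric)
}

group_allele_freq <- function(m, groups) {
  sp <- split(seq_len(nrow(m)), groups)
  out <- vapply(sp, function(idx) {
    sub <- m[idx, , drop = FALSE]
    n <- colSums(!is.na(sub))
    ifelse(n > 0, colSums(sub, na.rm = TRUE) / (4 * n), NA_real_)
  }, numeric(ncol(m)))
  matrix(out, nrow = ncol(m), ncol = length(sp),
         dimnames = list(colnames(m), names(sp)))
}

#' Pairwise FST between groups (Nei-style)
#'
#' For each pair of groups, per-locus gene diversities are computed from the
#' dosage-derived allele frequencies: \eqn{H_S} is the mean within-group
#' \eqn{2p(1-p)} and \eqn{H_T = 2\bar p(1-\bar p)} with \eqn{\bar p} the
#' unweighted mean of the two group frequencies. FST is the mean over loci
#' with \eqn{H_T > 0} of \eqn{(H_T - H_S)/H_T}. Significance is assessed by
#' permuting group labels.
#'
#' @param m a [dosage_matrix()].
#' @param groups grouping vector (>= 2 groups, each >= 2 samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame of class `fst_result`: `group1`, `group2`, `fst`,
#'   `p_value`, `n_perm`.
#' @export
nei_fst <- function(m, groups, n_perm = 999, seed = 1) {
  assert_dosage(m)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 samples each")
  }
  fst_pair <- function(calls, lab, g1, g2) {
    idx <- lab %in% c(g1, g2)
    pf <- group_allele_freq(calls[idx, , drop = FALSE], lab[idx])
    p1 <- pf[, 1L]; p2 <- pf[, 2L]
    ok <- !is.na(p1) & !is.na(p2)
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    use <- ok & ht > 0
    if (!any(use)) stop("all loci monomorphic across the two groups; FST undefined")
    mean((ht[use] - hs[use]) / ht[use])
  }
  gs <- names(tab)
  pairs <- utils::combn(gs, 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    idx <- which(groups %in% c(g1, g2))
    obs <- fst_pair(m, groups, g1, g2)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      lab_perm <- groups
      lab_perm[idx] <- sample(groups[idx])
      f <- tryCatch(fst_pair(m, lab_perm, g1, g2), error = function(e) NA_real_)
      if (!is.na(f) && f >= obs) exceed <- exceed + 1L
    }
    data.frame(group1 = g1, group2 = g2, fst = obs,
               p_value = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fst_result", class(out))
  out
}

amova_phi <- function(d2, groups) {
  # distance-based AMOVA on squared distances; one grouping level
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  sp <- split(seq_len(n), groups)
  ss_within <- sum(vapply(sp, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 1))
  ss_among <- ss_total - ss_within
  k <- length(sp)
  ng <- vapply(sp, length, 1L)
  df_among <- k - 1L
  df_within <- n - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n - sum(ng^2) / n) / df_among
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  truncated <- sigma_among < 0
  if (truncated) sigma_among <- 0
  phi <- sigma_among / (sigma_among + sigma_within)
  list(phi = phi, ss_among = ss_among, ss_within = ss_within,
       ss_total = ss_total, df_among = df_among, df_within = df_within,
       sigma_among = sigma_among, sigma_within = sigma_within,
       truncated = truncated)
}

#' Distance-based AMOVA with permutation test
#'
#' One-level analysis of molecular variance on a distance matrix. Total and
#' within-group sums of squares are computed from squared distances
#' (\eqn{SS = \sum_{i<j} d_{ij}^2 / n}), the among-group SS by difference;
#' variance components follow the standard AMOVA mean-square equations with
#' coefficient \eqn{n_0 = (N - \sum n_g^2/N)/(K-1)}. Phi is the among-group
#' fraction of total variance, tested by permuting group labels (p-value
#' with the +1 correction, so the smallest attainable p is
#' `1/(n_perm + 1)`). Negative among-group components are truncated at zero
#' and flagged.
#'
#' @param d a `dist_matrix` (see [mrd_matrix()], [gower_distance()]).
#' @param groups grouping vector (>= 2 groups, each >= 2 samples).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list of class `amova_result`: `phi`, `p_value`, `n_perm`,
#'   `variance_components` (among/within), `percent` (among/within, summing
#'   to 100), `ss` table, `truncated`.
#' @export
amova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups")
  if (any(tab < 2L)) stop("every group needs >= 2 samples")
  d2 <- d^2
  obs <- amova_phi(d2, groups)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (amova_phi(d2, sample(groups))$phi >= obs$phi) exceed <- exceed + 1L
  }
  total_var <- obs$sigma_among + obs$sigma_within
  pct_among <- if (total_var > 0) 100 * obs$sigma_among / total_var else 0
  out <- list(
    phi = obs$phi,
    p_value = (exceed + 1) / (n_perm + 1),
    n_perm = n_perm,
    variance_components = c(among = obs$sigma_among,
                            within = obs$sigma_within),
    percent = c(among = pct_among, within = 100 - pct_among),
    ss = data.frame(source = c("among", "within", "total"),
                    ss = c(obs$ss_among, obs$ss_within, obs$ss_total),
                    df = c(obs$df_among, obs$df_within,
                           obs$df_among + obs$df_within)),
    truncated = obs$truncated)
  class(out) <- "amova_result"
  out
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: Phi = %.3f, p = %.4g (%d permutations)\n",
              x$phi, x$p_value, x$n_perm))
  cat(sprintf("  variation among groups: %.2f%%, within: %.2f%%\n",
              x$percent["among"], x$percent["within"]))
  if (x$truncated) cat("  note: negative among-group component truncated at 0\n")
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
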