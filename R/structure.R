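#' PCA of a dosage matrix
#'
#' Missing calls are imputed with the marker mean, markers are centered
#' (no variance scaling — all dosages share the 0-4 scale), and scores are
#' obtained by singular value decomposition. Percent variance explained per
#' component is reported relative to the total variance of the centered,
#' imputed matrix.
#'
#' @param m a [dosage_matrix()] (ideally filtered; see [filter_dosage()]).
#' @param n_components number of components to return (default 10, capped
#'   at the matrix rank).
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `percent_variance`, `n_components`, `degenerate` (TRUE when the matrix
#'   has zero total variance, in which case scores are all zero and percent
#'   variance is `NA`).
#' @export
dosage_pca <- function(m, n_components = 10) {
  assert_dosage(m)
  if (nrow(m) < 2L) stop("PCA needs >= 2 samples")
  x <- unclass(m) * 1.0
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2L, colMeans(x))
  total_var <- sum(x^2)
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  if (total_var <= .Machine$double.eps * length(x)) {
    scores <- matrix(0, nrow(x), k,
                     dimnames = list(rownames(m), paste0("PC", seq_len(k))))
    out <- list(scores = scores, percent_variance = rep(NA_real_, k),
                n_components = k, degenerate = TRUE)
    class(out) <- "pca_result"
    return(out)
  }
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(k)))
  pct <- 100 * sv$d[seq_len(k)]^2 / total_var
  out <- list(scores = scores, percent_variance = pct, n_components = k,
              degenerate = FALSE)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components\n", nrow(x$scores),
              x$n_components))
  if (!x$degenerate) {
    cat("  percent variance:",
        paste(sprintf("%.2f", utils::head(x$percent_variance, 5)),
              collapse = ", "), "...\n")
  } else cat("  degenerate input (zero variance)\n")
  invisible(x)
}

#' Seeded k-means group assignment
#'
#' Best-of-`nstart` k-means on ordination scores; deterministic for a fixed
#' seed.
#'
#' @param scores numeric matrix (samples x components).
#' @param K number of groups.
#' @param seed RNG seed.
#' @param nstart random restarts (default 10).
#' @return named character vector of labels `"G1"`... per sample.
#' @export
kmeans_assign <- function(scores, K, seed = 1, nstart = 10) {
  scores <- as.matrix(scores)
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(scores)) stop("K cannot exceed the number of samples")
  if (K == nrow(scores)) {
    lab <- paste0("G", seq_len(nrow(scores)))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(scores, centers = K, nstart = nstart,
                        iter.max = 100)
    lab <- paste0("G", km$cluster)
  }
  stats::setNames(lab, rownames(scores))
}

calinski_harabasz <- function(scores, cluster) {
  n <- nrow(scores)
  k <- length(unique(cluster))
  grand <- colMeans(scores)
  w <- 0; b <- 0
  for (g in unique(cluster)) {
    sub <- scores[cluster == g, , drop = FALSE]
    cen <- colMeans(sub)
    w <- w + sum(sweep(sub, 2L, cen)^2)
    b <- b + nrow(sub) * sum((cen - grand)^2)
  }
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Choose the number of genetic groups from ordination scores
#'
#' For each candidate K in `k_min:k_max`, a seeded best-of-`nstart` k-means
#' is fitted on the first `n_use` components and two clustering indices are
#' evaluated: mean silhouette width and the Calinski-Harabasz index. The
#' chosen K is the majority vote of the indices' argmax; on disagreement
#' the smaller K wins and the result is flagged low-confidence.
#'
#' @param scores ordination scores (samples x components), e.g. from
#'   [dosage_pca()].
#' @param k_min,k_max candidate range (defaults 2..10); `k_max` must be
#'   below the number of samples.
#' @param seed RNG seed.
#' @param n_use number of leading components used (default 3).
#' @param nstart k-means restarts per candidate.
#' @return list of class `group_assignment`: `K`, `labels` (named vector),
#'   `index_scores` data.frame (`K`, `silhouette`, `calinski_harabasz`),
#'   `low_confidence`.
#' @export
choose_k <- function(scores, k_min = 2, k_max = 10, seed = 1, n_use = 3,
                     nstart = 10) {
  scores <- as.matrix(scores)
  if (k_max >= nrow(scores)) stop("k_max must be < number of samples")
  if (k_min < 2L) stop("k_min must be >= 2")
  use <- scores[, seq_len(min(n_use, ncol(scores))), drop = FALSE]
  dd <- stats::dist(use)
  ks <- k_min:k_max
  labs <- list()
  sil <- ch <- numeric(length(ks))
  for (i in seq_along(ks)) {
    lab <- kmeans_assign(use, ks[i], seed = seed + i, nstart = nstart)
    labs[[i]] <- lab
    cl <- as.integer(factor(lab))
    sil[i] <- mean(cluster::silhouette(cl, dd)[, "sil_width"])
    ch[i] <- calinski_harabasz(use, cl)
  }
  best_sil <- ks[which.max(sil)]
  best_ch <- ks[which.max(ch)]
  if (best_sil == best_ch) {
    K <- best_sil; low_conf <- FALSE
  } else {
    K <- min(best_sil, best_ch); low_conf <- TRUE
  }
  out <- list(K = K, labels = labs[[match(K, ks)]],
              index_scores = data.frame(K = ks, silhouette = sil,
                                        calinski_harabasz = ch),
              low_confidence = low_conf)
  class(out) <- "group_assignment"
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("chosen K = %d%s\n", x$K,
              if (x$low_confidence) " (low confidence: indices disagree)" else ""))
  print(x$index_scores, row.names = FALSE)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
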