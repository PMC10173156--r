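# shared fixtures and independent oracles

# random dosage matrix with optional missingness
random_dosage <- function(n, L, missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    calls <- matrix(sample(0:4, n * L, replace = TRUE), n, L)
    if (missing_rate > 0) {
      calls[runif(n * L) < missing_rate] <- NA_integer_
    }
    # ensure no all-missing rows/cols
    calls[, colSums(!is.na(calls)) == 0] <- 0L
    calls[rowSums(!is.na(calls)) == 0, 1L] <- 0L
    dosage_matrix(calls)
  })
}

# random symmetric distance matrix (not necessarily metric)
random_dist <- function(n, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(runif(n * n), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(sprintf("A%02d", 1:n), sprintf("A%02d", 1:n))
    dist_matrix(d)
  })
}

# brute-force MRD oracle: explicit double loop over sample pairs
mrd_brute <- function(m) {
  x <- unclass(m) / 4
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    d[i, j] <- sqrt(sum((x[i, ok] - x[j, ok])^2) / sum(ok))
  }
  d
}

# exhaustive A-NE optimum over all k-subsets
exhaustive_ane <- function(d, k) {
  d <- as.matrix(d)
  subsets <- utils::combn(nrow(d), k)
  vals <- apply(subsets, 2L, function(s) {
    mean(apply(d[, s, drop = FALSE], 1L, min))
  })
  list(objective = min(vals),
       entries = rownames(d)[subsets[, which.min(vals)]])
}
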