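test_that("observed heterozygosity counts dosages 1-3", {
  expect_equal(unname(observed_heterozygosity(
    dosage_matrix(rbind(a = c(2, 2, 2))))$per_sample), 1)
  expect_equal(unname(observed_heterozygosity(
    dosage_matrix(rbind(a = c(0, 4, 0, 4))))$per_sample), 0)
  expect_equal(unname(observed_heterozygosity(
    dosage_matrix(rbind(a = c(0, 1, 2, 3, 4, 4))))$per_sample), 0.5)
  m <- dosage_matrix(rbind(a = c(2, 2), b = c(0, 4), c = c(2, 0)))
  ho <- observed_heterozygosity(m, groups = c("x", "x", "y"))
  expect_equal(ho$by_group$mean, c(0.5, 0.5))
  expect_equal(ho$by_group$n, c(2L, 1L))
})

test_that("MRD matches hand values and the brute-force oracle", {
  m <- dosage_matrix(rbind(i = c(0, 4), j = c(4, 4)))
  expect_equal(mrd_matrix(m)["i", "j"], sqrt(1 / 2), tolerance = 1e-12)
  same <- dosage_matrix(rbind(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(mrd_matrix(same)["a", "b"], 0)
  extremes <- dosage_matrix(rbind(a = c(0, 0), b = c(4, 4)))
  expect_equal(mrd_matrix(extremes)["a", "b"], 1)
  for (seed in 1:4) {
    m <- random_dosage(10, 20, missing_rate = 0.1, seed = seed)
    expect_equal(unclass(mrd_matrix(m))[, ], mrd_brute(m),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("MRD errors when a pair shares no markers", {
  calls <- rbind(a = c(0L, NA), b = c(NA, 4L), c = c(2L, 2L))
  expect_error(mrd_matrix(dosage_matrix(calls)), "share no non-missing")
})

test_that("dist_matrix enforces symmetry and zero diagonal", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(dist_matrix(bad), "symmetric")
  bad2 <- diag(2) * 0.5
  expect_error(dist_matrix(bad2), "diagonal")
  d <- random_dist(5)
  expect_true(all(unclass(d) >= 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dist_tsv(d, path)
  expect_equal(unclass(read_dist_tsv(path))[, ], unclass(d)[, ],
               tolerance = 1e-9)
})

test_that("nei_fst matches hand values and the simulator's truth", {
  # identical group frequencies -> FST 0
  m <- dosage_matrix(rbind(a = c(0, 4), b = c(4, 0), c = c(0, 4),
                           d = c(4, 0)))
  res <- nei_fst(m, c("g1", "g1", "g2", "g2"), n_perm = 9)
  expect_equal(res$fst, 0)
  # one locus, group freqs 0.2 vs 0.8 -> (0.5 - 0.32) / 0.5
  m2 <- dosage_matrix(cbind(m1 = c(4L, 0L, 0L, 0L, 0L,
                                   4L, 4L, 4L, 4L, 0L)))
  res2 <- nei_fst(m2, rep(c("g1", "g2"), each = 5), n_perm = 9)
  expect_equal(res2$fst, 0.36, tolerance = 1e-12)
  # diverged groups: estimate close to FST from the true group frequencies
  cfg <- synthetic_panel_config(n_groups = 2, group_sizes = c(60, 60),
                                group_ploidy = c(4, 4), n_markers = 400,
                                divergence_f = 0.3, miscall_rate = 0,
                                missing_rate = 0, n_replicate_pairs = 0,
                                seed = 42)
  panel <- simulate_panel(cfg)
  est <- nei_fst(panel$matrix, panel$truth$group, n_perm = 49)$fst
  pf <- panel$truth$group_freq
  hs <- (2 * pf[, 1] * (1 - pf[, 1]) + 2 * pf[, 2] * (1 - pf[, 2])) / 2
  pbar <- rowMeans(pf)
  ht <- 2 * pbar * (1 - pbar)
  oracle <- mean(((ht - hs) / ht)[ht > 0])
  expect_equal(est, oracle, tolerance = 0.05)
  expect_lt(nei_fst(panel$matrix, panel$truth$group, n_perm = 99,
                    seed = 2)$p_value, 0.05)
})

test_that("nei_fst rejects degenerate groupings", {
  m <- dosage_matrix(rbind(a = c(0, 4), b = c(4, 0), c = c(0, 4)))
  expect_error(nei_fst(m, c("g1", "g1", "g2")), ">= 2 samples")
  mono <- dosage_matrix(matrix(4L, 4, 3))
  expect_error(nei_fst(mono, rep(c("a", "b"), each = 2), n_perm = 9),
               "monomorphic|undefined")
})

test_that("AMOVA handles perfect separation and sums percentages to 100", {
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(letters[1:6], letters[1:6])
  res <- amova(dist_matrix(d), rep(c("g1", "g2"), each = 3), n_perm = 99)
  expect_equal(res$phi, 1)
  expect_equal(unname(res$percent["among"]), 100)
  expect_equal(sum(res$percent), 100)
  expect_equal(res$p_value, min(res$p_value, 1))
  expect_gte(res$p_value, 1 / 100)
})

test_that("AMOVA sums of squares agree with vegan::adonis2", {
  d <- random_dist(12, seed = 9)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- amova(d, g, n_perm = 9)
  adn <- vegan::adonis2(stats::as.dist(unclass(d)) ~ g,
                        data = data.frame(g = g), permutations = 2)
  expect_equal(res$ss$ss[res$ss$source == "among"], adn$SumOfSqs[1],
               tolerance = 1e-10)
  expect_equal(res$ss$ss[res$ss$source == "within"], adn$SumOfSqs[2],
               tolerance = 1e-10)
  # variance components recomputed independently from the oracle SS
  n <- 12; k <- 3
  ms_a <- adn$SumOfSqs[1] / (k - 1); ms_w <- adn$SumOfSqs[2] / (n - k)
  n0 <- (n - sum(table(g)^2) / n) / (k - 1)
  sigma_a <- max(0, (ms_a - ms_w) / n0)
  expect_equal(res$phi, sigma_a / (sigma_a + ms_w), tolerance = 1e-10)
})

test_that("AMOVA toy table matches a hand computation", {
  # 4 samples, 2 groups; squared distances chosen for easy arithmetic
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 1
  d["a", "c"] <- d["c", "a"] <- 2
  d["a", "d"] <- d["d", "a"] <- 2
  d["b", "c"] <- d["c", "b"] <- 2
  d["b", "d"] <- d["d", "b"] <- 2
  # SS_total = (1+1+4*4)/4 = 4.5 ; SS_within = 1/2 + 1/2 = 1
  # SS_among = 3.5 ; MS_a = 3.5, MS_w = 0.5, n0 = 2
  # sigma_a = 1.5, sigma_w = 0.5, Phi = 0.75
  res <- amova(dist_matrix(d), c("g1", "g1", "g2", "g2"), n_perm = 9)
  expect_equal(res$ss$ss, c(3.5, 1, 4.5))
  expect_equal(res$phi, 0.75)
})

test_that("permutation p-values are seed-reproducible and order-invariant", {
  d <- random_dist(16, seed = 4)
  g <- rep(c("x", "y"), each = 8)
  r1 <- amova(d, g, n_perm = 99, seed = 11)
  r2 <- amova(d, g, n_perm = 99, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  perm <- withr::with_seed(2, sample(16))
  r3 <- amova(d[perm, perm], g[perm], n_perm = 99, seed = 11)
  expect_equal(r3$phi, r1$phi, tolerance = 1e-12)
  expect_error(amova(d, c("x", rep("y", 15))), ">= 2 samples")
})

test_that("tetraploid mean Ho approaches the closed form 1 - p^4 - q^4", {
  cfg <- synthetic_panel_config(n_groups = 1, group_sizes = 40,
                                group_ploidy = 4, n_markers = 1500,
                                divergence_f = 0, miscall_rate = 0,
                                missing_rate = 0, n_replicate_pairs = 0,
                                seed = 8)
  panel <- simulate_panel(cfg)
  marker_ho <- colMeans(unclass(panel$matrix) >= 1 &
                          unclass(panel$matrix) <= 3)
  expected <- integrate(function(p) (1 - p^4 - (1 - p)^4) / 0.9,
                        0.05, 0.95)$value
  se <- sd(marker_ho) / sqrt(length(marker_ho))
  expect_lt(abs(mean(marker_ho) - expected), 3 * se + 1e-3)
})
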