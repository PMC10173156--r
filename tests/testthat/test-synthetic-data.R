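test_that("config validation rejects impossible panels", {
  expect_error(synthetic_panel_config(n_groups = 2, group_sizes = 10),
               "group_sizes")
  expect_error(synthetic_panel_config(group_ploidy = c(2, 5)),
               "group_ploidy")
  expect_error(synthetic_panel_config(miscall_rate = 1.2), "rates")
  expect_error(synthetic_panel_config(n_groups = 1, group_sizes = 2,
                                      group_ploidy = 4,
                                      n_replicate_pairs = 5),
               "replicate")
})

test_that("identical seeds give byte-identical panels", {
  cfg <- synthetic_panel_config(seed = 123, n_markers = 100,
                                group_sizes = c(10, 15))
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(unclass(p1$matrix), unclass(p2$matrix))
  expect_identical(p1$truth$group_freq, p2$truth$group_freq)
  p3 <- simulate_panel(synthetic_panel_config(seed = 124, n_markers = 100,
                                              group_sizes = c(10, 15)))
  expect_false(identical(unclass(p1$matrix), unclass(p3$matrix)))
})

test_that("error-free diploids emit only dosages 0, 2, 4", {
  cfg <- synthetic_panel_config(n_groups = 1, group_sizes = 30,
                                group_ploidy = 2, n_markers = 200,
                                miscall_rate = 0, missing_rate = 0,
                                n_replicate_pairs = 0, seed = 5)
  panel <- simulate_panel(cfg)
  expect_true(all(unclass(panel$matrix) %in% c(0L, 2L, 4L)))
  expect_true(all(simplex_triplex_freq(panel$matrix) == 0))
  ho <- observed_heterozygosity(panel$matrix)
  # diploid heterozygotes appear only as dosage 2
  het <- unclass(panel$matrix) == 2L
  expect_equal(ho$per_sample, rowMeans(het))
})

test_that("diploid mean Ho matches the integrated closed form", {
  cfg <- synthetic_panel_config(n_groups = 1, group_sizes = 40,
                                group_ploidy = 2, n_markers = 1500,
                                divergence_f = 0, miscall_rate = 0,
                                missing_rate = 0, n_replicate_pairs = 0,
                                seed = 17)
  panel <- simulate_panel(cfg)
  marker_ho <- colMeans(unclass(panel$matrix) == 2L)
  expected <- integrate(function(p) 2 * p * (1 - p) / 0.9,
                        0.05, 0.95)$value
  se <- sd(marker_ho) / sqrt(length(marker_ho))
  expect_lt(abs(mean(marker_ho) - expected), 3 * se + 1e-3)
})

test_that("missingness, miscalls, and replicates are applied as configured", {
  cfg <- synthetic_panel_config(n_groups = 1, group_sizes = 50,
                                group_ploidy = 4, n_markers = 400,
                                miscall_rate = 0, missing_rate = 0.1,
                                n_replicate_pairs = 4, seed = 2)
  panel <- simulate_panel(cfg)
  expect_equal(nrow(panel$matrix), 54)
  expect_equal(mean(is.na(panel$matrix)), 0.1, tolerance = 0.02)
  reps <- panel$metadata[!is.na(panel$metadata$replicate_group), ]
  expect_equal(nrow(reps), 8)   # 4 originals + 4 duplicates
  grp <- split(reps$sample_id, reps$replicate_group)
  expect_true(all(lengths(grp) == 2))
  # replicates share the underlying genotype: same group and ploidy
  for (g in grp) {
    expect_equal(panel$truth$group[[g[1]]], panel$truth$group[[g[2]]])
  }
})

test_that("triploid dosages land on the mapped classes", {
  cfg <- synthetic_panel_config(n_groups = 1, group_sizes = 20,
                                group_ploidy = 3, n_markers = 300,
                                miscall_rate = 0, missing_rate = 0,
                                n_replicate_pairs = 0, seed = 3)
  panel <- simulate_panel(cfg)
  expect_true(all(unclass(panel$matrix) %in% c(0L, 1L, 3L, 4L)))
  st <- simplex_triplex_freq(panel$matrix)
  expect_true(all(st > 0.15))   # triploids live in/above the grey area
})

test_that("reference panel carries exact chromosome and noisy chloroplast counts", {
  cfg <- synthetic_panel_config(seed = 11, n_markers = 50,
                                group_sizes = c(200, 200),
                                n_replicate_pairs = 0)
  panel <- simulate_panel(cfg)
  meta <- simulate_reference_panel(panel, seed = 11)
  pl <- panel$truth$ploidy[meta$sample_id]
  expect_true(all(meta$chromosome_count == 12 * pl))
  dip <- meta$chloroplast_count[pl == 2]
  tet <- meta$chloroplast_count[pl == 4]
  expect_lt(abs(mean(dip) - 7.6), 3 * 0.83 / sqrt(length(dip)))
  expect_lt(abs(mean(tet) - 13.2), 3 * 1.06 / sqrt(length(tet)))
  sub <- simulate_reference_panel(panel, n_reference = 50, seed = 1)
  expect_equal(sum(!is.na(sub$chromosome_count)), 50)
})

test_that("simulated phenotypes are group-structured and clamped", {
  truth <- list(group = setNames(rep(c("G1", "G2", "G3"), each = 30),
                                 sprintf("S%03d", 1:90)))
  ph0 <- simulate_phenotypes(truth, traits = list(ATW = c(20, 0.001)),
                             effect_size = 1000, seed = 4)
  grp_sd <- tapply(ph0$ATW, truth$group[ph0$accession_id], sd)
  expect_true(all(grp_sd < 0.01))            # ~zero noise within groups
  expect_equal(length(unique(round(ph0$ATW))), 3)
  ph <- simulate_phenotypes(truth, seed = 4)
  expect_true(all(ph$ATW >= 0 & ph$TTY >= 0, na.rm = TRUE))
  res <- anova_oneway(ph$ATW, truth$group[ph$accession_id])
  expect_lt(res$p, 0.01)
  phm <- simulate_phenotypes(truth, missing_rate = 0.3, seed = 4)
  expect_lt(abs(mean(is.na(phm$ATW)) - 0.3), 0.15)
})

test_that("end-to-end: pipeline recovers the default panel's structure", {
  cfg <- synthetic_panel_config(seed = 7)   # 60 diploid + 120 tetraploid
  panel <- simulate_panel(cfg)
  calls <- ploidy_calls(panel$matrix)
  truth_call <- ifelse(panel$truth$ploidy == 2, "diploid", "tetraploid")
  match_rate <- mean(as.character(calls$call) ==
                       truth_call[calls$sample_id])
  expect_gte(match_rate, 0.99)
  mrd <- mrd_matrix(panel$matrix)
  res <- amova(mrd, panel$truth$group[rownames(mrd)], n_perm = 99,
               seed = 1)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$phi, 0.1)
})
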