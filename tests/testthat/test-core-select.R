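test_that("core_size reproduces the published entry counts", {
  expect_identical(core_size(1291, 0.03), 39L)
  expect_identical(core_size(1291, 0.10), 129L)
  expect_identical(core_size(1291, 0.15), 194L)
  expect_identical(core_size(1291, 0.20), 258L)
  expect_identical(core_size(10, 1.0), 10L)
  expect_identical(core_size(3, 0.01), 1L)
  expect_error(core_size(10, 0), "fraction")
  expect_error(core_size(10, 1.5), "fraction")
})

test_that("objectives match hand evaluations", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.2
  d["a", "c"] <- d["c", "a"] <- 0.4
  d["b", "c"] <- d["c", "b"] <- 0.5
  d <- dist_matrix(d)
  expect_equal(ane_objective(d, c("a", "b", "c")), 0)
  expect_equal(ane_objective(d, "a"), (0 + 0.2 + 0.4) / 3)
  expect_error(ane_objective(d, "z"), "unknown entry")
  expect_equal(ene_objective(d, c("a", "b")), 0.2)
  expect_equal(ee_objective(d, c("a", "b")), 0.2)
  expect_error(ene_objective(d, "a"), "fewer than 2")
  # equilateral triple
  eq <- matrix(0.5, 3, 3) - diag(0.5, 3)
  dimnames(eq) <- list(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(ene_objective(dist_matrix(eq), c("x", "y", "z")), 0.5)
  expect_equal(ee_objective(dist_matrix(eq), c("x", "y", "z")), 0.5)
})

test_that("single-entry A-NE equals the medoid row mean", {
  d <- random_dist(9, seed = 14)
  vals <- vapply(rownames(d), function(id) ane_objective(d, id), 1)
  expect_equal(unname(vals), unname(rowMeans(unclass(d))))
  sel <- select_core(d, 1, seed = 1, n_restarts = 5)
  expect_equal(sel$entry_ids, names(which.min(rowMeans(unclass(d)))))
})

test_that("E-NE and E-E equal brute-force pair enumeration", {
  d <- random_dist(7, seed = 8)
  entries <- rownames(d)[c(1, 3, 4, 6)]
  sub <- unclass(d)[entries, entries]
  ene_brute <- mean(vapply(seq_along(entries), function(i) {
    min(sub[i, -i])
  }, 1))
  pairs <- utils::combn(seq_along(entries), 2)
  ee_brute <- mean(apply(pairs, 2, function(p) sub[p[1], p[2]]))
  expect_equal(ene_objective(d, entries), ene_brute, tolerance = 1e-12)
  expect_equal(ee_objective(d, entries), ee_brute, tolerance = 1e-12)
})

test_that("select_core attains the exhaustive optimum on small instances", {
  for (seed in 1:6) {
    n <- 8
    d <- random_dist(n, seed = 100 + seed)
    sel <- select_core(d, 3, seed = seed)
    ora <- exhaustive_ane(d, 3)
    expect_equal(unname(sel$objective_values["A_NE"]), ora$objective,
                 tolerance = 1e-12)
  }
})

test_that("select_core edge cases and monotone improvement", {
  d <- random_dist(10, seed = 55)
  full <- select_core(d, 10, seed = 1)
  expect_equal(unname(full$objective_values["A_NE"]), 0)
  expect_setequal(full$entry_ids, rownames(d))
  expect_error(select_core(d, 0), "k must be")
  expect_error(select_core(d, 11), "k must be")
  # swaps can only improve on the initializations
  no_swap <- select_core(d, 4, seed = 9, n_restarts = 5,
                         max_no_improve = 0)
  swapped <- select_core(d, 4, seed = 9, n_restarts = 5)
  expect_lte(swapped$objective_values["A_NE"],
             no_swap$objective_values["A_NE"])
  expect_identical(select_core(d, 4, seed = 9)$entry_ids,
                   select_core(d, 4, seed = 9)$entry_ids)
})

test_that("nest_minicore follows the greedy nearest-replacement rule", {
  d <- random_dist(10, seed = 3)
  ids <- rownames(d)
  core <- ids[1:6]
  # identity: mini already inside the core
  res <- nest_minicore(ids[c(2, 4)], core, d)
  expect_identical(attr(res, "entry_ids"), sort(ids[c(2, 4)]))
  expect_true(all(res$distance == 0))
  # forced single replacement: m -> nearest core entry
  d2 <- matrix(0.5, 5, 5) - diag(0.5, 5)
  dimnames(d2) <- list(letters[1:5], letters[1:5])
  d2["e", "b"] <- d2["b", "e"] <- 0.05
  res2 <- nest_minicore(c("a", "e"), c("a", "b", "c", "d"),
                        dist_matrix(d2))
  expect_identical(res2$replacement[res2$mini_entry == "e"], "b")
  # collision: two mini entries nearest to the same core entry
  d3 <- matrix(0.9, 6, 6) - diag(0.9, 6)
  dimnames(d3) <- list(letters[1:6], letters[1:6])
  d3["e", "a"] <- d3["a", "e"] <- 0.10   # e-a nearest overall
  d3["f", "a"] <- d3["a", "f"] <- 0.20   # f also prefers a
  d3["f", "b"] <- d3["b", "f"] <- 0.30   # f's fallback
  res3 <- nest_minicore(c("e", "f"), c("a", "b", "c", "d"),
                        dist_matrix(d3))
  expect_identical(res3$replacement[res3$mini_entry == "e"], "a")
  expect_identical(res3$replacement[res3$mini_entry == "f"], "b")
  expect_error(nest_minicore(letters[1:5], letters[1:3], dist_matrix(d3)),
               "larger")
})

test_that("nest_minicore output is a subset of the core with input size", {
  for (seed in 1:5) {
    d <- random_dist(14, seed = 200 + seed)
    ids <- rownames(d)
    core <- withr::with_seed(seed, sample(ids, 7))
    mini <- withr::with_seed(seed + 50, sample(ids, 4))
    res <- nest_minicore(mini, core, d)
    out <- attr(res, "entry_ids")
    expect_length(out, 4)
    expect_true(all(out %in% core))
    expect_false(anyDuplicated(out) > 0)
  }
})

test_that("evaluate_cores reports the metric table across fractions", {
  d <- random_dist(12, seed = 77)
  sels <- list(
    half = select_core(d, 6, seed = 1, fraction = 0.5),
    full = select_core(d, 12, seed = 1, fraction = 1.0))
  tab <- evaluate_cores(d, sels)
  expect_equal(tab$A_NE[tab$selection == "full"], 0)
  expect_lte(tab$A_NE[tab$selection == "full"],
             tab$A_NE[tab$selection == "half"])
  # optimal A-NE is non-increasing in k (exhaustive, small instance)
  dd <- random_dist(9, seed = 31)
  opt <- vapply(1:9, function(k) exhaustive_ane(dd, k)$objective, 1)
  expect_true(all(diff(opt) <= 1e-12))
})

test_that("A-NE-optimal beats E-E-optimal selections on A-NE", {
  d <- random_dist(9, seed = 62)
  k <- 3
  subsets <- utils::combn(9, k)
  ane_vals <- apply(subsets, 2, function(s)
    ane_objective(d, rownames(d)[s]))
  ee_vals <- apply(subsets, 2, function(s)
    ee_objective(d, rownames(d)[s]))
  best_ee <- subsets[, which.max(ee_vals)]
  expect_lte(min(ane_vals), ane_objective(d, rownames(d)[best_ee]))
})
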