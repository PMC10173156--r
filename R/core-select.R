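#' Number of entries for a core collection fraction
#'
#' Nearest-integer rounding with halves up, never below 1. With 1,291
#' accessions this yields the familiar sizes 39 / 129 / 194 / 258 for
#' fractions 3 / 10 / 15 / 20 percent.
#'
#' @param n collection size.
#' @param fraction target fraction in `(0, 1]`.
#' @return integer number of entries.
#' @export
core_size <- function(n, fraction) {
  if (n < 1L) stop("n must be >= 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  max(1L, as.integer(floor(n * fraction + 0.5)))
}

check_entries <- function(d, entries) {
  ids <- rownames(d)
  bad <- setdiff(entries, ids)
  if (length(bad)) {
    stop("unknown entry id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(entries)) stop("duplicate entry ids")
  entries
}

#' Accession-to-nearest-entry objective
#'
#' Mean, over all accessions in the distance matrix, of the distance to the
#' closest selected entry. Entries represent themselves, contributing 0, so
#' A-NE = 0 exactly when every accession is an entry. Minimizing A-NE gives
#' core collections that uniformly represent the whole collection.
#'
#' @param d a `dist_matrix` over all accessions.
#' @param entries character vector of selected entry ids (non-empty subset
#'   of the accession ids).
#' @return numeric scalar >= 0.
#' @export
ane_objective <- function(d, entries) {
  d <- as.matrix(d)
  entries <- check_entries(d, entries)
  if (length(entries) == 0L) stop("entries must be non-empty")
  mean(apply(d[, entries, drop = FALSE], 1L, min))
}

#' Entry-to-nearest-entry and entry-to-entry objectives
#'
#' E-NE is the mean over entries of the distance to the nearest *other*
#' entry; E-E is the mean distance over all unordered entry pairs. Both
#' need at least two entries.
#'
#' @inheritParams ane_objective
#' @return numeric scalar.
#' @export
ene_objective <- function(d, entries) {
  d <- as.matrix(d)
  entries <- check_entries(d, entries)
  if (length(entries) < 2L) stop("E-NE undefined for fewer than 2 entries")
  sub <- d[entries, entries, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' @rdname ene_objective
#' @export
ee_objective <- function(d, entries) {
  d <- as.matrix(d)
  entries <- check_entries(d, entries)
  if (length(entries) < 2L) stop("E-E undefined for fewer than 2 entries")
  sub <- d[entries, entries, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

# nearest and second-nearest entry distance per accession
nearest_two <- function(d, entry_idx) {
  sub <- d[, entry_idx, drop = FALSE]
  if (length(entry_idx) == 1L) {
    return(list(min1 = sub[, 1L], which1 = rep(entry_idx, nrow(d)),
                min2 = rep(Inf, nrow(d))))
  }
  ord1 <- max.col(-sub, ties.method = "first")
  min1 <- sub[cbind(seq_len(nrow(sub)), ord1)]
  sub2 <- sub
  sub2[cbind(seq_len(nrow(sub)), ord1)] <- Inf
  min2 <- sub2[cbind(seq_len(nrow(sub2)),
                     max.col(-sub2, ties.method = "first"))]
  list(min1 = min1, which1 = entry_idx[ord1], min2 = min2)
}

greedy_start <- function(d, k) {
  n <- nrow(d)
  medoid <- which.min(rowMeans(d))
  sel <- medoid
  cur <- d[, medoid]
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    # A-NE after adding c = mean(pmin(cur, d[, c]))
    gains <- colMeans(pmin(matrix(cur, n, length(cand)),
                           d[, cand, drop = FALSE]))
    best <- cand[which.min(gains)]           # ties: smallest index (asc id)
    sel <- c(sel, best)
    cur <- pmin(cur, d[, best])
  }
  sort(sel)
}

swap_local_search <- function(d, sel, max_swaps = 1000) {
  n <- nrow(d)
  n_swaps <- 0L
  repeat {
    nt <- nearest_two(d, sel)
    obj <- mean(nt$min1)
    best_delta <- 0
    best_move <- NULL
    out_idx <- setdiff(seq_len(n), sel)
    if (length(out_idx) == 0L) break
    for (e in sel) {                         # ascending id scan order
      base <- ifelse(nt$which1 == e, nt$min2, nt$min1)
      vals <- colMeans(pmin(matrix(base, n, length(out_idx)),
                            d[, out_idx, drop = FALSE]))
      j <- which.min(vals)                   # ties: smallest candidate id
      delta <- vals[j] - obj
      if (delta < best_delta - 1e-12) {
        best_delta <- delta
        best_move <- c(e, out_idx[j])
      }
    }
    if (is.null(best_move) || n_swaps >= max_swaps) break
    sel <- sort(c(setdiff(sel, best_move[1L]), best_move[2L]))
    n_swaps <- n_swaps + 1L
  }
  list(sel = sel, objective = mean(nearest_two(d, sel)$min1),
       n_swaps = n_swaps)
}

#' Select a core collection minimizing A-NE
#'
#' Multi-start steepest-improvement swap local search: starting from a
#' greedy (medoid-seeded) solution plus `n_restarts - 1` random subsets,
#' repeatedly replace the single entry/non-entry pair whose swap most
#' reduces [ane_objective()] until no improving swap exists. Scan order and
#' tie-breaking follow ascending accession position, and all randomness is
#' seeded, so runs are reproducible. The best restart is returned.
#'
#' @param d a `dist_matrix` over all accessions.
#' @param k number of entries (`1 <= k <= n`); see [core_size()].
#' @param seed RNG seed for the random restarts.
#' @param n_restarts number of starts including the greedy one (default 20).
#' @param max_no_improve cap on swap iterations per restart (default 1000).
#' @param fraction optional fraction annotation stored in the result.
#' @return list of class `core_selection`: `entry_ids`, `k`, `fraction`,
#'   `objective_values` (named: `A_NE`, `E_NE`, `E_E`; the latter two `NA`
#'   for `k < 2`), and `trace` (per-restart objective, swap counts, seed).
#' @export
select_core <- function(d, k, seed = 1, n_restarts = 20,
                        max_no_improve = 1000, fraction = NA_real_) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1L || k > n) stop("k must be in 1..n")
  ids <- rownames(d)
  if (k == n) {
    sel <- seq_len(n)
    trace <- data.frame(restart = 0L, start = "full", objective = 0,
                        n_swaps = 0L)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    starts <- c(list(greedy_start(d, k)),
                lapply(seq_len(max(0L, n_restarts - 1L)),
                       function(i) sort(sample.int(n, k))))
    runs <- lapply(starts, swap_local_search, d = d,
                   max_swaps = max_no_improve)
    objs <- vapply(runs, `[[`, 1, "objective")
    best <- which.min(objs)
    sel <- runs[[best]]$sel
    trace <- data.frame(
      restart = seq_along(runs),
      start = c("greedy", rep("random", length(runs) - 1L)),
      objective = objs,
      n_swaps = vapply(runs, `[[`, 1L, "n_swaps"))
  }
  entries <- ids[sel]
  obj <- c(A_NE = mean(nearest_two(d, sel)$min1),
           E_NE = if (k >= 2L) ene_objective(d, entries) else NA_real_,
           E_E = if (k >= 2L) ee_objective(d, entries) else NA_real_)
  out <- list(entry_ids = entries, k = k, fraction = fraction,
              objective_values = obj,
              trace = list(restarts = trace, seed = seed,
                           max_no_improve = max_no_improve))
  class(out) <- "core_selection"
  out
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("core selection: %d entries%s, A-NE = %.4f\n", x$k,
              if (!is.na(x$fraction))
                sprintf(" (%.0f%%)", 100 * x$fraction) else "",
              x$objective_values["A_NE"]))
  invisible(x)
}

#' Nest a mini-core inside a core collection
#'
#' Adjusts a mini-core so that every entry belongs to the core: mini
#' entries already in the core are kept; each remaining mini entry is
#' replaced by its nearest unused core entry. Replacements are processed in
#' ascending order of replacement distance (ties by id), so when two mini
#' entries compete for the same core entry the nearer one wins and the
#' other takes its next-nearest unused core entry.
#'
#' @param mini_entries,core_entries entry id vectors, `|mini| <= |core|`.
#' @param d a `dist_matrix` covering all entries.
#' @return data.frame: `mini_entry`, `replacement` (equal to `mini_entry`
#'   when kept), `distance` (0 when kept); attribute `entry_ids` holds the
#'   adjusted mini-core ids (a subset of `core_entries`, same size as the
#'   input mini-core).
#' @export
nest_minicore <- function(mini_entries, core_entries, d) {
  d <- as.matrix(d)
  check_entries(d, mini_entries)
  check_entries(d, core_entries)
  if (length(mini_entries) > length(core_entries)) {
    stop("mini-core cannot be larger than the core")
  }
  kept <- intersect(mini_entries, core_entries)
  todo <- setdiff(mini_entries, core_entries)
  used <- kept
  rows <- data.frame(mini_entry = kept, replacement = kept,
                     distance = rep(0, length(kept)),
                     stringsAsFactors = FALSE)
  # candidate (mini, core) pairs sorted by distance then ids
  while (length(todo) > 0L) {
    avail <- setdiff(core_entries, used)
    sub <- d[todo, avail, drop = FALSE]
    ord <- order(as.vector(sub),
                 rep(todo, times = length(avail)),
                 rep(avail, each = length(todo)))[1L]
    i <- (ord - 1L) %% length(todo) + 1L
    j <- (ord - 1L) %/% length(todo) + 1L
    rows <- rbind(rows, data.frame(mini_entry = todo[i],
                                   replacement = avail[j],
                                   distance = sub[i, j],
                                   stringsAsFactors = FALSE))
    used <- c(used, avail[j])
    todo <- todo[-i]
  }
  rows <- rows[order(rows$mini_entry), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "entry_ids") <- sort(rows$replacement)
  rows
}

#' Evaluate core selections across fractions
#'
#' Computes the three distance-based quality metrics for each selection.
#' For selections that are optimal (or near-optimal) at each size, A-NE is
#' non-increasing in the fraction: the larger the core, the smaller the
#' mean accession-to-nearest-entry distance.
#'
#' @param d a `dist_matrix`.
#' @param selections a named list of `core_selection` objects or entry-id
#'   vectors; names are used as row labels (e.g. fractions).
#' @return data.frame: `selection`, `fraction`, `k`, `A_NE`, `E_NE`, `E_E`.
#' @export
evaluate_cores <- function(d, selections) {
  d <- as.matrix(d)
  rows <- lapply(names(selections), function(nm) {
    sel <- selections[[nm]]
    entries <- if (inherits(sel, "core_selection")) sel$entry_ids else sel
    frac <- if (inherits(sel, "core_selection")) sel$fraction else NA_real_
    k <- length(entries)
    data.frame(selection = nm, fraction = frac, k = k,
               A_NE = ane_objective(d, entries),
               E_NE = if (k >= 2L) ene_objective(d, entries) else NA_real_,
               E_E = if (k >= 2L) ee_objective(d, entries) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
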