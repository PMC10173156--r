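#' Configuration for the synthetic mixed-ploidy panel simulator
#'
#' The simulator emulates the salient features of a clonal genebank panel
#' genotyped on a tetraploid-scale SNP array: K genetic groups diverged
#' from a common ancestral allele-frequency pool under the Balding-Nichols
#' model, groups of fixed ploidy (diploid, triploid or tetraploid), a small
#' neighbouring-cluster dosage miscall rate, random missing calls, and
#' duplicated biological replicates. Defaults describe a two-group panel of
#' 60 diploids and 120 tetraploids at divergence F = 0.25 across 1,000
#' markers, with a 1% miscall rate and 2% missing data.
#'
#' @param n_groups number of genetic groups K.
#' @param group_sizes integer vector of group sizes (length K).
#' @param group_ploidy ploidy per group, each in `c(2, 3, 4)`.
#' @param n_markers number of biallelic markers L.
#' @param ancestral_freq_range range of the uniform ancestral allele
#'   frequency distribution (default `c(0.05, 0.95)`).
#' @param divergence_f Balding-Nichols F per group (scalar recycled);
#'   `F = 0` means group frequencies equal the ancestral ones exactly.
#' @param miscall_rate probability a call shifts by +/-1 (clamped to 0..4).
#' @param missing_rate probability a call is set missing.
#' @param n_replicate_pairs number of samples duplicated as biological
#'   replicates (error and missingness re-applied independently).
#' @param seed RNG seed.
#' @return list of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(n_groups = 2,
                                   group_sizes = c(60, 120),
                                   group_ploidy = c(2, 4),
                                   n_markers = 1000,
                                   ancestral_freq_range = c(0.05, 0.95),
                                   divergence_f = 0.25,
                                   miscall_rate = 0.01,
                                   missing_rate = 0.02,
                                   n_replicate_pairs = 5,
                                   seed = 1) {
  stopifnot(n_groups >= 1, length(group_sizes) == n_groups,
            all(group_sizes >= 1), n_markers >= 1,
            all(group_ploidy %in% c(2, 3, 4)),
            length(group_ploidy) == n_groups)
  divergence_f <- rep_len(divergence_f, n_groups)
  rates <- c(divergence_f, miscall_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (n_replicate_pairs > sum(group_sizes)) {
    stop("more replicate pairs than samples")
  }
  cfg <- list(n_groups = n_groups, group_sizes = group_sizes,
              group_ploidy = group_ploidy, n_markers = n_markers,
              ancestral_freq_range = ancestral_freq_range,
              divergence_f = divergence_f, miscall_rate = miscall_rate,
              missing_rate = missing_rate,
              n_replicate_pairs = n_replicate_pairs, seed = seed)
  class(cfg) <- "synthetic_panel_config"
  cfg
}

# dosage for one group x marker block; p is the marker's group frequency
draw_dosage <- function(n, p, ploidy) {
  g <- stats::rbinom(n, ploidy, p)
  switch(as.character(ploidy),
         "2" = 2L * g,                       # diploid calls land on {0,2,4}
         "3" = c(0L, 1L, 3L, 4L)[g + 1L],    # round(4g/3)
         "4" = g)
}

apply_miscalls <- function(calls, rate) {
  if (rate <= 0) return(calls)
  hit <- which(stats::runif(length(calls)) < rate)
  if (length(hit)) {
    shift <- sample(c(-1L, 1L), length(hit), replace = TRUE)
    calls[hit] <- pmin(4L, pmax(0L, calls[hit] + shift))
  }
  calls
}

#' Simulate a mixed-ploidy SNP dosage panel
#'
#' Generative model, per marker l: ancestral frequency
#' \eqn{p_l \sim U(a, b)}; group frequency
#' \eqn{p_{kl} \sim \mathrm{Beta}(p_l(1-F_k)/F_k, (1-p_l)(1-F_k)/F_k)}
#' (Balding-Nichols; \eqn{p_{kl} = p_l} when \eqn{F_k = 0}). A tetraploid
#' sample's call is Binomial(4, p); a diploid genotype is Binomial(2, p)
#' reported on the tetraploid scale as twice the genotype (so only 0/2/4);
#' a triploid genotype Binomial(3, p) is reported as round(4g/3). Each call
#' is then shifted by one dosage class with probability `miscall_rate` and
#' set missing with probability `missing_rate`. Replicate pairs duplicate a
#' sample's underlying genotype and re-apply error and missingness.
#'
#' @param config a [synthetic_panel_config()].
#' @return list of class `synthetic_panel`: `matrix` (a [dosage_matrix()]),
#'   `metadata` (a [sample_metadata()] data.frame with `taxon_label` =
#'   simulated group, `replicate_group` for duplicated samples), and
#'   `truth` (list: `group` named vector, `ploidy` named vector,
#'   `group_freq` markers x groups matrix, `config`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  K <- config$n_groups
  L <- config$n_markers
  anc <- stats::runif(L, config$ancestral_freq_range[1L],
                      config$ancestral_freq_range[2L])
  group_freq <- matrix(NA_real_, L, K,
                       dimnames = list(NULL, paste0("G", seq_len(K))))
  for (k in seq_len(K)) {
    f <- config$divergence_f[k]
    group_freq[, k] <- if (f == 0) anc else
      stats::rbeta(L, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
  }
  n <- sum(config$group_sizes)
  group <- rep(paste0("G", seq_len(K)), config$group_sizes)
  ploidy <- rep(config$group_ploidy, config$group_sizes)
  ids <- sprintf("S%04d", seq_len(n))
  clean <- matrix(0L, n, L)
  for (k in seq_len(K)) {
    rows <- which(group == paste0("G", k))
    for (l in seq_len(L)) {
      clean[rows, l] <- draw_dosage(length(rows), group_freq[l, k],
                                    config$group_ploidy[k])
    }
  }
  perturb <- function(calls) {
    calls <- apply_miscalls(calls, config$miscall_rate)
    if (config$missing_rate > 0) {
      calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
    }
    calls
  }
  observed <- matrix(perturb(as.vector(clean)), n, L)
  rep_group <- rep(NA_character_, n)
  if (config$n_replicate_pairs > 0) {
    picked <- sort(sample.int(n, config$n_replicate_pairs))
    rep_ids <- paste0(ids[picked], "r")
    rep_calls <- matrix(perturb(as.vector(clean[picked, , drop = FALSE])),
                        length(picked), L)
    observed <- rbind(observed, rep_calls)
    rep_group[picked] <- ids[picked]
    rep_group <- c(rep_group, ids[picked])
    group <- c(group, group[picked])
    ploidy <- c(ploidy, ploidy[picked])
    ids <- c(ids, rep_ids)
  }
  m <- dosage_matrix(observed, sample_ids = ids,
                     marker_ids = sprintf("M%05d", seq_len(L)))
  meta <- sample_metadata(data.frame(
    sample_id = ids, taxon_label = group, origin = "simulated",
    replicate_group = rep_group, stringsAsFactors = FALSE))
  truth <- list(group = stats::setNames(group, ids),
                ploidy = stats::setNames(ploidy, ids),
                group_freq = group_freq, config = config)
  structure(list(matrix = m, metadata = meta, truth = truth),
            class = "synthetic_panel")
}

#' Simulate reference ploidy evidence for a panel
#'
#' Adds cytology-style reference evidence to the metadata of a simulated
#' panel: exact chromosome counts (12 x ploidy: 24, 36 or 48) and guard-cell
#' chloroplast counts drawn from Normal(7.6, 0.83) for diploids and
#' Normal(13.2, 1.06) for tetraploids — the means and spreads reported for
#' cytologically verified reference accessions — and Normal(10.0, 1.0) for
#' triploids (midpoint stand-in).
#'
#' @param panel a `synthetic_panel` from [simulate_panel()].
#' @param n_reference number of samples given reference counts (default
#'   all).
#' @param seed RNG seed.
#' @return the panel's metadata with `chromosome_count` and
#'   `chloroplast_count` filled for the reference samples.
#' @export
simulate_reference_panel <- function(panel, n_reference = NULL, seed = 1) {
  stopifnot(inherits(panel, "synthetic_panel"))
  meta <- panel$metadata
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- seq_len(nrow(meta))
  if (!is.null(n_reference) && n_reference < nrow(meta)) {
    idx <- sort(sample.int(nrow(meta), n_reference))
  }
  pl <- panel$truth$ploidy[meta$sample_id[idx]]
  meta$chromosome_count[idx] <- 12 * pl
  mu <- c("2" = 7.6, "3" = 10.0, "4" = 13.2)[as.character(pl)]
  sdv <- c("2" = 0.83, "3" = 1.0, "4" = 1.06)[as.character(pl)]
  meta$chloroplast_count[idx] <- pmax(1, stats::rnorm(length(idx), mu, sdv))
  meta
}

#' Simulate group-correlated phenotypes
#'
#' Each trait value is its group mean plus Normal noise, clamped at zero.
#' Group means are evenly spaced around a trait-specific base value with
#' spacing chosen so that, at `effect_size = 1` (default), the
#' between-group variance of the means approximately equals the
#' within-group noise variance — structure that is detectable but not
#' degenerate. `effect_size` scales the spacing: larger values give more
#' strongly group-determined phenotypes. Trait bases follow the tuber
#' traits' scales: ATW 20 g (sd 8), NTP 12 tubers (sd 4), TTY 0.8 kg/plant
#' (sd 0.3).
#'
#' @param truth the `truth` element of a [simulate_panel()] result (or any
#'   list with a named `group` vector).
#' @param traits named list of `c(base, sd)` pairs per trait.
#' @param effect_size multiplier on the between-group mean spacing.
#' @param missing_rate probability a trait value is missing.
#' @param seed RNG seed.
#' @return a [phenotype_table()] data.frame (one row per unique sample).
#' @export
simulate_phenotypes <- function(truth,
                                traits = list(ATW = c(20, 8),
                                              NTP = c(12, 4),
                                              TTY = c(0.8, 0.3)),
                                effect_size = 1,
                                missing_rate = 0, seed = 1) {
  group <- truth$group
  ids <- names(group)
  gl <- sort(unique(group))
  K <- length(gl)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  df <- data.frame(accession_id = ids, stringsAsFactors = FALSE)
  for (tr in names(traits)) {
    base <- traits[[tr]][1L]; sdv <- traits[[tr]][2L]
    # spacing s with var of evenly spaced means = s^2 (K^2 - 1) / 12 = sd^2
    s <- if (K > 1L) effect_size * sdv * sqrt(12 / (K^2 - 1)) else 0
    mu <- base + s * (match(group, gl) - (K + 1) / 2)
    v <- pmax(0, stats::rnorm(length(ids), mu, sdv))
    if (missing_rate > 0) {
      v[stats::runif(length(v)) < missing_rate] <- NA_real_
    }
    df[[tr]] <- v
  }
  suppressWarnings(phenotype_table(df, names(traits)))
}
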