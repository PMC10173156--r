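#' Build a validated pipeline configuration
#'
#' @param dosage_tsv path to the dosage matrix TSV (or NULL when a matrix
#'   is passed directly to [run_pipeline()]).
#' @param metadata_csv,phenotype_csv optional metadata / phenotype paths.
#' @param maf_min,missing_max QC filter thresholds (defaults 0.03 / 0.05).
#' @param dip_max,tet_min ploidy classification thresholds (0.15 / 0.20).
#' @param k_min,k_max candidate range for the number of genetic groups.
#' @param core_fractions core collection size fractions
#'   (default `c(0.03, 0.10, 0.15, 0.20)`).
#' @param n_perm permutations for AMOVA/FST (default 999).
#' @param n_restarts core-optimizer restarts (default 10).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param out_dir optional output directory; when set, every stage writes
#'   its outputs there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dosage_tsv = NULL, metadata_csv = NULL,
                            phenotype_csv = NULL, maf_min = 0.03,
                            missing_max = 0.05, dip_max = 0.15,
                            tet_min = 0.20, k_min = 2, k_max = 10,
                            core_fractions = c(0.03, 0.10, 0.15, 0.20),
                            n_perm = 999, n_restarts = 10, seed = 1,
                            out_dir = NULL) {
  if (any(core_fractions <= 0 | core_fractions > 1)) {
    stop("core fractions must be in (0, 1]")
  }
  if (seed != round(seed)) stop("seed must be an integer")
  cfg <- list(dosage_tsv = dosage_tsv, metadata_csv = metadata_csv,
              phenotype_csv = phenotype_csv, maf_min = maf_min,
              missing_max = missing_max, dip_max = dip_max,
              tet_min = tet_min, k_min = k_min, k_max = k_max,
              core_fractions = core_fractions, n_perm = n_perm,
              n_restarts = n_restarts, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML (`.yaml` / `.yml`, requires the yaml package) or JSON. Unknown keys
#' are errors, not warnings, so typos cannot silently change a run.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
pipeline_config_read <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

# derive a reproducible per-stage seed from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full curation pipeline
#'
#' Executes, in order: QC filtering, ploidy inference (with replicate
#' consistency when replicate groups exist), observed heterozygosity,
#' Modified Rogers distances, PCA, selection of the number of genetic
#' groups, AMOVA and pairwise FST on the inferred groups, core selection at
#' each configured fraction (the smallest fraction is nested inside the
#' smallest fraction >= 0.10 when both exist), and — when phenotypes are
#' supplied — Gower-distance validation and trait summary statistics.
#' Results are returned as a self-contained run report (and written as JSON
#' plus per-stage TSVs when `out_dir` is configured).
#'
#' @param config a [pipeline_config()].
#' @param matrix optional [dosage_matrix()] overriding `config$dosage_tsv`.
#' @param metadata,phenotypes optional in-memory tables overriding paths.
#' @return list of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(config, matrix = NULL, metadata = NULL,
                         phenotypes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(matrix)) {
    if (is.null(config$dosage_tsv)) stop("no dosage matrix configured")
    matrix <- stage("input", read_dosage_tsv(config$dosage_tsv))
  }
  if (is.null(metadata) && !is.null(config$metadata_csv)) {
    metadata <- stage("input", read_sample_metadata(config$metadata_csv))
  }
  if (is.null(phenotypes) && !is.null(config$phenotype_csv)) {
    phenotypes <- stage("input", read_phenotypes(config$phenotype_csv))
  }
  report <- list(config = unclass(config))

  fr <- stage("filter",
              filter_dosage(matrix, config$maf_min, config$missing_max))
  report$filter <- unclass(fr$report)
  m <- fr$matrix

  calls <- stage("ploidy", ploidy_calls(m, config$dip_max, config$tet_min))
  report$ploidy <- list(counts = as.list(table(calls$call)),
                        mean_st_freq = mean(calls$st_freq))
  if (!is.null(metadata)) {
    rc <- stage("ploidy", replicate_consistency(calls, metadata))
    report$ploidy$replicate_groups <- nrow(rc)
    report$ploidy$replicate_consistent <- sum(rc$consistent)
  }

  ho <- stage("diversity", observed_heterozygosity(m))
  mrd <- stage("diversity", mrd_matrix(m))

  pca <- stage("structure", dosage_pca(m))
  grp <- stage("structure",
               choose_k(pca$scores, config$k_min,
                        min(config$k_max, nrow(m) - 1L),
                        seed = stage_seed(config$seed, "structure")))
  labels <- grp$labels
  report$structure <- list(K = grp$K,
                           low_confidence = grp$low_confidence,
                           percent_variance =
                             utils::head(pca$percent_variance, 5),
                           group_sizes = as.list(table(labels)))

  am <- stage("diversity",
              amova(mrd, labels, n_perm = config$n_perm,
                    seed = stage_seed(config$seed, "amova")))
  fst <- stage("diversity",
               nei_fst(m, labels, n_perm = min(config$n_perm, 199),
                       seed = stage_seed(config$seed, "fst")))
  report$diversity <- list(
    phi = am$phi, phi_p = am$p_value,
    percent_among = unname(am$percent["among"]),
    percent_within = unname(am$percent["within"]),
    fst = fst[, c("group1", "group2", "fst", "p_value")],
    ho_mean = mean(ho$per_sample), ho_sd = stats::sd(ho$per_sample))

  fractions <- sort(config$core_fractions)
  selections <- list()
  for (f in fractions) {
    k <- core_size(nrow(m), f)
    selections[[sprintf("core_%02.0f", 100 * f)]] <-
      stage("core", select_core(mrd, k,
                                seed = stage_seed(config$seed, "core"),
                                n_restarts = config$n_restarts,
                                fraction = f))
  }
  if (length(fractions) >= 2L && any(fractions >= 0.10)) {
    mini_f <- fractions[1L]
    host_f <- min(fractions[fractions >= 0.10])
    if (mini_f < host_f) {
      mini_nm <- sprintf("core_%02.0f", 100 * mini_f)
      host_nm <- sprintf("core_%02.0f", 100 * host_f)
      nest <- stage("core", nest_minicore(
        selections[[mini_nm]]$entry_ids,
        selections[[host_nm]]$entry_ids, mrd))
      report$nested_minicore <- list(
        mini = mini_nm, host = host_nm,
        n_replaced = sum(nest$mini_entry != nest$replacement),
        entry_ids = attr(nest, "entry_ids"))
    }
  }
  report$cores <- stage("core", evaluate_cores(mrd, selections))
  report$ho_by_collection <- compare_collections_impl(ho, labels, selections,
                                                      rownames(m))

  if (!is.null(phenotypes)) {
    gd <- stage("pheno", gower_distance(phenotypes))
    sets <- c(list(whole = intersect(rownames(m),
                                     phenotypes$accession_id)),
              lapply(selections, `[[`, "entry_ids"))
    report$phenotypes <- list(
      metrics = stage("pheno", evaluate_cores_pheno(gd, selections)),
      summary = stage("pheno", summary_stats(phenotypes, sets)))
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(report, m, calls, ho, mrd, pca, labels,
                           selections, config$out_dir)
  }
  attr(report, "selections") <- selections
  report
}

compare_collections_impl <- function(ho, labels, selections, all_ids) {
  sets <- c(list(whole = all_ids), lapply(selections, `[[`, "entry_ids"))
  rows <- lapply(names(sets), function(nm) {
    v <- ho$per_sample[sets[[nm]]]
    data.frame(collection = nm, n = length(v), ho_mean = mean(v),
               ho_sd = stats::sd(v), stringsAsFactors = FALSE)
  })
  overall <- do.call(rbind, rows)
  by_group <- do.call(rbind, lapply(sort(unique(labels)), function(g) {
    ids <- names(labels)[labels == g]
    v <- ho$per_sample[ids]
    data.frame(group = g, n = length(v), ho_mean = mean(v),
               ho_sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  list(by_collection = overall, by_group = by_group)
}

#' Compare observed heterozygosity across collections
#'
#' Extracts from a completed run report the mean +/- sd Ho for the whole
#' collection, each core collection, and each genetic group — the summary
#' used to verify that core selections retain (typically slightly enrich)
#' the collection's diversity.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @return list: `by_collection` and `by_group` data.frames.
#' @export
compare_collections <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  report$ho_by_collection
}

write_pipeline_outputs <- function(report, m, calls, ho, mrd, pca, labels,
                                   selections, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_dosage_tsv(m, p("filtered_matrix.tsv"))
  calls_out <- calls
  calls_out$st_freq <- round(calls_out$st_freq, 4)
  utils::write.table(calls_out, p("ploidy.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_dist_tsv(mrd, p("mrd.tsv"))
  scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                       group = labels[rownames(pca$scores)])
  utils::write.table(scores, p("structure.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$cores, p("core_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(selections)) {
    jsonlite::write_json(
      list(entry_ids = selections[[nm]]$entry_ids,
           fraction = selections[[nm]]$fraction,
           objective_values = as.list(selections[[nm]]$objective_values),
           seed = selections[[nm]]$trace$seed),
      p(paste0(nm, ".json")), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(unclass(report), p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat(sprintf("  markers: %d -> %d, samples: %d -> %d\n",
              x$filter$n_markers_in, x$filter$n_markers_out,
              x$filter$n_samples_in, x$filter$n_samples_out))
  cat("  ploidy counts:",
      paste(names(x$ploidy$counts), unlist(x$ploidy$counts),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  structure: K = %d; AMOVA Phi = %.3f (p = %.4g)\n",
              x$structure$K, x$diversity$phi, x$diversity$phi_p))
  print(x$cores, row.names = FALSE)
  invisible(x)
}
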