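#' Validate a sample metadata table
#'
#' Sample metadata carries curation context for each genotyped sample:
#' a free-text taxonomic label (e.g. Andigenum, Phureja, Tuberosum, Guata,
#' unknown), the geographic origin, an optional `replicate_group` shared by
#' biological repetitions of one accession, and optional reference ploidy
#' evidence: a root-cell chromosome count and/or the mean number of
#' chloroplasts per guard cell.
#'
#' @param df a data.frame with at least a `sample_id` column; recognised
#'   optional columns: `taxon_label`, `origin`, `replicate_group`,
#'   `chromosome_count`, `chloroplast_count`.
#' @return The validated data.frame (missing optional columns added as NA).
#' @export
sample_metadata <- function(df) {
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  for (col in c("taxon_label", "origin", "replicate_group")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  for (col in c("chromosome_count", "chloroplast_count")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop(col, " must be positive where present")
    }
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read sample metadata from CSV
#' @param path CSV with header; see [sample_metadata()] for columns.
#' @return validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a phenotype table
#'
#' One row per accession with up to three tuber traits: average tuber weight
#' `ATW` (g), number of tubers per plant `NTP`, and total tuber yield `TTY`
#' (kg/plant). Multi-year evaluations are expected to be averaged per
#' accession before loading. Rows with all traits missing are dropped with
#' a warning.
#'
#' @param df data.frame with columns `accession_id`, `ATW`, `NTP`, `TTY`
#'   (traits numeric, `NA` allowed).
#' @param traits trait column names (default the three tuber traits).
#' @return validated data.frame.
#' @export
phenotype_table <- function(df, traits = c("ATW", "NTP", "TTY")) {
  if (!"accession_id" %in% names(df)) {
    stop("phenotype table needs an accession_id column")
  }
  missing_traits <- setdiff(traits, names(df))
  if (length(missing_traits)) {
    stop("missing trait column(s): ", paste(missing_traits, collapse = ", "))
  }
  if (anyDuplicated(df$accession_id)) stop("duplicate accession_id")
  for (tr in traits) {
    v <- df[[tr]]
    if (!is.numeric(v)) stop("trait ", tr, " must be numeric")
    if (any(!is.na(v) & v < 0)) stop("trait ", tr, " has negative values")
  }
  all_na <- rowSums(!is.na(df[, traits, drop = FALSE])) == 0L
  if (any(all_na)) {
    warning(sprintf("dropped %d accession(s) with no phenotype data",
                    sum(all_na)))
    df <- df[!all_na, , drop = FALSE]
  }
  df$accession_id <- as.character(df$accession_id)
  rownames(df) <- NULL
  df
}

#' Read a phenotype table from CSV
#' @param path CSV with header `accession_id,ATW,NTP,TTY`.
#' @param traits trait column names.
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path, traits = c("ATW", "NTP", "TTY")) {
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE), traits)
}
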