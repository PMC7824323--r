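#' Run configuration
#'
#' A single flat configuration object shared by all reporting functions.
#' `flora_size` is the floristic denominator of the ethnobotanicity index
#' (default 4200, the autochthonous-flora estimate for the Catalan
#' linguistic area); `reliability_min_informants` the minimum-independent-
#' informants threshold (default 3); `percentage_denominator` selects
#' whether UR percentages and the F_IC denominator use all use reports or
#' only those citing specific/subspecific-rank taxa; `rounding` is the
#' number of decimals used when percentages are displayed or serialized
#' (internal arithmetic is never rounded).
#'
#' @param flora_size Positive count.
#' @param reliability_min_informants Positive count.
#' @param percentage_denominator `"all_ur"` or `"specific_rank_ur"`.
#' @param rounding Decimal places for reported percentages.
#' @param seed Integer seed or `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(flora_size = 4200,
                       reliability_min_informants = 3,
                       percentage_denominator = c("all_ur", "specific_rank_ur"),
                       rounding = 2,
                       seed = NULL) {
  percentage_denominator <- match.arg(percentage_denominator)
  flora_size <- assert_count(flora_size, "flora_size", min = 1)
  reliability_min_informants <-
    assert_count(reliability_min_informants, "reliability_min_informants", min = 1)
  rounding <- assert_count(rounding, "rounding", min = 0)
  if (!is.null(seed)) seed <- assert_count(seed, "seed", min = 0)
  structure(
    list(
      flora_size = flora_size,
      reliability_min_informants = reliability_min_informants,
      percentage_denominator = percentage_denominator,
      rounding = rounding,
      seed = seed
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(paste0("Unsupported config format: .", ext))
  )
  if (is.null(vals)) vals <- list()
  bad <- setdiff(names(vals), names(formals(run_config)))
  if (length(bad) > 0) {
    abort(paste0("Unknown config keys: ", toString(bad)))
  }
  do.call(run_config, vals)
}

survey_columns <- c("informant_id", "study_id", "taxon_name", "family",
                    "part", "preparation")

#' Read a use-report survey from CSV/TSV
#'
#' Reads a tabular survey file with header
#' `informant_id,study_id,taxon_name,family,part,preparation`, applies the
#' part and preparation vocabulary maps (which must be total: any unmapped
#' label is an error naming it), normalizes taxon names, deduplicates use
#' records and returns a fully validated [survey_dataset()]. Row, dedupe
#' and registry counts are logged to the message stream.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file, UTF-8.
#' @param part_vocab,prep_vocab Optional [vocabulary_map()]s; by default
#'   only canonical labels are accepted.
#' @param config A [run_config()]; supplies `flora_size`.
#' @param informants Optional informant registry tibble.
#' @param quiet Suppress log messages.
#' @return A `survey_dataset`.
#' @export
read_survey <- function(path, part_vocab = NULL, prep_vocab = NULL,
                        config = run_config(), informants = NULL,
                        quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("Survey file not found: ", path))
  }
  delim <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  miss <- setdiff(survey_columns, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Survey file ", path, " is missing columns: ", toString(miss)))
  }
  if (is.null(part_vocab)) part_vocab <- vocabulary_map(scope = "part")
  if (is.null(prep_vocab)) prep_vocab <- vocabulary_map(scope = "preparation")
  n_rows <- nrow(raw)
  if (n_rows == 0) {
    ds <- survey_dataset(
      records = tibble::tibble(
        informant_id = character(), study_id = character(),
        taxon_key = character(), part = character(), preparation = character()
      ),
      informants = informants %||% tibble::tibble(informant_id = character()),
      taxa = tibble::tibble(key = character(), rank = character(), family = character()),
      flora_size = config$flora_size
    )
    attr(ds, "n_collapsed") <- 0L
    if (!quiet) inform(paste0("read_survey: 0 rows in ", path))
    return(ds)
  }
  raw$part <- apply_vocabulary(raw$part %||% "unknown", part_vocab)
  raw$preparation <- apply_vocabulary(raw$preparation, prep_vocab)
  ds <- dedupe_records(raw, flora_size = config$flora_size,
                       informants = informants)
  if (!quiet) {
    inform(sprintf(
      "read_survey: %d rows -> %d use records (%d duplicates collapsed), %d informants, %d taxa (%d specific-rank)",
      n_rows, n_ur(ds), attr(ds, "n_collapsed"), n_informants(ds),
      n_taxa(ds), n_taxa(ds, "species_or_below")
    ))
  }
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a summary table to CSV
#'
#' Writes any summary table produced by this package as RFC-4180-style
#' UTF-8 CSV with `.` as the decimal separator. Columns whose names end in
#' `percent` (and the `ci` column) are serialized with `rounding` decimals
#' ("6.62", not "6.619047"); other numerics are written exactly. The file
#' round-trips: reading it back yields the written cells field-for-field.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param rounding Decimal places for percentage-like columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, rounding = 2) {
  table <- tibble::as_tibble(table)
  fmt <- names(table)[grepl("percent$", names(table)) | names(table) == "ci"]
  for (col in fmt) {
    if (is.numeric(table[[col]])) {
      table[[col]] <- sprintf(paste0("%.", rounding, "f"),
                              round_half_up(table[[col]], rounding))
    }
  }
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Write the survey records of a dataset back to CSV
#'
#' Emits the same schema [read_survey()] consumes, so datasets (including
#' synthetic ones) round-trip through disk.
#'
#' @param dataset A `survey_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(dataset, path) {
  assert_dataset(dataset)
  tax <- dataset$taxa
  recs <- dataset$records
  idx <- match(recs$taxon_key, tax$key)
  out <- tibble::tibble(
    informant_id = recs$informant_id,
    study_id = recs$study_id,
    taxon_name = display_name(tax[idx, ]),
    family = tax$family[idx],
    part = recs$part,
    preparation = recs$preparation
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

display_name <- function(taxa) {
  nm <- taxa$genus
  has_ep <- nzchar(taxa$epithet)
  nm[has_ep] <- paste(nm[has_ep], taxa$epithet[has_ep])
  infra <- taxa$infraspecific_rank != "none" & nzchar(taxa$infraspecific_epithet)
  nm[infra] <- paste(nm[infra], taxa$infraspecific_rank[infra],
                     taxa$infraspecific_epithet[infra])
  nm
}
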