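#' Run the full survey analysis pipeline
#'
#' End-to-end orchestration: read and validate a survey file, compute the
#' index report (EI, F_IC, CI, reliability filter), write ranked and
#' categorical summary tables, the alluvial export and optional
#' cross-reference flag tables, echo the configuration for provenance, and
#' return a run manifest with content digests of the inputs. Output is a
#' pure function of (inputs, configuration, seed).
#'
#' Files written to `out_dir`: `indices.json`, `ci_by_taxon.csv`,
#' `ranking_taxon.csv`, `ranking_genus.csv`, `ranking_family.csv`,
#' `distribution_part.csv`, `distribution_preparation.csv`,
#' `alluvial.csv`, `alluvial.json`, `validation_<name>.csv` per reference
#' list, `config.json`, `manifest.json`.
#'
#' @param survey_path Survey CSV/TSV (see [read_survey()]).
#' @param out_dir Output directory, created if needed.
#' @param config A [run_config()] or a path readable by
#'   [read_run_config()].
#' @param reference_lists Named list of reference-list file paths (or
#'   [reference_list()] objects) to cross-reference against.
#' @param part_vocab,prep_vocab Optional vocabulary maps or CSV paths.
#' @param top_n Taxa kept in the alluvial export.
#' @param quiet Suppress log messages.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(survey_path, out_dir, config = run_config(),
                         reference_lists = list(),
                         part_vocab = NULL, prep_vocab = NULL,
                         top_n = 30, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.character(part_vocab)) part_vocab <- read_vocabulary(part_vocab, "part")
  if (is.character(prep_vocab)) prep_vocab <- read_vocabulary(prep_vocab, "preparation")
  if (!file.exists(survey_path)) {
    abort(paste0("Survey file not found: ", survey_path))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ds <- read_survey(survey_path, part_vocab, prep_vocab, config, quiet = quiet)
  if (n_ur(ds) == 0) {
    abort("Pipeline needs a non-empty survey.")
  }

  report <- index_report(ds, config)
  jsonlite::write_json(
    list(
      ei_percent = report$ei_percent,
      fic = report$fic,
      reliability = report$reliability[c("n_kept", "n_total", "kept_percent")],
      counts = report$counts
    ),
    file.path(out_dir, "indices.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_table(report$ci_by_taxon, file.path(out_dir, "ci_by_taxon.csv"),
              rounding = config$rounding)

  for (lev in c("taxon", "genus", "family")) {
    write_table(rank_entities(ds, lev, config$percentage_denominator),
                file.path(out_dir, paste0("ranking_", lev, ".csv")),
                rounding = config$rounding)
  }
  write_table(distribution(ds, "part", rollup = TRUE),
              file.path(out_dir, "distribution_part.csv"), config$rounding)
  write_table(distribution(ds, "preparation"),
              file.path(out_dir, "distribution_preparation.csv"), config$rounding)

  allu <- alluvial_export(ds, top_n = min(top_n, n_taxa(ds)))
  write_table(allu, file.path(out_dir, "alluvial.csv"), config$rounding)
  jsonlite::write_json(allu, file.path(out_dir, "alluvial.json"),
                       dataframe = "rows", digits = NA)

  for (nm in names(reference_lists)) {
    ref <- reference_lists[[nm]]
    if (is.character(ref)) ref <- read_reference_list(ref, nm)
    res <- crossref(ds, ref)
    flags <- res$flags
    flags$list <- nm
    write_table(flags, file.path(out_dir, paste0("validation_", nm, ".csv")),
                config$rounding)
    if (!quiet) {
      inform(sprintf("crossref %s: %d/%d matched (%.2f%% incl. species-level)",
                     nm, res$n_matched, res$n_total, res$percent_matched))
    }
  }

  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ethnoindex")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = unclass(config),
    inputs = list(survey = list(
      path = survey_path,
      md5 = unname(tools::md5sum(survey_path))
    )),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
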