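#' Construct a validated survey dataset
#'
#' The central container of the package: a set of deduplicated use records
#' plus the informant registry, the taxon table and the floristic context
#' needed by the indices. A use report (UR) is one distinct
#' `(informant, taxon, part, preparation)` tuple; `|records|` is therefore
#' the dataset's UR total. Construction validates every invariant: records
#' resolve against both registries, part/preparation labels are canonical,
#' record tuples are unique, every taxon has a non-empty family, and the
#' flora size is at least the number of taxa used.
#'
#' @param records Tibble with columns `informant_id`, `study_id`,
#'   `taxon_key`, `part`, `preparation`.
#' @param informants Tibble with column `informant_id` (plus optional
#'   `gender`, `study_id`). Defaults to the informants present in `records`.
#' @param taxa Tibble as returned by [normalize_name()] plus a `family`
#'   column; must cover every `taxon_key` in `records`.
#' @param flora_size Positive count of autochthonous flora taxa in the
#'   study territory (the ethnobotanicity denominator).
#' @return An object of class `survey_dataset`.
#' @seealso [dedupe_records()] to build one from raw rows, [read_survey()]
#'   to read one from disk, [generate_survey()] to simulate one.
#' @export
survey_dataset <- function(records, informants = NULL, taxa, flora_size = 4200) {
  records <- tibble::as_tibble(records)
  need <- c("informant_id", "study_id", "taxon_key", "part", "preparation")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("`records` is missing columns: ", toString(miss)))
  }
  records <- dplyr::select(records, dplyr::all_of(need))
  taxa <- tibble::as_tibble(taxa)
  if (!all(c("key", "rank", "family") %in% names(taxa))) {
    abort("`taxa` must have columns key, rank, family.")
  }
  if (anyDuplicated(taxa$key)) {
    abort("`taxa` has duplicate normalization keys.")
  }
  if (is.null(informants)) {
    informants <- tibble::tibble(informant_id = sort(unique(records$informant_id)))
  }
  informants <- tibble::as_tibble(informants)
  if (!"informant_id" %in% names(informants)) {
    abort("`informants` must have an informant_id column.")
  }
  if (anyDuplicated(informants$informant_id)) {
    abort("Duplicate entries in the informant registry.")
  }

  bad_tax <- setdiff(records$taxon_key, taxa$key)
  if (length(bad_tax) > 0) {
    abort(paste0("Record taxa missing from taxon table: ", toString(head(bad_tax, 5))))
  }
  bad_inf <- setdiff(records$informant_id, informants$informant_id)
  if (length(bad_inf) > 0) {
    abort(paste0("Record informants missing from registry: ", toString(head(bad_inf, 5))))
  }
  if (anyNA(records)) {
    abort("`records` contains missing values.")
  }
  chk_part <- setdiff(records$part, part_categories()$label)
  if (length(chk_part) > 0) {
    abort(paste0("Non-canonical part labels in records: ", toString(chk_part)))
  }
  chk_prep <- setdiff(records$preparation, prep_categories()$label)
  if (length(chk_prep) > 0) {
    abort(paste0("Non-canonical preparation labels in records: ", toString(chk_prep)))
  }
  used <- taxa$key[taxa$key %in% records$taxon_key & taxa$family == ""]
  if (length(used) > 0) {
    abort(paste0("Used taxa with empty family: ", toString(head(used, 5))))
  }
  dup <- dplyr::distinct(records, .data$informant_id, .data$taxon_key,
                         .data$part, .data$preparation)
  if (nrow(dup) != nrow(records)) {
    abort("`records` contains duplicate (informant, taxon, part, preparation) tuples; run dedupe_records() first.")
  }
  flora_size <- assert_count(flora_size, "flora_size", min = 1)
  n_used <- dplyr::n_distinct(records$taxon_key)
  if (flora_size < n_used) {
    abort("`flora_size` is smaller than the number of taxa used.")
  }

  # canonical row order so downstream output is bit-stable regardless of
  # input order
  records <- dplyr::arrange(records, .data$informant_id, .data$taxon_key,
                            .data$part, .data$preparation)
  structure(
    list(
      records = records,
      informants = dplyr::arrange(informants, .data$informant_id),
      taxa = dplyr::arrange(taxa, .data$key),
      flora_size = flora_size
    ),
    class = "survey_dataset"
  )
}

#' Deduplicate raw use rows into a survey dataset
#'
#' Collapses duplicate `(informant, taxon, part, preparation)` tuples --
#' e.g. the same informant citing thyme as a raw condiment in two interview
#' passes -- into single use records, normalizing taxon names on the way.
#' The result is independent of the input row order; when duplicate rows
#' disagree on `study_id`, the lexicographically smallest one is kept so the
#' collapse is deterministic.
#'
#' @param rows Tibble with columns `informant_id`, `study_id`, `taxon_name`,
#'   `family`, `part`, `preparation`; part/preparation already mapped to
#'   canonical vocabulary (see [apply_vocabulary()]).
#' @param flora_size Passed to [survey_dataset()].
#' @param informants Optional informant registry; defaults to the ids seen.
#' @return A `survey_dataset`; the number of collapsed rows is available as
#'   `attr(x, "n_collapsed")`.
#' @export
#' @examples
#' rows <- tibble::tibble(
#'   informant_id = c("i1", "i1", "i2"), study_id = "s1",
#'   taxon_name = "Thymus vulgaris L.", family = "Lamiaceae",
#'   part = "leaf", preparation = c("condiment", "condiment", "raw")
#' )
#' ds <- dedupe_records(rows)
#' attr(ds, "n_collapsed")  # 1
dedupe_records <- function(rows, flora_size = 4200, informants = NULL) {
  rows <- tibble::as_tibble(rows)
  need <- c("informant_id", "study_id", "taxon_name", "family", "part", "preparation")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0) {
    abort(paste0("`rows` is missing columns: ", toString(miss)))
  }
  if (anyNA(rows$informant_id) || anyNA(rows$taxon_name)) {
    abort("informant_id and taxon_name are required on every row.")
  }

  parsed <- normalize_name(rows$taxon_name)
  rows$taxon_key <- parsed$key

  # family attribution must be unique per taxon key
  fam <- dplyr::distinct(
    tibble::tibble(key = parsed$key, family = rows$family)
  )
  clash <- fam$key[duplicated(fam$key)]
  if (length(clash) > 0) {
    abort(paste0("Conflicting family attribution for: ", toString(unique(clash))))
  }

  taxa <- dplyr::distinct(parsed, .data$key, .keep_all = TRUE)
  taxa <- dplyr::select(taxa, -"input")
  taxa <- dplyr::left_join(taxa, fam, by = "key")
  taxa$family[is.na(taxa$family)] <- ""

  n_in <- nrow(rows)
  recs <- rows |>
    dplyr::group_by(.data$informant_id, .data$taxon_key, .data$part, .data$preparation) |>
    dplyr::summarise(study_id = min(.data$study_id), .groups = "drop")
  ds <- survey_dataset(recs, informants = informants, taxa = taxa,
                       flora_size = flora_size)
  attr(ds, "n_collapsed") <- n_in - nrow(recs)
  ds
}

#' Basic counts of a survey dataset
#'
#' `n_ur()` is the number of use records; `n_informants()` the registry
#' size; `n_taxa()` the number of distinct taxa cited in at least one
#' record, optionally restricted by determination rank. Index conventions
#' follow quantitative-ethnobotany practice: the ethnobotanicity index and
#' the informant consensus factor are computed over taxa determined at
#' least to species, while UR totals include genus-only citations.
#'
#' @param dataset A `survey_dataset`.
#' @param rank `"all"`, `"species_or_below"` or `"genus_only"`.
#' @return An integer count.
#' @export
n_ur <- function(dataset) {
  assert_dataset(dataset)
  nrow(dataset$records)
}

#' @rdname n_ur
#' @export
n_informants <- function(dataset) {
  assert_dataset(dataset)
  nrow(dataset$informants)
}

#' @rdname n_ur
#' @export
n_taxa <- function(dataset, rank = c("all", "species_or_below", "genus_only")) {
  assert_dataset(dataset)
  rank <- match.arg(rank)
  keys <- unique(dataset$records$taxon_key)
  if (rank == "all") {
    return(length(keys))
  }
  sum(dataset$taxa$rank[match(keys, dataset$taxa$key)] == rank)
}

assert_dataset <- function(x) {
  if (!inherits(x, "survey_dataset")) {
    abort("Expected a `survey_dataset` object.")
  }
  invisible(x)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat(sprintf("  use records : %d\n", n_ur(x)))
  cat(sprintf("  informants  : %d\n", n_informants(x)))
  cat(sprintf("  taxa cited  : %d (%d at species level or below)\n",
              n_taxa(x), n_taxa(x, "species_or_below")))
  cat(sprintf("  flora size  : %d\n", x$flora_size))
  invisible(x)
}
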