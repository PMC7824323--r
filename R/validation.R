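#' Build a reference name list
#'
#' External reference lists (an edibility repository, a nutraceutical /
#' functional-food dictionary) are plain collections of botanical names.
#' Entries are normalized with the same [normalize_name()] rules as survey
#' taxa so that comparison is exact on keys. The package never downloads:
#' lists are supplied by the user as files or vectors.
#'
#' @param entries Character vector of raw botanical names.
#' @param name Short label for the list (used in report columns).
#' @return A `reference_list` object.
#' @export
reference_list <- function(entries, name = "reference") {
  if (length(entries) > 0) {
    keys <- unique(normalize_name(entries)$key)
  } else {
    keys <- character()
  }
  structure(list(name = name, entries = keys), class = "reference_list")
}

#' Read a reference list from a one-name-per-line file
#'
#' Blank lines and `#` comment lines are skipped.
#'
#' @param path UTF-8 text file, one botanical name per line.
#' @param name Label for the list; defaults to the file stem.
#' @return A [reference_list()].
#' @export
read_reference_list <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Reference list not found: ", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_squish(lines)
  lines <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
  reference_list(lines, name %||% tools::file_path_sans_ext(basename(path)))
}

#' Cross-reference used taxa against a reference list
#'
#' Flags every cited specific/subspecific-rank taxon of the dataset as
#' `exact` (key present in the list), `species_level` (the survey taxon is
#' subspecific and only its parent `genus epithet` key is in the list) or
#' `none`. Because published coverage figures do not always state whether
#' subspecies were matched at species level, both counting conventions are
#' returned: `n_exact`/`percent_exact` and `n_matched`/`percent_matched`
#' (exact plus species-level fallback).
#'
#' An empty reference list is allowed and yields zero matches.
#'
#' @param dataset A `survey_dataset`.
#' @param ref A [reference_list()].
#' @return A list: `flags` (tibble `taxon_key`, `match`), `n_exact`,
#'   `n_matched`, `n_total`, `percent_exact`, `percent_matched`,
#'   `unmatched` (character vector of keys).
#' @export
crossref <- function(dataset, ref) {
  assert_dataset(dataset)
  if (!inherits(ref, "reference_list")) {
    abort("`ref` must be a reference_list.")
  }
  spec <- dataset$taxa$key[dataset$taxa$rank == "species_or_below"]
  cited <- sort(intersect(spec, unique(dataset$records$taxon_key)))
  match_type <- dplyr::case_when(
    cited %in% ref$entries ~ "exact",
    species_key(cited) != cited & species_key(cited) %in% ref$entries ~ "species_level",
    .default = "none"
  )
  flags <- tibble::tibble(taxon_key = cited, match = match_type)
  n_total <- length(cited)
  n_exact <- sum(match_type == "exact")
  n_matched <- sum(match_type != "none")
  list(
    name = ref$name,
    flags = flags,
    n_exact = n_exact,
    n_matched = n_matched,
    n_total = n_total,
    percent_exact = if (n_total > 0) share_percent(n_exact, n_total) else 0,
    percent_matched = if (n_total > 0) share_percent(n_matched, n_total) else 0,
    unmatched = flags$taxon_key[flags$match == "none"]
  )
}
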