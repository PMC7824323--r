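#' Rank taxa, genera or families by use reports
#'
#' The descriptive backbone of a survey report: UR counts and shares per
#' taxon, genus or family, sorted by decreasing UR with alphabetical
#' tie-break on the normalization key so output is bit-stable across runs.
#' Genus and family rows carry the number of distinct taxa they cover;
#' taxon rows carry the cultural importance index. Shares are computed
#' against either all UR or the specific-rank UR subtotal -- survey reports
#' mix both conventions, so the denominator actually used is recorded in
#' the `denominator_n` attribute.
#'
#' @param dataset A `survey_dataset` with at least one record.
#' @param level `"taxon"`, `"genus"` or `"family"`.
#' @param denominator `"all_ur"` (default) or `"specific_rank_ur"`.
#' @return A tibble `(entity, [n_taxa,] ur, ur_percent, [ci,] rank)` with
#'   attribute `denominator_n`.
#' @export
rank_entities <- function(dataset, level = c("taxon", "genus", "family"),
                          denominator = c("all_ur", "specific_rank_ur")) {
  assert_dataset(dataset)
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  if (n_ur(dataset) == 0) {
    abort("Cannot rank an empty dataset.")
  }
  denom <- switch(denominator,
    all_ur = n_ur(dataset),
    specific_rank_ur = specific_rank_ur(dataset)
  )
  recs <- dataset$records
  tax <- dataset$taxa
  idx <- match(recs$taxon_key, tax$key)
  recs$entity <- switch(level,
    taxon = recs$taxon_key,
    genus = stringr::str_to_lower(tax$genus[idx]),
    family = tax$family[idx]
  )
  out <- recs |>
    dplyr::group_by(.data$entity) |>
    dplyr::summarise(
      n_taxa = dplyr::n_distinct(.data$taxon_key),
      ur = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(ur_percent = 100 * .data$ur / denom) |>
    dplyr::arrange(dplyr::desc(.data$ur), .data$entity) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (level == "taxon") {
    ci <- compute_ci(dataset, "single_food")
    out <- out |>
      dplyr::select(-"n_taxa") |>
      dplyr::left_join(ci, by = c(entity = "taxon_key")) |>
      dplyr::select("entity", "ur", "ur_percent", "ci", "rank")
  }
  attr(out, "denominator_n") <- denom
  attr(out, "denominator") <- denominator
  out
}

#' Mean and sample standard deviation of UR counts
#'
#' The "mean ± SD" row of a ranking table. The standard deviation uses the
#' sample (n − 1) denominator, the convention that reproduces published
#' summary rows of this kind.
#'
#' @param values Numeric vector of counts; at least 1 for the mean, at
#'   least 2 for the SD.
#' @return A list with `mean` and `sd` (exact, not display-rounded).
#' @export
#' @examples
#' mean_sd(c(1, 2, 3))  # mean 2, sd 1
mean_sd <- function(values) {
  if (!is.numeric(values) || length(values) < 1 || anyNA(values)) {
    abort("`values` must be a non-empty numeric vector without NA.")
  }
  if (length(values) < 2) {
    abort("Sample SD needs at least 2 values.")
  }
  list(mean = mean(values), sd = sd(values))
}

#' Cumulative UR share of the top k rows of a ranking
#'
#' @param table A ranking table with an `ur` column, sorted by decreasing
#'   UR (e.g. from [rank_entities()]).
#' @param k Number of leading rows, `1 <= k <= nrow(table)`.
#' @param denominator_n Total UR to divide by; defaults to the table's
#'   `denominator_n` attribute, or the table's own UR sum when absent (a
#'   free-standing top-n table).
#' @param digits Display rounding; `NULL` for exact.
#' @return A percentage.
#' @export
top_share <- function(table, k, denominator_n = NULL, digits = 2) {
  if (!"ur" %in% names(table)) {
    abort("`table` must have a `ur` column.")
  }
  k <- assert_count(k, "k", min = 1)
  if (k > nrow(table)) {
    abort("`k` exceeds the number of rows.")
  }
  denom <- denominator_n %||% attr(table, "denominator_n") %||% sum(table$ur)
  out <- 100 * sum(table$ur[seq_len(k)]) / denom
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Distribution of use reports over parts or preparation modes
#'
#' One row per canonical category -- including the explicit `unknown`
#' category for unreported parts/preparations -- with UR counts and
#' percentages over all UR. For parts, `rollup = TRUE` appends the
#' morphological superclass totals (aerial organs, subterranean organs,
#' plant products, unknown) as extra rows flagged `level = "superclass"`.
#' Within each level the percentages sum to 100 up to rounding.
#'
#' @param dataset A `survey_dataset`.
#' @param axis `"part"` or `"preparation"`.
#' @param rollup Append superclass totals (parts only).
#' @return A tibble `(level, category, ur, percent)`.
#' @export
distribution <- function(dataset, axis = c("part", "preparation"),
                         rollup = FALSE) {
  assert_dataset(dataset)
  axis <- match.arg(axis)
  total <- n_ur(dataset)
  labels <- if (axis == "part") part_categories()$label else prep_categories()$label
  col <- if (axis == "part") "part" else "preparation"
  counts <- table(factor(dataset$records[[col]], levels = labels))
  out <- tibble::tibble(
    level = "category",
    category = labels,
    ur = as.integer(counts),
    percent = if (total > 0) 100 * as.integer(counts) / total else 0
  )
  if (rollup) {
    if (axis != "part") {
      abort("Superclass rollup applies to the part axis only.")
    }
    roll <- out |>
      dplyr::mutate(superclass = part_superclass(.data$category)) |>
      dplyr::group_by(.data$superclass) |>
      dplyr::summarise(ur = sum(.data$ur), percent = sum(.data$percent),
                       .groups = "drop") |>
      dplyr::mutate(level = "superclass") |>
      dplyr::rename(category = "superclass") |>
      dplyr::select("level", "category", "ur", "percent")
    out <- dplyr::bind_rows(out, roll)
  }
  out
}

#' Long-format taxon-by-preparation export for alluvial diagrams
#'
#' Restricts the dataset to its `top_n` taxa by UR and emits one row per
#' (taxon, preparation) combination with its UR count -- the input format
#' generic alluvial/sankey tools consume. The per-taxon row sums equal the
#' taxa's total UR in the ranking (exact conservation).
#'
#' @param dataset A `survey_dataset`.
#' @param top_n Number of leading taxa to keep (default 30).
#' @return A tibble `(taxon_key, preparation, ur)` sorted by the taxon's
#'   rank then preparation.
#' @export
alluvial_export <- function(dataset, top_n = 30) {
  assert_dataset(dataset)
  top_n <- assert_count(top_n, "top_n", min = 1)
  ranking <- rank_entities(dataset, "taxon")
  keep <- head(ranking$entity, top_n)
  dataset$records |>
    dplyr::filter(.data$taxon_key %in% keep) |>
    dplyr::count(.data$taxon_key, .data$preparation, name = "ur") |>
    dplyr::mutate(.rank = match(.data$taxon_key, keep)) |>
    dplyr::arrange(.data$.rank, .data$preparation) |>
    dplyr::select("taxon_key", "preparation", "ur")
}
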