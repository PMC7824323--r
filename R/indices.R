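#' Ethnobotanicity index (EI)
#'
#' The percentage of a territory's autochthonous flora that carries a
#' recorded traditional use: `EI = 100 * n_used_taxa / flora_size`. In the
#' wild-food-plant setting `n_used_taxa` counts the taxa determined at
#' specific or subspecific level, and `flora_size` is a floristic estimate
#' for the territory (default context in this package: 4200 autochthonous
#' taxa for the Catalan linguistic area).
#'
#' @param n_used_taxa Count of used taxa, `0 <= n_used_taxa <= flora_size`.
#' @param flora_size Positive count of flora taxa.
#' @param digits Display rounding (decimal places); `NULL` for the exact
#'   quotient.
#' @return The index as a percentage.
#' @export
#' @examples
#' compute_ei(278, 4200)        # 6.62
#' compute_ei(419, 8882 - 136)  # 4.79
compute_ei <- function(n_used_taxa, flora_size, digits = 2) {
  flora_size <- assert_count(flora_size, "flora_size", min = 1)
  n_used_taxa <- assert_count(n_used_taxa, "n_used_taxa", min = 0)
  if (n_used_taxa > flora_size) {
    abort("`n_used_taxa` cannot exceed `flora_size`.")
  }
  share_percent(n_used_taxa, flora_size, digits)
}

#' Informant consensus factor (F_IC)
#'
#' `F_IC = (n_ur - n_used_taxa) / (n_ur - 1)`: the ratio of the number of
#' use reports minus the number of used taxa to the number of use reports
#' minus one. Values near 1 indicate that many reports converge on few
#' taxa, i.e. a strong consensus among informants; the index is 0 when
#' every report cites a different taxon.
#'
#' @param n_ur Number of use reports, at least 2.
#' @param n_used_taxa Number of used taxa, `1 <= n_used_taxa <= n_ur`.
#' @param digits Display rounding; `NULL` for the exact ratio.
#' @return The factor in `[0, 1]`.
#' @export
#' @examples
#' compute_fic(10078, 278)  # 0.97
#' compute_fic(5, 1)        # 1
compute_fic <- function(n_ur, n_used_taxa, digits = 2) {
  n_ur <- assert_count(n_ur, "n_ur", min = 0)
  if (n_ur < 2) {
    abort("F_IC is undefined for fewer than 2 use reports.")
  }
  n_used_taxa <- assert_count(n_used_taxa, "n_used_taxa", min = 1)
  if (n_used_taxa > n_ur) {
    abort("`n_used_taxa` cannot exceed `n_ur`.")
  }
  out <- (n_ur - n_used_taxa) / (n_ur - 1)
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Cultural importance index (CI)
#'
#' For each taxon, the sum over use categories of the proportion of
#' informants that cite the taxon in that category:
#' `CI_s = (1/N) * sum_c |{informants citing s in c}|`, with `N` the total
#' number of informants surveyed. An informant counts once per
#' (taxon, category) no matter how many parts or preparation sub-forms they
#' reported. With the default single food-use category the index reduces to
#' the proportion of informants citing the taxon at all, so `CI_s * N` is an
#' integer and the CI ranking equals the distinct-informant ranking; with
#' `category_scheme = "by_preparation"` each canonical preparation mode is a
#' category and `CI_s` can approach the number of categories.
#'
#' @param dataset A `survey_dataset`.
#' @param category_scheme `"single_food"` (default) or `"by_preparation"`.
#' @return A tibble `(taxon_key, ci)` sorted by decreasing CI then key.
#' @export
compute_ci <- function(dataset, category_scheme = c("single_food", "by_preparation")) {
  assert_dataset(dataset)
  category_scheme <- match.arg(category_scheme)
  n <- n_informants(dataset)
  if (n == 0) {
    abort("CI is undefined with an empty informant registry.")
  }
  recs <- dataset$records
  if (category_scheme == "single_food") {
    recs$category <- "food"
  } else {
    recs$category <- recs$preparation
  }
  out <- recs |>
    dplyr::distinct(.data$taxon_key, .data$category, .data$informant_id) |>
    dplyr::count(.data$taxon_key, .data$category, name = "n_informants") |>
    dplyr::group_by(.data$taxon_key) |>
    dplyr::summarise(ci = sum(.data$n_informants) / n, .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$ci), .data$taxon_key)
  out
}

#' Reliability filter on minimum independent informants
#'
#' An established convention treats a plant use as reliable when it is
#' backed by reports from at least `min_informants` independent informants
#' (three, by default). The filter is applied to taxa determined at
#' specific or subspecific rank; "independent" means distinct
#' `informant_id` values.
#'
#' @param dataset A `survey_dataset`.
#' @param min_informants Minimum distinct informants, at least 1.
#' @return A list with `kept` (character vector of taxon keys, sorted),
#'   `n_kept`, `n_total` (cited specific-rank taxa) and `kept_percent`
#'   (display-rounded share of kept over total).
#' @export
reliability_filter <- function(dataset, min_informants = 3) {
  assert_dataset(dataset)
  min_informants <- assert_count(min_informants, "min_informants", min = 1)
  spec_keys <- dataset$taxa$key[dataset$taxa$rank == "species_or_below"]
  cited <- dataset$records |>
    dplyr::filter(.data$taxon_key %in% spec_keys) |>
    dplyr::distinct(.data$taxon_key, .data$informant_id) |>
    dplyr::count(.data$taxon_key, name = "n_informants")
  kept <- sort(cited$taxon_key[cited$n_informants >= min_informants])
  n_total <- nrow(cited)
  list(
    kept = kept,
    n_kept = length(kept),
    n_total = n_total,
    kept_percent = if (n_total > 0) share_percent(length(kept), n_total) else NA_real_
  )
}

#' Full index report for a dataset
#'
#' Computes EI, F_IC and per-taxon CI together with the counts that
#' produced them, under a run configuration. EI and F_IC follow the
#' specific/subspecific-rank convention for the used-taxa count; the F_IC
#' use-report denominator is either all UR (default) or only UR citing
#' specific-rank taxa, controlled by `config$percentage_denominator`.
#'
#' @param dataset A `survey_dataset`.
#' @param config A [run_config()].
#' @param category_scheme Passed to [compute_ci()].
#' @return An `index_report` list: `ei_percent`, `fic`, `ci_by_taxon`,
#'   `reliability` and `counts`.
#' @export
index_report <- function(dataset, config = run_config(),
                         category_scheme = c("single_food", "by_preparation")) {
  assert_dataset(dataset)
  category_scheme <- match.arg(category_scheme)
  n_spec <- n_taxa(dataset, "species_or_below")
  if (n_spec == 0) {
    abort("Index report needs at least one specific-rank taxon cited.")
  }
  flora <- if (is.null(config$flora_size)) dataset$flora_size else config$flora_size
  nur <- switch(config$percentage_denominator,
    all_ur = n_ur(dataset),
    specific_rank_ur = specific_rank_ur(dataset)
  )
  rel <- reliability_filter(dataset, config$reliability_min_informants)
  out <- list(
    ei_percent = compute_ei(n_spec, flora, digits = config$rounding),
    fic = compute_fic(nur, n_spec, digits = config$rounding),
    ci_by_taxon = compute_ci(dataset, category_scheme),
    reliability = rel,
    counts = list(
      n_used_taxa = n_spec,
      n_taxa_all = n_taxa(dataset),
      flora_size = flora,
      n_ur = n_ur(dataset),
      n_ur_denominator = nur,
      n_informants = n_informants(dataset)
    )
  )
  class(out) <- "index_report"
  out
}

specific_rank_ur <- function(dataset) {
  spec_keys <- dataset$taxa$key[dataset$taxa$rank == "species_or_below"]
  sum(dataset$records$taxon_key %in% spec_keys)
}

#' @export
print.index_report <- function(x, ...) {
  cat("<index_report>\n")
  cat(sprintf("  EI   : %.2f%% (%d of %d flora taxa)\n",
              x$ei_percent, x$counts$n_used_taxa, x$counts$flora_size))
  cat(sprintf("  F_IC : %.2f (%d UR, %d taxa)\n",
              x$fic, x$counts$n_ur_denominator, x$counts$n_used_taxa))
  cat(sprintf("  CI   : top taxon %s (%.2f)\n",
              x$ci_by_taxon$taxon_key[1], x$ci_by_taxon$ci[1]))
  cat(sprintf("  reliability: %d of %d specific-rank taxa kept (%.2f%%)\n",
              x$reliability$n_kept, x$reliability$n_total,
              x$reliability$kept_percent))
  invisible(x)
}
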