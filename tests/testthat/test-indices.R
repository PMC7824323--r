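test_that("ethnobotanicity index is the flora share as a percentage", {
  expect_equal(compute_ei(278, 4200), 6.62)
  expect_equal(compute_ei(419, 8746), 4.79)
  expect_equal(compute_ei(0, 4200), 0)
  expect_equal(compute_ei(4200, 4200), 100)
  # linear in the numerator
  expect_equal(compute_ei(200, 1000, digits = NULL),
               2 * compute_ei(100, 1000, digits = NULL))
  expect_error(compute_ei(10, 0), "flora_size")
  expect_error(compute_ei(10, 5), "exceed")
})

test_that("informant consensus factor follows (UR - taxa) / (UR - 1)", {
  expect_equal(compute_fic(10078, 278), 0.97)
  expect_equal(compute_fic(5, 1), 1)
  for (k in c(2, 7, 100)) expect_equal(compute_fic(k, k), 0)
  expect_error(compute_fic(1, 1), "fewer than 2")
  expect_error(compute_fic(5, 6), "exceed")
})

test_that("F_IC is monotone in both arguments", {
  ur <- seq(10, 200, by = 10)
  vals_ur <- vapply(ur, compute_fic, numeric(1), n_used_taxa = 8, digits = NULL)
  expect_true(all(diff(vals_ur) > 0))
  taxa <- 1:49
  vals_tx <- vapply(taxa, function(t) compute_fic(50, t, digits = NULL), numeric(1))
  expect_true(all(diff(vals_tx) < 0))
})

test_that("CI sums informant proportions per use category", {
  # N = 4, taxon cited by 2 informants, single food category -> 0.50
  recs <- tibble::tibble(
    informant_id = c("a", "b"), study_id = "s",
    taxon_key = "thymus vulgaris", part = "leaf",
    preparation = c("raw", "condiment")
  )
  taxa <- normalize_name("Thymus vulgaris L.")
  taxa$family <- "Lamiaceae"
  inf4 <- tibble::tibble(informant_id = c("a", "b", "c", "d"))
  ds <- survey_dataset(recs, inf4, taxa, 4200)
  expect_equal(compute_ci(ds, "single_food")$ci, 0.5)

  # one informant, two preparation categories -> (1 + 1) / 4
  recs2 <- tibble::tibble(
    informant_id = "a", study_id = "s", taxon_key = "thymus vulgaris",
    part = c("leaf", "leaf"), preparation = c("raw", "cooked")
  )
  ds2 <- survey_dataset(recs2, inf4, taxa, 4200)
  expect_equal(compute_ci(ds2, "by_preparation")$ci, 0.5)
  expect_equal(compute_ci(ds2, "single_food")$ci, 0.25)
})

test_that("CI equals the incidence-cube oracle on synthetic data", {
  ds <- generate_survey(small_synth_config(seed = 11))
  for (scheme in c("single_food", "by_preparation")) {
    got <- dplyr::arrange(compute_ci(ds, scheme), taxon_key)
    want <- dplyr::arrange(oracle_ci(ds, scheme), taxon_key)
    expect_equal(got$taxon_key, want$taxon_key)
    expect_equal(got$ci, want$ci, tolerance = 1e-12)
  }
})

test_that("single-food CI times N is an integer matching informant counts", {
  ds <- generate_survey(small_synth_config(seed = 12))
  ci <- compute_ci(ds, "single_food")
  n <- n_informants(ds)
  expect_equal(ci$ci * n, round(ci$ci * n), tolerance = 1e-9)
  counts <- ds$records |>
    dplyr::distinct(taxon_key, informant_id) |>
    dplyr::count(taxon_key)
  m <- match(ci$taxon_key, counts$taxon_key)
  expect_equal(ci$ci * n, as.numeric(counts$n[m]))
  # CI ordering equals informant-count ordering
  expect_true(all(diff(counts$n[m]) <= 0))
})

test_that("reliability filter keeps specific-rank taxa with enough informants", {
  # taxa cited by 5, 3, 2, 1 informants; threshold 3 keeps two of four
  mk <- function(tx, n) tibble::tibble(
    informant_id = sprintf("i%02d", seq_len(n)), study_id = "s",
    taxon_name = tx, family = "Famaceae", part = "leaf", preparation = "raw"
  )
  rows <- dplyr::bind_rows(
    mk("Aus alpha", 5), mk("Bus beta", 3), mk("Cus gamma", 2), mk("Dus delta", 1),
    mk("Eus sp.", 4)  # genus-only: never counted in the filter
  )
  ds <- dedupe_records(rows)
  res <- reliability_filter(ds, 3)
  expect_equal(res$n_kept, 2L)
  expect_equal(res$n_total, 4L)
  expect_equal(res$kept_percent, 50)
  expect_setequal(res$kept, c("aus alpha", "bus beta"))
  all_in <- reliability_filter(ds, 1)
  expect_equal(all_in$n_kept, 4L)
  expect_equal(all_in$kept_percent, 100)
})

test_that("indices are invariant under informant relabeling", {
  ds <- generate_survey(small_synth_config(seed = 13))
  relabel <- setNames(sprintf("R%04d", sample(9999, n_informants(ds))),
                      ds$informants$informant_id)
  recs <- dplyr::mutate(ds$records, informant_id = unname(relabel[informant_id]))
  inf <- dplyr::mutate(ds$informants, informant_id = unname(relabel[informant_id]))
  ds2 <- survey_dataset(recs, inf, ds$taxa, ds$flora_size)
  r1 <- index_report(ds)
  r2 <- index_report(ds2)
  expect_identical(r1$ei_percent, r2$ei_percent)
  expect_identical(r1$fic, r2$fic)
  expect_identical(sort(r1$ci_by_taxon$ci), sort(r2$ci_by_taxon$ci))
  expect_identical(r1$reliability$n_kept, r2$reliability$n_kept)
})

test_that("index report wires counts, denominators and errors correctly", {
  ds <- generate_survey(small_synth_config(seed = 14))
  rep_all <- index_report(ds, run_config())
  rep_spec <- index_report(ds, run_config(percentage_denominator = "specific_rank_ur"))
  expect_equal(rep_all$counts$n_ur_denominator, n_ur(ds))
  expect_lt(rep_spec$counts$n_ur_denominator, n_ur(ds))
  expect_equal(rep_all$counts$n_used_taxa, n_taxa(ds, "species_or_below"))
  # empty informant registry / empty dataset error cleanly
  empty <- survey_dataset(
    tibble::tibble(informant_id = character(), study_id = character(),
                   taxon_key = character(), part = character(),
                   preparation = character()),
    tibble::tibble(informant_id = character()),
    tibble::tibble(key = character(), rank = character(), family = character()),
    4200
  )
  expect_error(compute_ci(empty), "empty informant registry")
  expect_error(index_report(empty), "at least one")
})
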