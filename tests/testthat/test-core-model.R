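test_that("duplicate tuples collapse and distinct tuples survive", {
  base <- toy_rows()[1, ]
  two_same <- dplyr::bind_rows(base, base)
  ds <- dedupe_records(two_same)
  expect_equal(n_ur(ds), 1L)
  expect_equal(attr(ds, "n_collapsed"), 1L)

  two_parts <- dplyr::bind_rows(base, dplyr::mutate(base, part = "fruit"))
  expect_equal(n_ur(dedupe_records(two_parts)), 2L)

  # authorship variants of the same name are the same taxon
  synonymous <- dplyr::bind_rows(
    base, dplyr::mutate(base, taxon_name = "Thymus vulgaris")
  )
  expect_equal(n_ur(dedupe_records(synonymous)), 1L)
})

test_that("dedupe is a set quotient, independent of row order", {
  # 200-row fixture with 37 planted duplicate rows
  set.seed(404)
  uniq <- tibble::tibble(
    informant_id = sprintf("i%02d", sample(30, 163, replace = TRUE)),
    study_id = sample(c("s1", "s2"), 163, replace = TRUE),
    taxon_name = paste0("Genus ", sample(letters, 163, replace = TRUE), "us"),
    family = "Famaceae",
    part = sample(part_categories()$label, 163, replace = TRUE),
    preparation = sample(prep_categories()$label, 163, replace = TRUE)
  )
  uniq <- uniq[!duplicated(paste(uniq$informant_id, uniq$taxon_name,
                                 uniq$part, uniq$preparation)), ]
  # top up to exactly 163 unique tuples
  while (nrow(uniq) < 163) {
    extra <- uniq[sample(nrow(uniq), 1), ]
    extra$informant_id <- sprintf("i%02d", sample(99, 1))
    uniq <- dplyr::bind_rows(uniq, extra)
    uniq <- uniq[!duplicated(paste(uniq$informant_id, uniq$taxon_name,
                                   uniq$part, uniq$preparation)), ]
  }
  rows <- dplyr::bind_rows(uniq, uniq[sample(163, 37, replace = TRUE), ])
  expect_equal(nrow(rows), 200L)

  shuffled <- rows[sample(nrow(rows)), ]
  ds1 <- dedupe_records(rows)
  ds2 <- dedupe_records(shuffled)
  expect_equal(n_ur(ds1), oracle_distinct_tuples(rows))
  expect_equal(n_ur(ds1), 163L)
  expect_identical(ds1$records, ds2$records)
})

test_that("record order never changes downstream index values", {
  ds <- generate_survey(small_synth_config(seed = 5))
  perm <- ds
  perm$records <- perm$records[sample(nrow(perm$records)), ]
  perm <- survey_dataset(perm$records, perm$informants, perm$taxa,
                         perm$flora_size)
  expect_identical(index_report(ds)$ei_percent, index_report(perm)$ei_percent)
  expect_identical(index_report(ds)$fic, index_report(perm)$fic)
  expect_identical(compute_ci(ds), compute_ci(perm))
  expect_identical(rank_entities(ds, "family"), rank_entities(perm, "family"))
})

test_that("dataset invariants are enforced at construction", {
  rows <- toy_rows()
  ds <- dedupe_records(rows)
  # unresolved informant
  expect_error(
    survey_dataset(dplyr::mutate(ds$records, informant_id = "ghost"),
                   ds$informants, ds$taxa, 4200),
    "missing from registry"
  )
  # duplicate tuples rejected
  expect_error(
    survey_dataset(dplyr::bind_rows(ds$records, ds$records[1, ]),
                   ds$informants, ds$taxa, 4200),
    "duplicate"
  )
  # non-canonical labels rejected
  expect_error(
    survey_dataset(dplyr::mutate(ds$records, part = "stalk"),
                   ds$informants, ds$taxa, 4200),
    "Non-canonical part"
  )
  # flora smaller than used taxa
  expect_error(survey_dataset(ds$records, ds$informants, ds$taxa, 2),
               "flora_size")
  # conflicting family attribution caught in dedupe
  clash <- dplyr::bind_rows(rows, dplyr::mutate(rows[1, ], family = "Rosaceae"))
  expect_error(dedupe_records(clash), "Conflicting family")
})

test_that("vocabulary maps are total and reject unmapped labels", {
  vm <- vocabulary_map(c("young leaf", "fulla"), c("leaf", "leaf"), "part")
  expect_equal(apply_vocabulary(c("Young  Leaf", "root", "fulla"), vm),
               c("leaf", "root", "leaf"))
  expect_error(apply_vocabulary("stalk", vm), "stalk")
  expect_error(vocabulary_map("x", "stalk", "part"), "closed vocabulary")
  expect_error(vocabulary_map(c("a", "A"), c("leaf", "stem"), "part"),
               "Duplicate raw labels")
  # superclass partition of the part vocabulary
  expect_equal(part_superclass(c("leaf", "fruit", "root", "product", "unknown")),
               c("aerial", "aerial", "subterranean", "product", "unknown"))
})
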