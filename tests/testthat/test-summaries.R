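test_that("rankings reproduce forced toy arithmetic", {
  mk <- function(fam, tx, n) tibble::tibble(
    informant_id = sprintf("%s%02d", tx, seq_len(n)), study_id = "s",
    taxon_name = tx, family = fam, part = "leaf", preparation = "raw"
  )
  ds <- dedupe_records(dplyr::bind_rows(
    mk("Aaceae", "Aus alpha", 6), mk("Baceae", "Bus beta", 3),
    mk("Caceae", "Cus gamma", 1)
  ))
  fam <- rank_entities(ds, "family")
  expect_equal(fam$entity, c("Aaceae", "Baceae", "Caceae"))
  expect_equal(fam$ur_percent, c(60, 30, 10))
  expect_equal(fam$n_taxa, c(1L, 1L, 1L))
  expect_equal(sum(fam$ur), attr(fam, "denominator_n"))

  one <- dedupe_records(mk("Aaceae", "Aus alpha", 4))
  rt <- rank_entities(one, "taxon")
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$ur_percent, 100)
  expect_error(rank_entities(one, "nope"))
})

test_that("rankings equal the naive group-by oracle on synthetic data", {
  ds <- generate_survey(small_synth_config(seed = 21))
  for (lev in c("taxon", "genus", "family")) {
    got <- rank_entities(ds, lev)
    want <- oracle_group_ur(ds, lev)
    expect_equal(got$entity, want$entity)
    expect_equal(got$ur, want$ur)
    expect_equal(got$ur_percent, 100 * want$ur / n_ur(ds))
    expect_equal(got$rank, seq_len(nrow(got)))
  }
})

test_that("mean_sd uses the sample (n-1) denominator", {
  expect_equal(mean_sd(c(5, 5, 5)), list(mean = 5, sd = 0))
  expect_equal(mean_sd(c(1, 2, 3)), list(mean = 2, sd = 1))
  expect_error(mean_sd(7), "at least 2")
  expect_error(mean_sd(numeric()), "non-empty")
  set.seed(31)
  for (i in 1:25) {
    x <- sample(1000, sample(2:40, 1), replace = TRUE)
    got <- mean_sd(x)
    want <- oracle_mean_sd(x)
    expect_equal(got$mean, want$mean, tolerance = 1e-9)
    expect_equal(got$sd, want$sd, tolerance = 1e-9)
  }
})

test_that("top_share accumulates leading rows over the right denominator", {
  tbl <- tibble::tibble(ur = c(6, 3, 1))
  expect_equal(top_share(tbl, 1), 60)
  expect_equal(top_share(tbl, 3), 100)
  expect_error(top_share(tbl, 4), "exceeds")
  ds <- generate_survey(small_synth_config(seed = 22))
  rk <- rank_entities(ds, "taxon")
  expect_equal(top_share(rk, nrow(rk)), 100)
  expect_equal(top_share(rk, 5, digits = NULL),
               100 * sum(rk$ur[1:5]) / n_ur(ds))
})

test_that("distributions cover every category and conserve percent mass", {
  mk <- function(part, n, off = 0) tibble::tibble(
    informant_id = sprintf("i%02d", off + seq_len(n)), study_id = "s",
    taxon_name = "Aus alpha", family = "Aaceae", part = part,
    preparation = "raw"
  )
  ds <- dedupe_records(dplyr::bind_rows(mk("leaf", 3), mk("root", 1, off = 3)))
  d <- distribution(ds, "part", rollup = TRUE)
  cats <- d[d$level == "category", ]
  expect_equal(cats$category, part_categories()$label)
  expect_equal(cats$percent[cats$category == "leaf"], 75)
  expect_equal(cats$percent[cats$category == "root"], 25)
  roll <- d[d$level == "superclass", ]
  expect_equal(roll$percent[roll$category == "aerial"], 75)
  expect_equal(roll$percent[roll$category == "subterranean"], 25)
  expect_equal(sum(cats$percent), 100)
  expect_equal(sum(roll$percent), 100)
  expect_error(distribution(ds, "preparation", rollup = TRUE), "part axis")

  # synthetic data vs base-R table oracle
  synth <- generate_survey(small_synth_config(seed = 23))
  for (axis in c("part", "preparation")) {
    got <- distribution(synth, axis)
    tab <- table(synth$records[[if (axis == "part") "part" else "preparation"]])
    expect_equal(got$ur[match(names(tab), got$category)], as.integer(tab))
    expect_equal(sum(got$percent), 100, tolerance = 1e-9)
  }
})

test_that("alluvial export conserves per-taxon UR against the ranking", {
  ds <- generate_survey(small_synth_config(seed = 24))
  allu <- alluvial_export(ds, top_n = 10)
  rk <- rank_entities(ds, "taxon")
  marg <- tapply(allu$ur, allu$taxon_key, sum)
  top10 <- rk[rk$rank <= 10, ]
  expect_setequal(names(marg), top10$entity)
  expect_identical(as.integer(marg[top10$entity]), top10$ur)
  # two-key group-by oracle
  key <- paste(ds$records$taxon_key, ds$records$preparation, sep = "\r")
  tab <- table(key)
  allu_key <- paste(allu$taxon_key, allu$preparation, sep = "\r")
  expect_equal(allu$ur, as.integer(tab[allu_key]))
  # single-taxon dataset: full breakdown of that taxon
  one <- dedupe_records(tibble::tibble(
    informant_id = c("a", "b"), study_id = "s", taxon_name = "Aus alpha",
    family = "Aaceae", part = "leaf", preparation = c("raw", "cooked")
  ))
  expect_equal(sum(alluvial_export(one, 1)$ur), 2L)
})

test_that("display rounding is half-up and exact arithmetic is preserved", {
  expect_equal(round_half_up(6.619048), 6.62)
  expect_equal(round_half_up(56.475), 56.48)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(share_percent(157, 278), 56.47)
  expect_equal(share_percent(157, 278, NULL), 100 * 157 / 278)
  expect_error(share_percent(5, 0), "positive")
  expect_error(share_percent(6, 5), "\\[0, n\\]")
})
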