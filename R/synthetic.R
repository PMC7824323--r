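# Default category probabilities emulate the published category shares of
# the Catalan-linguistic-area wild food plant survey. The printed part
# superclass percentages (aerial 91.59, subterranean 2.20, product 0.17,
# unknown 4.70) sum to 98.66, not 100; we renormalize proportionally. The
# within-superclass split is not published and is a package choice (leaf-
# and fruit-dominated, as is typical for Mediterranean wild food floras).
default_part_probs <- function() {
  sup <- c(aerial = 91.59, subterranean = 2.20, product = 0.17, unknown = 4.70)
  sup <- sup / sum(sup)
  aerial_split <- c(leaf = 0.28, fruit = 0.24, aerial_part = 0.19,
                    stem = 0.13, flower = 0.10, whole_plant = 0.06)
  sub_split <- c(root = 0.5, tuber = 0.2, bulb = 0.2, rhizome = 0.1)
  probs <- c(
    aerial_split * sup[["aerial"]],
    sub_split * sup[["subterranean"]],
    product = sup[["product"]],
    unknown = sup[["unknown"]]
  )
  probs[part_categories()$label]
}

default_prep_probs <- function() {
  c(raw = 0.3477, condiment = 0.3271, cooked = 0.1922,
    preserved = 0.0371, curd = 0.0216, unknown = 0.0743)
}

#' Configuration for the synthetic survey generator
#'
#' The defaults are the study conditions of the Catalan-linguistic-area
#' wild food plant dataset this generator emulates: 1659 informants (53.65%
#' men), 291 taxa (278 specific/subspecific + 13 genus-only) in 193 genera
#' and 67 families across 31 studies, 10,078 use reports with heavy-tailed
#' per-taxon counts, and the published part/preparation category shares.
#' The Zipf exponent (0.826) is calibrated so that the expected share of
#' the most-cited taxon is 9.50% of all UR, matching the published top
#' taxon (957 of 10,078).
#'
#' @param n_informants,n_taxa_specific,n_taxa_genus_only,n_genera,n_families,n_studies
#'   Registry sizes.
#' @param target_ur Exact number of distinct use records to generate.
#' @param zipf_exponent Positive decay exponent of taxon popularity.
#' @param part_probs,prep_probs Named probability vectors over the
#'   canonical vocabularies; must sum to 1 (tolerance 1e-9).
#' @param gender_split Proportion of men among informants.
#' @param max_records_per_pair Cap on use records per informant-taxon pair
#'   (the unknowable real joint distribution is exposed as this knob).
#' @param flora_size Floristic context stored on the generated dataset.
#' @param seed Integer seed; same seed, same dataset, byte for byte.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_informants = 1659,
                             n_taxa_specific = 278,
                             n_taxa_genus_only = 13,
                             n_genera = 193,
                             n_families = 67,
                             n_studies = 31,
                             target_ur = 10078,
                             zipf_exponent = 0.826,
                             part_probs = default_part_probs(),
                             prep_probs = default_prep_probs(),
                             gender_split = 0.5365,
                             max_records_per_pair = 3,
                             flora_size = 4200,
                             seed = 1L) {
  n_informants <- assert_count(n_informants, "n_informants", min = 1)
  n_taxa_specific <- assert_count(n_taxa_specific, "n_taxa_specific", min = 1)
  n_taxa_genus_only <- assert_count(n_taxa_genus_only, "n_taxa_genus_only", min = 0)
  n_genera <- assert_count(n_genera, "n_genera", min = 1)
  n_families <- assert_count(n_families, "n_families", min = 1)
  n_studies <- assert_count(n_studies, "n_studies", min = 1)
  target_ur <- assert_count(target_ur, "target_ur", min = 1)
  seed <- assert_count(seed, "seed", min = 0)
  max_records_per_pair <- assert_count(max_records_per_pair, "max_records_per_pair", min = 1)
  if (!is.numeric(zipf_exponent) || zipf_exponent <= 0) {
    abort("`zipf_exponent` must be positive.")
  }
  if (gender_split < 0 || gender_split > 1) {
    abort("`gender_split` must lie in [0, 1].")
  }
  check_probs <- function(p, labels, what) {
    if (!all(labels %in% names(p)) || length(p) != length(labels)) {
      abort(paste0("`", what, "` must be named over: ", toString(labels)))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0("`", what, "` must be non-negative and sum to 1."))
    }
    p[labels]
  }
  part_probs <- check_probs(part_probs, part_categories()$label, "part_probs")
  prep_probs <- check_probs(prep_probs, prep_categories()$label, "prep_probs")
  n_taxa <- n_taxa_specific + n_taxa_genus_only
  capacity <- as.double(n_informants) * n_taxa *
    sum(part_probs > 0) * sum(prep_probs > 0)
  if (target_ur > capacity) {
    abort("`target_ur` exceeds the number of distinct tuples available.")
  }
  if (n_genera < n_taxa_genus_only) {
    abort("Need at least as many genera as genus-only taxa.")
  }
  structure(
    list(
      n_informants = n_informants, n_taxa_specific = n_taxa_specific,
      n_taxa_genus_only = n_taxa_genus_only, n_genera = n_genera,
      n_families = n_families, n_studies = n_studies, target_ur = target_ur,
      zipf_exponent = zipf_exponent, part_probs = part_probs,
      prep_probs = prep_probs, gender_split = gender_split,
      max_records_per_pair = max_records_per_pair,
      flora_size = flora_size, seed = seed
    ),
    class = "synthetic_config"
  )
}

#' Closed-form F_IC implied by a generator configuration
#'
#' `(target_ur - n_taxa_specific) / (target_ur - 1)`, the informant
#' consensus factor the generated dataset will realize given that the
#' generator guarantees every taxon at least one citation. Useful for
#' planning simulation experiments.
#'
#' @param config A [synthetic_config()].
#' @return The expected consensus factor.
#' @export
#' @examples
#' expected_fic(synthetic_config())  # ~0.97
expected_fic <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config.")
  }
  if (config$target_ur < 2) {
    abort("F_IC is undefined for fewer than 2 use reports.")
  }
  (config$target_ur - config$n_taxa_specific) / (config$target_ur - 1)
}

# Pronounceable deterministic identifiers: index -> syllable string.
SYLLABLES <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni",
               "po", "ru", "sa", "te", "vi", "xo", "zu")

syllable_name <- function(i, n_syl = 4) {
  base <- length(SYLLABLES)
  out <- character(length(i))
  for (k in seq_along(i)) {
    v <- i[k] - 1
    digs <- integer(n_syl)
    for (d in seq_len(n_syl)) {
      digs[d] <- v %% base
      v <- v %/% base
    }
    out[k] <- paste(SYLLABLES[digs + 1], collapse = "")
  }
  out
}

#' Generate a synthetic use-report survey
#'
#' Draws a fully validated [survey_dataset()] with the statistical
#' structure described by the configuration: taxon popularity follows a
#' truncated Zipf law over ranks (genus-only taxa occupy the tail), every
#' taxon is cited at least once, informants are cited uniformly, part and
#' preparation categories follow the configured probabilities, and exactly
#' `target_ur` distinct `(informant, taxon, part, preparation)` tuples are
#' emitted -- duplicates are rejected and resampled rather than collapsed,
#' so the UR total is exact. Each informant belongs to one study;
#' `study_id` rides along on their records. The draw is a pure function of
#' the configuration: the same seed reproduces the identical dataset.
#'
#' @param config A [synthetic_config()].
#' @return A `survey_dataset`.
#' @export
#' @examples
#' ds <- generate_survey(synthetic_config(
#'   n_informants = 40, n_taxa_specific = 12, n_taxa_genus_only = 2,
#'   n_genera = 10, n_families = 5, target_ur = 300, seed = 7
#' ))
#' n_ur(ds)  # 300
generate_survey <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config.")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n_taxa <- config$n_taxa_specific + config$n_taxa_genus_only

  # --- registries -----------------------------------------------------
  families <- paste0(cap_genus(syllable_name(seq_len(config$n_families), 3)), "aceae")
  genera <- cap_genus(paste0(syllable_name(seq_len(config$n_genera), 3), "us"))
  # heavy-tailed family sizes: genera pick families with Zipf weights
  fam_w <- seq_len(config$n_families)^-1
  genus_family <- families[sample.int(config$n_families, config$n_genera,
                                      replace = TRUE, prob = fam_w)]

  gen_w <- seq_len(config$n_genera)^-1
  spec_genus_idx <- sample.int(config$n_genera, config$n_taxa_specific,
                               replace = TRUE, prob = gen_w)
  epithets <- syllable_name(seq_len(config$n_taxa_specific), 4)
  # a fixed twentieth of the specific taxa are subspecific, to exercise
  # infraspecific keys downstream
  is_subsp <- seq_len(config$n_taxa_specific) %% 20 == 0
  spec <- tibble::tibble(
    genus = genera[spec_genus_idx],
    epithet = epithets,
    infraspecific_rank = ifelse(is_subsp, "subsp.", "none"),
    infraspecific_epithet = ifelse(is_subsp, paste0(epithets, "la"), ""),
    authorship = "",
    rank = "species_or_below",
    family = genus_family[spec_genus_idx]
  )
  taxa <- spec
  if (config$n_taxa_genus_only > 0) {
    gidx <- sample.int(config$n_genera, config$n_taxa_genus_only)
    taxa <- dplyr::bind_rows(taxa, tibble::tibble(
      genus = genera[gidx], epithet = "",
      infraspecific_rank = "none", infraspecific_epithet = "",
      authorship = "", rank = "genus_only", family = genus_family[gidx]
    ))
  }
  taxa$key <- mapply(taxon_key_parts, taxa$genus, taxa$epithet,
                     taxa$infraspecific_rank, taxa$infraspecific_epithet,
                     USE.NAMES = FALSE)
  if (anyDuplicated(taxa$key)) {
    taxa <- dplyr::distinct(taxa, .data$key, .keep_all = TRUE)
    if (nrow(taxa) < n_taxa) {
      abort("Internal: synthetic taxon keys collided.")  # nocov
    }
  }

  informants <- tibble::tibble(
    informant_id = sprintf("inf%05d", seq_len(config$n_informants)),
    gender = ifelse(
      seq_len(config$n_informants) <= round(config$gender_split * config$n_informants),
      "man", "woman"
    ),
    study_id = sprintf("study%02d", sample.int(config$n_studies, config$n_informants,
                                               replace = TRUE))
  )

  # --- per-taxon UR allocation: 1 guaranteed citation + Zipf remainder --
  w <- seq_len(n_taxa)^-config$zipf_exponent
  w <- w / sum(w)
  extra <- config$target_ur - n_taxa
  if (extra < 0) {
    # fewer UR than taxa: cite the most popular ones once each
    counts <- integer(n_taxa)
    counts[seq_len(config$target_ur)] <- 1L
  } else {
    counts <- 1L + as.integer(stats::rmultinom(1, extra, w))
  }

  # ranks 1..n_taxa: specific taxa first (in generated order), genus-only
  # in the tail -- genus-level determinations are rare citations
  taxon_keys <- taxa$key

  part_labels <- part_categories()$label
  prep_labels <- prep_categories()$label

  sample_tuples <- function(k, key, max_per_pair) {
    seen <- character(0)
    out <- vector("list", 0)
    pair_n <- integer(0)   # named: records already drawn per informant
    deficit <- k
    while (deficit > 0) {
      m <- max(deficit * 2L, 16L)
      cand <- tibble::tibble(
        informant_id = informants$informant_id[
          sample.int(config$n_informants, m, replace = TRUE)],
        part = sample(part_labels, m, replace = TRUE, prob = config$part_probs),
        preparation = sample(prep_labels, m, replace = TRUE, prob = config$prep_probs)
      )
      tup <- paste(cand$informant_id, cand$part, cand$preparation, sep = "\r")
      keep <- !duplicated(tup) & !(tup %in% seen)
      cand <- cand[keep, ]
      tup <- tup[keep]
      # enforce the per-informant record cap for this taxon
      prior <- pair_n[cand$informant_id]
      prior[is.na(prior)] <- 0L
      within <- stats::ave(seq_len(nrow(cand)), cand$informant_id, FUN = seq_along)
      ok <- within + prior <= max_per_pair
      cand <- cand[ok, ]
      tup <- tup[ok]
      if (nrow(cand) > deficit) {
        cand <- cand[seq_len(deficit), ]
        tup <- tup[seq_len(deficit)]
      }
      seen <- c(seen, tup)
      newc <- table(cand$informant_id)
      for (nm in names(newc)) {
        cur <- pair_n[nm]
        pair_n[nm] <- if (is.na(cur)) newc[[nm]] else cur + newc[[nm]]
      }
      out[[length(out) + 1]] <- cand
      deficit <- deficit - nrow(cand)
    }
    res <- dplyr::bind_rows(out)
    res$taxon_key <- key
    res
  }

  per_taxon_cap <- config$n_informants *
    min(config$max_records_per_pair,
        sum(config$part_probs > 0) * sum(config$prep_probs > 0))
  if (any(counts > per_taxon_cap)) {
    abort("Allocated UR for a taxon exceed its distinct-tuple capacity; raise `max_records_per_pair` or `n_informants`.")
  }

  recs <- vector("list", n_taxa)
  for (t in seq_len(n_taxa)) {
    if (counts[t] > 0) {
      recs[[t]] <- sample_tuples(counts[t], taxon_keys[t],
                                 config$max_records_per_pair)
    }
  }
  records <- dplyr::bind_rows(recs)
  records$study_id <- informants$study_id[
    match(records$informant_id, informants$informant_id)]

  ds <- survey_dataset(
    records = records[, c("informant_id", "study_id", "taxon_key", "part", "preparation")],
    informants = informants,
    taxa = taxa[, c("key", "genus", "epithet", "infraspecific_rank",
                    "infraspecific_epithet", "authorship", "rank", "family")],
    flora_size = max(config$flora_size, n_taxa)
  )
  attr(ds, "config") <- config
  ds
}
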