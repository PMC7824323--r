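#' Controlled vocabularies for plant part and preparation mode
#'
#' Ethnobotanical surveys record free-text part and preparation labels that
#' must be aggregated into a closed set of analysis categories before any
#' counting. `part_categories()` returns the canonical part vocabulary with
#' its morphological superclass (aerial organs, subterranean organs, plant
#' products such as latex/nectar/sap, or unknown); `prep_categories()`
#' returns the canonical preparation-mode vocabulary. "unknown" is a
#' first-class category in both: unreported parts and preparations are kept
#' and reported as their own share, never dropped.
#'
#' @return A tibble. For parts: columns `label` and `superclass`; for
#'   preparations: column `label`.
#' @export
#' @examples
#' part_categories()
#' prep_categories()
part_categories <- function() {
  tibble::tibble(
    label = c(
      "stem", "leaf", "aerial_part", "whole_plant", "fruit", "flower",
      "root", "tuber", "bulb", "rhizome",
      "product",
      "unknown"
    ),
    superclass = c(
      rep("aerial", 6L),
      rep("subterranean", 4L),
      "product",
      "unknown"
    )
  )
}

#' @rdname part_categories
#' @export
prep_categories <- function() {
  tibble::tibble(
    label = c("raw", "condiment", "cooked", "preserved", "curd", "unknown")
  )
}

#' Superclass of canonical part labels
#'
#' @param label Character vector of canonical part labels.
#' @return Character vector of superclasses (`aerial`, `subterranean`,
#'   `product`, `unknown`).
#' @export
#' @examples
#' part_superclass(c("leaf", "root", "product"))
part_superclass <- function(label) {
  parts <- part_categories()
  bad <- setdiff(unique(label), parts$label)
  if (length(bad) > 0) {
    abort(paste0("Not canonical part labels: ", toString(bad)))
  }
  parts$superclass[match(label, parts$label)]
}

#' Build a vocabulary map
#'
#' A vocabulary map sends raw survey labels (dialectal, orthographic or
#' sub-form variants) to canonical categories. The map must be *total* over
#' any dataset it is applied to: an unmapped label is an error naming the
#' offending labels, never a silent "unknown". Raw labels are matched
#' case-insensitively after whitespace trimming; every canonical label maps
#' to itself so already-clean data needs no explicit map.
#'
#' @param raw Character vector of raw labels.
#' @param canonical Character vector of canonical labels, same length.
#' @param scope `"part"` or `"preparation"`; controls which closed label set
#'   the canonical side is validated against.
#' @return A `vocabulary_map` object (tibble with attributes).
#' @export
#' @examples
#' vm <- vocabulary_map(c("young leaf", "fulla"), c("leaf", "leaf"), "part")
#' apply_vocabulary(c("young leaf", "ROOT"), vm)
vocabulary_map <- function(raw = character(), canonical = character(),
                           scope = c("part", "preparation")) {
  scope <- match.arg(scope)
  if (length(raw) != length(canonical)) {
    abort("`raw` and `canonical` must have the same length.")
  }
  allowed <- if (scope == "part") part_categories()$label else prep_categories()$label
  bad <- setdiff(unique(canonical), allowed)
  if (length(bad) > 0) {
    abort(paste0(
      "Canonical ", scope, " labels not in the closed vocabulary: ",
      toString(bad)
    ))
  }
  key <- norm_label(raw)
  if (anyDuplicated(key)) {
    dup <- unique(raw[duplicated(key)])
    abort(paste0("Duplicate raw labels in vocabulary map: ", toString(dup)))
  }
  # identity entries for canonical labels come last so user rows win
  tbl <- tibble::tibble(raw_key = key, canonical = canonical)
  ident <- tibble::tibble(raw_key = setdiff(allowed, key), canonical = setdiff(allowed, key))
  out <- dplyr::bind_rows(tbl, ident)
  structure(out, scope = scope, class = c("vocabulary_map", class(out)))
}

norm_label <- function(x) stringr::str_to_lower(stringr::str_squish(x))

#' Apply a vocabulary map to raw labels
#'
#' @param labels Character vector of raw labels.
#' @param map A [vocabulary_map()].
#' @return Character vector of canonical labels.
#' @export
apply_vocabulary <- function(labels, map) {
  if (!inherits(map, "vocabulary_map")) {
    abort("`map` must be a vocabulary_map.")
  }
  key <- norm_label(labels)
  idx <- match(key, map$raw_key)
  if (anyNA(idx)) {
    miss <- unique(labels[is.na(idx)])
    abort(paste0(
      "Unmapped ", attr(map, "scope"), " labels (vocabulary must be total): ",
      toString(miss)
    ))
  }
  map$canonical[idx]
}

#' Read a vocabulary map from a two-column CSV
#'
#' Expected header: `raw,canonical`.
#'
#' @param path CSV file path.
#' @inheritParams vocabulary_map
#' @return A [vocabulary_map()].
#' @export
read_vocabulary <- function(path, scope = c("part", "preparation")) {
  scope <- match.arg(scope)
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("raw", "canonical")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("Vocabulary file ", path, " is missing columns: ", toString(miss)))
  }
  vocabulary_map(tbl$raw, tbl$canonical, scope)
}
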