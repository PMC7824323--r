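# Token grammar for botanical name strings.
# A name is: Genus [epithet [authorship] [rank-marker infra-epithet [authorship]]]
# Authorship (author abbreviations, "in", "ex", parenthesised basionym
# authors) is recognised positionally -- everything between the epithet and a
# rank marker, and everything after the infraspecific epithet -- and is
# discarded from the match key so that studies citing different author
# abbreviations agree on the same taxon.
RX_GENUS <- "^×?[A-Za-z][a-zë-]*$"
RX_EPITHET <- "^×?[a-z][a-zë-]+$"
RX_SP <- "^(sp|spp)\\.?$"
RANK_MARKERS <- c(
  "subsp." = "subsp.", "subsp" = "subsp.", "ssp." = "subsp.", "ssp" = "subsp.",
  "var." = "var.", "var" = "var."
)

#' Normalize a botanical name
#'
#' Parses raw scientific-name strings as they appear in survey tables
#' ("Foeniculum vulgare Mill. subsp. piperitum (Ucria) Cout.") into a taxon
#' record with the authorship stripped and the rank inferred, and derives
#' the *normalization key*: the lowercase `"genus epithet"` (plus
#' `"subsp."`/`"var."` and infraspecific epithet when present) on which all
#' matching, deduplication and counting in this package operates. Two names
#' with equal keys are the same taxon. Names determined only to genus
#' ("Mentha sp.", or a bare genus) get rank `genus_only`.
#'
#' The function is deterministic and idempotent: feeding a key back in
#' returns the same key. No fuzzy matching or synonym resolution against
#' taxonomic backbones is attempted.
#'
#' @param raw Character vector of name strings.
#' @return A tibble with one row per input: `input`, `genus`, `epithet`,
#'   `infraspecific_rank` (`"none"`, `"subsp."` or `"var."`),
#'   `infraspecific_epithet`, `authorship`, `rank` (`"species_or_below"` or
#'   `"genus_only"`) and `key`.
#' @export
#' @examples
#' normalize_name("Thymus vulgaris L.")$key
#' normalize_name("Foeniculum vulgare Mill. subsp. piperitum (Ucria) Cout.")$key
#' normalize_name("Mentha sp.")$rank
normalize_name <- function(raw) {
  if (length(raw) == 0) {
    abort("`raw` must contain at least one name.")
  }
  rows <- lapply(raw, parse_one_name)
  dplyr::bind_rows(rows)
}

parse_one_name <- function(raw) {
  if (is.na(raw) || !nzchar(stringr::str_squish(raw))) {
    abort("Empty botanical name string.")
  }
  txt <- stringr::str_squish(raw)
  bad <- stringr::str_remove_all(txt, "[\\p{L}().&×\\-.'’,\\s]")
  if (nzchar(bad)) {
    abort(sprintf("Unparseable name \"%s\": illegal fragment \"%s\".", raw, bad))
  }
  tok <- strsplit(txt, "\\s+")[[1]]

  if (!stringr::str_detect(tok[1], RX_GENUS)) {
    abort(sprintf("Unparseable name \"%s\": \"%s\" is not a genus token.", raw, tok[1]))
  }
  genus <- cap_genus(tok[1])
  epithet <- ""
  infra_rank <- "none"
  infra_epithet <- ""
  auth <- character()

  rest <- tok[-1]
  if (length(rest) > 0 && stringr::str_detect(rest[1], RX_SP)) {
    auth <- rest[-1]
    rest <- character()
  } else if (length(rest) > 0 && stringr::str_detect(rest[1], RX_EPITHET) &&
             !rest[1] %in% names(RANK_MARKERS)) {
    epithet <- stringr::str_to_lower(rest[1])
    rest <- rest[-1]
    # authorship runs until a rank marker (if any)
    m <- which(rest %in% names(RANK_MARKERS))
    if (length(m) > 0) {
      j <- m[1]
      auth <- rest[seq_len(j - 1)]
      infra_rank <- RANK_MARKERS[[rest[j]]]
      if (length(rest) < j + 1 || !stringr::str_detect(rest[j + 1], RX_EPITHET)) {
        abort(sprintf(
          "Unparseable name \"%s\": rank marker \"%s\" not followed by an epithet.",
          raw, rest[j]
        ))
      }
      infra_epithet <- stringr::str_to_lower(rest[j + 1])
      auth <- c(auth, rest[-seq_len(j + 1)])
    } else {
      auth <- rest
    }
  } else {
    # bare genus, possibly with authorship ("Thymus L.")
    auth <- rest
  }

  rank <- if (nzchar(epithet)) "species_or_below" else "genus_only"
  key <- taxon_key_parts(genus, epithet, infra_rank, infra_epithet)
  tibble::tibble(
    input = raw,
    genus = genus,
    epithet = epithet,
    infraspecific_rank = infra_rank,
    infraspecific_epithet = infra_epithet,
    authorship = paste(auth, collapse = " "),
    rank = rank,
    key = key
  )
}

cap_genus <- function(x) {
  hybrid <- stringr::str_detect(x, "^×")
  core <- stringr::str_remove(x, "^×")
  core <- paste0(
    stringr::str_to_upper(stringr::str_sub(core, 1, 1)),
    stringr::str_to_lower(stringr::str_sub(core, 2))
  )
  ifelse(hybrid, paste0("×", core), core)
}

taxon_key_parts <- function(genus, epithet, infra_rank, infra_epithet) {
  key <- stringr::str_to_lower(genus)
  if (nzchar(epithet)) key <- paste(key, epithet)
  if (infra_rank != "none" && nzchar(infra_epithet)) {
    key <- paste(key, infra_rank, infra_epithet)
  }
  key
}

#' Species-level key of a taxon key
#'
#' Drops any infraspecific part of a normalization key, e.g.
#' `"foeniculum vulgare subsp. piperitum"` becomes `"foeniculum vulgare"`.
#' Used by [crossref()] for species-level fallback matching.
#'
#' @param key Character vector of normalization keys.
#' @return Character vector of keys truncated to genus + epithet.
#' @export
species_key <- function(key) {
  stringr::str_replace(key, "\\s+(subsp\\.|var\\.)\\s+.*$", "")
}
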