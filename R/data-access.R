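#' Published top-30 wild food plant ranking of the Catalan linguistic area
#'
#' The printed per-taxon summary of the 30 most-reported wild food plants
#' from the Catalan-linguistic-area survey: scientific name with
#' authorship, family, use-report total, cultural importance index, and
#' presence flags against an edibility repository (`pfaf`) and a
#' nutraceutical/functional-food dictionary (`fff`). These are *published
#' inputs*, not outputs of this package; they are shipped so that summary
#' statistics whose ingredients are themselves printed (the mean ± SD row,
#' cumulative top-k shares) can be recomputed, and to serve as a realistic
#' small example table.
#'
#' @return A tibble with columns `taxon_name`, `family`, `ur`, `ci`,
#'   `pfaf`, `fff` (flags as 0/1 integers), in published rank order.
#' @export
#' @examples
#' top30 <- cla_top30()
#' mean_sd(top30$ur)          # 242.53 +/- 179.11
#' top_share(top30, 5)        # top-5 share of the top-30 UR total
cla_top30 <- function() {
  path <- system.file("extdata", "cla_top30.csv", package = "ethnoindex",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    taxon_name = readr::col_character(),
    family = readr::col_character(),
    ur = readr::col_integer(),
    ci = readr::col_double(),
    pfaf = readr::col_integer(),
    fff = readr::col_integer()
  ))
}
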