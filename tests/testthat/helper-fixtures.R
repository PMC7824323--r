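# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use base-R primitives (paste/table/tapply) so they share no code path with
# the dplyr-based implementation they check.

toy_rows <- function() {
  tibble::tibble(
    informant_id = c("i1", "i1", "i1", "i2", "i2", "i3"),
    study_id = "s1",
    taxon_name = c(
      "Thymus vulgaris L.", "Thymus vulgaris L.", "Laurus nobilis L.",
      "Thymus vulgaris L.", "Rubus ulmifolius Schott", "Mentha sp."
    ),
    family = c("Lamiaceae", "Lamiaceae", "Lauraceae",
               "Lamiaceae", "Rosaceae", "Lamiaceae"),
    part = c("leaf", "flower", "leaf", "leaf", "fruit", "leaf"),
    preparation = c("condiment", "condiment", "condiment",
                    "raw", "raw", "cooked")
  )
}

small_synth_config <- function(seed = 1, target_ur = 400) {
  synthetic_config(
    n_informants = 50, n_taxa_specific = 18, n_taxa_genus_only = 2,
    n_genera = 12, n_families = 6, n_studies = 3,
    target_ur = target_ur, seed = seed
  )
}

# distinct-tuple cardinality, the set-quotient oracle for dedupe_records
oracle_distinct_tuples <- function(rows) {
  key <- paste(rows$informant_id,
               normalize_name(rows$taxon_name)$key,
               rows$part, rows$preparation, sep = "\r")
  length(unique(key))
}

# incidence-cube CI oracle: materializes informant x taxon x category
# presence and sums proportions
oracle_ci <- function(ds, scheme = "single_food") {
  recs <- as.data.frame(ds$records)
  recs$category <- if (scheme == "single_food") "food" else recs$preparation
  n <- nrow(ds$informants)
  cube <- unique(recs[, c("informant_id", "taxon_key", "category")])
  counts <- table(cube$taxon_key)
  taxa <- sort(unique(recs$taxon_key))
  tibble::tibble(taxon_key = taxa, ci = as.numeric(counts[taxa]) / n)
}

# naive group-by oracle over records
oracle_group_ur <- function(ds, by = c("taxon", "genus", "family")) {
  by <- match.arg(by)
  recs <- as.data.frame(ds$records)
  tax <- as.data.frame(ds$taxa)
  idx <- match(recs$taxon_key, tax$key)
  g <- switch(by,
    taxon = recs$taxon_key,
    genus = tolower(tax$genus[idx]),
    family = tax$family[idx]
  )
  tab <- table(g)
  out <- data.frame(entity = names(tab), ur = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$ur, out$entity), ]
}

# two-pass textbook mean/sd oracle
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# random plausible botanical name strings for fuzzing the parser
fuzz_names <- function(n, seed = 1) {
  set.seed(seed)
  genera <- c("Thymus", "Mentha", "Quercus", "Silene", "Rorippa", "Allium")
  eps <- c("vulgaris", "spicata", "ilex", "bonus-henricus", "alba", "maritima")
  auth <- c("", "L.", "Mill.", "(L.) Roth", "Weber in Wiggers", "(Moench) Garcke")
  marker <- c("", "subsp.", "var.", "ssp.")
  infra <- c("piperitum", "uncinata", "judaica")
  iauth <- c("", "(Ucria) Cout.", "Domin")
  vapply(seq_len(n), function(i) {
    g <- sample(genera, 1)
    e <- sample(eps, 1)
    a <- sample(auth, 1)
    m <- sample(marker, 1)
    nm <- paste(g, e)
    if (nzchar(a)) nm <- paste(nm, a)
    if (nzchar(m)) nm <- paste(nm, m, sample(infra, 1), sample(iauth, 1))
    trimws(nm)
  }, character(1))
}
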