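---
title: "Quantitative ethnobotany with use reports: models, conventions and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ethnobotany with use reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoindex)
```

## The use report as the atomic unit

Everything in `ethnoindex` counts *use reports* (UR). One UR is one
distinct tuple

> (informant, taxon, plant part, preparation mode)

after deduplication. This granularity is a deliberate modelling decision:
published per-taxon UR totals in wild-food-plant surveys exceed what
distinct informant×taxon pairs could produce (a taxon with 957 UR among
1659 informants but a cultural-importance value of 0.52, i.e. ~863
informants, must be counted at a finer grain), and part×preparation is the
finest granularity survey appendices report. Duplicate rows are collapsed
by `dedupe_records()`, which is a pure set quotient: its output — and
every index downstream — is invariant under input row order, with the
lexicographically smallest `study_id` retained when duplicates disagree.

Taxon identity is a *normalization key*: the lowercase
`genus epithet [subsp.|var. infraepithet]` with authorship stripped.
Authorship is recognised positionally (everything between the epithet and
a rank marker, and everything after the infraspecific epithet), so
`"Foeniculum vulgare Mill. subsp. piperitum (Ucria) Cout."` and
`"Foeniculum vulgare subsp. piperitum"` are the same taxon. The parser is
idempotent and does **no** fuzzy matching or synonym resolution against
taxonomic backbones — two different valid names for one biological species
are two taxa, a known limitation that mirrors how multi-study survey
databases are actually keyed.

Part and preparation labels live in closed vocabularies (12 part
categories with aerial / subterranean / product superclasses; 6
preparation modes). Free-text survey labels must be mapped into them with
a `vocabulary_map()`, and the map must be *total*: an unmapped label
aborts the run naming the label, because silently coercing to `unknown`
would corrupt the `unknown` category, which is itself meaningful
(unreported parts and preparations are published as their own shares).
Whether preparation sub-forms ("boiled in water" vs "boiled in water and
oil") should merge is survey-specific, which is exactly why the mapping is
user-configurable input rather than package logic.

## The indices and their conventions

For `N` informants, `n_UR` use reports, `n_t` used taxa, flora size `F`:

* `compute_ei()`: `EI = 100 · n_t / F`. Linear in `n_t`; `EI = 100` when
  the whole flora is used. The default flora context is 4200
  autochthonous taxa (the published estimate for the Catalan linguistic
  area); any territory's estimate can be supplied, e.g. `8882 − 136` for
  Spain's flora excluding continental-Portuguese endemics.
* `compute_fic()`: `F_IC = (n_UR − n_t)/(n_UR − 1)`, defined for
  `n_UR ≥ 2`; strictly increasing in `n_UR`, strictly decreasing in
  `n_t`, 0 when every report cites a different taxon, → 1 as reports pile
  onto fixed taxa.
* `compute_ci()`: `CI_s = (1/N) Σ_c |{informants citing s in c}|`, an
  informant counted once per (taxon, category) however many parts or
  sub-forms they reported.

Three conventions are applied consistently and deserve justification:

1. **Rank restriction.** `n_t` for EI and F_IC counts taxa determined at
   specific or subspecific level; genus-only determinations ("*Mentha*
   sp.") still contribute UR to totals and rankings. This mirrors how the
   indices are reported in the literature this package serves.
2. **The F_IC denominator.** Published F_IC values do not always state
   whether `n_UR` included genus-only UR — with ~10⁴ reports both
   denominators round to the same 0.97 — so the choice is explicit
   configuration (`percentage_denominator`: `all_ur`, the default, or
   `specific_rank_ur`), not a guess.
3. **CI category scheme.** The default is a single "food" category, under
   which `CI_s · N` is exactly the distinct-informant count (an integer —
   this is tested) and CI ordering equals informant-count ordering.
   `by_preparation` treats each preparation mode as a category. Published
   per-taxon CI values in the motivating survey are consistent with
   distinct-informant counting and not with `UR/N`, which is why
   single-category is the default; the exact category partition behind any
   given published CI cannot be recovered from a paper, so CI on real data
   is verified structurally (oracle equivalence, integrality), not against
   published per-taxon values.

The reliability filter (`reliability_filter()`, default ≥ 3 distinct
informants) treats "independent informants" as distinct identifiers, with
no kinship or locality adjustment — surveys that assign records to
municipalities rather than people can pass a municipality pseudo-identifier
as `informant_id`, which understates informant counts; no correction is
applied because none is applied in the tradition this models.

Percentages are rounded **half-up** (`round_half_up()`) and only at the
reporting boundary (`write_table()`, display); internal arithmetic is kept
exact so chained statistics never accumulate rounding. Ranking tie-breaks
are alphabetical on the normalization key, making every output table
bit-stable across runs. Degenerate inputs fail loudly rather than
returning defaults: F_IC with fewer than 2 UR, CI with an empty registry,
rankings of an empty dataset and SD of fewer than 2 values are all errors.

The `mean ± SD` rows of ranking tables use the sample (n − 1) standard
deviation: recomputing the published top-30 row of the motivating survey
(mean 242.53, SD 179.11 — shipped as `cla_top30()`) confirms that only the
n − 1 convention reproduces it.

## External-list validation

`crossref()` flags each cited specific-rank taxon against a user-supplied
reference list (an edibility repository, a nutraceutical dictionary)
normalized with the same name rules. Subspecific survey taxa whose parent
species is on the list are flagged `species_level` and counted separately
from `exact` matches, because published coverage fractions rarely state
which convention they used; both counts and percentages are returned so
either can be reproduced. `matched + unmatched = total` always holds, and
a list built from the dataset's own names matches 100% — both are tested
invariants. The package never downloads anything.

## What the synthetic generator emulates — and what it does not

`generate_survey(synthetic_config())` draws a survey with the published
structure of the Catalan-linguistic-area wild food plant dataset, which is
available only on request and therefore cannot ship with the package:

| parameter | default | source of the default |
|---|---|---|
| informants | 1659 (53.65% men) | published registry size |
| taxa | 278 specific + 13 genus-only, 193 genera, 67 families | published counts |
| use reports | exactly 10,078 | published total |
| Zipf exponent | 0.826 | calibrated so the expected top-taxon share is 9.50% (957/10,078) |
| part shares | published superclass shares, renormalized | see below |
| preparation shares | raw 34.77, condiment 32.71, cooked 19.22, preserved 3.71, curd 2.16, unknown 7.43 (%) | published shares |

Design choices inside the generator:

* **Heavy tail.** Per-taxon UR counts are `1 +` a multinomial draw with
  Zipf weights `r^−0.826` over popularity ranks; the guaranteed single
  citation makes taxon coverage exact, so the closed form
  `expected_fic() = (n_UR − n_t)/(n_UR − 1)` holds by construction and
  realized F_IC recovers it to < 0.005 (tested over 20 seeds). Genus-only
  taxa occupy the tail ranks, since genus-level determinations are rare
  citations in practice.
* **Exact UR totals.** Duplicate tuples are rejected and resampled, never
  collapsed, so `target_ur` is hit exactly.
* **Published part shares sum to 98.66.** The published superclass
  percentages (aerial 91.59, subterranean 2.20, product 0.17, unknown
  4.70) do not total 100; the missing 1.34 points are unexplained in the
  source. The defaults renormalize the four proportionally. The
  within-superclass split (leaf- and fruit-dominated) is not published and
  is a package choice.
* **Informant-taxon concentration.** The real joint distribution of
  records per informant×taxon pair is unknowable from published summaries;
  it is exposed as the `max_records_per_pair` knob (default 3) instead of
  being guessed implicitly.
* **Determinism.** The draw is a pure function of the seed and restores
  the caller's RNG state; the same seed yields byte-identical datasets.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: geographic and dialect structure; the
municipality-level bias of one constituent study; informant-level
heterogeneity (all informants are exchangeable, so per-informant UR counts
are thinner-tailed than reality); the empirical informant-per-taxon tail
(with the calibrated Zipf head, tail taxa still draw ~10 UR each, so the
generator does not reproduce the published result that only 56% of taxa
reach 3 informants — that statistic depends on the real tail shape, which
no published summary pins down); and real nomenclatural noise (names are
generated clean). Tests on synthetic data validate *mechanics* — index
arithmetic, set semantics, invariances — not ecological realism.

## Problem sizes and verification strategy

The test suite checks every operation against independent brute-force
oracles built from base-R primitives (set cardinality via `unique()` on
pasted tuples, an informant×taxon×category incidence cube for CI,
`table()` group-bys, two-pass mean/SD), on 100 fuzzed small synthetic
surveys (10–40 informants, ≤ 21 taxa, ≤ 200 UR) plus 20 full-size
(10,078-UR) generator draws — sizes chosen to make the oracles affordable
while covering the full-scale configuration; the complete suite runs in
well under a minute. Published values are asserted only where their inputs
are themselves published (index arithmetic, the top-30 table statistics);
dataset-dependent headline numbers of the motivating survey are not
reproducible without the restricted primary data and are deliberately not
asserted.
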