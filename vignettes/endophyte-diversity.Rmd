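---
title: "Diversity and bioassay analytics for culture-based endophyte surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity and bioassay analytics for culture-based endophyte surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endodiv)
library(dplyr)
```

## The setting

Culture-based surveys of endophytic fungi follow a common design: tissue
segments (flowers, leaves, stems, roots) from several host plants are
surface-sterilised, plated, and every emerging colony is assigned to a
morphospecies. The resulting inventory supports two kinds of questions —
community-ecological ones (how diverse is each host's endophyte community,
how do tissues overlap, which genera track which tissues) and
bioprospecting ones (which isolates' extracts inhibit pathogens, scavenge
radicals, or kill tumour cells selectively). `endodiv` implements both
analysis tracks over plain tabular inputs, with seeded simulators so every
stage can be exercised without external data.

## The community data model

A `community_table` couples two tibbles. The **isolate records** hold one
row per plant x tissue x morphospecies with a colony count; a genus of
`"unclassified"` marks sterile mycelia that never sporulated, which count
toward abundance and richness but drop out of genus-level summaries when
requested. The **segment tallies** hold, per plant and tissue, how many
segments were examined and how many yielded at least one endophyte.
Validation enforces the closed tissue vocabulary (flower, leaf, stem,
root), the two-area location code, uniqueness of the
(plant, tissue, morphospecies) triple, and the tally bounds
`0 <= colonized <= examined`. Zero-count rows are legal and retained, but
never contribute to richness or abundance.

Two derived percentages sit directly on these tables. The **occurrence**
of a species is its colony count over all colonies in the study, times
100; by construction the values sum to 100 over species. The
**colonization frequency** CF% is `100 * colonized / examined` per plant
and tissue. CF% comparisons only make sense against the same denominator,
which is why the tissue vocabulary is closed.

## Diversity indices and their conventions

All indices act on the per-plant abundance vector (colony counts summed
over tissues within a plant):

* Shannon-Wiener `H' = -sum p_i log p_i`, in **nats**. The natural
  logarithm is not negotiable here: with richness 8 and `H' = 1.79` the
  evenness `1.79 / ln 8 = 0.861`, which matches how such tables are
  reported; a base-10 convention would not.
* Simpson complement `1 - sum p_i^2`, the probability that two random
  isolates differ in species. Tables sometimes head this column "1 - D"
  while defining `D` as the same complement; we sidestep the notational
  clash by always reporting the complement-of-concentration value and
  calling it `simpson`.
* Camargo's index, implemented **literally as 1/S** — the reciprocal-
  richness convention used alongside the other indices in this literature,
  not Camargo's original evenness statistic.
* Berger-Parker dominance `max(n_i) / N`.
* Evenness `E = H'/ln S`, undefined for `S < 2` (typed `NA`, not zero).

The mathematical constraints `H' <= ln S`, `1 - D <= 1 - 1/S` and
`BP >= 1/S` — each with equality exactly at perfect evenness — are
enforced as tested invariants, and `check_index_table()` applies them to
*published* tables, where transcription and rounding slips are common.
Plants with no isolates get a typed "no data" profile (`no_data = TRUE`,
indices `NA`); reporting zeros would silently claim an observed absence
of diversity rather than an absence of data.

### Rounding

Published index tables mix precisions (two decimals for Shannon, three
for the Simpson complement, and occasionally truncation rather than
rounding: `1/6` printed as `0.16`). Profiles therefore store full
precision, and `format_diversity_profile()` applies per-index decimal
places with either `"half_up"` or `"truncate"` conventions
(`round_fixed()`). Base R's round-half-to-even is deliberately avoided
when comparing against printed values: `0.125` must format to `0.13`.

### Reconstructing abundance vectors from printed indices

Published tables print rounded indices but not the abundance vectors
behind them. Because counts are small integers, the inverse problem is
tractable by brute force: `reconstruct_abundances()` enumerates every
non-increasing positive integer vector of a given richness with total
abundance in a bounded range (default 1..30, which keeps the search in
milliseconds), scores each vector, rounds per the stated convention and
keeps the consistent ones. Two instructive outcomes from the packaged
tables:

```{r}
reconstruct_abundances(
  8, list(shannon = 1.79, simpson = 0.789, berger_parker = 0.35)
)
```

The solution is *unique*: `(6, 4, 2, 1, 1, 1, 1, 1)` with total 17 —
independently matching the reported total abundance of that host. And for
a four-species host with `H' = 1.39`, `1 - D = 0.75`, `BP = 0.25`, every
solution is an equal-abundance vector, as the equality conditions of the
index bounds require.

The packaged `reconstructed_abundances.csv` fixture carries one such
vector per plant. Not every printed row is attainable: one host's
`H' = 1.46` exceeds the mathematical maximum `ln 4 = 1.386` for its
richness, and for another no vector jointly reproduces its Shannon and
dominance values; the fixture's `matched_indices` column records per
plant which printed values its vector does reproduce, and the consistency
checker flags the impossible rows rather than repairing them.

## Overlaps and ordination

`tissue_overlaps()` computes per-tissue morphospecies sets and the
cardinality of every region of the Venn partition; the region sizes are
checked to partition the union. `pca_ordination()` centres the genus x
tissue colony-count matrix per tissue column — no variance scaling, since
all entries share count units — and extracts principal components with a
deterministic sign convention (the largest-magnitude loading of each
component is made positive), so scores are reproducible run to run. The
test suite confirms the scores and variance fractions against an
independent eigendecomposition of the covariance matrix.

## Bioassay analytics

**DPPH scavenging** is `(C - T)/C * 100` per replicate at 517 nm. The
transform is applied *before* averaging — transforming a mean absorbance
changes the replicate spread. Negative values (sample more absorbent than
control) are flagged with a warning and retained; clipping would discard
evidence of pro-oxidant behaviour.

**Inhibition zones** are summarised per extract x pathogen and compared
within each pathogen by one-way ANOVA followed by **Duncan's multiple
range test** at `alpha = 0.05`. The implementation ranks means in
decreasing order and tests each contiguous span of `p` means against the
least significant range
`R_p = q(1 - (1 - alpha)^(p-1); p, df) * sqrt(MS_within / n_h)`,
with studentized-range quantiles computed numerically (`qtukey`) rather
than from printed alpha = 0.05 tables, and the harmonic mean of replicate
counts for unequal replication. A wide span that tests homogeneous
shields every pair inside it (Duncan's protection rule); letters are the
maximal homogeneous spans. The letter display is validated against a
brute-force oracle that tests every span directly, and is invariant to
the input order of groups. Solvent-control rows stay in the summary but
out of the ranking.

**Dose-response.** Viability percentages from MTT plates are fitted with
the four-parameter logistic
`v(c) = lower + (upper - lower) / (1 + (c/midpoint)^hill)`
by bounded Levenberg-Marquardt least squares on log-concentration
(tolerance 1e-8; starts: `lower = min(v)`, `upper = max(v)`,
`hill = +/-1` by the observed trend, midpoint at the geometric centre of
the series). The IC50 — and the CC50, which is the identical computation
on a normal-cell curve — is solved analytically from the fitted
parameters and reported **only when 50% lies strictly between the fitted
asymptotes**; a plateau entirely above 50% yields a typed "undefined"
result, not an extrapolated number. The **selectivity index**
`SI = CC50 / IC50` is kept at full precision, with a truncated-to-two-
decimals formatting (`si_printed`) matching how such figures are quoted
(196.2 / 41.75 = 4.6994 is quoted as 4.69, not 4.70), and the
conventional `SI > 3` rule (strict) marks high selectivity.

One reporting subtlety: evenness quoted next to a rounded Shannon value
is itself computed *from the rounded value* (`1.79 / ln 8 = 0.861`, while
the full-precision vector gives 0.862). `evenness_index()` takes `H'` as
an argument precisely so both conventions are available.

## The simulators and what they do (not) emulate

* `simulate_community()` draws, per plant and tissue, a
  `Binomial(segments, p)` number of colonized segments (default 12
  segments per tissue — segment counts are rarely published; 12 keeps CF%
  granularity near the ~2.8% steps seen in survey tables — and `p = 0.3`,
  mid-range for the published per-tissue CF% values); each colonized
  segment yields one colony whose species comes from a geometric
  (default ratio 0.7, a classic skewed species-abundance model),
  log-series, or even distribution over a 20-species pool, grouped
  three-per-genus. Locations are assigned deterministically ~3:1 to
  mirror a two-area design.
* `simulate_dose_response()` parameterises the 4PL by its 50% crossing
  (default 41.75 over the 1-500 concentration range) and applies
  multiplicative Gaussian noise (default 5%) before back-computing
  absorbances against a fixed untreated absorbance, so zero-noise plates
  invert exactly through the fit.
* `simulate_dpph()` inverts the scavenging transform so zero-noise pairs
  return their targets exactly.

Every generator scopes its RNG with `withr::with_seed`: identical
parameters and seed give byte-identical output, and the caller's random
stream is untouched. Simulated tables are validated by the same reader
contracts as real ones (schema closure).

What they do *not* emulate: spatial or phylogenetic structure among
hosts, tissue-specific species filtering, inter-plate drift or edge
effects in assays, and heteroscedastic absorbance noise. Passing
parameter-recovery tests on these simulations therefore demonstrates
correctness of the estimators under the stated sampling models, not
robustness to every artefact of real plates and plates' layouts.

## Problem sizes used in the checks

The routine checks run at desk scale, chosen to exercise the estimators
meaningfully while staying quick: exhaustive index-bound verification
over all abundance vectors with `S <= 5`, `N <= 12`; 4PL recovery over
200 simulated plates at 5% noise (median relative IC50 error is required
below 5%); ANOVA type-I error over several thousand null simulations
(required within 0.05 +/- 0.01); Duncan displays against the brute-force
oracle on constructed four-group datasets.

## Known limitations

* Camargo's index follows the reciprocal-richness convention of this
  literature; anyone wanting Camargo (1993) evenness should compute it
  separately.
* `reconstruct_abundances()` is exhaustive and intended for small
  communities (the default `N <= 30`); it is a reproduction aid, not an
  estimator, and multiple consistent vectors are returned whenever the
  printed precision does not pin the community down.
* The 4PL fit reports asymptote-bounded IC50s only; extrapolation beyond
  the tested concentration range is out of scope.
* Published CF% tables ship as data: without the segment denominators
  they cannot be recomputed, only displayed alongside computed profiles.
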