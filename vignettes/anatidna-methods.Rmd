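---
title: "anatidna: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{anatidna: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatidna)
```

`anatidna` analyses waterfowl eDNA metabarcoding surveys: it evaluates
degenerate ND2 primer pairs in silico, turns raw ASV count tables into
date-by-taxon community matrices, and relates those matrices to visual
survey counts. This vignette records the models behind each stage, the
parameters that matter, and the conventions adopted where more than one
reasonable choice existed.

## In-silico PCR

A primer position *matches* a reference position when the IUPAC base sets
of the two symbols intersect; the mismatch count of a primer against a
window is the number of positions with empty intersection. This treats
degenerate codes symmetrically on both sides, so a reference `N` never
penalises a primer. The scanner finds forward-primer sites and
reverse-complemented reverse-primer sites within a per-primer mismatch
budget (each primer is allowed up to `max_mismatch` mismatches; budgets
are not summed across the pair), on both strands, and pairs them into
products.

Conventions, stated once:

- **Coordinates** are 0-based, half-open, on the plus strand. Minus-strand
  products are reported in plus coordinates with `strand = "-"`, and their
  `amplicon_seq` is the product 5'→3' (the reverse complement of the plus
  slice), so a product's sequence is strand-invariant.
- **Amplicon length includes both primer footprints.** The shipped pairs
  satisfy `amplicon = insert + nchar(forward) + nchar(reverse)` (332 =
  297 + 18 + 17, and likewise 241 and 217), and `primer_pair()` enforces
  that arithmetic for user-supplied pairs.
- **Pairing resolution.** When several legal forward/reverse pairings
  exist, the scanner reports the shortest legal product per forward site
  and suppresses products strictly nested inside a reported one,
  mimicking the dominance of short products in PCR kinetics. The
  brute-force oracle used in the tests (expand every degenerate primer,
  slide every concrete expansion, enumerate pairings) applies the same
  convention, so the two routes are comparable hit-for-hit.
- **Product span** is capped at twice the pair's expected amplicon by
  default (2000 nt when no expectation is set), which bounds the scan and
  discards biologically implausible products.

`run_insilico_pcr()` aggregates per-record best hits (fewest total
mismatches, ties broken by position) and reports amplified species counts
by family and class, plus the percentage of amplified species in the
target family (Anatidae by default). Records absent from the lineage table
are counted as "unclassified" with a warning rather than dropped.

## Taxonomic assignment

Per ASV the top five hits by (score, then percent identity) are kept; let
B be the hits attaining the maximum identity among them. The rules, in
order:

1. B is one species and identity >= 98%: assign that species.
2. B spans several species of one genus: assign the genus; several genera
   of one family: assign the family.
3. Best identity < 98%: never assign a species; fall back to the lowest
   common rank of B (genus or family).
4. No family-level agreement, or no hits at all: exclude the ASV.

The 98% species threshold is configurable
(`identity_threshold`). The sub-98% fallback (rule 3) reflects that a
weak best hit still carries genus/family information even when it cannot
support a species call; excluded ASVs never reach downstream tables, and
every ASV receives exactly one assignment row with its basis recorded.

## Control filtering and depth standardization

The filter threshold is computed from extraction and PCR blanks only
(field and filtration blanks are reported for QC but do not enter the
threshold). Two readings of "the average number of non-zero reads summed
across the negative controls" are defensible, and both are implemented:

- `per_asv` (default): sum each ASV's reads across those blanks, then
  average the non-zero sums;
- `per_control`: average the non-zero per-blank column totals.

An ASV is removed when its **field-sample total** is strictly below the
threshold ("fewer than" is strict, so an ASV exactly at the threshold
survives), and removal takes the whole ASV row. Filtering is monotone in
the threshold by construction.

Standardization rescales each field sample to the minimum field depth
(`count * D_min / D_j`), leaving values fractional; column sums then equal
the minimum depth to within 1e-6 relative tolerance, and the operation is
idempotent. Zero-depth field samples are dropped with a warning rather
than producing division by zero.

Aggregation sums standardized reads over ASVs per assigned taxon, then
over same-date field replicates, then pools the three indistinguishable
species pairs (mallard/American black duck, tundra/trumpeter swan,
greater/lesser scaup — `default_species_pools()`); the same pooling is
applied to survey matrices so both layers use identical taxon labels.
Each step conserves the grand total of retained reads. Checklist means use
the absent-as-zero rule: a species not on a complete checklist was not
seen, so it contributes 0 to that checklist's mean.

## Community statistics

Counts span orders of magnitude, so time-course and snapshot similarity
use Pearson correlation on `log(x + pseudocount)` with pseudocount 1 by
default (zeros are structural in migration data; the pseudocount is
configurable and can be set to 0 when inputs are strictly positive).
Snapshot concordance across species uses Kendall tau-b, the tie-corrected
variant, because count data are tied frequently. "Significant" throughout
means one-tailed p < 0.05 for *positive* association; per-species tables
also carry a Benjamini-Hochberg column for transparency, but the headline
significance flag is the raw one-tailed test, and no correction is applied
to the network's many date-pair tests.

The lagged analysis correlates eDNA on sampling date *t* against surveys
on *t − l* for day-lags 0-5, emitting both per-date (cross-species
Kendall) and per-species (log-log Pearson across dates) tables; lagged
dates without surveys are skipped and the skips recorded. The 5-day
look-back matches the persistence window over which aquatic eDNA
plausibly reflects recent bird presence.

The correlation network has (date, layer) nodes; candidate edges are all
visual-visual and visual-eDNA date pairs (eDNA-eDNA pairs only on
request), and an edge is kept iff r >= 0.6 (configurable) with one-tailed
p < alpha. Edge sets are nested in the threshold. Checklist concordance
uses percentile bootstrap CIs over checklists (1000 resamples, seeded),
restricted to dates with at least three checklists.

## The synthetic-data generator

The generator emulates the study design end to end with known ground
truth. Its defaults are the emulated field conditions: 10 weekly sampling
dates in fall (late September to late November 2020), 3 field replicates
plus a field blank per date, extraction/PCR blanks, and ~650,000 reads
per field sample.

- **Migration curves** are Gaussian passage functions,
  `round(peak * exp(-(t - peak)^2 / (2 w^2)))` — the simplest two-parameter
  shape that produces the early-dabbler/late-diver turnover of fall
  migration. The default 17-species roster staggers peaks from late
  September (wood duck, green-winged teal) to late November (swans,
  scaup) with peak abundances from 8 to 5000 individuals.
- **Observer counts** are negative-binomial with mean
  `detection_prob * abundance` and dispersion `observer_dispersion`
  (Poisson at 0) — overdispersed counts are the norm for bird surveys.
  Checklists are generated for sampling dates and their 5-day look-back,
  with a recycled per-date checklist count mixing values below and above
  three so the at-least-3-checklists analyses have both included and
  excluded dates.
- **Reference sequences** embed an exact concrete expansion of the
  species' tribe-matched primer pair around an insert of the expected
  length; decoy fish/mammal records are rejection-sampled to carry no
  site within 2 mismatches of any pair. By construction each target
  yields exactly one product under its own pair at 0 mismatches.
- **Read tables** draw each field sample's species counts
  Dirichlet-multinomially: expected shares proportional to
  `shedding_factor * sum_l lag_kernel[l] * abundance(t - l)`, total
  `read_depth_per_sample`, overdispersion `read_overdispersion` (pure
  multinomial at 0); species counts are split across 1-k ASVs by fixed
  per-species proportions. Negative controls receive sparse geometric
  contamination (each ASV present with probability `contamination_rate`),
  which produces a non-degenerate filter threshold. Hit tables give each
  ASV its true species at >= 98% identity plus lower-ranked in-genus and
  sub-98% distractor hits, and optional extra ASVs exercising the
  tie/exclusion branches.
- **Reproducibility**: all randomness flows from one root seed through
  named substreams (surveys, references, reads), so each stage is
  independently byte-reproducible and the global RNG state is restored
  after each call.

What the generator does *not* emulate: sequencing error, chimeras and
read-level artefacts (upstream denoising territory), hydrological eDNA
transport and degradation kinetics, taxonomic reference-database gaps, and
observer heterogeneity beyond a single dispersion parameter. Passing tests
therefore demonstrate that the pipeline's algebra and statistics behave
correctly under a faithful but idealized generative model — not that field
data will correlate as cleanly.

## Test and calibration choices

The test suite checks scanner/oracle equivalence on 100 random 2-kb
references at mismatch budgets 0-2 (planted, optionally mutated sites on
both strands in half of them); type-I calibration of both correlation
paths under a log-normal independence null at n = 20 with 1000 replicates
against the 99% binomial band around 0.05; lag-kernel recovery for lags
{0, 2, 5} over 20 seeds each, run at `read_overdispersion = 0` because
Dirichlet overdispersion adds date-level noise that masks day-scale
signal shifts at weekly sampling — the recovery claim concerns the lag
machinery under sampling noise, not robustness to arbitrary
overdispersion; and network distance decay pooled over 20 seeded turnover
simulations. These problem sizes keep the default suite around a minute
on one core while leaving each check statistically meaningful.

## Known limitations

- The in-silico scanner models mismatch counts only: no melting
  temperature, ΔG, 3'-end weighting or primer-dimer checks.
- ASV counts are treated as relative-abundance signals; the package
  deliberately fits no calibration model from reads to absolute
  abundance.
- The control-filter sentence it implements is ambiguous; both readings
  are available, and results can differ between them when blank
  contamination is concentrated in few ASVs.
- Genus- and family-rank assignments become their own taxa in the
  community matrix; they are not reallocated to member species.
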