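---
title: "Abundance-stratified QC for qPCR miR arrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-stratified QC for qPCR miR arrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstrata)
library(dplyr)
```

`ctstrata` analyses Ct-value exports from 384-well microfluidic qPCR
microRNA cards: 365 individual miR assays, three duplicated endogenous
small-nucleolar-RNA controls, and duplicated blank wells per card. This
vignette is the package's own account of the methods: the data model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## The data model

A Ct value is the PCR cycle at which a well crosses the detection
threshold; lower Ct means more template. Runs stop at 40 cycles, so
"Undetermined" wells are recorded as Ct = 40 with a censoring flag. The
package treats 40 strictly as a *detection bound*: values above 40 are a
range error (never clamped), the flag must agree with `ct == 40` row by
row, and every downstream statistic declares how it treats censored
values. Missing wells are representable (absent rows in the long dialect,
empty cells in the wide dialect) and are excluded pairwise, so partial
plates never abort a run.

The long CSV dialect `(assay_id, condition_id, ct)` is the canonical
interchange format because it matches instrument exports; the wide
dialect (assays × conditions) exists for spreadsheet review. Round-trip
identity between the two, including censoring flags, is part of the test
surface.

## Abundance strata

Assays are partitioned by Ct into high (Ct < 30), medium (30 ≤ Ct ≤ 35)
and low (Ct > 35) strata. The medium stratum is closed on both ends; this
is the only boundary convention consistent with stating the strata as
"Ct < 30", "30 ≤ Ct ≤ 35" and "Ct > 35" simultaneously. Censored values
fall in the low stratum for count tables (so column totals equal the
number of wells measured) but are excluded from duplicate-agreement
points and, by default, from correlations; both behaviours are arguments,
because a detection bound is defensibly either "very low abundance" or
"no measurement" depending on the question.

The empirical justification for the cutoffs is the duplicate-agreement
diagnostic: |ΔCt| between duplicate plates plotted against the duplicate
mean, with pairs touching 40 removed (a censored difference is
meaningless), smoothed by a cubic smoothing spline. The smoothing
parameter is chosen by generalized cross-validation — a defensible,
reproducible default that does not bind the package to any one tool's
unstated settings. The fit requires at least 10 points spanning more than
2 cycles; anything less cannot support a curvature estimate.

## Well failures

For duplicate plates, a well failure is one duplicate at Ct = 40 with the
other amplifying. When *both* duplicates read 40, the assay's Ct values
in reference conditions (the same sample at other concentrations, or the
Universal RNA positive control) decide between a *double failure* (any
reference < 40: both wells are charged, one per plate) and *not
expressed* (no reference evidence: no failure charged — conservative,
since absence of evidence of expression should not inflate failure
rates). The failure percentage is

> average failures between duplicate plates / number of miRs expressed × 100,

where the denominator counts miR assays not classified not-expressed.
Blank and control wells never enter failure counts: blanks are expected
40s and controls have their own QC role. For single plates (e.g. a cDNA
dilution series) the rule degrades gracefully: a failure is any Ct = 40
for an assay known to be expressed in that sample from other runs.

## Concordance and shift tests

Pearson correlations are computed on pairwise-complete pairs; the default
censor policy excludes pairs with any Ct = 40, consistent with the
agreement-plot rule. p-values refer `t = r·sqrt((n−2)/(1−r²))` to a t
distribution with n − 2 degrees of freedom; `|r| = 1` maps to p = 0. For
stratified concordance each assay is assigned to exactly one stratum by
its **mean Ct across the compared conditions** (censored values entering
at 40), so strata partition the assay set and no assay is double-counted.

Stratum-occupancy shifts are tested with the Pearson chi-square statistic
Σ(O−E)²/E, E = row total × column total / grand total, no continuity
correction (the tables are 3×2 or larger; Yates' correction is a 2×2
device). Degrees of freedom are (r−1)(c−1) and the p-value is the upper
chi-square tail. Zero marginal totals are a hard error; expected counts
below 5 warn but do not abort, because small synthetic tables are
legitimate test inputs. Counts come from one of two aggregations:

* `per_sample_average` (default): stratify every measurement, count per
  condition, average across the group, round **half-up** to an integer
  (contingency tests need integer counts);
* `mean_ct`: stratify each assay's mean Ct across the group.

Both are exposed because published per-group count tables of this kind do
not always state which aggregation produced them, and recomputing a
chi-square from printed integer counts can differ by a few percent from a
test run on unrounded per-sample data. The 3×3 migration table
cross-tabulates each assay's stratum under two methods; its off-diagonal
asymmetry is the direct readout of an abundance shift.

The "adjusted" correlation sometimes reported from mixed-model regression
of repeated measures is **not** implemented: without a stated model it
cannot be reproduced faithfully. Unadjusted per-pair correlations are
reported instead. Likewise, the paired two-sided t-test used for group
mean-Ct comparisons is an explicit interpretation choice, made because a
paired design with per-assay means is the natural reading of a
matched-sample comparison.

## Sample structure

Condition-level structure uses the one-minus-Pearson correlation distance
(d ∈ [0, 2], invariant to per-condition affine rescaling of Ct) with
agglomerative clustering via `stats::hclust`. Complete linkage is the
default — the unstated default of the tool named in the methodology this
package follows — and linkage is an argument. `hclust` breaks ties by
lowest pair index, so dendrograms are deterministic. Clustering a single
condition is rejected (a one-leaf tree is not representable in the
`hclust` container and carries no information). PCA treats conditions as
observations of per-assay-centred Ct profiles (SVD, no scaling); assays
with missing wells are dropped since PCA needs a complete matrix, and
each component's sign is fixed so its first nonzero loading is positive,
making scores reproducible. Stratum-restricted distances support
per-stratum clustering heat-maps.

## The synthetic-data generator

`simulate_study()` is the test substrate for every other module. For
assay *i* in condition *c*:

```
true_ct = base_i
          − efficiency_slope · log2(conc_c / reference_conc)
          + dilution_penalty · log2(dilution_c / min dilution)
          + shift_i · [FFPE] + effect_i · [tumour]
observed = true_ct + Normal(0, σ0 + σ1 · max(0, true_ct − knee))
```

with an independent logistic well failure,
`P(fail) = plogis((true_ct − midpoint_c) · steepness)`, and censoring of
failed or ≥ 40 observations at Ct 40. Defaults and their rationale:

| parameter | default | units | why |
|---|---|---|---|
| baseline mixture | N(26, 2), N(32, 1.5), N(37, 1.2), weights .35/.35/.30 | cycles | populates all three strata at the reference concentration (order 100+ assays each) |
| `efficiency_slope` | 1.0 | cycles per log2 input | ideal PCR doubling: halving template costs one cycle |
| `reference_conc`, `concentrations` | 200; 10–200 | ng/µL | the input-RNA titration of the emulated study design |
| `ffpe_shift_mean`, `ffpe_shift_sd` | 1.25, 0.25 | cycles | centre of the 1.0–1.5 cycle FFPE-associated Ct loss reported for formalin fixation |
| `noise_sigma0`, `noise_sigma1`, `noise_knee` | 0.15, 0.25, 30 | cycles | tight replication below Ct 30, rapidly growing noise above it — the shape of the duplicate-agreement diagnostic |
| `failure_midpoint`, `failure_steepness` | 38, 1 | cycles, per cycle | failures concentrate where template is scarce |
| `dilution_penalty` | 0 | cycles per log2 dilution | dilution mainly raises failure rates rather than shifting Ct location, so it acts through the failure model |
| `dilution_failure_coupling` | 0.5 | cycles per log2 dilution | each twofold extra dilution halves the headroom to the failure midpoint by half a cycle |
| `n_de`, `de_effect` | ~1 in 6 assays, ±2 | cycles | a fourfold expression change in a sixth of miRs — a realistic tumour/normal contrast strong enough to dominate the FFPE technical pattern |
| `n_tumour`, `n_normal` | 3, 3 | samples | the paired clinical design being emulated |

The default study bundles an input-RNA titration with duplicate plates, a
single-plate cDNA dilution series, an equivalent-samples trio (200/15×,
100/7.5×, 66.7/5× — identical effective template concentration within the
1% equivalence tolerance), paired tumour/normal samples under three
extractions (FFPE RecoverAll, frozen mirVana, frozen TRIzol–Qiagen) and a
Universal RNA control: 40 conditions × 369 assays ≈ 15,000 wells, which
simulates and analyses in seconds. All randomness flows through one seed
recorded in the config; identical seeds reproduce identical studies.

**What the generator does not emulate.** Amplification curves and
sequence-level effects; spatial plate artefacts; correlated failures
(failures are independent given true Ct); extraction-method differences
between the two frozen protocols (deliberately none, matching the
near-null comparison it emulates); sample-level biological variability
beyond the tumour effect (same-group samples differ only by noise and
censoring). Passing tests on this substrate therefore demonstrate that
the *analysis* recovers what the *model* put in — they do not certify
performance on real arrays, where failure correlation and inter-sample
heterogeneity are larger.

One consequence worth stating: with these defaults the frozen-vs-FFPE 3×2
occupancy chi-square on the default seed is significant at the 0.05 level
but not at 0.01 — the FFPE shift moves real mass between strata, but a
±0.25-cycle per-assay shift spread across 30/35 boundaries is a weaker
contrast than a real archival cohort shows. The direction of the shift
and the migration asymmetry are the robust readouts, and those are what
the test suite asserts.

## Numerical conventions

* Equivalent samples: relative tolerance 1% on input-RNA / dilution
  ratios (the canonical trio differs by 0.05%).
* Count rounding: half-up (`floor(x + 0.5)`), so averaged counts are
  reproducible integers.
* Degenerate inputs: zero-variance vectors, n < 3 pairs, empty groups,
  zero contingency margins and an all-not-expressed failure denominator
  are errors with named causes; strata with < 3 assays in stratified
  correlation are flagged not-computable without failing the others.
* A group compared against itself in the paired t-test returns a zero
  estimate with NA inference rather than an error (zero-variance
  differences).
* Chi-square statistics are checked against a brute-force Σ(O−E)²/E
  evaluation to 1e−10 and against `chisq.test(correct = FALSE)`;
  p-values against numerical integration of the chi-square density to
  1e−8; Pearson r against its closed form to 1e−12.

## Problem sizes

The test suite runs the default 365-assay study once (cached across test
files), 1,000 random tables for the chi-square oracle, 10,000 null tables
for the type-I error check (3×2 tables, 200 counts per column, expected
counts all ≥ 5), and 100 random vectors for the correlation oracle —
about half a minute in total. These sizes were chosen to make the
stochastic assertions stable at fixed seeds while keeping the suite quick
to iterate on.

## Known limitations

* Cutoffs (30/35) are configuration, not data-derived; the spline is a
  diagnostic, not an optimizer.
* No GEO/SOFT ingestion; CSV dialects only.
* No mixed-model "adjusted" correlation (model unspecified); no exact
  multinomial or Fisher-style tests for 3×k tables; no Spearman or
  concordance-correlation alternatives on the acceptance surface.
* The per-sample-average versus mean-Ct count ambiguity is exposed, not
  resolved; recomputed chi-squares from printed integer tables can sit a
  few percent from values computed on unrounded per-sample counts.
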