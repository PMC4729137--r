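---
title: "Methods: low-frequency mutation calling on ultra-deep amplicon data"
author: "ampvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-frequency mutation calling on ultra-deep amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampvar)
```

## Scope and model

`ampvar` analyses a single PCR amplicon sequenced to ultra-deep coverage
(5,000–20,000x) in circulating cell-free DNA, where somatic substitutions of
interest occur at frequencies from roughly 0.1 % to 25 %. The statistical
problem is separating those variants from the per-position substitution
background of the library. Two library regimes are distinguished:

* **native** — amplicons sequenced directly from cfDNA;
* **wga2** — cfDNA first whole-genome amplified (for low-input samples),
  which raises the substitution background by roughly an order of magnitude.

The caller makes no parametric assumption about the background other than
that, within a sample, the non-reference percentages across positions are
exchangeable draws from a common noise distribution once true variants are
excluded. A candidate must be an upper-tail outlier of that empirical
distribution (`percent > mean + 4 sd`) *and* exceed an absolute regime floor
(0.1 % native, 1 % wga2). The floor encodes prior knowledge that the
empirical mean/sd can be driven arbitrarily low at very deep coverage while
process artifacts (PCR, amplification chemistry) still occur at fixed rates.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `base_quality_min` | 25 | Phred | a base is scored only if strictly above this |
| `mapping_quality_min` | 18 | mapping Phred | a read is scored only if strictly above this |
| `sd_multiplier` | 4 | sd units | one-sided outlier threshold |
| `floor_native` / `floor_wga2` | 0.1 / 1.0 | percent | regime calling floors |
| `cohort_artifact_fraction` | 0.75 | fraction | recurrence above this flags an artifact |
| `mismatch_cap` | 7 | mismatches/read | haplotype informativeness cutoff |
| `rescue_sd_multiplier` | 2 | sd units | patient-linked rescue threshold |
| `percent_decimals` | 2 | digits | half-up rounding of reported percentages |

All comparisons are strict inequalities: a base at exactly Phred 25, a read
at mapping quality 18, a candidate at exactly the threshold, or a call in
exactly 75 % of samples all *fail* the respective test.

## Background estimation: a documented open choice

The reference population for the outlier statistic is not uniquely
determined by the rule itself. Two constructions are possible: pooling all
non-reference percentages **within a sample across positions**, or comparing
**the same position across samples**. This package pools within-sample,
because it is the only construction available for a per-sample,
single-amplicon pipeline (cohorts may be small or absent, and cross-sample
comparison is already served separately by the artifact filter). With ~3
alternate bases x hundreds of positions, the pool has on the order of 10^3
observations. Observations at or above the regime floor are excluded before
estimation so genuine variants cannot inflate their own null; the *population*
(n-denominator) standard deviation is used, which is immaterial at this n and
keeps the constant-vector edge case (`sd = 0`) exact.

Patient-linked rescue replaces a manual review step (outlier inspection on
scatter plots of matched samples) with a reproducible rule: same substitution
passing in another sample of the same patient, plus an own-sample margin of
`mean + 2 sd`. The 2-sd multiplier is configurable; rescued calls are always
flagged, never silently merged, and artifact-flagged keys are not eligible
for rescue (rescuing systematic noise would contradict the filter's purpose).
A final human review of flagged output is still expected in practice; the
pipeline only guarantees that every verdict is recorded and logged.

## Haplotype counting

Read-backed haplotype estimation is defined exclusively: a read supports a
substitution pattern iff it shows the pattern's alternate alleles at all of
the pattern's positions *and* the reference allele at every other called
position it observes (a position is "observed" only with a base above the
quality threshold). A double-mutant read therefore counts only toward the
double pattern. Each pattern's denominator is the number of informative reads
covering all of that pattern's positions, which is why two patterns of one
sample can have different totals. When a sample has calls at more than one
position, reads with more than `mismatch_cap` mismatches (the SAM `NM`
value) are excluded as uninformative. Published per-haplotype tables derived
from manual read curation follow the same row arithmetic (mutant + wild-type
= total), but exact replication of manually curated totals from raw reads is
not claimed — the exclusive-pattern contract is this package's reproducible
formalisation.

## The simulator: what it emulates, and what it does not

`simulate_amplicon()` generates gapless pre-aligned reads from a haplotype
mixture over one reference (alignment is deliberately out of scope: with a
single amplicon it is trivial and external aligners handle real data). Two
error processes are injected after haplotype assignment:

* **amplification background**: for each (position, alternate base) a rate is
  drawn once per dataset from a Gamma distribution — native mean 0.03 %,
  wga2 mean 0.3 %, shape 2 — then applied per read-base as a Bernoulli. The
  gamma draw makes noise position-specific, which is what the 4-sd rule must
  tolerate.
* **sequencing error**: a uniform per-base substitution rate (default 0.1 %).

Injected error bases receive Phred 15, with 10 % "high-quality errors" at
Phred 30, while haplotype bases receive Phred 35 — so the quality filter is
exercised non-trivially and passes ~10 % of injected errors. Mapping
qualities default to 95 % at 60 with small mass at 18 and 10, exercising the
strict mapping filter. The regime means are calibration choices (the source
analysis quantifies wga2 noise only through the 1 % floor); they produce a
tenfold post-filter background contrast, which the test suite asserts over
20 seeds.

Not emulated: indels and homopolymer artifacts (the variant universe is
substitutions only), paired-end chemistry, PCR duplicate lineages, and
quality/error correlation along reads. Real whole-genome-amplified artifacts
are template changes that would be base-called at native-like qualities;
here amplification errors share the error-quality model, and the calling
floors — not the quality filter — are the defence the wga2 regime actually
exercises. Passing simulation tests therefore demonstrates the *logic* of
the filters at realistic rates, not instrument-level realism.

## Dose–response fitting and classification

Potencies are fitted with the four-parameter logistic on the
log10-concentration axis, `bottom + (top-bottom) / (1 + 10^(hill (logEC50 -
logc)))`, by Levenberg–Marquardt least squares (`minpack.lm::nls.lm`; the
low-level optimizer is used because the `nls` model wrapper fails on
zero-residual data). The zero dose cannot sit on the log axis; it anchors
the starting value of the zero-drug asymptote (bottom for activation, top
for inhibition). A half-max is censored to "> max tested" when the fit
places it beyond the highest tested concentration, when an activation curve
never reaches 20 % of reference activity in the tested range ("very weak
activation" is not defined numerically in the source analysis; 20 % is this
package's configurable operationalisation), or on non-convergence (warning,
never an error).

Agonist conversion is classified from inhibition-mode curves normalised to a
100 % stimulated control, with a symmetric `delta = 10` % band (the source
definition is qualitative; the band makes it decidable): never above
`100 + delta` is **No**; terminal response above `100 + delta` is **Yes** if
the curve never dips below `100 - delta`, else **Partial** (inhibition at
low dose, stimulation at high dose). Shapes matching none of the three (rise
then fall) return "No" with an anomaly flag and warning. The verdict depends
only on response values, hence is invariant to rescaling concentrations.

The packaged knowledge base transcribes the published mutant-by-drug
potencies and agonist classes for the wild-type receptor and 24 CRPC
mutants. The wild-type antagonist row is derived from the running text
rather than the summary table (marked `source = "text"`); lowercase
"partial" cells are stored canonically as "Partial"; and the published table
value 0.10 uM is kept for the M896T x VPC-13566 IC50 even though the
accompanying text cites 0.12 uM as the range bottom.

## Numerical and degenerate-input conventions

* Percentages are rounded half-up (`floor(x 10^d + 0.5)/10^d` with a 1e-9
  guard against binary representation of exact .5 rationals), reproducing
  the published percent-mutant column digit-for-digit.
* Zero filtered depth makes a percentage undefined — an error in
  `percent_mutant()`, `NA` in tables.
* `N` bases never count toward depth; reads beyond the reference bounds or
  with missing qualities reject the dataset.
* Background estimation requires >= 10 covered positions and >= 2 usable
  below-floor observations, otherwise it signals rather than guessing.
* A single-sample cohort skips the artifact filter with a logged warning.
* All analysis stages are deterministic; the simulator is fully determined
  by its seed.

## Problem sizes in the test suite

The suite verifies caller sensitivity and the floor property on 50 + 50
seeded wga2 simulations at 10,000 reads over a 300-bp amplicon (one variant
at 5 % and 0.5 % respectively), oracle agreement on 100 random <= 20-position
pileups, the artifact filter on simulated 10- and 4-sample cohorts at 3,000
reads, and 4PL recovery on 100 curves with 5 % multiplicative noise sampled
on a 1:4 serial dilution from a 500 nM top dose with EC50s log-uniform in
1–100 nM — a bracketed design, as an activation assay would be planned.
These sizes were chosen as the smallest at which the binomial error bands in
the assertions are meaningful.

## Known limitations

* The within-sample background construction cannot detect a position that is
  noisy in *every* sample at sub-floor levels; the cohort filter only
  catches recurrent *calls*.
* Haplotype patterns are counted, not statistically phased: partially
  overlapping reads contribute only to patterns they fully cover, and no EM
  sharing is attempted across partial covers.
* Protein annotation handles single-codon substitutions on a configured
  reading frame; splice effects and full HGVS syntax are out of scope.
* The knowledge base covers exactly the transcribed constructs; lookups of
  unknown mutants return explicit no-profile records and never interpolate.
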