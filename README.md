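# ampvar

Low-frequency mutation detection in ultra-deep amplicon sequencing of
circulating cell-free DNA (cfDNA).

Tumours shed a minor fraction of their DNA into plasma. Sequencing a single
PCR amplicon of a driver gene to depths of 5,000–20,000x can therefore reveal
resistance mutations non-invasively — for example androgen receptor (AR)
ligand-binding-domain substitutions that arise in castration-resistant
prostate cancer (CRPC) under anti-androgen therapy and convert the drugs into
receptor agonists. At variant fractions of 0.1–25 %, the signal competes with
the substitution background of the library itself, which is roughly tenfold
higher when low-input samples must first be whole-genome amplified (WGA2).
`ampvar` implements the complete analysis as a tested, deterministic R
pipeline, together with a seeded read simulator so that every stage is
verifiable against known truth.

## The method

For each sample, bases are counted per position after strict quality
filtering: a read base is scored only if its Phred quality exceeds 25 and its
read's mapping quality exceeds 18. Counts are converted to percentages of the
filtered depth. The per-sample background model pools every non-reference
percentage across positions (excluding values at or above the calling floor)
into a mean m and population standard deviation s, and a non-reference base
with percentage p is a mutation candidate iff

```
p > m + 4 s        (one-sided outlier rule)
p > f              (regime floor: f = 0.1 % native, 1 % WGA2)
```

Candidates recurring in more than 75 % of the cohort's samples are discarded
as systematic artifacts; sub-threshold candidates are rescued when the same
substitution is a passing call in another sample of the same patient and
exceeds m + 2 s in its own sample. Haplotypes are then counted directly from
reads: a read supports a substitution pattern only if it carries all of the
pattern's alternate alleles and the reference allele at every other called
position it covers (so double-mutant reads never inflate the single-mutant
rows), with reads above 7 mismatches excluded when multiple calls exist.
Calls are annotated to protein changes through a transcript-coordinate
configuration and the standard genetic code, and detected mutants are looked
up in a packaged knowledge base of AR mutant drug-response profiles —
EC50/IC50 potencies (with "> 500 nM" censoring) and agonist-conversion
classes (Yes/Partial/No) for four clinical anti-androgens — to flag
antagonists that remain usable ("retained-antagonist options"). A
four-parameter logistic (4PL) fitter with censoring and an
agonist-conversion classifier handle new dose–response data.

## Worked example

Simulate a WGA2-regime sample carrying a haplotype mixture (8 % single
mutant, 2 % double mutant) at 10,000x, then run the calling chain:

```r
library(ampvar)

ref  <- random_reference(300, seed = 7)
spec <- sim_spec(ref,
  haplotypes = list(
    list(subs = c("120" = alt_base(ref, 120)), freq = 0.08),
    list(subs = c("120" = alt_base(ref, 120),
                  "210" = alt_base(ref, 210)), freq = 0.02)),
  n_reads = 10000, regime = "wga2", seed = 99)
sim <- simulate_amplicon(spec)

cfg  <- pipeline_config(regime = "wga2")
tab  <- build_pileup(sim$reads, ref, cfg)
bg   <- estimate_background(tab, cfg)
cand <- call_candidates(tab, bg, cfg, sample_id = "S1", patient_id = "P1")
subset(cand, called, select = c(pos, ref, alt, count, depth, percent))
#>     pos ref alt count depth percent
#> 315 120   A   C   991  9450   10.49
#> 839 210   G   T   205  9423    2.18

called <- subset(cand, called, select = c(pos, ref, alt))
build_haplotype_table(assign_read_patterns(sim$reads, called, cfg))
#>           label mutant_reads wildtype_reads total_reads percent
#> 1        120A>C          803           9015        9818    8.18
#> 2 120A>C/210G>T          191           9538        9729    1.96
#> 3        210G>T            7           9783        9790    0.07
```

The background (mean 0.032 %, sd 0.028 % over 898 below-floor observations)
puts both variants far beyond the `m + 4s` threshold and the 1 % WGA2 floor.
The pileup percentages (10.49 %, 2.18 %) measure the *positions*: position
120 carries the allele in both haplotypes (8 % + 2 %). The haplotype table
separates them — exclusive patterns at 8.18 % and 1.96 %, each with its own
coverage-dependent total; the 7-read `210G>T` singleton row is residual error
(0.07 %, far below any calling threshold). Detected protein-level mutants map
to therapy guidance:

```r
lookup_profile(c("F877L", "T878A"))
#> Therapy profile for: F877L, T878A
#>  construct hydroxyflutamide bicalutamide enzalutamide  ARN509
#>      F877L          Partial           No      Partial Partial
#>      T878A          Partial          Yes      Partial Partial
#>   retained-antagonist options: none
```

For F877L alone, bicalutamide is retained; the T878A co-occurrence removes
it. `run_pipeline()` (see `?run_manifest`) composes all stages over a cohort
manifest, and `inst/scripts/ampvar-pipeline.R` exposes the same entry points
from a shell.

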