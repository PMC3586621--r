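# skinktrace

Phylogeographic tracing of invasive lizards intercepted by biosecurity
agencies.

When a stowaway lizard is intercepted at (or after) a national border, three
explanations compete: it belongs to the already-established invasive
population, it was moved within the country by freight ("jump dispersal"),
or it is a fresh arrival direct from the native range. `skinktrace`
implements the mitochondrial-DNA workflow that separates these cases for the
delicate skink (*Lampropholis delicata*), New Zealand's only invasive
lizard, and scores the interception database's recorded origin predictions
against the molecular evidence. Everything is driven by tibbles and composes
with the pipe, so the package slots into ordinary tidyverse analyses.

## The method

1. **Haplotypes.** Aligned mtDNA sequences (the study used 1221 bp of
   concatenated *ND2* + *ND4*) are checked for premature stop codons under
   the vertebrate mitochondrial code and collapsed to haplotypes: sequences
   sharing an identical aligned string share a haplotype.
2. **Distances.** Pairwise divergence is corrected with the Tamura–Nei
   (TN93) model, which allows unequal base frequencies and distinct purine
   (A↔G) and pyrimidine (C↔T) transition rates:

   *d* = −*k*₁ ln *w*₁ − *k*₂ ln *w*₂ − *k*₃ ln *w*₃,

   with *k*₁ = 2*g*A*g*G/*g*R, *k*₂ = 2*g*T*g*C/*g*Y,
   *k*₃ = 2(*g*R*g*Y − *g*A*g*G*g*Y/*g*R − *g*T*g*C*g*R/*g*Y),
   *w*₁ = 1 − *P*₁*g*R/(2*g*A*g*G) − *Q*/(2*g*R),
   *w*₂ = 1 − *P*₂*g*Y/(2*g*T*g*C) − *Q*/(2*g*Y) and
   *w*₃ = 1 − *Q*/(2*g*R*g*Y), where *P*₁, *P*₂ and *Q* are the observed
   purine-transition, pyrimidine-transition and transversion proportions.
   p, Jukes–Cantor and Kimura-2-parameter distances, base-composition
   summaries, a compositional-homogeneity chi-square test and
   variable/parsimony-informative site counts are included.
3. **Trees.** Neighbour-joining with the rate-corrected Q criterion, a
   deterministic tie rule, non-negative branch lengths and newick I/O;
   per-clade monophyly reports over the resulting tree.
4. **Classification.** Each intercepted specimen is run through a cascade:
   distance 0 to the established-population haplotype set → local origin;
   within 0.3 % (`close_tol`) → a previously undetected haplotype from the
   same source region, still local origin; otherwise a **new arrival**,
   whose source region is the locality of the nearest native-range
   haplotype. Local-origin animals detected outside the established range
   are **within-country movements**.
5. **Records.** Interception-record analytics (austral seasonality,
   transport vector, border vs post-border stage, survival, life stage,
   freight origins and destinations) and tiered scoring of the recorded
   origin predictions (exact / near, i.e. within roughly 100 km / far),
   with the study's three interception tables bundled as fixtures.
6. **Simulation.** A TN93 sequence simulator generates clade-structured
   reference panels (inter-clade divergence 1.8–8.3 %, within-region
   divergence ≤ 0.3 %, empirical base frequencies) and detection batches of
   all three true categories, so the whole pipeline is testable without any
   downloads.

## Worked example

Seasonality of the 13 confirmed new arrivals, from the bundled table:

```r
library(skinktrace)
t1 <- load_records("table1_delicata_new_arrivals")
summarize_records(t1, "season")
#> # A tibble: 4 × 5
#>   dimension level      n fraction percent
#>   <chr>     <chr>  <int>    <dbl>   <dbl>
#> 1 season    summer     1   0.0769       8
#> 2 season    autumn     4   0.308       31
#> 3 season    winter     5   0.385       38
#> 4 season    spring     3   0.231       23
```

Interceptions peak in the cooler months (winter 38 %, autumn 31 %). Scoring
the interception database's predicted source regions against the molecular
assignments:

```r
eq <- read_region_equivalence()
prediction_accuracy(t1, eq)
#> # A tibble: 1 × 7
#>       n n_exact n_near n_far n_no_prediction exact_pct exact_or_near_pct
#>   <int>   <int>  <int> <int>           <int>     <dbl>             <dbl>
#> 1    13       7      3     2               1      53.8                77
```

The database named the right source region for 7 of 13 arrivals (53.8 %)
and was within about 100 km for three more (77 % exact-or-near).
`tidy()` on the result returns the per-record tiers.

A full in-silico round trip — simulate a clade-structured native range,
draw detections of all three categories, classify them and compare with the
truth:

```r
cfg <- simulation_config(seed = 42, n_clades = 4, seq_length = 600,
                         detection_mix = c(local = 3, movement = 2, arrival = 3))
rec <- recovery_experiment(cfg)
glance(rec)
#> # A tibble: 1 × 3
#>       n category_accuracy source_accuracy
#>   <int>             <dbl>           <dbl>
#> 1     8                 1               1
```

In the separated-divergence regime the cascade recovers every category and
every source locality. `autoplot(rec)` draws the confusion matrix;
`autoplot()` methods also exist for distance matrices and record summaries.

A thin command-line binding with subcommands `haplotypes`, `distances`,
`tree`, `classify`, `summarize` and `simulate` is installed at
`system.file("cli", "skinktrace.R", package = "skinktrace")`.

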