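---
title: "Tracing intercepted invasive skinks from mitochondrial DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing intercepted invasive skinks from mitochondrial DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinktrace)
```

## The inference problem

An intercepted specimen of an invasive species admits three explanations:
it is a **local resident** of the established invasive population, a
**within-country movement** (human-assisted jump dispersal of a local
animal to a locality where the species has not established), or a **new
arrival** direct from the native range. Mitochondrial haplotypes separate
these cases because the established population descends from a narrow
introduction: its haplotype set is small and known, while the native range
is partitioned into geographically non-overlapping clades whose divergence
(about 1.8–8.3 % corrected distance in the system this package was built
around) dwarfs within-region variation (at most about 0.3 %). A query
haplotype therefore either sits inside the established set's neighbourhood
or points, via its nearest native-range relative, to a source region.

The package assumes (i) maternal, non-recombining inheritance, so each
specimen carries one haplotype; (ii) a reference panel dense enough that a
new arrival's true source region is represented; and (iii) the separation
of divergence scales above. Assumption (iii) is what makes a fixed distance
threshold meaningful; the simulator exists to make it explicit and
testable.

## The classification cascade

For a query sequence aligned to the panel, with `d_est` its minimum
corrected distance to the established haplotype set:

1. `d_est <= identical_tol` (default **0**): the haplotype is already known
   from the established population — local origin.
2. `d_est <= close_tol` (default **0.003** substitutions/site): a
   previously undetected haplotype, but within the band expected of the
   same source region — still local origin. The band's upper end follows
   the 0.2–0.3 % divergence observed between such haplotypes and the
   established set; because the boundary is a judgement call in the
   original analysis, it is an explicit, configurable parameter here.
3. otherwise: a new arrival, assigned to the locality of the nearest
   native-range haplotype (all ties at the minimum are reported).

Local-origin detections at a locality outside the established range are
within-country movements; inside it, local residents. Because
mitochondrial data cannot distinguish a resident from a fresh arrival out
of the *same* source region, tier-1/2 results carry the caveat
`local-or-same-source` rather than pretending to resolve the ambiguity.

Two properties follow by construction and are enforced by tests: a query
identical to an established haplotype is never classified as a new
arrival, for any thresholds; and raising `close_tol` never converts a
local-origin classification into a new arrival.

## Distances

The Tamura–Nei (TN93) correction is the workhorse because the empirical
base composition is strongly unequal (A = 0.326, C = 0.310, G = 0.120,
T = 0.244) and transitions dominate. Observed proportions are counted under
**pairwise deletion**: any site with a gap or ambiguity code in either
sequence of a pair is excluded for that pair only (complete deletion is
available by flag). The composition entering the correction is **pooled**
over the whole set by default, matching the convention of reporting one
composition per alignment; per-pair composition is available.

Numerical choices:

* **Saturation.** Whenever a logarithm argument of the correction is
  non-positive the distance is undefined; the pair is flagged `saturated`
  (value `NA`) instead of being replaced by an arbitrary large number. The
  neighbour-joining builder refuses saturated input outright, listing the
  offending pairs — silently substituting a cap would distort every branch
  of the tree.
* **Degenerate compositions.** If a base frequency required by a term is
  zero, the term is evaluated only when its observed proportion is also
  zero (it then contributes nothing); otherwise an error is raised.
* **Verification.** The implementation is checked against two independent
  routes: the closed forms collapse to Kimura-2-parameter under uniform
  composition (to 1e-12), and on regimes generated from a TN93 rate matrix
  via the matrix exponential the inversion recovers the generating
  divergence to better than 1e-9.

The compositional-homogeneity chi-square uses the per-sequence A/C/G/T
counts against the pooled expectation, with df = 3(N − 1) and an
upper-tail p-value.

## Neighbour joining

Standard Saitou–Nei agglomeration with the rate-corrected criterion
Q(i,j) = (m − 2)d(i,j) − R(i) − R(j). Ties are broken by the
lexicographically smallest (row, column) pair in current matrix order, so a
fixed matrix always yields the same tree. Negative branch lengths (which
cannot occur on additive input, recovered exactly in the tests) are clamped
to zero with the deficit transferred to the adjacent branch of the same
join; raw lengths are kept in a diagnostic attribute. No bootstrap support
is computed — support assessment belongs to likelihood/Bayesian machinery
outside this package's scope.

## Haplotype collapsing and frame checks

Two sequences share a haplotype iff they are character-identical
(`strict`, the default). The `ignore-ambiguous-sites` option first removes
every column containing a gap, `N` or IUPAC ambiguity anywhere in the set —
appropriate when sequencing artefacts would otherwise split real
haplotypes. Collapsing is performed on the concatenated multi-gene
alignment (not per gene): the concatenation is what the distance and tree
stages consume, and per-gene collapsing would only re-merge information the
pipeline immediately re-joins. Labels are assigned in first-appearance
order with a zero-padded suffix, so permuting the input permutes labels but
never the partition.

Protein-coding fragments are screened for premature stop codons under the
vertebrate mitochondrial code (AGA/AGG are stops there, in addition to
TAA/TAG); the reading-frame offset is a parameter because a trimmed
alignment need not start on a codon boundary.

## Record analytics

Seasons use the **austral** mapping (Dec–Feb summer, Mar–May autumn,
Jun–Aug winter, Sep–Nov spring) — the only mapping consistent with every
seasonal percentage the bundled tables imply. Percentages are rounded half
away from zero to integers; the exact-tier prediction accuracy is reported
to one decimal. Group detections (one shipping container held about eight
animals, of which one was vouchered) are one record with a `group_size`
field, and all proportions count detection events, not individuals.

Source-region matching is **name-based**, not geodesic: the underlying
reasoning is in named localities and approximate distances, so a bundled
equivalence table encodes the stated pairings at two tiers (`exact`, e.g.
Caboolture bordering northern Brisbane; `near` for localities roughly
within 100 km, e.g. Gold Coast–Brisbane, Wyong–Sydney). Locality names are
normalized case-insensitively with punctuation stripped; a parenthetical
qualifier is a sub-region, so a bare "Brisbane" matches "Brisbane (South)"
at the exact tier while "Brisbane (North)" vs "Brisbane (South)" is only
near. Predictions listing alternatives ("Adelaide or Melbourne") and tied
confirmations score at their best tier — a documented generosity.

Two fixture caveats are surfaced rather than reconciled: the within-country
table's adult flags give 15/24 = 62.5 % while the accompanying text says
58 %; and whether Palmerston North counts 6 or 7 movement records depends
on the locality's establishment date (~2007), which the table's month-only
records cannot resolve — those rows carry a note column. The established
range is supplied as an explicit locality list
(`read_established_localities()`), bundled with the northern-North-Island
localities the tables require.

## What the simulator emulates — and what it does not

`simulate_reference_panel()` draws a root sequence from the configured
composition, evolves one ancestor per clade by discrete TN93-rate
substitutions at distinct sites to depths that place between-clade
distances inside the target band, then scatters locality founders and
haplotypes within the intra-region band. The discrete scheme (exact
substitution counts at sampled sites, not a continuous-time matrix
exponential) is deliberately simple and auditable: the divergence bands are
verified empirically by recomputing distances with the package's own
distance module, with 20 % sampling slack. The established set is drawn
from the first locality of the source clade, each haplotype within one
substitution of the founder.

The generator reproduces the features the cascade relies on — clade
structure, band-separated divergence scales, a compact established set —
but not coalescent genealogies, demography, migration, rate heterogeneity
among sites, or coding constraints (generated sequences are not ORFs; the
stop-codon check is exercised on hand-built alignments instead). Passing
recovery tests therefore demonstrate the *logic* of the cascade under its
stated assumptions, not robustness to real-data violations of them.

Default problem sizes keep the suite quick while exercising every path:
panels of nine clades × three localities at 1221 bp, recovery batches of
300 detections, 50 random trees for the additive-recovery property and 100
random regimes for the distance-inversion property.

## Limitations

* Assignment is nearest-haplotype by distance; no probabilistic or
  tree-topology-based placement, and no admixture inference.
* A new arrival from the established population's own source region is
  indistinguishable from a resident (flagged, not resolved).
* GTR-class corrections, rate heterogeneity (+I, +G) and model selection
  are out of scope; saturated pairs are refused, not rescued.
* Region equivalence is only as good as the bundled table; users with
  coordinates may prefer to extend it rather than rely on name matching.
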