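---
title: "Methods: two-track provenance inference from mtDNA panels and stable isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-track provenance inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoprov)
```

paleoprov infers the likely geographic origin of unidentified skeletal
remains from two independent lines of evidence: maternal ancestry, read
from mitochondrial DNA genotyped at a diagnostic SNP panel, and residence
history, read from oxygen and carbon isotope ratios in tooth enamel
carbonate. The two tracks share nothing but the final report, so either
can run alone.

## The genetic track

### Haplogroup trees and diagnostic panels

Human mtDNA variation is organised as a rooted tree of haplogroups, each
defined by the substitutions accumulated on its branch relative to the
revised Cambridge Reference Sequence (rCRS, 16,569 bp, 1-based
coordinates). `parse_haplotree()` reads the common tab-indented export
dialect: one label per line, one extra leading tab per nesting level,
defining variants as space-separated tokens like `C16223T` (ancestral
base, position, derived base) with `!` marking a back-mutation and an
optional omitted ancestral base resolved against an rCRS FASTA.
Insertions, deletions and heteroplasmy notation are out of scope: the
intended genotyping platform (multiplex primer-extension mass
spectrometry) assays point substitutions only.

The packaged tree is a curated synthetic stand-in of ~70 nodes that
covers the macrohaplogroups (L0--L3, M, N, R) and the South Asian, West
Eurasian and East Eurasian clades needed by the default region rules.
Its defining variants are plausible rCRS-coordinate substitutions, with
a handful of well-known anchors; it is not a copy of any published tree,
and both the tree and the 115-site panel (four multiplex pools of 23,
36, 31 and 25 sites) are user-replaceable files. The packaged panel's
positions are exactly the variant positions of the packaged tree, which
lets the reference allele at every site be derived from the tree itself
(the ancestral allele of the variant nearest the root).

### Scoring and calling

A sample's genotype vector is scored against every haplogroup with the
Kulczynski similarity used in standard haplogroup-calling practice: the
mean of *recall* (matched expected derived states over all expected
derived states) and *precision* (matched over all observed derived
calls), with the convention 0/0 = 1 so the root scores 1 on an
all-reference sample. Three choices matter:

* **Missing calls are excluded from every count.** An assay dropout
  carries no information; treating it as a reference call would bias
  scores towards shallow nodes.
* **Genotyping error is absorbed by the precision term.** A spurious
  derived call penalises every haplogroup that does not expect it.
  Panel-scale data (115 sites) are too sparse to fit an explicit error
  model, so none is attempted.
* **Ties break towards depth, then lexicographically.** When a
  terminal clade's private sites all drop out, its score equals its
  parent's; we return the deeper label so that output is deterministic
  and the call is as specific as the data allow. Whether a human analyst
  would resolve such ties towards the terminal or the ancestral label is
  genuinely ambiguous; the choice is recorded in the call output.

`call_haplogroup()` evaluates every node exhaustively (the tree is
desk-scale), and the test suite checks it against an independently
written brute-force oracle, so any future pruning must preserve exact
argmax equivalence.

### Regional ancestry

`default_region_map()` encodes the standard regional affiliations of
South Asian mtDNA haplogroups: South Asian (M2--M6, M18, M25, M30--M67,
N5, R5--R8, R30--R32, U2a, U2b), West Eurasian (HV, H, J, K, R0, R1,
R2, U1--U5, U7, U8, U9, W, X) and East Eurasian (the macro-clade
letters A--G, M7--M12, R22, N9). Numeric ranges expand to explicit
labels; the "A--G" set is alphabetic, a list of seven macro-clade
letters, because no numeric reading of that range is coherent.
`assign_region()` walks a haplogroup's ancestor path and lets the
longest matching rule pattern win, which is what gives the sub-clade
carve-outs meaning: U2a is South Asian although its parent U2 falls in
the West Eurasian U1--U5 block. Prefix matches stop at letter/digit
boundaries so that a rule for M3 can never capture M39. Unmatched
labels are reported as Unclassified rather than dropped, so regional
counts always sum to the cohort size.

Cohort-level differences in one ancestry component are tested with
Fisher's exact test on the 2x2 table (focus region vs the rest, cohort
A vs cohort B), two-tailed as the sum of all table probabilities no
larger than the observed table's. An exact test was chosen over a
normal-approximation z-test because archaeological cohorts are small
(tens of samples) and component counts are often near zero.

### Population placement by PCA

`pca_frequencies()` performs principal component analysis of the
population-by-haplogroup frequency matrix: columns are mean-centered
but not rescaled (frequencies already share a scale, and unit-variance
scaling would inflate the noise of rare haplogroups), then decomposed
by SVD. The study cohort is included as an active row rather than
projected post hoc, matching how such analyses are usually plotted.
Eigenvalues use the sample-covariance convention (denominator
`n - 1`), so their sum equals the total variance of the centered
matrix. Sign indeterminacy is resolved by making the
largest-magnitude loading positive within each component. The
haplogroup resolution of the columns (macro vs sub-haplogroup) is left
to the caller, since published analyses differ; the packaged reference
table uses sub-haplogroup resolution.

The packaged reference table is itself synthetic (see below); real
published state-wise frequencies should be supplied as a long-format
CSV for real analyses.

## The isotope track

Enamel-carbonate oxygen isotope ratios record the drinking water
consumed during tooth formation. The package inverts the empirical
enamel calibration

d18Oc = 0.77 x d18Odw + 28.1 (permil, VSMOW)

to back-calculate drinking-water values, keeping full precision
internally and rounding to one decimal only in reports. Applied to
carbonate extrema of 25.8, 23.3 and 26.0 permil this gives -3.0, -6.2
and -2.7 permil. Note that a carbonate value of 21.4 permil yields
-8.7 at one decimal through this equation; a quoted lower bound of
-8.8 for such data is not reproducible from the equation and is
treated as a reporting discrepancy, not a target.

`classify_locality()` compares the drinking-water value against
regional reference intervals, widened by a tolerance (default 0.5
permil, acknowledging analytical error and seasonal spread of meteoric
water) and closed at the boundaries. The packaged reference ranges are
illustrative configuration, editable CSV, because reliable regional
values must come from local water-survey data.

Diet is read from carbon: bioapatite carbonate is enriched in 13C by
roughly 9--15 permil relative to diet, and C3 plants (wheat, barley,
legumes) are strongly depleted relative to C4 plants (millets). With
diet endmembers of -26.5 (C3) and -12.5 (C4) permil VPDB and the
midpoint enrichment of 11.5 permil, the enamel endmembers default to
-15.0 and -1.0 permil. `percent_c4()` interpolates linearly between
them (clipped to [0, 1]) and `classify_diet()` buckets the fraction at
0.25 and 0.75, boundaries counted as mixed. VSMOW/VPDB scale
conversions, phosphate-oxygen thermometry and strontium systems are
out of scope.

## The synthetic-data generator

Every stage is testable offline because the package can generate
cohorts with the statistical structure the analysis assumes:

* `simulate_cohort_genotypes()` draws each sample's haplogroup from a
  stated distribution, emits its exact expected panel profile, then
  applies independent per-call dropout and uniform-substitution
  genotyping error. The default cohort of 50 samples at 5% dropout and
  1% error reflects a well-preserved ancient-DNA panel run; the
  "Gangetic" scenario distribution mirrors the kind of composition the
  package targets (M39-rich, R32 present, ~10% West Eurasian
  lineages).
* `simulate_reference_frequencies()` builds a 14-population reference
  table along a 1-D geographic coordinate with the West-Eurasian
  fraction declining linearly from 0.45 in the north-west to 0.05 in
  the far east/south, a constant 5% East-Eurasian component, and
  within-pool compositions tied to a shared Dirichlet base at
  concentration 50 — published state-wise tables are spatially
  autocorrelated, and without that coupling pool-composition noise
  would drown the cline.
* `simulate_isotope_cohort()` draws drinking water from region-specific
  Gaussians (Punjab -7.5 +/- 0.6, Gangetic plain -4.5 +/- 0.9, coastal
  -2.5 +/- 0.6 permil), pushes it through the forward carbonate model
  with 0.2 permil analytical noise, and generates d13C from
  Beta(2, 4)-distributed C4 fractions through the forward mixing model.

All randomness flows from one explicit seed per spec and the caller's
RNG state is restored afterwards, so runs are reproducible and
composable. What the generator does **not** emulate: post-mortem DNA
damage (deamination), contamination, heteroplasmy, coalescent
relatedness between samples, linkage between panel sites beyond the
tree structure, and diagenetic alteration of enamel. Passing tests
therefore demonstrate the pipeline's correctness and statistical
behaviour under its own model, not robustness to every artefact of
real ancient material.

## Numerical choices and problem sizes

Scores and frequencies are exact rational arithmetic in doubles; no
tolerance is applied when ranking haplogroups (ties are exact). PCA
checks use 1e-8 tolerances against an independent
eigendecomposition. The isotope round trip holds to 1e-9 before
rounding. Fisher p-values match a brute-force hypergeometric
enumeration to 1e-9 over every 2x2 table with all margins at most 30
(about 160,000 tables). Caller validation uses a 500-sample seeded
cohort at 20% missingness, where the generating haplogroup or one of
its ancestors must be recovered in at least 95% of samples; these
sizes give stable statistics while keeping the default test run at
roughly two minutes.

## Known limitations

* The packaged tree, panel and reference frequencies are synthetic
  stand-ins: adequate to validate the machinery, not a basis for real
  inference. Supply the published tree, the real panel definition and
  published frequency tables.
* The caller has no explicit likelihood model; with very high error or
  missingness the Kulczynski score degrades gracefully but offers no
  calibrated uncertainty.
* Reference-population Fisher comparisons convert published
  frequencies to pseudo-counts at an assumed sample size
  (`reference_n`, default 100), which approximates, rather than
  reproduces, the original studies' cohort sizes.
* Locality classification is interval membership against drinking-water
  ranges; it does not model altitude, evaporation or breastfeeding
  effects on enamel values.
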