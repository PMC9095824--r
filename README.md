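# paleoprov

Two-track geographic-provenance inference for unidentified skeletal
remains, aimed at biomolecular archaeologists and forensic
anthropologists working with degraded material.

**Genetic track.** Mitochondrial haplogroups are called from a
diagnostic SNP panel (point substitutions against the rCRS, genotyped
in multiplex pools) by scoring each sample against every node of a
PhyloTree-style haplogroup tree with the Kulczynski similarity

    score(s, h) = 1/2 * ( n_matched / n_expected  +  n_matched / n_observed_derived )

where `n_expected` counts the haplogroup's expected derived states at
evaluable (non-missing) panel sites, `n_observed_derived` the sample's
non-reference calls there, and 0/0 = 1. Calls are aggregated into
haplogroup and macrohaplogroup frequencies, mapped onto regional
ancestry classes (South Asian / West Eurasian / East Eurasian),
compared between cohorts with Fisher's exact test, and placed among
reference populations by PCA of the population-by-haplogroup frequency
matrix (column-centered, unscaled, SVD).

**Isotope track.** Tooth-enamel carbonate δ18O is converted to
drinking-water δ18O by inverting the enamel calibration

    δ18Oc = 0.77 · δ18Odw + 28.1   (‰, VSMOW)

and compared against regional drinking-water reference intervals
(closed, tolerance-widened) to flag each individual as local or
non-local. Enamel δ13C is converted to a C4 dietary fraction by linear
two-endmember mixing (defaults −15.0 ‰ for a pure C3 diet, −1.0 ‰ for
pure C4, i.e. diet endmembers −26.5/−12.5 ‰ plus 11.5 ‰ bioapatite
enrichment) and bucketed into C3-dominant / mixed / C4-dominant diets.

A seeded synthetic-data generator (genotype cohorts with dropout and
genotyping error, reference frequency tables along a west-Eurasian
cline, region-specific Gaussian isotope cohorts) makes every stage
testable with no external data. The packaged tree, panel and reference
frequencies are labelled synthetic stand-ins; supply real files for
real analyses.

## Worked example

Simulate a 50-sample cohort with Gangetic-plain parameters, analyse it
against a Punjab locality, and print the report:

```r
library(paleoprov)

report <- run_provenance(list(
  cohort_id = "Aj",
  simulate_genotypes = list(scenario = "Gangetic", n_samples = 50),
  simulate_isotopes  = list(region = "GangeticPlain", n = 50),
  local_region = "Punjab"), seed = 13)
print(report)
```

```
== paleoprov provenance report: Aj ==
seed 13 | config b7f23dd7a6a56a707f34d5e7f429aa87 

-- Genetics --
top haplogroups: M39 (0.20), M30 (0.10), M6 (0.10), M2 (0.08) 
macro frequencies: M 0.68, N 0.04, R 0.28 
ancestry: SouthAsian 0.92, WestEurasian 0.06, EastEurasian 0.02, Unclassified 0.00 
nearest reference populations: Ap, Up, Mp 

-- Isotopes --
n = 50; non-local fraction vs Punjab: 0.94
diet: C3-dominant 18, C4-dominant 1, mixed 31 

-- Verdict --
majority ancestry: SouthAsian 
fraction non-local: 0.94
```

Reading the output: the cohort is dominated by the South Asian
haplogroups M39 and other M sub-clades (macro-M 0.68) with a minor West
Eurasian component, its PCA position falls nearest the eastern
reference populations (Andhra Pradesh, Uttar Pradesh, Madhya Pradesh),
and 94% of individuals carry drinking-water δ18O values inconsistent
with the Punjab reference interval — a non-local, eastern-origin
cohort with a C3-to-mixed diet. Passing `out_dir =` writes the
per-stage CSV artifacts (`calls.csv`, `ancestry.csv`,
`pca_coordinates.csv`, `isotope_results.csv`, ...) plus `report.json`
and `report.txt`, each stamped with version, config hash and seed.

Individual stages are available as plain functions
(`call_cohort()`, `ancestry_proportions()`, `compare_ancestry()`,
`pca_frequencies()`, `analyze_isotopes()`, `simulate_*()`), and a thin
CLI with subcommands (`run`, `call`, `ancestry`, `pca`, `isotope`,
`simulate`) ships in `inst/scripts/paleoprov.R`.

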