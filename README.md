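# bcrcompare

Cross-species comparison of naive B-cell receptor (BCR) repertoires in R.

Humanised immunoglobulin-loci transgenic mice (such as the Kymouse, which
carries the human IGH/IGK/IGL variable genes on mouse constant regions) are
widely used for therapeutic antibody discovery and vaccine-response
modelling, which raises a quantitative question: how human-like are their
naive repertoires? `bcrcompare` implements the repertoire-level statistics
needed to answer it from AIRR-seq data — for immunologists and
computational biologists comparing antigen-inexperienced heavy/light chain
repertoires between humans, wild-type mice and humanised models — and
ships a seeded V(D)J recombination simulator with human, C57BL/6 and
Kymouse presets so that the full workflow runs and is tested without any
external downloads.

## What it computes

* **Germline gene usage** — per-subject V/D/J gene and subgroup frequency
  profiles, kappa:lambda ratios, Z-normalised hierarchical clustering, and
  a separability protocol: repeated random subsampling to a common depth
  (default 105 sequences, 100 repeats), reclustering, and the fraction of
  repeats in which the species separate perfectly by the adjusted Rand
  index (ARI = 1).
* **Clonotypes and sharing** — clonotypes per the standard rule (shared
  IGHV and IGHJ genes and ≥ 90% amino-acid identity across length-matched
  CDRH3s, single-linkage closure), exact-CDRH3 sets, and pairwise sharing
  matrices under three denominator conventions (mean of directional
  fractions, min, Jaccard).
* **Diversity** — Shannon entropy `H = −Σᵢ pᵢ ln pᵢ` of CDRH3 or clonotype
  abundances, overall and per CDRH3 length, plus unique-per-sequence
  ratios and subsampled gene richness.
* **Junction decomposition** — per-sequence CDR3 anatomy
  (`cdr3_nt = v_tail + np1 + d_align + np2 + j_head`) and a five-factor
  bootstrap decomposition of the CDRH3 length difference between two
  groups: each factor's contribution in nucleotides with a percentile 95%
  CI and sign-crossing p-value.
* **Structural-cluster usage** — comparison of repertoires by usage of
  per-sequence categorical structural annotations (CDRH3 structural
  cluster IDs, canonical classes): usage-distance clustering with ARI,
  species-origin composition of the clusters used, length-stratified
  enrichment versus a template background (exact binomial, 1% level),
  greedy leader clustering, and length-balanced subsampling.

## Worked example

```r
library(bcrcompare)

# simulate two small cohorts of naive repertoires
hu <- simulate_repertoire(simulation_config("human",   3, 2000, seed = 1))
ky <- simulate_repertoire(simulation_config("kymouse", 3, 2000, seed = 2))
hu <- lapply(hu, collapse_unique); ky <- lapply(ky, collapse_unique)
hu[[1]]
#> <repertoire> subject human_01 (human): 2397 records (1333 heavy, 1064 light)
#>   provenance: simulated (seed 1140350788); collapsed 4000 reads to 2397 unique sequences

# light-chain locus usage: the humanised model is near 50:50
round(kappa_lambda_ratio(ky[[1]]), 1)
#>  kappa lambda
#>   52.2   47.8

# fraction of sequences with no VD / DJ insertions
round(zero_insertion_fractions(ky[[1]]), 3)
#>   vd_zero   dj_zero both_zero
#>     0.206     0.137     0.027

# five-factor bootstrap decomposition of the CDRH3 length difference
dec <- decompose_length_difference(hu, ky, n_reps = 1000, seed = 3)
dec$summary
#>   factor    estimate   ci_lo  ci_hi     p units
#> 1 v_cdr3_nt   0.0318 -0.0840  0.152 0.574 nt
#> 2 np1         3.87    3.63    4.12  0.001 nt
#> 3 d_align     1.61    1.25    1.95  0.001 nt
#> 4 np2         3.89    3.65    4.10  0.001 nt
#> 5 j_cdr3_nt  -1.06   -1.19   -0.932 0.001 nt
#> 6 total_aa    2.78    2.62    2.96  0.001 aa
```

Reading the decomposition: human CDRH3s are ~2.8 aa longer than Kymouse
CDRH3s in these simulations, and almost all of that difference comes from
the VD (`np1`, +3.9 nt) and DJ (`np2`, +3.9 nt) non-templated insertions,
with a smaller contribution from longer D-gene alignments (+1.6 nt),
slightly offset by the Kymouse's preference for long IGHJ genes (−1.1 nt).
The germline V-tail factor is null (CI spans 0). The five nucleotide
factors sum to exactly three times the amino-acid total.

## Analysis workflow

The numbered scripts under `analysis/` run the whole study as a narrative
workflow: `01_simulate.R` writes AIRR Rearrangement TSVs for three
simulated cohorts under `scratch/data/`, then `02_gene_usage.R`,
`03_clonal_diversity.R`, `04_junction_decomposition.R` and
`05_structural_usage.R` re-read them through the package's I/O path and
write tidy summary tables under `results/`. Run them in order from the
repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`run_pipeline()` offers the same stages as a single call driven by one
(optionally YAML) config with every convention surfaced as a named flag.

## Scope notes

The simulator models naive, unmutated repertoires only (no somatic
hypermutation, class switching or selection). Structural analyses consume
annotation tables (the output contract of tools like SCALOP/FREAD-based
pipelines); structure prediction itself is out of scope. See the methods
vignette (`vignettes/repertoire-comparison.Rmd`) for the models,
parameter calibration and design decisions.
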