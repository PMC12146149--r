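# csfcompile

Cross-study compilation of differential protein expression in cerebrospinal
fluid (CSF) proteomics.

## The problem

CSF proteomics studies of Alzheimer's disease versus amyloid-negative
controls are published on three incompatible platform classes — mass
spectrometry (MS), Olink proximity extension assays and SomaScan aptamer
panels — with inconsistent protein identifiers, per-study significance
cutoffs, mixed fold-change scales and orientations, and partially
overlapping measured panels. `csfcompile` is for researchers who want to
ask, reproducibly: *which proteins recur as differentially expressed across
studies, in which direction, with what compiled effect, in which biological
processes, and at which disease stage?*

## What it computes

- **Harmonization** (`harmonize_protein_id`, `read_study_table`): protein
  groups keep their first entry, UniProt isoform suffixes are stripped
  (hyphenated gene symbols like `NKX2-1` survive), symbols are uppercased;
  fold-changes are mapped to log2 scale and to a common case-over-control
  orientation at ingest.
- **Recomputation** (`recompute_diffexp`): for studies shipping raw
  abundances, log2FC = mean difference (log2 scale) or log2 ratio of means
  (linear), unpaired two-sided t-test (Welch by default), BH step-up FDR.
- **Cross-study landscape** (`count_study_overlap`, `select_top_deps`,
  `upset_intersections`, `platform_partition`,
  `classify_direction_consistency`, `compile_summary`): recurrence counts,
  exact UpSet membership patterns, MS/affinity partition, and strict
  any-disagreement direction consistency.
- **Forest compilation** (`forest_table`): per-protein unweighted mean
  log2FC over all quantifying MS studies regardless of significance, with a
  95% t interval (mean ± t₀.₉₇₅,ₙ₋₁·sd/√n); affinity effect scores are
  never mixed in.
- **Enrichment** (`build_background`, `hypergeometric_enrichment`,
  `cluster_query`): upper-tail hypergeometric P(X ≥ k) against the union of
  MS-measured proteins, BH-FDR ≤ 0.05 and strength
  log10((k/n)/(K/N)) ≥ 0.01; k-means grouping of annotation profiles.
- **Progression & tissue** (`assign_stage`, `tissue_concordance`): binning
  of first-change times relative to familial-disease onset into
  Early/Mid/Onset/Late, and CSF–brain-tissue direction concordance above a
  recurrence threshold.
- **Covariates** (`covariate_analysis`): Pearson r and simple least-squares
  regression of DEP counts on panel depth and sample size.
- **Synthetic worlds** (`sim_config`, `generate_studies`): multi-study
  simulations with planted recurrent DEPs, platform asymmetry and known
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(csfcompile)

cfg <- sim_config(n_studies = 10,
                  platform_assignment = rep(c("MS", "Olink", "SomaScan"), c(7, 2, 1)),
                  n_proteins_universe = 800, panel_size = 400,
                  n_planted_top = 25, planted_min_recurrence = 5,
                  effect_size_log2 = 1, seed = 42)
sim <- generate_studies(cfg)
reg <- build_registry(sim$datasets)
reg
#> <study_registry> 10 comparisons (MS: 7, Olink: 2, SomaScan: 1)
#>   union of measured symbols: 793

s <- compile_summary(reg, min_studies = 5)
s$n_deps_total; s$n_single_study; s$n_top
#> [1] 215
#> [1] 166
#> [1] 25
s$platform_partition
#>       ms_only affinity_only          both
#>           126            52            37
```

215 distinct proteins were significant somewhere; 166 in a single study
only; all 25 planted recurrent DEPs reach the recurrence threshold
(`setequal(s$top_symbols, sim$truth$true_top_set)` is `TRUE`). Direction
consistency over the top set: 20 consistently up, 5 consistently down —
exactly the planted split. Compiled effects:

```r
head(forest_table(s$top_symbols, reg), 3)[, c(1, 3:7)]
#>      symbol mean_log2fc    ci_low     ci_high n_studies_quantified call
#> 1 PROT00024  -1.1632476 -1.308851 -1.01764447                    5 down
#> 2 PROT00303  -0.7634074 -1.379666 -0.14714926                    5 down
#> 3 PROT00283  -0.7540053 -1.430530 -0.07748053                    5 down
```

A `down` call means the mean and both 95% bounds are below zero.

On the shipped overview of 21 published comparisons
(`csf_study_overview()`), screening depth — not sample size — tracks the
number of DEPs a study reports:

```r
res <- covariate_analysis(overview_covariates(), platform = "MS")
#> depth vs DEPs:        r = 0.722 (p = 0.0024), adjusted R^2 = 0.4848
#> sample size vs DEPs:  r = -0.059 (p = 0.828)
```

## Command line

```sh
inst/exec/csfcompile simulate   --config sim.json --out simdir/
inst/exec/csfcompile overlap    --registry simdir/registry.json --min-studies 6 --top-n 32 --out results/
inst/exec/csfcompile covariates --registry simdir/registry.json --platform MS --out results/
```

See `vignettes/csf-compilation-methods.Rmd` for the model, parameter
choices, boundary conventions and known limitations.
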