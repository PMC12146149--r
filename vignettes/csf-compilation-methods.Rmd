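---
title: "Methods: compiling differential protein expression across CSF proteomics studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compiling differential protein expression across CSF proteomics studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfcompile)
```

## The problem

Dozens of cerebrospinal fluid (CSF) proteomics studies have compared
Alzheimer's disease patients with amyloid-negative controls, on three
incompatible platform classes: mass spectrometry (MS, in TMT/DIA/SRM/SWATH
flavours), Olink proximity extension assays, and SomaScan aptamer panels.
Each study publishes its own protein identifiers, its own significance
cutoff, sometimes a log2 fold-change, sometimes a linear one, sometimes only
an abstract effect score, and sometimes only raw per-sample abundances. A
protein reported as changed in one study may be absent from another simply
because it was never on that study's panel.

`csfcompile` turns this heterogeneous landscape into a single comparable
compilation: which proteins recur as differentially expressed across
studies, in which direction, with what compiled effect size, in which
biological processes, at which disease stage, and with what concordance to
brain tissue.

## Identifier harmonization

Cross-study counting needs one symbol per protein. The rules are purely
string-level and deterministic:

1. protein groups (`"YWHAZ;YWHAB;YWHAG"`) keep the first entry;
2. a trailing `-<digits>` is treated as a UniProt isoform suffix and
   stripped **only** when the remaining stem looks like a UniProt accession
   (a letter followed by 5 or 9 alphanumerics). This keeps hyphenated gene
   symbols such as `NKX2-1` intact, which naive suffix stripping would
   mangle;
3. uppercase.

No remote mapping service is consulted: synonymous gene symbols that differ
beyond case are *not* reconciled, which matches how the compiled study
tables were published but can in principle split one protein across two
symbols. Duplicate symbols inside one study (isoforms, case variants)
collapse to the row with the smallest p-value, or the first occurrence when
no p-value exists.

## Per-study significance and recomputation

A protein is a differentially expressed protein (DEP) in a study if that
study's own FDR cutoff flags it — the compilation respects each study's
definition rather than re-thresholding. When a study ships raw per-sample
abundances instead of summary statistics, `recompute_diffexp()` rebuilds
them: log2 fold-change as a difference of group means (log2 scale) or log2
ratio of group means (linear scale), an unpaired two-sided t-test, and
Benjamini–Hochberg step-up adjustment. Two choices deserve a note:

* **Welch vs pooled t.** "Unpaired two-sided t-test" underdetermines the
  variance assumption. The default is Welch (unequal variances), the default
  of the statistical environment this field works in; the pooled form is one
  flag away (`var_equal = TRUE`) and is what the hand-checkable worked
  example in the test suite uses (groups `{3,4,5}` vs `{1,2,3}`:
  t = 2.449, df = 4, p = 0.0705).
* **Degenerate variance.** When both groups have zero variance the t
  statistic is undefined; the package reports p = 0 when the means differ
  and p = 1 when they are equal, with a warning, rather than NaN.

Proteins with fewer than two usable values in either group are excluded
from recomputation and reported, never silently imputed.

## Fold-change harmonization and forest compilation

All comparable fold-changes are mapped to log2 space and to a common
orientation (positive = higher in disease); a contrast published
control-over-case is negated at ingest. Olink does not report fold-changes
and SomaScan's "beta" score is not translatable to one, so affinity
platforms contribute significance calls and panel membership but never
effect sizes.

For each top DEP, `forest_table()` compiles the mean log2 fold-change over
**every MS study quantifying it, regardless of significance** — restricting
to significant studies would bias effects away from zero. The 95% interval
is `mean ± t(0.975, n−1) · sd/√n`. A t interval (not normal) is used
because n is small (typically ≤ 13 contributing studies); with a single
contributing study no interval is drawn at all rather than fabricating one.
A protein is called consistently down only when the mean and both bounds
are below zero (symmetrically for up); everything else is indeterminate.
No inverse-variance or random-effects weighting is applied: per-study
variances are mostly unpublished, so the compiled mean is deliberately the
unweighted average of study-level effects.

## Direction consistency

`classify_direction_consistency()` looks only at studies where the protein
was *significant* and a comparable fold-change exists. Any disagreement in
sign makes a protein `inconsistent` — no minority-fraction threshold is
applied, because none is defensible at n ≈ 6–14 studies. A fold-change of
exactly zero counts toward neither direction; a protein with no comparable
fold-change at all is `unclassifiable` and excluded from tallies rather
than silently binned.

## Enrichment against a measured background

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ k) of drawing k term members in an n-protein query from an N-protein
background containing K members, BH-adjusted across the tested terms and
filtered at FDR ≤ 0.05 and strength = log10((k/n)/(K/N)) ≥ 0.01. The
background is the union of proteins quantified across the **MS** studies
only: that is the set that had a chance to be observed, and the targeted
composition of affinity panels would bias a wider universe. Terms need at
least 2 background members to enter the tested universe. Annotations come
from a GMT file and are taken as given — no ontology-graph propagation.

Functional grouping of a query set (`cluster_query()`) runs k-means (k = 9
by default, fixed seed, 10 restarts) on binary protein-by-term membership
vectors. This is an explicit methodological stand-in for network-based
clustering services, which are not reproducible offline: proteins with
similar annotation profiles co-cluster, but the output is not a replica of
any external network analysis, and query proteins with no annotation are
labelled `unclustered` and excluded from ORA-style interpretation — the
same behaviour a missing database entry produces.

## Disease-stage binning and tissue concordance

Familial (autosomal dominant) Alzheimer's disease has a predictable onset
age, so biomarker trajectories can be expressed in years relative to onset.
`assign_stage()` bins first-change times into Early (t ≤ −25), Mid
(−25 < t < −5), Onset (−5 ≤ t ≤ 5) and Late (t > 5). The published prose
for these bins overlaps at the boundaries (−25, −5, +5); the convention
here gives −25 to Early and both ±5 to Onset, is documented, configurable,
and partitions the real line. First-change times are consumed from a small
input table because they are extracted manually from trajectory data; the
shipped `example_stage_table_synthetic.tsv` uses real protein symbols with
**synthetic** illustrative years and is fixture data, not a published
measurement.

`tissue_concordance()` compares CSF direction calls against a brain-tissue
compilation with a recurrence score, keeping tissue rows with recurrence
≥ 5 by default. The threshold is configurable because published phrasings
of such cutoffs ("at least 5", "score > 5") are often internally
inconsistent; `>=` with 5 was chosen and logged.

## Study-level covariates

`covariate_analysis()` asks what drives a study's DEP count. Both the raw
and adjusted R² of the simple regression are reported because with ~15
points they differ materially (0.52 vs 0.48 on the shipped overview) and
published summaries may quote either; the slope p-value equals the Pearson
p-value by construction. The panel-size analysis excludes studies with a
total n given by `exclude_total_n` (default 13): a very deep panel measured
on a handful of samples has essentially no power and acts as a pure
leverage point. The sample-size correlation uses all comparisons of the
platform. On the shipped 21-comparison overview:

```{r covariates}
res <- covariate_analysis(overview_covariates(), platform = "MS")
unlist(res$measured_vs_deps)
res$fit$adj_r_squared
unlist(res$samplesize_vs_deps)
```

## The synthetic world

`generate_studies()` exists so every pipeline stage is testable with known
ground truth and no downloads. Its defaults are a fixed stated world chosen
once to mirror the compiled real landscape, not tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_studies` / platforms | 21 (16 MS, 3 Olink, 2 SomaScan) | the compiled registry's shape |
| `n_proteins_universe` | 6704 | the MS-measured background size |
| `panel_size` | 1400 | median panel depth of the compiled studies (real panels range 48–6361; a scalar is a simplification) |
| `n_planted_top` | 61, recurrence ≥ 6 | the top-DEP set size and threshold |
| `frac_down` | 11/61 | the observed down-regulated share among top DEPs |
| `effect_size_log2` | 0.5 | typical reported CSF DEP magnitude; not stated anywhere, chosen once |
| `effect_sd` | 0.2 | between-study spread of effects, same rationale |
| `within_sd` | 1 | per-sample log2 abundance SD driving significance power |
| `alpha` | 0.05 | per-study significance level |

Each planted DEP is assigned to exactly `planted_min_recurrence` studies
and forced into their panels; panels share a common core
(`panel_overlap_fraction`) plus study-specific picks, reproducing the
observation that panel depth drives DEP counts. Null proteins draw
p ~ U(0,1) and are flagged at rate α — the generator emulates each study's
cutoff as a calibrated per-protein false-positive rate, which is exactly
the property the validation suite measures (0.05 ± 0.01 over 200
replicates). Planted proteins get p from a z-statistic
`effect · √n_eff / within_sd`. With `deterministic_sig = TRUE` the
noiseless regime recovers the planted top set, directions and forest mean
signs exactly, by construction.

What the generator does **not** emulate: peptide-level roll-up, missingness
structure, batch effects, correlated proteins, or affinity-platform effect
scores. A green synthetic test therefore establishes the correctness of the
counting, classification and compilation logic — not robustness to real
data pathologies upstream of protein-level tables.

## Known limitations

* Identifier harmonization is string-level; cross-study synonym splits are
  possible and uncorrected.
* The published sample-size/DEP-count correlation (−0.069) is not exactly
  recoverable from the shipped study-overview counts (closest
  reconstruction: −0.059 over all 16 MS comparisons); the overview's sample
  sizes are pre-QC, and the acceptance suite documents the residual
  mismatch rather than widening its tolerance.
* The per-protein compilation counts of the original landscape (1448 total
  DEPs, 61 top, ...) require the original per-study DEP lists, which are
  not redistributable here; the counting pipeline is validated on synthetic
  registries with enumerated truth instead.
* Enrichment results depend entirely on the supplied GMT; no ontology
  propagation is performed, so term-level results differ from services that
  propagate ancestors.
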