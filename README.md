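# chronopattern

Temporal-pattern analysis for two-condition time-course RNA-seq, built for
experiments of the form *vehicle vs. drug, sampled hourly, a few replicates
per point* — the typical design of chronological-lifespan and other
short-time-course intervention studies in yeast. Given a gene × sample
abundance matrix and its sample sheet, the package answers three questions:
which genes respond to time, to the drug, or to their interplay; *what shape*
each response takes; and which functional gene sets those shapes are
enriched for. A companion module handles lifespan-curve statistics.

## The method

For each gene *g*, expression on the log2 scale is modelled by a balanced
fixed-effects two-way ANOVA over T timepoints (default hours 1–6; hour 0 is
excluded) and 2 conditions with r replicates per cell:

```
y_ijk = μ + α_i (time) + β_j (drug) + (αβ)_ij + ε_ijk,   ε ~ N(0, σ²)
```

The three term-wise p-values (Time, Drug, Interaction) gate everything
downstream: genes with any `p ≤ α` (default 0.01) are differentially
expressed (DEGs), and the subset of significant terms places each DEG in an
Euler sector (`T`, `D`, `I`, `T&D`, …).

DEGs from the Time/Drug sectors are then matched to a library of canonical
temporal templates — flat, first/last-point changes, plateaus, spikes,
linear — each in two vertical reflections, crossed with three drug-effect
classes (↑/↓/↔ by the drug main effect), giving **63 patterns** for a
6-timepoint design. A gene is assigned the template with the highest Pearson
correlation to its standardized timepoint-mean profile, provided `r > 0.85`.
Templates holding more DEGs than the uniform 1/63 expectation are flagged by
a one-sided binomial test (`p ≤ 0.01`).

Interaction-significant genes change shape under treatment, so their
vehicle and drug profiles are matched independently and tabulated on a
21 × 21 shape grid; heavily populated cells (> 100 genes) are flagged, and
each gene's per-timepoint drug effect is classified by Fisher's protected
LSD on the pooled ANOVA error together with the log2 fold change.

Gene lists from any stage can be tested against GMT gene-set collections by
exact hypergeometric overrepresentation (Tot/Sig/Exp/Ratio, p, BH FDR), and
lifespan viability curves are compared by per-replicate trapezoid AUC with a
pooled-variance t-test and confidence interval.

A synthetic-data generator (`simulate_timecourse()`) plants known templates,
drug effects and log-normal noise with ground-truth labels, so the whole
pipeline is testable without any external data.

## Worked example

```r
library(chronopattern)

sim <- simulate_timecourse(synth_config(n_genes = 2000, frac_patterned = 0.3,
                                        drug_timepoints = 5:6, seed = 42))
fit <- chronopattern(sim$data, filter = FALSE)
summary(fit)
```

```
Temporal-pattern analysis summary
  genes analyzed: 2000; DEGs (any term p <= 0.01): 630
  Euler sectors:
    T      201
    D      11
    I      9
    T&D    3
    T&I    3
    D&I    1
    T&D&I  402
    ns     1370
  template-assigned T/D/T&D DEGs: 209 (97.2%)
  over-assigned patterns: 01b(nc), 05a(nc), 09a(nc), ... (77% of assigned DEGs)
```

30% of the simulated genes carry a planted template, with drug shifts
confined to hours 5–6 — so most drug-affected genes land in interaction
sectors (`T&D&I`: 402), while purely temporal genes populate `T` (201) and
are almost all assigned a template (97.2%). Planted templates are recovered
as over-assigned patterns.

Lifespan curves are compared in two lines:

```r
res <- cls_test(curves, "myr", "veh")   # curves: group/replicate/day/viability
res
```

```
Lifespan AUC comparison (Two Sample t-test)
  mean AUC: A = 905.333 (n=3), B = 713.500 (n=3)
  difference A-B = 191.833, 95% CI [111.896, 271.771], p = 0.002636
```

Here the drug-treated group keeps higher viability, so its mean AUC exceeds
the vehicle group's by ~192 percent·days, significant at p ≈ 0.003.

`run_pipeline("run.cfg")` drives the same analysis file-to-file from a flat
key=value config, writing each stage as TSV plus a JSON run summary.

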