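---
title: "Methods: temporal-pattern analysis of two-condition time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-pattern analysis of two-condition time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronopattern)
```

# Scope and model

`chronopattern` analyses balanced two-condition (vehicle vs. drug)
time-course expression data. The core statistical object is, per gene, the
balanced fixed-effects two-way ANOVA

$$ y_{ijk} = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} +
\varepsilon_{ijk}, \qquad \varepsilon_{ijk} \sim N(0, \sigma^2), $$

with $i$ indexing timepoints (default hours 1–6), $j \in \{\text{vehicle},
\text{drug}\}$ and $k$ the replicates (at least 2 per cell). Because the
design is balanced, the sums of squares decompose exactly into Time, Drug,
Interaction and Error components, and the implementation computes them in
closed form on cell means for all genes at once; this is algebraically
identical to `aov()` per gene (the test suite verifies agreement to
1e-10) but orders of magnitude faster at transcriptome scale.

Assumptions worth stating: homoscedastic Gaussian noise on the analysis
scale, independence across samples, and a *fixed* (not mixed) effects
model. The analysis scale defaults to `log2(TPM + 1)` — a variance
stabilization, not a fitted transform; raw TPM can be analysed by setting
`log_offset` and transforming manually, but the defaults assume log-scale
noise. No moderation/shrinkage of variances is performed, and no
multiple-testing correction is applied at the gate: the gate reproduces a
raw per-term `p <= alpha` rule, with BH correction reserved for the
gene-set stage.

## Timepoint handling

Hour 0 is sampled in the supported designs but excluded from the ANOVA by
default, leaving 6 time levels: the zero-hour sample is the shared
inoculum, measured before the conditions diverge, so including it would
dilute the drug and interaction terms. Any balanced subset of timepoints
can be selected via `timepoints=`.

## Degenerate genes

A gene whose 36 observations are identical has zero residual variance;
F ratios are then 0/0. Such genes are flagged `degenerate` and assigned
p = 1 on all terms — they carry no evidence of any effect. The degeneracy
threshold is relative (`MSE <= eps * max(SS_total, 1)`) so it is unit-safe.

# The template library

Temporal shapes over T timepoints comprise: a flat shape (`00`); a change
confined to the first (`01`) or last timepoint; plateaus reached at each
intermediate timepoint; single-timepoint spikes at interior timepoints;
and a linear trend (`10` for T = 6). Every non-flat shape also exists as
its vertical reflection (`b` = negated `a`), giving 21 shapes for T = 6;
crossed with the three drug-effect classes (up/down/unchanged) this yields
the 63-pattern library. For general T ≥ 3 the same families produce
4T − 3 shapes.

The canonical vectors are minimal: unit spikes, unit plateaus, a 0→1
ramp. One deliberate exception: plateau shapes rise through a **half-step
onset** (e.g. `02a = (0, 0.5, 1, 1, 1, 1)`). With a hard step the
step-after-hour-1 plateau would be the exact complement of the
first-point spike, i.e. Pearson-correlated −1 with it, making shape `01`
indistinguishable from reflected shape `02` — best-fit assignment would
be ill-defined and noiseless recovery impossible. The soft onset keeps
every pair of candidate vectors below |r| ≈ 0.93 while preserving the
verbal semantics of "plateau". Since Pearson correlation is invariant to
affine rescaling, only the direction of each vector matters.

## Assignment rule

A gene's profile is its per-timepoint mean; for Time/Drug-sector genes
the mean is pooled over both conditions (both conditions share the shape,
the drug class captures level shifts), while interaction genes are
profiled per condition. Profiles are z-standardized and correlated with
every non-flat template; reflections contribute the negated correlation.
The best correlation wins if it exceeds `r_min = 0.85` (strict
inequality), otherwise the gene stays unassigned; exact ties break to the
lowest shape code. Two special routes:

* zero-variance profiles go to `00` directly (correlation with a
  constant is undefined);
* genes significant *only* for Drug have, by the gate's own verdict, no
  temporal effect, and are routed to `00` rather than matched against
  noise. This is why flat patterns such as `00(up)` can be populated.

## Over-assignment test

Under a uniform null each assigned gene lands in any of the 63 patterns
with probability 1/63. Each pattern's count is tested against
Binomial(n_assigned, 1/63), one-sided upper tail, flagged at `p <= 0.01`.
The uniform null is a deliberate simplification — shapes are not equally
likely a priori — so flags should be read as "well above a neutral
yardstick", not as a calibrated error rate.

# Interaction analysis

Interaction-significant genes (`p_interaction <= alpha`, regardless of
the other terms) get independent vehicle and drug shape assignments and
are tabulated on the 21 × 21 grid; cells with more than `flag_threshold`
(default 100, exclusive) genes are reported. Per timepoint, the drug
effect is classified by Fisher's protected LSD: with cell means
$\bar y_{Dt}, \bar y_{Vt}$ and the pooled residual mean square,

$$ t_t = \frac{\bar y_{Dt} - \bar y_{Vt}}{\sqrt{MSE \cdot 2/r}}, $$

two-sided against $t_{df_E}$. Protection is enforced: the function
refuses genes that did not pass the omnibus gate. The reported fold
change is computed on abundance-scale cell means with a `+1` guard
(`log2((D+1)/(V+1))`); the guard's effect is logged whenever it moves a
value by more than 1%.

# Overrepresentation analysis

Exact hypergeometric upper-tail test per gene set, reporting the
familiar web-tool columns Tot, Sig, Exp = n·Tot/N, Ratio = Sig/Exp, p and
BH FDR. The default universe is the genes annotated to ≥ 1 set; the
pipeline intersects that with the analyzed (filtered) genes, matching the
convention of web ORA tools. A user-supplied `universe` is taken as-is.
Only over-representation is tested (one-tailed), and set-size bounds
default to 10–2000. BH adjustment delegates to `stats::p.adjust` after
validation; the test suite cross-checks it against a hand step-up.

# Lifespan statistics

Viability curves (percent vs. day, per replicate) are summarized by
trapezoid AUC over the measured days only — no extrapolation below the
first or beyond the last measurement, since integration bounds outside
the data are not defensible. Groups are compared by a two-tailed
pooled-variance Student t-test with a confidence interval for the
difference of means (Welch available via `var_equal = FALSE`). Zero
pooled variance is flagged degenerate: the interval collapses to the
observed difference rather than fabricating an error estimate.

# The synthetic generator

`simulate_timecourse()` emulates the study design the package targets: 2
conditions × 7 timepoints (hours 0–6) × 3 replicates, ~5,000 genes.
Per-gene baselines are drawn log-normal (log2 mean 6, sd 2), giving a
TPM-like dynamic range; a fraction `frac_patterned` of genes follows a
template scaled by `amplitude` (default 1.5 log2 units), with
`drug_shift` (default 1) added to drug samples of up/down genes — at all
hours by default, or only at `drug_timepoints` to plant interactions;
noise is additive Gaussian on the log2 scale (`noise_sd`, default 0.15).
These defaults are fixtures chosen to be realistic for bulk RNA-seq of
synchronized yeast cultures, not estimates of any particular dataset.

What the generator does *not* emulate: count sampling noise
(mean–variance dependence à la negative binomial), library-size effects,
correlated genes, batch structure, or shapes outside the library. Passing
recovery tests therefore demonstrates correctness of the matching
machinery under the stated noise model, not performance on arbitrary real
data — in particular, real profiles not resembling any template are
expected to stay unassigned, which is the intended behaviour of the
`r > 0.85` rule.

The generator is a pure function of its config (seed included) and
restores the session RNG state, so simulated fixtures are reproducible
and side-effect free.

# Numerical and design choices

* **Inclusive thresholds**: `p <= alpha` gates and flags; `r > r_min`
  (strict) for assignment; grid flags are strict (`count > 100`).
* **Tie-breaks**: equal correlations resolve to the lowest shape code;
  a significant drug term with exactly equal condition means resolves to
  "unchanged" with a warning.
* **Filtering**: "sufficient signal" defaults to non-zero in ≥ 50% of
  samples and mean ≥ 1 TPM, plus unique symbol annotation when a symbol
  map is supplied (duplicated symbols drop all claimants). All removals
  are reported per criterion.
* **Problem sizes in the test suite**: recovery is demonstrated on 2,000
  planted genes, null calibration on 5,000 genes, binomial calibration on
  200 replicates of 1,000 uniform assignments — sizes at which the rates
  of interest stabilize while the whole suite runs in seconds.

# Known limitations

* The gate's raw-p thresholding makes the DEG count sensitive to the
  analysis scale (raw vs. log TPM); with ~36 observations per gene the
  default log scale is the variance-stabilized choice, but counts of
  significant genes from other tools will differ accordingly.
* Template vectors are canonical cartoons; genes following a shape
  intermediate between two templates are assigned to the nearer one, and
  per-pattern counts depend on the exact vectors chosen.
* The binomial uniform null and the protected-LSD error rate are
  per-pattern / per-comparison controls, not family-wise ones.
* The survival module compares AUCs only; it deliberately does not fit
  survival models or correct for regrowth after the measured window.
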