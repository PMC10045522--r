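---
title: "Methods: germination kinetics, ROS assays and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germination kinetics, ROS assays and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedvigor)
```

# The problem

Seed priming (controlled imbibition followed by dry-back) is meant to
improve germination speed and uniformity, while damaging treatments such
as a 90 °C heat shock destroy it. Reactive oxygen species (ROS) sit at
the centre of this: the pre-germinative metabolism needs ROS signalling
inside an "oxidative window", and lots that have drifted outside it
(too much oxidative load) germinate poorly. `seedvigor` implements the
full computational chain of a seed-quality study built on this idea:
germination kinetics indices, two noninvasive ROS readouts, relative
gene expression for ROS-turnover enzymes, and the statistical layer
that ties them together.

# Germination indices

A germination test sows `total_seeds` per replicate dish (20 by
default, three dishes per treatment) and scores newly germinated seeds
once per day for a species-dependent window (3 days for soybean, 5 for
wheat, 6 for tomato). With counts $n_i$ at days $t_i$,
$N = \sum_i n_i$ and $f_i = n_i/N$, the seven indices are

* $G = 100\,N/\text{total\_seeds}$ (germinability, %),
* $PV = \max_i \left(\sum_{j\le i} n_j\right)/t_i$ (peak value,
  seeds/day), using the cumulative count because that keeps
  $PV \le$ seeds sown per day of elapsed time, the magnitude at which
  the index is conventionally reported,
* $MGT = \sum_i n_i t_i / N$ (days), $MGR = 1/MGT$ (day$^{-1}$),
  $CVG = 100\,MGR$,
* $U = -\sum_{i: n_i>0} f_i \log_2 f_i$ (bits): Shannon entropy of the
  germination-day distribution,
* $Z = \sum_i \binom{n_i}{2} / \binom{N}{2}$: the fraction of pairs of
  germinated seeds that germinated the same day.

Design choices worth stating explicitly:

* **Right-censoring convention.** Non-germinated seeds enter only G
  and PV; MGT, MGR, CVG, U and Z are defined on germinated seeds.
* **Degenerate cases.** When no seed germinates, G, PV, U and Z are 0
  and MGT/MGR/CVG are *not defined* (`NA`, printed `"n.d."`); U is 0
  whenever $N \le 1$, Z is 0 whenever $N < 2$. This matches how
  heat-shock columns are conventionally printed (`0 ± 0` rather than
  `n.d.` for PV/U/Z).
* **Log base.** U uses base-2 logarithms (bits), the convention of the
  germination-measurement literature; the `base` argument makes this
  configurable since published values at these magnitudes do not
  discriminate between bases.
* **Per-replicate computation.** Indices are computed per replicate and
  then averaged; counts are never pooled. The identities
  $MGR \cdot MGT = 1$ and $CVG = 100\,MGR$ hold exactly within each
  replicate, but not between column means — which is exactly the
  rounding-level discrepancy one sees in published summary tables, and
  one of the package's consistency checks.
* **Dispersion.** Summaries print sample SD ($n-1$) by default; SEM is
  available via `dispersion = "sem"`. Two-sided equal-variance Student
  t-tests against the control at $\alpha = 0.05$ set the significance
  flags. Groups with zero variance are handled explicitly (identical
  groups give $p = 1$; constant-but-different give $p = 0$) so
  all-zero heat-shock replicates can still be flagged against a
  variable control.

# ROS quantification

**DCFH-DA.** The dye readout is a single-cycle fluorimeter measurement;
no kinetic fitting is attempted. `subtract_baseline()` subtracts a
dye-only technical blank measured under the same assay parameters and
flags (but keeps) readings below the blank.

**FOX-1.** Standards at 0, 1.25, 2.50 and 5 µM H~2~O~2~ are fitted by
ordinary least squares of A560 on concentration (`fit_calibration()`).
The intercept is left free because the 0 µM standard is a measured
blank with nonzero colour; forcing the origin would bias inverse
prediction. A fit with $R^2 < 0.98$ warns rather than errors — the
curve may still be usable, but the operator should know.
`predict_concentration()` inverts the line; negative predictions are
clipped to 0 µM with a `clipped` flag (concentrations cannot be
negative, and downstream ANOVA needs valid inputs, but the audit trail
is preserved), and predictions outside the standards' range carry an
`extrapolated` flag. Per-seed wells (five per sample) are the analysis
unit.

# qPCR relative expression (X0 method)

Threshold cycles relate exponentially to starting template, so Ct
values are linearised *before* averaging or normalising:
$X_0 = (1+E)^{-Ct}$ with amplification efficiency $E$ (default 1,
i.e. perfect doubling; per-gene overrides via the `efficiency`
argument, since efficiencies are rarely reported). The arbitrary
threshold-fluorescence constant of the published X0 formulation cancels
in every relative quantity, so it is omitted. Technical triplicates are
averaged on the Ct scale by default (`tech_average = "x0"` switches
the order). Each target's X0 is divided by the geometric mean of the
reference genes (CYP and RP40S in the motivating design) — the
standard multi-reference combination — and each gene × treatment mean
is expressed relative to the control mean, so the control is 1 by
construction. Undetermined Ct values drop that sample for that gene
with a warning; nothing is imputed. With a single reference and
$E = 1$ the whole chain reduces algebraically to per-sample
$2^{-\Delta Ct}$ ratios, which the test suite checks against an
independently coded oracle.

# Statistical layer

* **t-tests vs control** (`t_test_vs_control()`): two-sided,
  equal-variance, $p < \alpha$.
* **ANOVA + Tukey–Kramer** (`anova_tukey_kramer()`): fixed-effects
  `stats::aov` with one or two crossed factors; the interaction is
  included when every cell has ≥ 2 replicates, otherwise the model is
  additive, and empty cells raise an explicit degenerate-design error.
  Pairwise comparisons on the first factor use the studentized-range
  distribution with the Kramer unequal-$n$ correction (via
  `stats::TukeyHSD`). The compact letter display is derived by a
  deterministic insert-and-absorb procedure over the significance
  matrix, with groups ordered by descending mean and ties broken by
  label, so that two groups share a letter **iff** their comparison is
  non-significant. The study's published two-way factors are not named
  in the motivating design, so the interface is a generic two-factor
  one; the pipeline uses treatment × assay on within-assay z-scores.
* **Pearson matrix** (`pearson_matrix()`): pairwise-complete
  correlations; p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df,
  reported raw (as is conventional for these correlation heatmaps) with
  an optional BH adjustment. Zero-variance columns yield `NA` with a
  warning.
* **PCA** (`pca_features()`): z-score standardisation per column (the
  features mix %, days, µM and RFU) followed by SVD; constant columns
  are dropped with a warning, rows with missing cells listwise. Each
  component's sign is fixed so its largest-magnitude loading is
  positive, making scores deterministic. Explained-variance fractions
  are non-increasing and sum to 1.

# The synthetic-data generator

No raw measurements are deposited for the motivating design, so the
generator is a first-class module that emulates its statistical
structure:

* **Germination** (`germination_scenario()`): each of 20 seeds per
  dish germinates independently with probability `p_germ`; germination
  day is a discretized gamma draw (unimodal, positive support — the
  family is a modelling choice, nothing in the design constrains it)
  with mean `mgt_true` and SD `dispersion`, rounded to the daily grid,
  with sub-day-1 mass scored at the first inspection. Draws beyond the
  monitoring window are silently censored, as in the real assay.
  `expected_mgt()` gives the analytic censoring-adjusted mean the MGT
  estimates converge to.
* **Assays** (`assay_scenario()`): lognormal biological scatter (CV
  0.1 by default) around per-treatment true means, standards generated
  from a calibration truth (slope 0.1 AU/µM, intercept 0.05 AU,
  instrument noise SD 0.005 AU — typical bench magnitudes).
* **qPCR** (`qpcr_scenario()`): a fold change $f$ shifts the target Ct
  by $-\log_{1+E} f$; reference genes jitter by a per-sample stability
  SD (0.1 cycles) and every well gets technical noise (0.15 cycles).

`study_template()` bundles the three into a study-shaped dataset:
HS germinates nothing; hydropriming raises germinability and speeds and
synchronises germination with an optimum at the intermediate imbibition
time; ROS means are ordered HS > CTRL > HP for both assays; and
ROS-turnover genes are upregulated after imbibition and after dry-back.
True ROS and expression effect sizes are only available in the
motivating work as figure bars, so the template's magnitudes are
order-of-magnitude placeholders chosen once — they reproduce the
qualitative orderings, not any printed number. All randomness flows
through one seed per scenario; identical scenarios reproduce output
byte for byte, and the caller's RNG state is untouched.

What passing tests on these simulations shows — and does not show: they
verify that the pipeline recovers known truths under clean,
well-specified noise (binomial germination, lognormal scatter, Gaussian
instrument and cycle noise). Real seed lots add features the generator
does not model: between-dish environmental gradients, non-independent
germination within a dish, plate effects and drift in fluorescence,
DCFH-DA's photochemical artefacts, and amplification inhibitors. Passing
here demonstrates correctness of the computations, not robustness to
those artefacts.

# Pipeline and join policy

`run_pipeline()` chains the stages and writes plain-CSV reports plus a
JSON manifest; plots are optional artefacts, never the source of
numbers, and re-running identical inputs reproduces outputs byte for
byte (the manifest deliberately contains no timestamps). The only
cross-stage contract is the replicate-level feature table: germination
indices per treatment × replicate, joined with assay results and, when
qPCR data are present, per-sample relative expression matched by
treatment and biological replicate. Per-seed assay wells carry no
replicate label in the input schema, so they are dealt round-robin into
pseudo-replicates by sorted sample id within treatment × assay and
averaged — a deterministic, documented policy rather than a guess at
dish identity. Correlations and PCA run on the features with at least
three complete, non-constant observations.

# Problem sizes and numerical choices

The test suite exercises the oracle equivalences on 1000 random time
courses, calibration recovery on 200 seeded runs at 0.005 AU noise,
fold-change recovery on 200 seeded runs at 0.2-cycle technical noise,
a 1000-rep simulated ANOVA null, and MGT recovery at 1000 replicates —
sizes at which Monte-Carlo error is far below the tolerances being
asserted while the whole suite stays fast. Numerical edge cases are
handled explicitly rather than left to floating point: near-zero
calibration slopes are refused for inversion, entropy terms sum only
over days with events, zero-variance groups have defined t-test
behaviour, and exact collinearity reports $R^2 = 1$ and $p = 0$.

# Known limitations

* The assay join's pseudo-replicate policy is arbitrary (if correct
  dish identities exist, supply them by averaging upstream).
* Efficiencies default to perfect doubling; strongly divergent true
  efficiencies bias fold changes unless overridden.
* The ANOVA letters are computed for the first factor only; no
  letters for interactions.
* The generator is phenomenological: no mechanistic ROS chemistry, no
  hydrotime/thermal-time germination modelling, no seedling biometry.
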