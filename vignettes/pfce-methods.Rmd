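---
title: "Multi-level fuzzy comprehensive evaluation of biochar application schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level fuzzy comprehensive evaluation of biochar application schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfce)
```

## The problem

Field agronomy routinely produces factorial trials in which no single
treatment wins on every indicator. In the motivating system — biochar
amendment of potato fields in an arid, sandy-loam region — the two factors
are the biochar's pyrolysis temperature (300/500/700 °C) and its
application rate (10/20/30 t ha⁻¹), plus an untreated control (CK).
Yield, tuber quality, water and fertilizer use efficiency, economics and
soil nutrient residues each respond differently, typically rising and then
falling along both factor axes. Choosing a scheme therefore requires a
multi-criteria aggregation, and `pfce` implements the standard chain used
in this literature:

1. **Subjective weights** by the Analytic Hierarchy Process (AHP);
2. **Objective weights** by the entropy method;
3. **Combination weighting** fusing the two by a least-squares rule;
4. **Fuzzy comprehensive evaluation** mapping each treatment's indicator
   values onto five ordered grades and a scalar score;
5. **Response-surface optimization** of the score over the factor
   rectangle.

The `pfce()` function runs the full chain on a `trial_table` and returns a
classed object with `print`, `summary`, `coef` and `plot` methods.

## Derived indicators

Raw field measurements are converted to the evaluation indicators with
closed-form accounting:

* `water_use_efficiency(Y, ET)` is $\mathrm{WUE} = Y/(10\,ET)$ with $Y$ in
  kg ha⁻¹ and $ET$ in mm, giving kg m⁻³. The factor 10 converts a
  millimetre of water over a hectare into cubic metres. This reading is
  the only dimensionally consistent one and reproduces the published
  magnitudes (e.g. back-solving the 2023 control row gives ET ≈ 322.6 mm).
* `crop_et()` closes the simplified balance $ET = P_0 + I - \Delta W - D$,
  with groundwater recharge and runoff set to zero (deep water table, flat
  terrain). Effective rainfall $P_0 = aP$ uses banded coefficients:
  $a = 0$ below 5 mm, $a \in [0.8, 1.0]$ for 5–50 mm events (default 0.9)
  and $a \in [0.70, 0.80]$ above 50 mm (default 0.75). The source bands
  are ranges, so the package requires a pinned per-band coefficient and
  validates it against the band; both boundaries (5 and 50 mm) belong to
  the middle band.
* `partial_factor_productivity(Y, FT)` with
  `fertilizer_total()` = Σ rate × nutrient fraction; the default schedule
  (urea 652.2 kg ha⁻¹ at 46 % N, superphosphate 391.3 at 46 % P₂O₅,
  potassium sulfate 666.6 at 45 % K₂O) gives FT ≈ 780 kg ha⁻¹.
* `net_income()` = gross income − water fee − fertilizer input − other
  input (may be negative: first-year biochar purchases can exceed the
  revenue gain).
* `nutrient_accumulation(M, H, B)` = $M \cdot H \cdot B / 10$ kg ha⁻¹ per
  layer, summed over layers.

`contrast_range()` computes the percent spread of a focal treatment
against all comparators. Years are **averaged cell-wise first**, then
ratios are taken; the per-year-ratio-then-average alternative gives
different numbers, and the averaged convention is applied uniformly. Under
it the published yield, vitamin-C, reducing-sugar and PFP ranges
recompute to ±0.01 percentage points, while the published starch maximum
(19.38 %) sits 0.016 points from the recomputation (19.364 %) — the
residue of a mixed convention or unrounded replicate means in the source;
`run_contrasts()` reports the discrepancy rather than absorbing it.

## Subjective weights: AHP

Pairwise importance judgments on the Saaty 1–9 scale form reciprocal
matrices at two levels (criteria over the goal; indicators within each
criterion). Weights are extracted by the **geometric-mean (root) method**:
$w_i \propto (\prod_j b_{ij})^{1/n}$ — the extraction the printed
formulas define. The principal-eigenvector method appears in the test
suite only, as an independent oracle: on perfectly consistent matrices the
two coincide exactly, and on matrices passing the consistency gate they
agree within 0.02 per component.

Consistency uses $CI = (\lambda_{\max} - n)/(n - 1)$,
$\lambda_{\max} = \frac{1}{n}\sum_i (B w)_i / w_i$, and $CR = CI/RI$ with
the tabulated random index (orders 3–10: 0.58, 0.9, 1.12, 1.24, 1.32,
1.41, 1.45, 1.49). Orders 1–2 are always consistent; the package sets
$CR = 0$ there to avoid dividing by $RI = 0$. The pipeline **aborts** when
any matrix has $CR \ge 0.1$.

The expert matrices behind the original study are not publicly available,
so `default_hierarchy()` ships clearly-labelled illustrative defaults in
which economic benefit dominates (matching the stated priorities of local
producers). Replace them with elicited matrices via CSV/YAML for any
substantive use. `aggregate_judgments()` merges a panel's matrices by the
element-wise geometric mean, which preserves reciprocity; merging rules
are otherwise an open question in this literature, so aggregation is
opt-in.

## Objective weights: entropy

Entropy weighting is computed on **min–max standardized** values, not raw
ones: negative indicators are reversed
($(max - x)/(max - min)$) so that 1 is always best, and 2023 net incomes
are negative, which would make raw-value column shares meaningless.
Column shares $P_{ij}$ give $e_j = -\frac{1}{\ln m}\sum_i P_{ij}\ln
P_{ij}$ (with $0\ln 0 := 0$), divergence $d_j = 1 - e_j$, and weights
$w_j \propto d_j$. Constant columns carry no information and receive zero
weight directly; a table whose columns are all constant is an error.

## Combination weighting

The fused vector is $W = \alpha_1 W_1 + \alpha_2 W_2$ with $\alpha$
solving the deviation-minimizing normal equations
$\begin{pmatrix} W_1^T W_1 & W_1^T W_2 \\ W_2^T W_1 & W_2^T W_2
\end{pmatrix} \alpha = \begin{pmatrix} W_1^T W_1 \\ W_2^T W_2
\end{pmatrix}$, normalized to sum 1. The system can be singular
($W_1 = W_2$) or yield a negative component; the default policy falls
back to $\alpha = (0.5, 0.5)$ and records the event in `method_note`,
while `negative_alpha_policy = "absolute_normalize"` applies the
absolute-value normalization common in the combination-weighting
literature. The conservative fallback is the default because the source
method does not state its policy.

## Fuzzy evaluation

Each indicator's value is mapped to memberships over five grades
(Excellent … Very Poor) anchored at thresholds $C_1..C_5$ — strictly
decreasing for positive indicators, increasing for negative ones. The
family is piecewise linear: trapezoidal saturation beyond $C_1$ and
$C_5$, triangular apexes at interior thresholds, and linear splitting
between adjacent grades, so memberships always sum to 1 exactly (a
property-tested partition of unity). A value equal to an interior
threshold has full membership in that grade.

Aggregation uses the weighted-average operator
$b_j = \min\{1, \sum_i a_i r_{ij}\}$; because the weights and each row of
$R$ sum to 1, the clamp is provably inactive (also tested). The grade is
the maximum membership, with ties resolved toward the better grade and
flagged; the score is $B \cdot (5,4,3,2,1) \in [1, 5]$.

The study's grade thresholds are also unavailable, so
`default_grade_scheme()` anchors grades at the 0.9/0.7/0.5/0.3/0.1
quantiles of the observed values (orientation-ordered, tie-jittered).
Data-driven schemes grade treatments *relative to the observed spread*;
results under them are method demonstrations, not reproductions of the
original evaluation values, and the yearly best-treatment rankings under
quantile schemes should be read accordingly.

## Response surface and recommendation

Per-treatment scores are regressed on the full quadratic in
(temperature, rate) by ordinary least squares, internally on centered and
scaled coordinates for conditioning and back-transformed for reporting.
CK is excluded by default: it has no pyrolysis temperature, and imputing
one is a modelling choice the caller should make explicitly. The bounded
maximizer is exact (interior stationary point when the Hessian is
negative definite, otherwise edge-restricted 1-D maxima and corners) and
is grid-verified in the tests. The `recommendation_band()` reports the
bounding box of the region within 1 % of the maximum predicted score,
mirroring how scheme recommendations are stated as ranges in practice.

With 9 factorial points and 6 parameters the fit has 3 residual degrees
of freedom; $R^2$ values are accordingly optimistic and are reported, not
interpreted inferentially.

## The synthetic generator

`generate_trial()` emulates the study conditions: the 3 × 3 factorial
(+CK), two years, ten indicators, each following a single-apex quadratic
surface (concave for positive indicators, convex for negative ones) with
independent additive Gaussian replicate noise, clipped at zero for
nonnegative indicators (with a counter). Defaults place every apex at
(500 °C, 20 t ha⁻¹) with peak values and spans on the scale of the
published tables, and noise sd at 2 % of each indicator's surface range
over the design region. Net income is derived from the synthetic yield
through the package's own economics (price 1600 CNY t⁻¹, obtained as the
published control gross income over its yield; fixed costs 17 115 CNY
ha⁻¹; optional year-1 biochar purchase at `biochar_price`, 1800 CNY t⁻¹
reproducing the published cost structure), so accounting identities hold
in synthetic data too. With the default `biochar_price = 0` the composite
optimum coincides with the configured apex, which keeps ground truth
interpretable for recovery experiments.

What the generator does **not** emulate: replicate-level plot structure
(cells are treatment means), spatial autocorrelation, year × treatment
interactions beyond fresh noise, or non-quadratic response shapes.
Passing the end-to-end recovery test therefore shows the pipeline can
find a known apex under idealized factorial data, not that it is robust
to real-field artefacts.

`true_optimum()` supplies the ground truth: configured apexes per
indicator, and a composite located by a dense-grid oracle (default
201 × 201) over the equal-weighted sum of orientation-standardized
surfaces.

## Numerical choices and degenerate inputs

* Reciprocity and the weight-sum invariant are checked at 1e-9/1e-8;
  entropy hand-oracle agreement at 1e-12.
* Judgment entries outside the Saaty set warn but do not error (experts
  sometimes interpolate); non-reciprocal entries error.
* Constant indicator columns: flagged in standardization, zero entropy
  weight, and an error in quantile scheme construction (thresholds would
  be degenerate).
* Ties: max-membership ties resolve toward the better grade; ranking ties
  order by treatment id; tied quantile thresholds are jittered by
  `1e-9 × range` with a warning.
* The surface optimizer treats `det(H)` below machine tiny as singular
  and falls back to edges/corners.

## Problem sizes used in the tests

The property suites run at deliberately small sizes — 200 consistency-
gated AHP draws for the eigenvector-agreement bound, 10⁴ random
(value, scheme) draws for the partition of unity, 100 seeded synthetic
replicates (9 treatments × 2 years) for end-to-end apex recovery (within
±50 °C and ±2.5 t ha⁻¹ in ≥90 % of replicates) — chosen to exercise the
claims while keeping the default test run fast on one CPU.

## Known limitations

* Evaluation results under default hierarchy and quantile schemes are
  demonstrations; substantive conclusions need elicited matrices and
  domain grade thresholds.
* Per-year evaluation is the default (matching how the motivating study
  reports 2023 and 2024 separately); `pooled: true` in a run config adds
  the two-year-average evaluation, but the package takes no stance on
  which a given study should report.
* Soil-residue indicators (Z41–Z43) have no packaged numeric fixtures
  (the source reports them only graphically); the evaluator renormalizes
  weights over the indicators present and warns loudly.
* The published net-income contrast range (2.83–159.85 %) is not
  recoverable from the packaged economics table under any contrast
  convention tried, and the published WUE endpoint 30.20 % recomputes to
  30.16 %; both are reported by the package as computed.
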