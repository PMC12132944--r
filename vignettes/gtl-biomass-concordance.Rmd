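---
title: "Estimating fish biomass from literature lengths: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fish biomass from literature lengths: methods and design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtlbiomass)
```

## The estimation problem

Ecosystem models need per-individual biomass for many fish species, but
direct weighing is rarely available outside dedicated surveys. When a
species' body length is known, the length–weight relationship (LWR)

$$W = a \, L^{b}$$

converts length $L$ (total length, cm) to wet mass $W$ (g); $a$ is a
scale coefficient (g·cm$^{-b}$, typically $10^{-3}$–$10^{-2}$) and $b$
the allometric exponent ($\approx 3$ for isometric growth). `gtlbiomass`
implements a fully literature-based version of this conversion and the
machinery needed to judge whether it works:

1. a **General Total Length (GTL)** per species — a single representative
   length taken from databases or field guides, either a stated average
   or the midpoint of a reported min–max range;
2. **representative LWR coefficients** pooled over the published records
   of a species: the geometric mean of the $a_k$ and the arithmetic mean
   of the $b_k$;
3. a **field-side individual biomass** from monitoring data, obtained as
   biomass density (g/m²) divided by number density (ind/m²), one data
   point per species × month;
4. **concordance diagnostics** comparing the estimated against the
   measured weights, stratified by habitat group.

The geometric mean is the right average for $a$ because published $a$
values scatter multiplicatively over orders of magnitude; it is computed
as $\exp(\mathrm{mean}(\ln a_k))$ to avoid underflow. For $b$, which
scatters additively around 3, the arithmetic mean is used. With a single
published record the representatives reduce to that record exactly.

### GTL rules

An explicitly stated average length always wins over a min–max range:
a curated average is a direct estimate of the representative length,
while a midpoint is a proxy for it. Range-based GTLs from meta-databases
are only eligible when backed by at least 20 measured individuals;
smaller samples give unstable ranges and the species falls through to
its next source or is dropped (with a logged reason). A range with no
recorded sample size is treated as eligible — the exclusion is applied
only where the evidence for it exists. All lengths are assumed to be
total length in cm; coefficients reported for other length types must be
converted upstream.

## Concordance statistics

Let $y_i$ be the measured and $\hat y_i$ the estimated weight of point
$i$. Two $R^2$ flavours are computed per dataset:

* **Regression $R^2$** — from the OLS fit of $y$ on $\hat y$ (measured on
  the vertical axis, estimated on the horizontal, matching the plots
  this kind of validation is read from). It measures trend consistency
  and lies in $[0, 1]$.
* **Identity-line $R^2$** — $1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i -
  \bar y)^2$, the coefficient of determination *against* $y = x$. It
  measures absolute agreement, and is negative whenever the estimates
  predict worse than the plain mean of the measured data. For any point
  set, identity-line $R^2 \le$ regression $R^2$, because OLS minimizes
  the error sum of squares over all lines including $y = x$.

Both are reported before and after two outlier treatments, applied in
this order:

1. **Q/MedAD filtering.** The residual of a point is the absolute raw-gram
   difference $|y_i - \hat y_i|$; MedAD is the median of these residuals
   and $Q_i = |y_i - \hat y_i| / \mathrm{MedAD}$. Points with $Q_i > 6$
   (strict inequality) are removed in a single pass — MedAD is not
   recomputed after removal. Residuals are kept on the raw gram scale
   (not logged): the score is defined on the weights themselves, and a
   log transform would change which points exceed the threshold. If
   MedAD is zero while some residuals are not, those points score
   $\infty$ and are always filtered; if every residual is zero, all
   scores are 0.
2. **Cook's-distance removal.** On the (possibly Q-filtered) set, the OLS
   deletion diagnostic $D_i = \sum_j (\hat y_j - \hat y_{j(i)})^2 /
   (p \cdot \mathrm{MSE})$ with $p = 2$ flags influential points. The
   leverage closed form (via `stats::cooks.distance`) is used; the test
   suite verifies it against brute-force leave-one-out refits at
   $10^{-10}$ relative tolerance. No universal cutoff convention exists,
   so the rule is a configuration knob: the conventional $D_i > 4/n$
   (default), a fixed cutoff, or top-$k$ removal — single pass in every
   case. Influential points are identified per dataset variant, not
   inherited across variants, because $D_i$ depends on the point set.

RMSE and MAE accompany each $R^2$, for both the identity-line and the
fitted-line model; RMSE $\ge$ MAE always (Jensen). A descriptive IQR
screen on $\ln$-weights (quartiles by linear interpolation,
`quantile(..., type = 7)`, whiskers at $1.5 \times$ IQR) reports extreme
weights but removes nothing.

### Habitat stratification

Species are partitioned by habitat set into freshwater-only,
seawater/mudflat-only, mixed, and no-record groups. Mixed and no-record
species are excluded from the analysis; the third analysis scope
("whole") is the union of the first two, and derives its own Q scores
from the union rather than reusing the per-scope decisions. Species
occupying only estuaries are classified as mixed (and flagged), since an
estuarine resident belongs to neither pure group. Species matching
across tables is exact on the trimmed, case-folded name — fuzzy joins
fail silently and are deliberately not offered; mismatches surface in
the drop log instead.

## The synthetic community generator

`community_sim_config()` defines a virtual community whose structure
mirrors what the pipeline assumes about real monitoring data: species
with true $(a, b, \mathrm{GTL})$, monthly surveys aggregating individual
masses into densities (so the density ratio recovers the realized mean
individual mass exactly), and several noisy published coefficient
reports per species. Defaults, chosen once as a plausible temperate
stream/coastal community:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 50 | species pool (half freshwater, half seawater) |
| `months` | 12 | monthly survey periods |
| `a_log_median`, `a_log_sd` | log(0.01), 0.35 | log-normal true $a$ |
| `b_mean`, `b_sd` | 3.0, 0.12 | normal true $b$, near-isometric |
| `gtl_min_cm`, `gtl_max_cm` | 5, 30 | log-uniform population GTL |
| `dispersion_freshwater` | 0.10 | log-sd of lengths about the GTL |
| `dispersion_seawater` | 0.45 | wide marine size distributions |
| `gtl_offset_seawater` | 1.5 | reported GTL vs population median |
| `juvenile_fraction` | 0 | probability a monthly record is a juvenile cohort |
| `juvenile_length_ratio` | 0.35 | juvenile/adult length ratio |
| `reports_per_species` | 3 | published $(a, b)$ pairs per species |
| `a_report_sd`, `b_report_sd` | 0.10, 0.05 | report noise (log-mult. / additive) |
| `mean_catch` | 30 | individuals per record (Poisson + 1) |

Two design points deserve explanation.

**Juvenile contamination acts per record, not per individual.** A
monthly survey point averages tens of individuals; sprinkling a fixed
fraction of juveniles into every record would only shift every mean mass
mildly and could never produce the discrete, heavy low-mass outliers
that Q-filtering exists to remove. Real surveys produce such outliers
when a month's catch is dominated by a recruitment pulse. The generator
therefore makes the whole record juvenile with probability
`juvenile_fraction` — its lengths are the adult draws scaled by
`juvenile_length_ratio`, so its measured mass is roughly
`ratio^b` (≈ 4% at the defaults) of the estimate, a Q outlier for all
but the smallest species.

**The marine failure mode is a length problem, not a coefficient
problem.** Seawater species get wide length dispersion *and* a reported
GTL offset above the population median; their $(a, b)$ are drawn from
the same distributions as freshwater species. This encodes the
hypothesis under test — LWR coefficients transfer between habitats, but
a single representative length does not represent wide marine size
distributions.

`benchmark_scenarios()` packages the regimes: `freshwater_like` (tight
dispersion, 2% juvenile cohorts), `seawater_like` (wide dispersion,
offset GTL for all species), `contaminated` (freshwater-like plus 25%
juvenile cohorts — about the fraction a Q > 6 rule then removes), and
`noiseless` (all noise at zero; the pipeline must return identity-line
$R^2 = 1$ in every variant, which the test suite asserts at $10^{-9}$).
Scenario parameters are generator conditions, not empirical claims about
any particular sea.

```{r scenarios, eval = FALSE}
res <- run_full_analysis(list(
  simulate = benchmark_scenarios(seed = 1)$contaminated,
  out_dir = "results/run_contaminated"))
res$reports[, c("dataset_label", "n_points", "r2_regression",
                "r2_identity", "r2_identity_removed")]
```

What passing these tests shows — and what it does not: the generator
draws log-normal lengths and masses with exact allometry, clean species
identities and no gear selectivity, spatial structure or seasonal
migration. Success on it demonstrates the pipeline's statistics and
plumbing are correct and that the Q filter removes the planted
contamination; it does not certify that literature GTLs match any real
population, which is exactly the question a run on compiled field data
answers.

## Numerical and degenerate-input choices

* Geometric means and weight estimates are evaluated in log space.
* A regression with zero MSE (all points exactly on a line) returns all
  Cook's distances as 0 — deleting a point cannot change a perfect fit —
  instead of 0/0.
* Dataset variants with fewer than 4 points (or left with fewer after
  removal) yield reports flagged `degenerate` with NA statistics rather
  than errors, so parameter sweeps never abort.
* Identity-line $R^2$ requires non-constant measured values (SST > 0)
  and errors otherwise.
* Both filters use strict `>` at their thresholds.
* All randomness flows from a single integer seed; the three generator
  stages use seed, seed + 1, seed + 2 so each stage is independently
  reproducible, and two runs with the same configuration are
  byte-identical on disk.

## Problem sizes

The test suite and acceptance script run the generator at 50 species ×
12 months (600 paired points per scenario), 10 paired seeds for scenario
contrasts, 100 random regressions up to n = 200 for the Cook's-distance
deletion check, and 1000 random paired sets for the $R^2$ ordering
property — sizes at which every property is stable run-to-run while the
whole suite completes in well under a minute of compute.

## Limitations

* The pipeline validates concordance; it does not correct a failing
  estimate (no condition factors, no seasonal or maturity stratification
  of coefficients).
* Coefficients must arrive in the W(g)–TL(cm) convention; no unit or
  length-type conversion is performed.
* The Q score on raw grams weights absolute error: among clean points it
  flags large-bodied species before equally (relatively) wrong small
  ones. This is inherent to the published definition the package
  implements; the threshold is exposed if users want sensitivity
  analyses.
* Only delimited text is read; spreadsheets must be exported to CSV/TSV
  first.
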