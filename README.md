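# gtlbiomass

Literature-based estimation of per-individual fish biomass from
length–weight relationships (LWRs), and the diagnostics to decide
whether that estimation can be trusted.

## The problem

Ecological models need the biomass of every fish species in a system,
but field weights exist only where someone surveyed. What usually *is*
available in the literature is (i) monitoring data reporting biomass
density (g/m²) and number density (ind/m²) per species and month,
(ii) published LWR coefficient pairs, and (iii) a representative body
length per species — the **General Total Length (GTL)**, either a stated
average or the midpoint of a reported min–max range. `gtlbiomass`
implements the estimation chain built from those pieces and scores its
agreement with field data, stratified by habitat, for analysts in
fisheries biometrics and aquatic ecosystem modelling:

* **Field side:** individual biomass = biomass density / number density,
  one point per species × month.
* **Estimated side:** `W = a_rep · GTL^b_rep`, with `a_rep` the geometric
  mean and `b_rep` the arithmetic mean of the published coefficients;
  range-based GTLs need ≥ 20 backing individuals.
* **Concordance:** regression R² of measured on estimated weights, and
  the identity-line R² against y = x,
  `1 − Σ(yᵢ − ŷᵢ)² / Σ(yᵢ − ȳ)²`, which is negative when estimates are
  worse than the plain mean.
* **Outlier handling:** per-point `Qᵢ = |yᵢ − ŷᵢ| / MedAD` (MedAD = the
  median absolute residual); points with Q > 6 are removed in a single
  pass. Cook's-distance removal (`Dᵢ > 4/n` by default, rule
  configurable) is applied afterwards, per dataset variant.
* **Stratification:** freshwater-only species, seawater/mudflat-only
  species, and their union, each raw and Q-filtered — six dataset
  variants per run.

A synthetic community generator (`community_sim_config()`,
`benchmark_scenarios()`) produces surveys, coefficient tables and
species profiles with the structure the pipeline assumes — including
habitat-dependent length dispersion and juvenile-cohort contamination —
so every stage is testable without field data.

## Worked example

Run the full study on the juvenile-contaminated benchmark scenario
(25% of monthly records are recruitment pulses of small-bodied
juveniles):

```r
library(gtlbiomass)
cfg <- benchmark_scenarios(seed = 1)$contaminated
res <- run_full_analysis(list(simulate = cfg))
res$reports[, c("dataset_label", "n_points", "slope", "r2_regression",
                "r2_identity", "n_influential", "r2_identity_removed")]
```

```
        dataset_label n_points slope r2_regression r2_identity n_influential
       freshwater_raw      300 0.712         0.640       0.516            19
 freshwater_qfiltered      240 1.041         0.979       0.977            30
         seawater_raw      300 0.740         0.601       0.513            24
   seawater_qfiltered      246 1.019         0.993       0.992            16
            whole_raw      600 0.714         0.643       0.525            33
      whole_qfiltered      473 1.023         0.991       0.990            35
 r2_identity_removed
               0.817
               0.981
               0.626
               0.984
               0.842
               0.980
```

Reading the whole-community rows: with the juvenile outliers left in,
absolute agreement is poor (identity-line R² = 0.53, slope 0.71 — the
juvenile records sit far below y = x and drag the fit down). Q > 6
filtering removes 127 of the 600 points (median removed-point Q ≈ 24)
and agreement snaps to the identity line: slope 1.02, identity-line
R² = 0.99. The per-point audit trail behind these numbers is in
`res$audit` (species, period, Q, Cook's distance, kept/removed flags),
and `write_report()` / `run_full_analysis(..., out_dir =)` persist
reports, audit table and a run manifest.

The numbered scripts under `analysis/` walk the same pipeline as a
narrative: `01_simulate_community.R` generates the benchmark
communities, `02_estimate_biomass.R` ingests and pairs one of them,
`03_concordance.R` evaluates all six variants per scenario, and
`04_scenario_contrast.R` runs the 10-seed paired contrast
(tight-dispersion vs wide-dispersion regimes, and filtering gains under
contamination). Each writes its tables under `results/`.

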