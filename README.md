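# relkin

Emulsion stability and encapsulated-oil release kinetics in R.

relkin is for formulation scientists working on hydrocolloid-stabilized
essential-oil emulsions and their spray-dried, matrix-embedded powders. It
implements the full quantitative chain such a study needs — turbidimetric
stability indices, kinetic-order fitting, release-curve normalization, two
routes to effective diffusivity for a disc monolith, powder yield and
encapsulation-efficiency arithmetic, and sample-level correlation
analysis — together with a seeded synthetic-data generator so every
estimator is testable against known ground truth.

## Models

**Stability.** The emulsion stability index after $t$ days is the uncapped
percent ratio $S(t) = 100\,A_t/A_0$ of stored to initial absorbance
(600 nm). Absolute trajectories, reconstructed with day 0 at the measured
activity, are fitted with both integrated rate laws

$$P(t) = P_0 - k\,t, \qquad P(t) = P_0\, e^{-kt},$$

the first by ordinary least squares and the second by Levenberg–Marquardt
nonlinear least squares on the original scale (log-linear initialization).

**Release.** A powder-loaded cellulose disc is weighed every 30 min at
35 °C until constant. After plateau trimming and normalization to a
remaining-oil fraction, the effective diffusivity is estimated twice,
independently:

- from the first-order rate constant through the slab relation
  $D = k L^2 / \pi^2$;
- by fitting the one-term truncated Fickian slab model
  $\frac{4}{\pi} \exp(-D \pi^2 t / L^2)$ over its physically valid window
  $\tau = D\pi^2 t/L^2 \ge \ln(4/\pi)$.

The characteristic length $L$ is always an explicit argument — the
published rate-constant diffusivities follow the disc radius convention
(0.020 m) while the truncated-model numbers follow the full thickness
(0.005 m), and relkin reproduces each without guessing a single one.

**Powder and correlations.** Process yield and encapsulation efficiency
are validated percent ratios; `build_parameter_table()` joins activity,
rates, diffusivities and efficiency into one row per sample (temperature
aggregation explicit and recorded) and `correlation_matrix()` gives all
pairwise Pearson coefficients.

## Worked example

Fit both kinetic orders to the all-xanthan sample stored at 5 °C
(activity 233 AU; stability 72, 48, 36 % on days 1–3):

```r
library(relkin)
traj <- reconstruct_trajectory(233, c(72, 48, 36), sample_id = "S6", condition = "T5")
fit_zero_order(traj)
#> <kinetic_fit> order 0: P0 = 224.6 (se 11.3), k = -50.33 per day (se 6.04), R^2 = 0.9720, n = 4
fit_first_order(traj)
#> <kinetic_fit> order 1: P0 = 233.7 (se 3.73), k = -0.3497 per day (se 0.0135), R^2 = 0.9975, n = 4
```

The zero-order fit says the emulsion loses about 50 absorbance units per
day from an intercept of ~225 AU; the first-order fit says it loses ~35%
of its remaining turbidity per day from ~234 AU, and describes this series
slightly better (R² 0.998 vs 0.972).

Convert the published per-minute release rate constants to diffusivities
(radius convention) and check the two routes agree:

```r
rel <- study_release_table()
signif(k_to_diffusivity(rel$k_per_min / 60, L = 0.020) * 1e10, 2)
#> [1] 9.9 4.5 5.2 2.8 3.3 4.1        # 1e-10 m^2/s
pearson_r(rel$D_from_k, rel$D_eff_fick)
#> [1] 0.995
truncated_remaining_fraction(2.4e-10, L = 0.005, t = 9000)
#> [1] 0.543                          # oil fraction left after 150 min
```

The two diffusivity routes, despite their different assumptions, rank the
six formulations almost identically (r = 0.995); the all-guar formulation
releases fastest and the xanthan-rich ones slowest. Note that the
conversion lands exactly on the published diffusivities for samples 2, 3
and 6, one last-digit rounding step away for sample 1, and visibly off
for samples 4–5 (2.8 and 3.3 vs the published 3.5 and 3.4) — no single
length convention reproduces those two rows, a discrepancy the package
surfaces rather than hides.

`run_pipeline(run_config(...))` orchestrates the whole chain and writes
fits, diffusivity, parameter-table and correlation CSVs plus a run log
with the seed and geometry conventions used. See the vignette
(`vignettes/release-kinetics.Rmd`) for the modeling details and design
choices.

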