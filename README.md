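# capmoist

Capacitive grain moisture modelling: a physics layer, a metaheuristic
optimizer, and a regression pipeline for estimating foxtail millet
moisture content from parallel-plate capacitance measurements.

Post-harvest grain quality control needs fast, non-destructive moisture
measurement. Because water's relative permittivity (~81) dwarfs dry
grain's (~3), grain moisture shifts the capacitance of a parallel-plate
cell; a differential (detection minus air-reference) design rejects
common-mode drift. This package is for instrument developers and
agricultural-sensing researchers who want a reproducible, testable version
of that modelling stack.

## What's inside

**Dielectric mixing model.** Treating the inter-plate volume as grain,
water and air mixed linearly by volume fraction, the capacitance collapses
to four structural constants A, B, D, F of the cell:

    C(W) = A / (W/(1-W) + B) + D + F

with W the wet-basis moisture fraction, `A = S ε₀ ρ_w (1-e)(ε_c - ε_w)/(d ρ_c)`,
`B = ρ_w/ρ_c`, `D = S ε₀ (1-e) ε_w / d`, `F = S ε₀ e ε_a / d`. The curve is
strictly increasing, and its inverse is closed-form: with
`G = A/(C - D - F) - B`, moisture is `W = G/(1+G)`
(`moisture_from_capacitance()`). An empirical straight-line calibration
`C = 0.30744 W + 17.28085` (pF, W in percent; valid at 22 °C, duty cycle
1/3) is available as `linear_calibration()`.

**Sparrow search algorithm (SSA) and LCSSA.** A box-bounded population
minimiser with finder/joiner/scout roles (`ssa_optimize()`), plus the
logistic-chaos initialised variant (`init_mode = "logistic"`): each
dimension is seeded with an iterate chain of `y ← 4y(1-y)`, spreading the
initial population over the box. `benchmark_function()` provides the F1–F6
test suite (sphere, |x|-sum-product, rotated hyper-ellipsoid, max-modulus,
Rosenbrock, step) and `compare_optimizers()` runs SSA vs LCSSA with paired
seeds.

**Regressors and tuning.** `elm_fit()` (extreme learning machine, 100
sigmoid hidden units, one-shot truncated-SVD least squares) and `bp_fit()`
(3-5-1 back-propagation network). `ssa_tune()` wraps SSA/LCSSA around
either: for ELM it searches the 400 hidden-layer parameters, for BP the 26
initial weights. `model_report()` evaluates each variant by correlation R,
RMSE, and the ratio performance deviation `RPD = 1/sqrt(1-R²)` with
reliability bands (<1.4 unreliable, 1.4–2.0 relatively reliable, >2.0
highly reliable).

**Synthetic campaign.** The reference 720-record sensor data set is not
public, so `generate_campaign()` simulates the factorial campaign (16
moisture levels 5.64–23.52%, 3 replicates, 3 temperatures, 5 duty cycles),
anchored to the calibration line at 22 °C/duty 1/3, with documented
synthetic temperature/duty-cycle trends and Gaussian sensor noise.
`split_train_test()` gives the 540/180 random split and `run_experiment()`
chains everything into the six-variant comparison table.

## Worked example

```r
library(capmoist)

# physics: moisture <-> capacitance, exact inverse
sc <- structural_constants(sensor_geometry(), material_constants())
capacitance_from_moisture(0.1442, sc)   # 8.629e-12 F for 14.42% moisture
moisture_from_capacitance(8.629e-12, sc)  # back to ~0.1442

# full pipeline on a synthetic campaign
res <- run_experiment(experiment_config(seed = 1))
res
```

```
Data set summary:
       data_set n_samples   max  min    mean      sd
   Training set       540 23.52 5.64 15.3450 5.46584
 Prediction set       180 23.52 5.64 15.6576 5.32093

Model comparison (R / RMSE / RPD, training C and prediction P):
     model    R_C RMSE_C  RPD_C    R_P RMSE_P  RPD_P
        BP 0.9715 1.2983 4.2165 0.9663 1.3639 3.8875
    SSA-BP 0.9713 1.3017 4.2056 0.9665 1.3606 3.8978
  LCSSA-BP 0.9714 1.3003 4.2150 0.9666 1.3671 3.9013
       ELM 0.9732 1.2585 4.3501 0.9674 1.3428 3.9475
   SSA-ELM 0.9741 1.2378 4.4227 0.9653 1.3837 3.8294
 LCSSA-ELM 0.9741 1.2382 4.4214 0.9663 1.3649 3.8846
```

Each row reports training (C) and prediction (P) correlation, RMSE in
percent moisture, and RPD. On this synthetic campaign every variant sits
in the "highly reliable" band (RPD > 2) because the simulated sensor noise
(0.4 pF) is mild relative to the calibration slope — absolute values are a
property of the generator, not of real grain data; on a real instrument
the same pipeline produces markedly lower correlations. What carries over
is the machinery: shared splits, paired seeds, six-metric reports, and the
RPD-from-R identity holding exactly on every row.

A thin CLI over the same functions lives at `inst/cli/capmoist.R`
(subcommands `simulate`, `split`, `fit`, `compare`, `invert`,
`benchmark`).

## Documentation

The methods vignette (`vignettes/capacitive-moisture-modelling.Rmd`)
documents the model derivation, the optimizer update rules and their
reading, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the package's numerical
choices.
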