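---
title: "Capacitive grain moisture modelling: models, optimizer and synthetic campaign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacitive grain moisture modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmoist)
```

# The measurement problem

Wet grain stores and processes badly; dry grain costs energy. Post-harvest
quality control therefore needs fast, non-destructive moisture measurement.
A parallel-plate capacitive cell exploits the fact that water
(relative permittivity about 81) dominates dry grain (about 3) and air
(about 1): grain of different wet-basis moisture content $W$ filling the
detection volume changes the effective permittivity and hence the measured
capacitance. A differential design (a second, air-filled reference cell,
subtracted from the detection cell) rejects common-mode environmental
drift; `difference_channels()` implements that subtraction.

# The dielectric mixing model

The cell capacitance is $C = S \varepsilon_0 \varepsilon_r / d$ with plate
area $S$, spacing $d$ and effective relative permittivity $\varepsilon_r$.
Treating the inter-plate volume as three phases (dry grain, water, air)
mixed linearly by volume fraction, with pore ratio $e$ (air fraction of the
filled volume) and wet-basis moisture
$W = \rho_w V_w / (\rho_c V_c + \rho_w V_w)$, the model collapses to four
structural constants of the cell:

$$
A = \frac{S\varepsilon_0 \rho_w (1-e)(\varepsilon_c - \varepsilon_w)}{d\,\rho_c},
\quad B = \frac{\rho_w}{\rho_c},
\quad D = \frac{S\varepsilon_0 (1-e)\varepsilon_w}{d},
\quad F = \frac{S\varepsilon_0\, e\, \varepsilon_a}{d},
$$

$$
C(W) = \frac{A}{\dfrac{W}{1-W} + B} + D + F .
$$

Two readings of the capacitance–moisture relation are typographically
possible ($A$ multiplying or dividing the bracket); only the division form
above is algebraically derivable from the volume-fraction mixing rule, and
only it is monotone increasing in $W$ (since $\varepsilon_w >
\varepsilon_c$ makes $A < 0$), matching the observed behaviour of real
cells. The package implements the division form, and the test suite checks
it against a direct numerical evaluation of the mixing rule on randomly
drawn geometries.

Because $C(W)$ is strictly monotone, the inverse is exact and closed-form:
with $G = A/(C - D - F) - B$, moisture is $W = G/(1+G)$
(`moisture_from_capacitance()`), valid on the open attainable interval
between the dry-grain and all-water limits.

```{r dielectric}
sc <- structural_constants(sensor_geometry(), material_constants())
capacitance_from_moisture(c(0.0564, 0.1442, 0.2352), sc)
moisture_from_capacitance(capacitance_from_moisture(0.1442, sc), sc)
```

**Parameter defaults.** Plate area 0.015 m² corresponds to the 150 mm x
100 mm detection plates of the reference instrument. Plate spacing
(`plate_spacing = 0.10` m) and pore ratio (`pore_ratio = 0.40`) are *not*
published instrument values — they are placeholders a user must calibrate;
both are ordinary constructor arguments. Material defaults
($\varepsilon_c = 3$, $\varepsilon_w = 81$, $\varepsilon_a = 1.00053$,
$\rho_c = 600$, $\rho_w = 1000$ kg/m³) are the usual room-temperature
values for foxtail millet. Temperature dependence of the permittivities is
real but has no accepted functional form at this level of modelling; it is
deliberately out of scope here and handled empirically by the regression
layer instead.

Separately from the physical model (which works in farads), the package
carries the empirical straight-line calibration of the differenced sensor
output, `linear_calibration()`: $C = 0.30744\,W + 17.28085$ in sensor
units (pF) with $W$ in percent, valid only at 22 °C and volume duty cycle
1/3. The farad-scale physics and the pF-scale calibration are never mixed
in one computation.

# The sparrow search optimizer and its chaotic initialisation

`ssa_optimize()` is a box-bounded population minimiser with three roles
re-assigned every iteration by fitness rank:

* **Finders** (best `finder_fraction`, default 0.2): on a safe iteration
  (a single alarm draw $R \sim U(0,1)$ below the safety threshold
  $ST = 0.8$) finder $i$ contracts multiplicatively,
  $x \leftarrow x\,e^{-i/(\alpha T)}$ with $\alpha \sim U(0,1]$ per finder;
  on an alarmed iteration it takes a unit Gaussian step per coordinate.
  The published update prints the exponent as $e^{-i\alpha T}$, which
  underflows for any realistic $i\,T$ and contradicts the algorithm's
  source literature; the canonical $e^{-i/(\alpha T)}$ is implemented,
  and this reading is a deliberate design choice of the package.
* **Joiners** (the rest, fitness rank $i$): the worse half jumps near the
  global worst, $x \leftarrow Q\, e^{(x_L - x)/i^2}$; the better half
  steps around the updated best finder $x_P$ along a random $\pm 1$
  direction row $A$ using the pseudo-inverse $A^+ = A^\top/(AA^\top)$,
  which for a row vector reduces to adding the scalar
  $\sum_j |x_j - x_{P,j}| A_j / d$ to every coordinate.
* **Scouts** (a fresh random 20% each iteration): sparrows with
  above-best fitness move toward the global best with a Gaussian step
  factor; the rest step away from the worst with a $U[-1,1]$ factor, the
  denominator guarded by $\varepsilon = 10^{-50}$.

Positions are clipped to the bounds after every phase; the whole
population is re-evaluated once per iteration, and the reported optimum is
elitist (best position ever evaluated), so the convergence trace is
non-increasing by construction. Random draws occur in a documented fixed
order (alarm, finder $\alpha$/$Q$, joiner draws, scout draws), making
seeded runs exactly reproducible; the test suite verifies the vectorised
updates against independent scalar-loop oracles under shared draws.

LCSSA differs from SSA only in initialisation: each dimension carries its
own logistic-map chain $y_{k+1} = a y_k (1 - y_k)$ at $a = 4$ (the fully
chaotic regime, with the arcsine-shaped invariant density) affinely mapped
into the bounds. Seed values are drawn in $(0.01, 0.99)$ avoiding the
collapsing points $\{0.25, 0.5, 0.75\}$, whose orbits hit the fixed points
of the map. `compare_optimizers()` runs both variants with identical seeds
on the F1–F6 benchmark suite (sphere, $\sum|x|+\prod|x|$, rotated
hyper-ellipsoid, max-modulus, Rosenbrock, step), population 30 and 20
iterations — the published comparison budget. Benchmark boxes are the
conventional ones ($[-100,100]^d$, F2 $[-10,10]^d$, F5 $[-30,30]^d$) and
$d = 30$, since the protocol does not fix them.

# Regressors and metaheuristic tuning

The regression task maps (temperature, volume duty cycle, differenced
capacitance) to moisture percent. Two regressors are provided:

* **ELM** (`elm_fit()`): 100 sigmoid hidden units with random input
  weights/biases in $[-1,1]$; output weights solved in one shot by
  least squares. With 100 smooth hidden functions over a 3-dimensional
  input, the activation matrix $H$ is severely collinear, so the solve is
  a truncated-SVD minimum-norm solution: singular values below `svd_tol =
  1e-4` of the largest are discarded. Directions below that cutoff
  amplify response noise by more than $10^4$ and produce output-weight
  norms of order $10^6$ with erratic off-sample behaviour; the cutoff
  keeps the solution bounded without restricting fit quality on smooth
  targets. This is a numerical rank decision in the pseudo-inverse, not a
  ridge penalty.
* **BP** (`bp_fit()`): a 3-5-1 network (the 5 follows the empirical rule
  $h = \mathrm{round}(\sqrt{m+n}) + a$ with $a = 3$,
  `hidden_nodes_rule()`), sigmoid hidden layer, linear output, trained by
  full-batch gradient descent. Inputs are standardised and the target is
  min–max scaled internally for conditioning; the published stopping
  target error 0.01 is applied to the training MSE on the original
  percent scale. The learning rate is not part of the published protocol;
  the default 0.5 on the scaled problem is chosen so that batch descent
  converges on smooth targets within a few hundred epochs (0.01 stalls
  for thousands of epochs at no accuracy benefit).

`ssa_tune()` wraps the optimizer around either regressor, following
standard metaheuristic-network practice: for ELM the search space is the
flattened hidden-layer parameters (400 dimensions) and the fitness of a
candidate is the training RMSE of the *deployed* model (output weights
re-solved with the same truncated pseudo-inverse); for BP the search space
is the flat initial weight vector (26 dimensions) scored by the untrained
network's RMSE, after which gradient descent fine-tunes from the optimised
initialisation. Population 20 and 20 iterations are the published training
budget. The fitness is training RMSE because the reference protocol uses
no validation split (deliberately, to keep the training set large); the
leakage guard is that all standardisation statistics are learned on the
training split only.

# Evaluation metrics

`model_report()` produces the six-metric row (training/prediction R, RMSE,
RPD) used in the model comparison. The RPD convention here is
$\mathrm{RPD} = 1/\sqrt{1 - R^2}$: the definition is printed elsewhere
without the square root, but the square-root form reproduces every printed
(R, RPD) pairing of the reference results to ±0.001, so it is adopted,
with the classical chemometrics ratio $\mathrm{SD}/\mathrm{RMSE}$ kept
available separately as `rpd_classic()`. Reliability bands: RPD ≤ 1.4
unreliable, 1.4–2.0 relatively reliable, > 2.0 highly reliable (boundaries
assigned to the lower band).

# The synthetic campaign generator

The reference data set (720 sensor records) is not deposited, so
`generate_campaign()` emulates the measurement campaign: 16 moisture
levels from 5.64% to 23.52% (including the 14.42% as-harvested level),
3 replicates, temperatures {15, 22, 33} °C, duty cycles
{0, 1/6, 1/4, 1/3, 1/2} — 720 records, split 3:1 into 540/180 by
`split_train_test()`. For duty cycle $v > 0$ the mean response is

$$
C = (0.30744\,W + 17.28085)\,
    \bigl[1 + k_T (T - 22)(1 + \lambda W)\bigr]\,
    \bigl[1 + k_v (v - \tfrac13)\bigr] + \eta,
    \qquad \eta \sim N(0, \sigma^2),
$$

anchored so that at 22 °C and duty 1/3 the noiseless mean is exactly the
empirical calibration line. The multiplicative factors encode the observed
qualitative trends — capacitance rises with temperature and duty cycle,
more steeply at high moisture ($\lambda > 0$) — for which no functional
form is published; the coefficients ($k_T = 0.004$/°C, $\lambda = 0.05$
per percent, $k_v = 0.6$, $\sigma = 0.4$ pF, air baseline 10 pF) are the
package's invented, documented defaults, chosen once as plausible for a
bench-scale differential cell. At duty cycle 0 the plates are empty and
the differenced channel is the air baseline plus noise — by construction
those records carry no moisture information, which is why
`run_experiment()` excludes them from the regression stage by default
(`include_empty_duty = FALSE`); the campaign and its 720/540/180 counts
always include them.

What the generator does *not* emulate: sensor drift, electrode fouling,
conductive contaminants, replicate-level systematic offsets, and any
temperature dependence of the grain permittivity beyond the multiplicative
trend. Passing tests on synthetic campaigns therefore demonstrate the
correctness and stability of the pipeline and the directional behaviour of
the model variants, not field accuracy: the synthetic task is smoother
than real grain data, so absolute correlations run higher than the
published ones (about 0.97 prediction-set R at the default noise level
versus about 0.70 on the real instrument), and only orderings and
internal identities are comparable.

# The experiment pipeline

`run_experiment()` chains the stages: campaign, split, six model variants
(BP, SSA-BP, LCSSA-BP, ELM, SSA-ELM, LCSSA-ELM) on the shared split, and
the report tables. A master seed fans out to campaign, split and model
seeds; the model stage draws one seed per regressor family so that the
SSA- and LCSSA-tuned variants of a family are true seed pairs differing
only in the population initialisation. Reports are written with metrics
rounded to 4 decimals plus a full-precision sidecar, and a provenance
block records seeds and configuration. A thin command-line front end over
these functions ships in `inst/cli/capmoist.R` (subcommands `simulate`,
`split`, `fit`, `compare`, `invert`, `benchmark`).

```{r pipeline, eval = FALSE}
cfg <- experiment_config(seed = 1)
res <- run_experiment(cfg, out_dir = "results")
res$report
```

# Numerical choices and degenerate inputs

* Fitness ties in the population sort are broken by index (stable order).
* Non-finite objective values are treated as $+\infty$.
* The scout denominator guard is $\varepsilon = 10^{-50}$.
* `moisture_from_capacitance()` rejects capacitances outside the
  attainable open interval and reports that interval in the error.
* A hidden layer whose activations are all constant triggers a warning
  from `elm_fit()`; the truncated solve still returns the minimum-norm
  solution (the sample mean).
* Split counts that are not divisible by 4 round the training size down.

# Problem sizes used by the test suite

The package's own verification runs at desk scale, chosen to exercise
every code path at full published hyperparameters where those are stated:
the dielectric oracle sweeps 1000 random cells; the optimizer comparison
uses the published budget (population 30, 20 iterations, 11 paired seeds,
$d = 30$); the regression comparison uses 11 paired synthetic campaigns
at the default noise level with the published model hyperparameters
(ELM 100 hidden units, tuning population 20 x 20 iterations).

# Known limitations

* The physical model's $d$ and $e$ defaults are uncalibrated placeholders.
* The correlation-based RPD is not the classical SD/RMSE ratio on held-out
  data; both are provided but only the former matches the reference
  convention.
* The BP trainer is plain batch gradient descent (no momentum or adaptive
  steps) by design; it is adequate for the 26-parameter network but not a
  general-purpose trainer.
* On near-noiseless synthetic data the margin between plain and
  metaheuristic-tuned ELM variants is at the fourth decimal of R —
  substantively a tie; the tuned variants' advantage grows with noise and
  with the difficulty of the response surface.
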