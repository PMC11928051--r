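---
title: "Allometric scaling of normal hovering flight: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric scaling of normal hovering flight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoverscale)
```

## The scientific question

Normal hovering — flapping in a nearly horizontal stroke plane with
symmetric half-strokes, as fruit flies, hawkmoths, bees and hummingbirds do
— spans some five decades of body mass, and across that range smaller
animals flap faster. `hoverscale` implements a scaling analysis of this
flight mode built around one physical idea: the negative allometry of the
flapping frequency is what keeps the body attitude sustainable during
hover. The package derives the theoretical mass exponents of every hover
parameter by exact rational arithmetic, simulates the body-pitch balance
that motivates the frequency law, and fits empirical power laws
$y = \beta m^\gamma$ to comparative data by ordinary least squares (OLS)
and phylogenetic generalized least squares (PGLS).

## The model

### Hover equilibrium and the nondimensional parameter set

In equilibrium hover, cycle-averaged lift balances weight. With mean
wing-tip velocity $U = 2\Phi f R$ (peak-to-peak stroke amplitude $\Phi$ in
radians, flapping frequency $f$, wing length $R$), this closure defines the
cycle-averaged lift coefficient

$$C_L = \frac{2 m g}{\rho U^2 S},$$

which absorbs all unsteady lift mechanisms (leading-edge vortex, wake
capture) rather than modelling them. The remaining nondimensional
parameters are the aspect ratio $AR = R^2/S$, the reduced frequency
$k = \pi f c/U = \pi/(2\Phi AR)$ with mean chord $c = S/R$, the Reynolds
number $Re = \rho U c/\mu$, the wing pitch angle $\alpha$, the body pitch
amplitude $\theta_a$, and the nondimensional body inertia
$I^* = I/(m R_b^2)$ and moment arm $\delta^* = \delta/R_b$.

### Assumptions and the exponent engine

The theoretical allometry follows from a small assumption set
(`hover_assumptions()`): geometric similarity of wing and body
($R, R_b, \delta \sim m^{1/3}$, $S \sim m^{2/3}$), bounded (mass-invariant)
angles $\Phi, \alpha, \theta_m, \theta_a$, mass-invariant $I^*$ and
$\delta^*$, and environmental constants $\rho, \mu, g \sim m^0$. Exponents
are carried as exact integer fractions (`rational()`); the engine is a
single linear chain of product-of-powers combinations
(`combine_exponents()`) plus one constraint solve — deliberately not a
general computer-algebra system, because the constraint system is that
small.

The one nontrivial step is the frequency law. In the longitudinal plane the
body pitch acceleration is balanced by the aerodynamic pitch moment,
$I\ddot\theta \sim \delta L$ with $L \sim mg$ at hover. Harmonic pitch
implies $\ddot\theta \sim \theta_a f^2$, so the pitch amplitude scales as
$\theta_a \sim g/(R_b f^2)$. Requiring $\theta_a \sim m^0$ — attitude must
stay bounded for every body size — yields

$$\gamma(\theta_a) = \gamma(g) - \gamma(R_b) - 2 e_f = 0
  \quad\Longrightarrow\quad e_f = -\tfrac{1}{6}.$$

`solve_frequency_exponent()` solves this one-equation system in either
direction: the forward solve gives $e_f = -1/6$, and fixing any
$e_f \neq -1/6$ makes the implied $\theta_a$ exponent non-zero — smaller
animals (steeper $e_f$) or larger ones (shallower $e_f$) would accumulate
unbounded pitch excursions. Propagating $e_f$ gives the full table:

```{r theory}
derive_exponents()[, c("quantity", "gamma")]
```

$U \sim m^{1/6}$, $Re \sim m^{1/2}$, and every other nondimensional
parameter is mass-invariant: hovering is dynamically similar across the
size range except for the Reynolds number.

## The pitch-dynamics simulator

`pitch_sim()` integrates the forced balance
$I\ddot\theta = \varepsilon m g \delta \cos(2\pi f t + \phi)$ with
fixed-step classical Runge-Kutta (via `deSolve`, 200 steps per cycle by
default, 20 cycles). Design choices worth stating:

* **Forcing waveform.** The oscillatory pitch moment is a single
  zero-mean harmonic with relative amplitude $\varepsilon$ (default 0.1).
  This is the simplest forcing consistent with a harmonic pitch response
  and lift scaling with weight; the actual magnitude and phase of the
  moment relative to the stroke are not well constrained by published
  measurements, and $\varepsilon$ cancels from every scaling conclusion.
  The mean moment is zero (hover trim), so the mean pitch holds without
  secular drift; initial conditions are the matched trim state of the
  periodic solution.
* **Amplitude estimator.** Half the peak-to-peak excursion over the final
  25% of the record, after discarding the first half, with parabolic
  refinement of the sampled extrema (removing the $O(\Delta t^2)$
  discrete-sampling bias at the peaks). This estimator is exact for the
  linear closed form $\theta_a = \varepsilon m g \delta/(I(2\pi f)^2)$ and
  remains meaningful for nonlinear extensions, unlike a spectral
  estimator. The tests verify agreement with the closed form to better
  than 0.1% over a 10×10 grid of masses ($10^{-7}$–$10^{-2}$ kg) and
  frequencies (5–500 Hz).
* **The sweep.** `pitch_invariance_sweep()` applies isometric body
  geometry ($R_b, \delta \propto m^{1/3}$, $I \propto m^{5/3}$) across a
  mass grid with $f \propto m^{e_f}$. Since
  $\theta_a \propto m\,\delta/(I f^2) \propto m^{-1/3} f^{-2}$, the
  log–log slope of amplitude against mass is $-1/3 - 2e_f$: zero exactly
  at $e_f = -1/6$ (amplitude ratio across five decades of mass stays
  within 1%), $-1/3$ at $e_f = 0$ and $+1/3$ at $e_f = -1/3$. This is the
  numerical confirmation of the attitude argument.

## Regression machinery

Each trait is aggregated to one value per species — the unit of analysis a
phylogenetic regression requires — by `weighted.mean` with the number of
replicate measurements behind each literature row as weights
(`species_means()`). Fits are on the $\log_{10}$ scale in the dataset's
native units (mg, mm, mm², Hz, degrees; $U$ in m/s), because intercepts
are only meaningful on the scale the data are reported in; SI is used
internally for all physics.

`ols_loglog()` implements the closed-form normal equations, reporting the
slope with its 95% t-interval, a two-sided test of slope = 0, and
**adjusted** $r^2$ — which can be negative, and is exactly the informative
behaviour for traits whose slope is indistinguishable from zero (the
mass-invariance checks). `pgls_loglog()` is the GLS estimator
$\hat b = (X^TV^{-1}X)^{-1}X^TV^{-1}y$ with
$\hat\sigma^2 = e^TV^{-1}e/(n-2)$, whitened through a Cholesky factor of
the phylogenetic covariance $V$. `phylo_covariance()` builds $V$ from
shared root-to-ancestor path lengths and applies Pagel's $\lambda$ to the
off-diagonals. Both estimators are intentionally hand-written so that the
test suite can cross-check them against independent references
(`lm()`, and `nlme::gls()` with `ape::corPagel` at fixed $\lambda$), which
they match to near machine precision.

Numerical and design choices:

* **$\lambda = 0.5$, fixed, by default.** A fixed $\lambda$ is the
  reproducible reading of a "Pagel's $\lambda$ at 0.5" analysis; a profile
  maximum-likelihood mode (`estimate_lambda()`, `lambda = "ML"`) is
  provided but off by default, since ML estimates of $\lambda$ on ~27
  species are noisy and change slopes only in the third decimal.
* **Unit branch lengths for cladograms.** Taxonomy-derived trees carry no
  branch lengths; they are assigned unit lengths with a warning. This is
  safe because the GLS slope is invariant under uniform rescaling of $V$
  (verified in the tests with factors 0.1 and 10).
* **Species means, not observations.** Weights act only inside the
  aggregation step; regressions then see one point per species. An
  observation-level OLS mode (`level = "observation"`) exists as a
  sensitivity analysis.
* **No silent regularisation.** A singular covariance is an error, not a
  nudged matrix.
* **Wing-area convention.** Published tables mix single-wing and wing-pair
  areas; the package applies whatever convention the input table uses,
  consistently, and the lift-coefficient intercept (not its exponent)
  absorbs the factor of two. The exponent analysis is unaffected.

## The synthetic clade generator

Because the compiled comparative dataset cannot be redistributed,
`synth_tree()` and `synth_observations()` generate study-shaped data with
known truth: a pure-birth ultrametric phylogeny of unit depth, species
masses log-uniform over 0.1 mg–10 g (fruit fly to large hummingbird), and
traits $y_s = \beta m_s^\gamma 10^{b_s + w}$ with species-level residual
$b_s$ mixing a Brownian-motion component on the tree with an independent
component (`lambda_signal`, default 0.5 — matching the $\lambda$ the
fitter assumes), plus per-observation scatter $w$. Defaults: 27 species,
generating exponents equal to the theoretical table, intercepts giving
realistic magnitudes (≈282 Hz and ≈114° stroke amplitude at 1 mg,
reduced frequency ≈0.2 — inside the dynamic-stall band), species SD 0.05
and observation SD 0.02 on the $\log_{10}$ scale, 2–10 rows per species
with 15% of rows lacking kinematics (exercising the partial-data path of
real literature tables). Noise is multiplicative (additive in logs): the
fitted model is linear in logs and negative trait values must be
impossible.

What the generator deliberately does **not** emulate: real species' trait
values or topology, heteroscedastic measurement error across sources,
correlated errors between traits measured in the same study, or any wing
kinematic detail beyond $(f, \Phi)$. Passing recovery tests therefore
demonstrates the statistical machinery is correct and unbiased under its
assumed model — not that the model captures every feature of literature
data.

Simulation sizes used by the test suite — 200 replicate clades of 27
species for the bias/coverage checks, 60 replicates for the
efficiency comparison, a 10×10 grid for the oscillator verification —
were chosen so Monte-Carlo error sits comfortably below the asserted
tolerances (e.g. the standard error of the mean slope over 200 replicates
is ≈0.0005 against a 0.01 bias bound).

## Limitations

The analysis is cycle-averaged throughout: no time-resolved forces, no
quasi-steady blade-element model, no wing flexibility or fluid–structure
interaction, no clap-and-fling model, and no treatment of asymmetric
hovering (bats). The pitch balance is linearised through a prescribed
forcing; the nonlinear coupling of $C_L$ to the instantaneous attitude has
no known exact solution and is outside scope. Hyperallometry (hummingbird
wing area) is supported only through subgroup exclusion and through
injection in the generator, not explained.
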