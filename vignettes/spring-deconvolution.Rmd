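---
title: "Deconvoluting single-cell stiffness with a series-parallel spring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting single-cell stiffness with a series-parallel spring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellspring)
```

## The problem

Walled plant cells (the motivating system is the tobacco BY-2 suspension
line) resist indentation through several coupled structures: the stiff
polysaccharide cell wall (CW), the turgor-pressurised protoplasm behind it,
and the two cytoskeletal polymer networks — microtubules (MT) and actin
filaments (AF). A single indentation measures only one effective stiffness;
the structural contributions are confounded. The experimental design that
this package analyses breaks the confound with six treatment conditions:
two osmotic states — growth medium (`GM`, turgid) and a plasmolysing
solution (`PS`, turgor removed) — each crossed with no drug, oryzalin
(depolymerises MTs, `-MT`) and latrunculin B (removes AFs, `-AF`), probed
at two scales: micro-indentation of whole cells (forces up to ~900 uN) and
AFM nano-indentation of the wall alone (15–70 nN, a 1 um silica bead).

## The mechanical model

The cell is modelled as two springs in series: the wall, and a parallel
branch containing everything inside it,

$$k_\mathrm{eff}(t) \;=\; \frac{R_t\,k_{cw}\cdot b_t}{R_t\,k_{cw} + b_t},
\qquad
b_t \;=\; k_\mathrm{res} + k_{mt}\,[\mathrm{MT\ present}] + k_{af}\,[\mathrm{AF\ present}],$$

where $k_{cw}$ and the residual protoplasm stiffness $k_\mathrm{res}$ take
osmotic-state-specific values (`k_cw_gm`/`k_cw_ps`, `k_gm`/`k_ps`), the
filament springs `k_mt`/`k_af` are shared across conditions, and $R_t$
rescales the wall in drug treatments. In the micro-indentation-only
analysis $R_t \equiv 1$ (drugs assumed not to touch the wall); in the
combined analysis $R_t$ is the ratio of mean AFM wall stiffness in the drug
condition to its no-drug osmotic match (`afm_ratios()`), carrying the
nanoscale observation that cytoskeletal drugs do soften the wall into the
whole-cell equations without new free parameters.

Assumptions inherited from the model: linear-elastic springs (no
viscosity, adhesion or plasticity), shallow indentations, and turgor
pressure absorbed into the GM/PS split rather than modelled explicitly.
Six treatment means constrain six constants, so the system is exactly
determined — but not equally well in every direction (see
*Identifiability* below).

## From raw curves to stiffness

`process_curve()` chains the per-curve steps; each is exposed separately.

* **Sensor compliance** (`estimate_sensor_stiffness()`,
  `correct_compliance()`). A reference indentation on glass gives the
  sensor stiffness $S$ as the slope over the last 1 um of approach; cell
  curves are corrected by $\delta_\mathrm{corr} = \delta - F/S$. The
  correction is exactly invertible, which the tests exploit.
* **Contact detection** (`detect_contact()`). Force thresholding: baseline
  mean and sd over the first 30% of approach samples; contact is the first
  crossing of mean $+ 5\,$sd that persists for 5 consecutive samples
  (spike rejection). With a noiseless baseline (sd = 0) a floor of
  3x the instrument force resolution applies. A drifting baseline window
  (two halves differing beyond the first half's standard error scale)
  raises an `unstable_baseline` warning.
* **Initial stiffness** (`fit_initial_stiffness()`). Ordinary
  least-squares slope of force against post-contact depth. The
  micro dialect fits the first 1 um of indentation; the AFM dialect fits up
  to 10% of the maximum force. Because the fit has an intercept, the
  one-sample quantisation of the detected contact does not bias the slope.
* **Hertz modulus** (`fit_hertz_modulus()`, AFM only). Rigid spherical
  indenter on an elastic half-space,
  $F = \tfrac{4}{3}\,\tfrac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$, fit as a
  regression through the origin in $\delta^{3/2}$. Poisson's ratio defaults
  to 0.5 (incompressible soft matter) and is exposed because $E$ scales
  with $1-\nu^2$. The 3/2-power rise clears the detection threshold well
  past true contact, so the contact displacement is refined by profiling
  the least squares over a window reaching back from the detected index —
  without this the modulus is biased by several tenths of a percent even
  on noise-free data. Depths beyond 20% of the bead radius trigger a
  validity warning.
* **Dissipated energy** (`dissipated_energy()`, micro). Trapezoidal area
  between approach and retract over their common displacement range, both
  resampled onto a uniform 1000-point grid (the two segments are never
  sampled at identical positions). Tests that never reach the configured
  force threshold are excluded by a classed condition, not a silent `NA`.
  Negative (adhesive) retract forces enter the signed area by default; a
  clip-at-zero option exists.

## The generative statistical model

Each treatment's observed stiffness sample is summarised by its mean; the
likelihood centres a Gaussian on that mean with standard deviation equal to
the standard error (`sd_model = "se"`; a pooled per-observation variant is
a config switch). The prior on the six constants is, by default,
independent truncated normals located at a moment-matched split of the
observed means (`empirical_priors()`: wall twice the no-drug mean, branch
sums by series inversion, filaments from branch differences), with scale
twice the location and support $(0,\ 10\times\max \bar y\,]$ — weakly
informative, data-scaled, and realising the parameter box constraint. A
flat-on-box prior is available; its log-density is the unnormalised 0.

The combined objective is

$$F(\kappa, w) = \sum_t w_t \,\ell_t(\kappa) + \log \pi(\kappa),
\qquad \sum_t w_t = 1,\quad w_t \in [0.05,\ 0.5],$$

maximised jointly over the parameters and the six weights. Because the
weights sum to one, weighting each treatment's log-posterior term is
equivalent to this form.

**Weights are solved exactly.** $F$ is linear in $w$, so for fixed
$\kappa$ the optimal weights are the solution of a bounded simplex linear
program, found in closed form by greedy allocation
(`optimal_weights()`): every weight starts at the floor and the remaining
budget goes to the largest terms first. A consequence worth knowing: the
optimum always sits on a vertex of the constrained simplex (here
$0.5, 0.3, 0.05, 0.05, 0.05, 0.05$ in order of fit quality), so
"weights at bounds" is the expected state, reported as a diagnostic field
rather than warned about.

**The outer problem.** With the weights profiled out the objective is a
function of $\kappa$ alone, optimised by box-constrained quasi-Newton
(L-BFGS-B) on $\log\kappa$ with analytic gradients, from multiple starts:
the root of the six mean equations (`solve_exact()` — with six means and
six unknowns the MAP sits essentially at that root whenever it is
admissible), the moment-matched heuristic, and seeded log-uniform draws
over the prior box (16 starts by default). A fixed-weight Newton polish
then drives the projected gradient norm below the KKT tolerance
($10^{-6}$ in log-parameter space). On noise-free data the likelihood is
needle-sharp and gradients cannot be resolved below machine precision
times the curvature; the convergence flag therefore uses
$\max(10^{-6},\ 10^{-12}\,\|H\|_\infty)$.

**Credible intervals.** The Laplace approximation at the MAP: the Hessian
of the profiled objective by symmetrised central differences (relative
step $10^{-4}$), and per-parameter 68% half-widths as square roots of the
diagonal of the inverse negative Hessian; the full covariance supports
pairwise projections (`map_projection()`).

## Solving the mean equations exactly

`solve_exact()` exploits the network structure rather than brute-forcing a
6-D root-find. Given a wall stiffness $c$, the series relation inverts in
closed form: branch sums $B_t(c) = y_t c/(c - z_t)$ with $z_t = y_t/R_t$.
Within one osmotic group the filament constants are branch differences,
and "$k_{mt}(c) = \tau$" is a quadratic in $c$. Fixing the PS wall
stiffness therefore determines everything else in closed form, and
consistency of the two implied GM wall stiffnesses is a one-dimensional
root-find solved by sign bracketing and `uniroot`. A damped
Levenberg–Marquardt Newton on log-parameters (QR-form steps, analytic
Jacobian) polishes the result and serves as fallback for caller-supplied
starts. The residual tolerance is $10^{-10}$ relative to the target-mean
scale; the Jacobian condition number is reported, with a warning beyond
$10^{10}$.

## The synthetic-data generator

No raw recordings are deposited with the motivating study, so the
generator produces all test inputs with the statistical structure the
analysis assumes:

* `default_truth()` fixes a trend-faithful ground truth,
  $\kappa^* = (10, 5, 20, 4, 3, 1.5)$ N/m: wall twice as stiff under
  turgor, residual protoplasm five times stiffer, microtubules twice the
  actin contribution — the orderings the analysis is designed to resolve,
  on the N/m scale reported for turgid BY-2 cells. The absolute values are
  plausible scales, not measurements.
* `simulate_treatment_stiffness()` draws per-cell stiffness as
  $N(k_\mathrm{eff}(t),\ (0.1\,k_\mathrm{eff}(t))^2)$ truncated at zero,
  65 cells per treatment — a 10% coefficient of variation at the sample
  sizes of the motivating figures.
* `simulate_micro_curve()` builds hysteretic load–unload curves: zero-force
  baseline (40% of samples), linear loading to 900 uN, retract scaled by
  $1 - h\,g(\delta)$ with the bump $g(u) = 4u(1-u)$, chosen so the
  enclosed area has the closed form $h\,k\,\delta_\mathrm{max}^2/3$ —
  an analytic oracle for the energy integrator. Additive Gaussian force
  noise only.
* `simulate_afm_curve()` follows the Hertz law with a 0.5 um bead radius
  and a peak force drawn in 15–70 nN.

What the generator does **not** emulate: drift and piezo creep, adhesion,
viscoelastic rate dependence, cell-to-cell geometry variation, and
non-Gaussian outliers. Passing tests therefore demonstrate correctness of
the computational chain under the model's own assumptions, not robustness
to every artefact of real recordings.

## Identifiability, honestly

Linear error propagation through the Jacobian of the mean equations at
$\kappa^*$ shows how unevenly the six constants are determined. With unit
ratios, removing a filament changes its treatment mean by only ~3–4%
while 65-cell means carry ~1.24% noise: the *ideal* estimator's median
relative error is several hundred percent for `k_mt` and `k_af`. This is
precisely why the combined analysis exists — wall ratios below one make
the drug conditions informative about the wall, and the same propagation
gives ideal median errors of roughly 3–35% per component. The package's
recovery study (20 replicates at the study conditions, ratio-informed)
measures a median per-component MAP error around 16–30% depending on the
seed set, with 68% interval coverage of 0.80–0.83. The weighted objective
itself costs precision: vertex weights use the six treatments unevenly,
inflating the estimator's sampling sd by roughly $\sqrt{6\sum_t w_t^2}
\approx 1.4$ relative to equal weighting. Interpretation of the filament
constants should lean on the credible intervals, not the point estimates.

```{r identifiability, eval = FALSE}
# reproduce the propagation at the default truth
p <- default_truth()$params
fit <- maximize_posterior(treatment_datasets(simulate_treatment_stiffness(default_truth())))
tidy(fit)
```

## Numerical and design choices, in one place

| Quantity | Default | Why |
|---|---|---|
| Poisson's ratio $\nu$ | 0.5 | incompressible soft matter; $E \propto (1-\nu^2)$ so it must be explicit |
| Micro stiffness window | 1 um depth | comparable to the hydrated wall thickness |
| AFM stiffness window | 10% of max force | shallow-contact wall response |
| Contact threshold | baseline mean + 5 sd, 5-sample persistence | rejects noise spikes; floor 3x force resolution at sd = 0 |
| Energy force threshold | 0 (configurable) | the motivating study's threshold is not machine-readable in the source |
| Weight box | [0.05, 0.5] | all treatments included, none dominant |
| Parameter box | $(0,\ 10 \max \bar y\,]$ | realises the spring-constant size constraint |
| sd model | standard error of the mean | treatment means are the modelled quantities |
| Multi-start | root + heuristic + 14 seeded draws | the root start makes sharp likelihoods tractable |
| Solver residual | $10^{-10}$ relative | comfortably below any data noise |
| Hessian step | $10^{-4}$ relative, symmetrised | central differences on a smooth profile |
| KS p-value | asymptotic at effective $n_1 n_2/(n_1+n_2)$; exact enumeration for $n_1+n_2 \le 20$ | labelled in the output, since the original software's variant is unstated |
| sd convention | $n-1$ | throughout |
| Multiple testing | none by default, Holm optional | raw pairwise p-values mirror the figure legends |

Problem sizes exercised by the test-suite studies: 65 cells per treatment,
20-replicate recovery runs, 500-replicate contact-detection calibration,
2000-replicate KS null calibration, 100-draw solver round trips. These are
the package's validation conditions; the same machinery runs unchanged at
other sizes.

## Known limitations

* The spring model is scalar and geometry-free: wall bending, anisotropy
  and cell shape are absorbed into effective constants.
* The filament constants are weakly identified without the AFM ratios (see
  above); reported intervals are honest about this.
* The Laplace region is a quadratic approximation around a constrained
  optimum; when the MAP pins against the parameter box the interval is
  unreliable and the code refuses (degenerate-curvature error) rather than
  reporting a number.
* Treatment means are modelled, not per-cell hierarchies: cell-to-cell
  variance enters only through the standard error.
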