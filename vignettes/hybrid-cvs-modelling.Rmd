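---
title: "Hybrid neural-ODE modelling of ventricular interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid neural-ODE modelling of ventricular interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The mechanistic model

`cvsude` implements a closed-loop lumped-parameter (pressure–volume) model of
the human cardiovascular system in the tradition of the minimal haemodynamic
model of Smith et al. (2004, *Med Eng Phys* 26:131–139). Six elastic chambers
— left ventricle, right ventricle, aorta, vena cava, pulmonary artery and
pulmonary vein — are connected in series by resistances, by inertances at the
four heart valves, and by diodes representing the valves themselves. The
state vector is

\[
U = [Q_{mt}, Q_{av}, Q_{tc}, Q_{pv},\;
     V_{lv}, V_{rv}, V_{ao}, V_{vc}, V_{pa}, V_{pu}],
\]

four valve flows (mL/s) and six chamber volumes (mL). Units are mmHg / mL / s
throughout, pressures relative to atmosphere.

**Chamber laws.** Passive chambers are linearly elastic,
\(P = E\,(V - V_d)\), with the intrathoracic offset \(P_{th} = -4\) mmHg
added for the chambers inside the thorax (pulmonary artery and vein). The
actively contracting walls (left and right ventricular free walls, septum)
blend a linear end-systolic law and an exponential end-diastolic law through
the cardiac driver \(e(t)\):

\[
P_w(V, t) = e(t)\,E_w (V - V_{d,w})
        + (1 - e(t))\,P_{0,w}\left(e^{\lambda_w (V - V_{0,w})} - 1\right).
\]

**Cardiac driver.** A Gaussian pulse per beat,
\(e(t) = A \exp\{-B(\operatorname{mod}(t,T) - C)^2\}\) with \(A = 1\),
\(B = 80\ \mathrm{s^{-2}}\), \(C = 0.27\) s and heart period \(T = 0.75\) s
(80 bpm).

**Ventricular interaction (VI).** The two ventricles couple through the
septum and the pericardium. The septum free-wall volume \(V_{spt}\) is
defined implicitly by the trans-septal pressure balance
\(P_{spt}(V_{spt}) = P_{lvf}(V_{lv} - V_{spt}) - P_{rvf}(V_{rv} + V_{spt})\),
which has no closed-form solution; `septum_volume()` solves it by
Newton–Raphson (analytic derivative, warm-started from the previous root,
absolute residual tolerance \(10^{-9}\) mmHg, 50 iterations, guarded
bisection fallback over \((-V_{rv}, V_{lv})\), on which the residual is
strictly increasing, hence the root unique). The pericardium pressure is

\[
P_{peri} = P_{0,pcd}\left(e^{\lambda_{pcd}(V_{lv} + V_{rv} - V_{0,pcd})} - 1\right) + P_{th},
\]

so \(P_{peri} = P_{th} = -4\) mmHg exactly at the pericardial unstressed
volume.

**Valve law.** Each valve flow has inertial dynamics
\(\dot Q = (\Delta P - R\,Q)/L\) while the valve conducts (\(Q > 0\) or
\(\Delta P > 0\)) and is pinned at \(\dot Q = 0\) otherwise; any transient
negative flow is clamped to zero in sampled output (and after each training
integrator step). This switching right-hand side, combined with a capped
solver step, stands in for event detection: the valve transitions are the
only non-smooth feature of the dynamics, and the cap keeps the solver from
stepping across them.

All constants live in a single shipped parameter file
(`inst/extdata/cvs_params_default.txt`, strict schema). The default initial
state is a periodic-steady-state snapshot at beat onset, computed once by a
30 s burn-in from a physiological cold start with ~1.5 L of total stressed
volume; from it the simulation is periodic from \(t = 0\) and conserves total
volume to \(<10^{-4}\) mL over 10 s.

## Synthetic data

`cvs_integrate()` solves the system with the adaptive Dormand–Prince 5(4)
pair (deSolve's `ode45`), maximum step \(10^{-2}\) s, absolute tolerance
\(10^{-7}\), relative tolerance \(10^{-4}\), sampled at 100 Hz
(`dt = 0.01` s). `add_noise()` adds i.i.d. zero-mean Gaussian measurement
noise per state, with standard deviation equal to a chosen fraction (0%, 2%,
5%) of that state's own standard deviation over the full 10 s series —
per-state because the states carry incompatible units. The noise is drawn
once (a fixed noisy dataset, reproducible by seed), not re-drawn during
training. The noise distribution is a modelling choice recorded in the
trajectory metadata; real measurement noise need not be Gaussian,
independent across time, or stationary — passing tests therefore validate
the pipeline mechanics and the method's noise robustness under this model,
not performance on clinical recordings.

```{r}
library(cvsude)
params <- cvs_params()
gt <- cvs_integrate(params, cvs_initial_state(), 10, vi_mechanistic(),
                    derived = TRUE)
noisy <- add_noise(gt, 0.05, seed = 1)
```

## The hybrid neural ODE

The two VI quantities are the only parts of the model with awkward numerics
(an embedded root solve), and the literature often simplifies or omits them.
The hybrid model replaces exactly these two terms with a fully connected
network \(5 \to 10 \to 10 \to 10 \to 2\) (ELU hidden activations, linear
output head) mapping the five volumes
\((V_{lv}, V_{rv}, V_{ao}, V_{vc}, V_{pa})\) to \((V_{spt}, P_{peri})\).
\(V_{pu}\) and the flows are deliberately excluded as inputs. On the hybrid
path no Newton–Raphson solve occurs anywhere.

**Input scaling.** The network inputs are standardized per input with the
mean and standard deviation of the training window, and the descriptor is
stored inside the model file so predictions are self-contained. Raw volumes
(order 100–800 mL) with fan-in/fan-out (Glorot) initialization put the ELU
layers deep into saturation and drive \(V_{spt}\) estimates of order
\(\pm 100\) mL, which overflow the free-wall exponentials before training
can react; standardization makes the untrained model integrable, which the
test suite requires. Identity scaling remains available
(`identity_scaling()`).

**Initialization.** Glorot uniform weights, zero biases, seeded
(`init_network(seed)`); the seed is stored with the weights.

## Training

The first 0.3 s of the series — less than one heart period, deliberately, so
the data do not cover a full cycle — is the training window: 30 samples at
100 Hz over 10 states, a pooled training set of \(N = 300\) points. The loss
is the pooled mean squared error

\[
L = \frac{1}{N}\sum_{i=1}^{N}(y_i - \hat y_i)^2 .
\]

Each iteration integrates the hybrid system across the window and
backpropagates through the integrator steps (discretize-then-optimize): a
fixed-step classical RK4 discretization with step \(h = dt/4 = 2.5\) ms, with
a hand-written discrete adjoint in compiled code. Discretize-then-optimize
was chosen over a continuous adjoint because the valve law switches
discontinuously; the exact gradient of the discretized trajectory (with zero
subgradients on the closed-valve and clamped branches) is robust there, and
it is validated against finite-difference oracles in the test suite. The
optimizer is Adam with the two-stage schedule: learning rate 0.01 for 1000
iterations, then \(10^{-4}\) for 100.

**Ensemble.** The same structure is trained 10 times from seeds
\(s, s+1, \dots\); a member is accepted if its final training MSE is at or
below the noise-dependent threshold (1.0 at 0% noise, 8.0 at 2%, 50.0 at 5%
— roughly the corresponding noise floors), and rejected runs are logged. At
most \(5\times\) ensemble-size attempts are made. Predictions (never
weights) are averaged: each member is integrated over the horizon, its five
input-volume series and two network-output series extracted, and the
pointwise mean taken.

```{r}
cfg <- training_config(noise = 0.05)
ens <- build_ensemble(cfg, noisy, params)
avg <- average_predictions(ens, horizon = 0.75)
```

## Distillation by symbolic regression

The trained ensemble is regressed into closed form: the member-averaged
volume series are the SR inputs and the member-averaged network outputs the
targets (the initial-condition row is dropped — it is not a prediction). The
default extraction horizon is one heart period (0.75 s), long enough for the
VI terms to traverse their full range; the dataset is capped at 2000 rows,
uniformly in time, and the cap recorded in the provenance.

The engine is a genetic-programming search over operator trees with binary
operators \(\{+, -, \times, \div\}\), unary \(\exp\), real constants and the
five volume variables — the smallest operator set that spans the shipped
reference expressions. Tournament selection, subtree crossover, subtree and
point mutation, elitism; fitness is the MSE after closed-form affine
rescaling of the candidate (Keijzer linear scaling), with non-finite
candidate output (e.g. vanishing denominators) penalized by a large finite
loss (\(10^{10}\)) during fitting. A hall of fame keeps the best expression
at each complexity (node count); at the end, the constants of each entry are
polished by Nelder–Mead/BFGS. Candidates are scored by the drop in log-loss
per unit complexity along the Pareto frontier,
\(s_i = (\log L_{i-1} - \log L_i)/(c_i - c_{i-1})\), the simplest member
scored against the constant-mean baseline; `select_best()` takes the highest
score, ties broken by lower complexity, then lexicographic serialization.
Expressions serialize to a canonical grammar (fully parenthesized infix,
commutative operands sorted, round-trip-exact constants).

`make_partially_learned_model()` substitutes the two selected expressions
for the VI terms, yielding a fully mechanistic, closed-form model again —
integrated with raw (unguarded) division, so a genuinely singular expression
fails loudly rather than silently.

```{r}
ds <- extract_sr_dataset(ens, horizon = 0.75)
cands <- fit_expressions(ds, sr_config(seed = 42))
plm <- make_partially_learned_model(select_best(cands$V_spt),
                                    select_best(cands$P_peri), params)
```

## Evaluation conventions

`pooled_rmse()` pools squared errors over all 10 states and all samples and
is deliberately unnormalized, so the large-volume states dominate — matching
the single-scalar convention of the headline comparisons. The reference for
all RMSE comparisons is the *noiseless* mechanistic trajectory (noise is a
property of the training data, not of the truth), over the full horizon
including the training window; both choices are configurable. VI-term MSEs
(`vi_term_mse()`) default to the 0.3 s training window, a choice the
evaluation records because the window behind the reference values is not
pinned down. The no-VI comparison variant omits the interaction terms
literally (\(V_{spt} = 0\), \(P_{peri} = 0\)), leaving the septum elastance
blended into neither free wall — the usual simplification in models that
ignore VI.

## Numerical choices and degenerate inputs

* Newton–Raphson: warm start, tolerance \(10^{-9}\) mmHg, bisection
  fallback; failure raises a typed condition carrying the last iterate.
* Training integration aborts (typed divergence condition) on non-finite or
  exploding states (\(|u| > 10^8\)); the ensemble logs and retries.
* Strict schemas everywhere: parameter files, trajectory CSVs (header-driven
  column mapping, errors name line and column), network weight files (shape
  manifest), run configurations (unknown keys rejected).
* All randomness (noise, initialization, GP) is seeded; every artifact
  records its seed, and stage seeds derive from one global seed by fixed
  offsets (+1000 noise, +2000 SR).

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full-scale protocol where
it is cheap (10 s ground truth; full 1000+100 training schedule; 10-member
ensemble at 0% noise) and reduced scales where only the mechanics are under
test (short windows, ensembles of 2, small GP populations). The reduced
sizes are stated inline in each test.

## Known limitations

* The valve switching makes the flows only first-order accurate at opening
  instants; pointwise convergence claims are made for the smooth volume
  states.
* Training quality varies noticeably across initialization seeds; the
  ensemble's acceptance thresholds bound the training fit, not the
  extrapolation error, and single-member 10 s extrapolations spread over
  an order of magnitude in pooled RMSE across seeds.
* The GP engine is a compact reference implementation: adequate for the
  planted-function and distillation tasks shipped here, not a replacement
  for a production SR system on large datasets.
* No respiratory coupling, baroreflex, time-varying parameters or spatial
  modelling; the generator emulates a single steady heart rhythm.
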