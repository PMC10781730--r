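---
title: "Identifying template signatures of center-of-mass dynamics in walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying template signatures of center-of-mass dynamics in walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Walking can be summarized by how the whole-body center of mass (CoM)
accelerates in response to leg loading.  *Template* models compress this
relationship into a handful of idealized mechanical elements acting between
the CoM and the feet.  The candidate mechanisms in this package form an
augmented bipedal spring-loaded inverted pendulum (SLIP): for each leg
$j \in \{R, L\}$ in ground contact,

$$
M(\ddot{\mathbf q} - \mathbf g) \;=\; \sum_j \Big(
  -\big[k_L (L - L_0) + c_L \dot L\big]\,\frac{\mathbf q}{L}
  \;-\; \big[k_s \theta + c_s \dot\theta\big]\,\frac{\mathbf q}{L_s^2}
  \;-\; \big[k_f \phi + c_f \dot\phi\big]\,\frac{\mathbf q}{L_f^2}
\Big)_j ,
$$

where $\mathbf q$ is the CoM position relative to the foot, $L$ the leg
length, $\theta$ and $\phi$ the sagittal- and frontal-plane leg angles from
vertical (planar projections, mirrored between legs), and $L_s$, $L_f$ the
in-plane projection lengths.  The radial spring–damper ($k_L$, $L_0$, $c_L$)
is the classical SLIP leg; the rotary spring–dampers ($k_s$, $c_s$, $k_f$,
$c_f$) allow forcing associated with leg rotation.  The rotary terms are
implemented, both in the simulator and in the regression library, exactly as
written above — scaled by the inverse squared planar projection and directed
along the leg vector.  A rotary element that physically torques the leg
would force *transverse* to it; both the simulator and `build_library()`
accept `rotary_mode = "transverse"` for that variant, and the default
`"as_printed"` keeps the two sides of the package mutually consistent.

A *template signature* is the subset of these mechanisms — and their
coefficients — that best describes an individual's CoM dynamics in a given
gait phase.  Gait phases are the hybrid regimes defined by foot contact:
first double support (`DS1`, after a right heel strike), right single
support (`SS_R`), second double support (`DS2`), left single support
(`SS_L`).

Coefficients are reported dimensionless: $\kappa_L = k_L L_{bio}/(Mg)$,
$\tilde L_0 = L_0/L_{bio}$, $\zeta_L = c_L / (2\sqrt{k_L M})$,
$\kappa_{s,f} = k_{s,f}/(M g L_{bio})$ and
$\zeta_{s,f} = c_{s,f}/\sqrt{\kappa_{s,f} M L_{bio}^2}$.  The rotary damping
ratios deliberately mix the normalized stiffness with raw constants; the
convention is kept for comparability with the quantities practitioners
report.  Internally the regression estimates damping on a linear
dimensionless scale and converts to ratios afterwards, because the ratios
are nonlinear in the estimated stiffnesses.

## The identification pipeline

`identify_signatures()` runs five stages, following the hybrid sparse
system-identification recipe for regime-dependent dynamics:

1. **States and phase** (`compute_states()`): per-leg lengths, angles,
   velocities, CoM accelerations, a continuous stride phase $\psi \in
   [0, 100)$ from the reference leg's normalized $(\theta, \dot\theta)$
   phase portrait (anchored at heel strike), and per-sample gait-phase
   labels.
2. **Clustering** (`cluster_by_phase()`): for each of the first
   `n_centroids` training samples, its `k_neighbors` nearest neighbors
   under the circular $\psi$ distance.  Clusters of kinematically similar
   samples make the per-cluster regressions robust to noise and reveal
   which sparse structures recur.
3. **Sparsity sweep** (`sweep_sparsity()`): per cluster, sequential
   thresholded least squares (`stlsq()`) at 40 log-spaced thresholds
   between 1% and 100% of the largest coefficient of the cluster's full
   fit; supports are deduplicated.
4. **Selection** (AICc): structures seen in at least 1% of clusters are
   refit per gait phase and scored on held-out data with
   $AIC = 2k + \rho\,\ln(RSS/\rho)$ plus the finite-sample correction;
   structures with $\Delta AICc \le 3$ are *plausible* and combined into a
   single signature by Akaike-weight averaging (absent terms count as
   zero).
5. **Uncertainty** (`bootstrap_signature()`): 200 resampled refits of the
   final structure per gait phase; the reported coefficient is the
   bootstrap mean and its reliability the coefficient of variation.

All tunables live in `signature_config()`.  The defaults mirror a full-size
treadmill recording (14,400 samples at 120 Hz: 3600 held-out samples, 3600
clusters of 800 neighbors — one cluster spans 7.4% of the training pool).
The examples below use a reduced configuration (600 clusters, scaled
neighbor counts) sized for a 40-stride synthetic trial; all problem sizes
in this vignette were chosen as sensible desk-scale defaults for the
synthetic study.

```{r, eval = FALSE}
library(templatesig)
trial <- canonical_trial(n_strides = 40)
cfg <- signature_config(n_test = 1200, n_centroids = 600, k_neighbors = 240,
                        resample_size = NULL, n_boot = 50)
res <- identify_signatures(trial, cfg, seed = 1)
res
subset(res$signature_table, leg == "R" & gait_phase == "SS_R")
```

## The synthetic walker

`simulate_slip()` forward-integrates the same augmented SLIP as a hybrid
system (adaptive integration with event detection; touchdown when the swing
leg, held at fixed touchdown angles with length $L_0$, reaches ground
height; liftoff when a trailing stance spring returns to rest length).  The
canonical fixture (`default_gait_params()`) is a conservative pure SLIP —
no dampers, no rotary elements — with the human-scale values
$\kappa_L = 16.7$, $\tilde L_0 = 0.97$, $M = 70$ kg, $L_{bio} = 1$ m,
walking at about 1.1 m/s with a 0.86 s stride and roughly 21% of the stride
in each double-support phase.

Two design choices deserve explanation:

* **Foot-placement feedback.** The passive 3D bipedal SLIP with strictly
  fixed touchdown angles is laterally unstable at this parameter point (the
  stride map's dominant eigenvalue is about 6.4 per stride, measured at a
  Newton-converged periodic orbit), so no recording of more than a dozen
  strides exists for it.  The canonical walker therefore adjusts its
  touchdown direction in proportion to the CoM-velocity error at placement
  (`k_sag`, `k_lat` in `slip_params()`), the standard discrete
  stabilization for SLIP walkers.  Placement feedback moves feet; it never
  alters the stance force law, so the mechanisms to be identified are
  untouched.
* **Swing-foot bookkeeping.** Legs are massless, so swing trajectories are
  reconstructed after integration: a smooth blend between liftoff and
  landing points with a clearance bump that leaves the ground briskly, as a
  lifted heel does.  These trajectories matter only for the swing-leg
  library columns and the kinematic contact fallback
  (`detect_contacts()`), which reproduces the simulator's contact flags
  exactly on the canonical gait.

What the generator emulates: treadmill-like stationarity, the
single/double-support hybrid structure, SLIP-like force generation, and
additive i.i.d. Gaussian marker noise (`add_noise()`, default 1 mm).  What
it does not emulate: stride-to-stride motor variability, soft-tissue and
low-frequency marker artifacts, torso dynamics, and measured swing-leg
inertia.  Passing tests on this generator therefore demonstrate the
machinery under idealized conditions, not performance on human data.

## Numerical choices

**Differentiation.**  Hybrid gait is only piecewise smooth: leg forces
switch at contact events, so accelerations have corners there.  A global
smoothing filter (the conventional Savitzky–Golay window; available as
`smoothing_config(method = "sgolay")`) always straddles a corner at
walking cadence and biases stiffness estimates by tens of percent.  The
default is therefore a degree-6 polynomial basis fitted independently on
every contact segment and differentiated analytically.  The fit is
*cross-fitted* on interleaved sample halves — states from one half,
accelerations from the other — so that measurement noise entering the
regressors is independent of the noise entering the target; without this,
the shared-noise covariance inflates stiffness estimates severely at
motion-capture noise levels.

**The integral-form library.**  With `library_form = "projected"` (the
default), each mechanism column is evaluated from the state splines on a
refined grid, double-integrated in time, fitted with the same per-segment
basis as the positions, and differentiated twice.  Columns and target then
pass through one and the same linear observation operator, so the basis
reconstruction error cancels from the regression residual instead of
masquerading as unexplained dynamics.  Double integration of a per-phase
force balance is only valid within a contact segment; this is precisely why
the basis is segment-local.

**Ridge-stabilized sweeps.**  Every library column is the leg vector times
a scalar state function, so cluster systems are strongly collinear and
unregularized fits produce enormous mutually cancelling coefficients that
corrupt the relative threshold grid.  The sweep therefore solves its
normal equations with a small relative ridge (`ridge = 0.01`); final
coefficients are never ridge-biased because the selected structures are
refit by plain least squares.

**Edge trimming.**  Derivative estimates are least reliable at segment
boundaries; `edge_trim` (default 2 samples) excludes them from the
regression, the clustering pool and all evaluations.

**Tie-breaking and boundaries.**  Nearest-neighbor ties break by sample
index; a candidate structure seen in exactly 1% of clusters is retained;
the empty structure is never pooled; rank-deficient least-squares systems
fall back to the smallest-norm solution with a warning.

## Known limitations

Two properties of noise-free, perfectly periodic synthetic data interact
badly with likelihood-based selection, and users should know about them:

* The residual left after fitting the *true* structure is the deterministic
  numerical-differentiation floor.  Because the gait is periodic, that
  floor generalizes from training to held-out samples, and because
  $\rho\,\ln RSS$ differences are scale-free, structures containing the
  truth plus small extra terms always gain more than their AICc penalty.
  On noise-free synthetic data the selected single-support signature
  therefore contains the true leg-spring terms (always, and with dominant
  coefficients) plus small swing-leg and rotary-damping terms.  Human
  single-support signatures show the same behavior — swing-leg SLIP terms
  are routinely selected — so this is a property of the method, not a bug
  of the implementation.
* Separating $\kappa_L$ from the $\kappa_L \tilde L_0$ product rests on the
  modulation of leg length during stance, which is only ~1% of leg length
  at human-scale stiffness.  With white 1 mm position noise at 120 Hz the
  per-trial information floor for $\kappa_L$ is a few percent even with the
  structure known, and structure uncertainty widens this substantially.
  $\tilde L_0$, a ratio of the two collinear coefficients, is far more
  robust (typically within 1%).  Double-support coefficients are less
  reliable still, consistent with their short data segments.

The `score` option selects how candidate structures are evaluated on
held-out data: `"refit"` (default) scores per-phase refits and is the
statistically sound choice when residuals are noise-dominated; `"cluster"`
scores the models fitted in a structure's source clusters (aggregated by
the median), which mirrors the clustering-based evaluation step directly
but inherits the clusters' narrow-arc collinearity.

## Comparison utilities

`constrained_refit()` holds a signature structure fixed and re-estimates
its coefficients on another condition's data, with AICc computed on that
condition's held-out samples — the cross-condition question "does the
baseline structure remain plausible?".  `structure_plausibility_test()`
formalizes it as a one-sample right-tailed t-test of whether mean
$\Delta AICc$ exceeds 3.  `compare_conditions()` runs paired t-tests per
(coefficient, gait phase) with Holm–Šidák step-down correction over a
declared comparison family, and `percent_difference()` handles
two-condition case-study contrasts.  A family of 56 comparisons reproduces
the conventional rank-1 and rank-2 critical levels of
$9.2\times10^{-4}$ and $9.3\times10^{-4}$.
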