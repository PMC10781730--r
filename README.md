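# templatesig

Data-driven identification of **template signatures** — individual-specific,
per-gait-phase sets of physically interpretable mechanisms that describe
whole-body center-of-mass (CoM) dynamics during walking — from CoM and foot
trajectories.

Who this is for: biomechanists and movement scientists who want a
reduced-order, mechanistic description of how a person accelerates their CoM
(for example to quantify how assistive devices or neurological impairment
change gait dynamics), and methods researchers working on sparse
identification of hybrid dynamical systems.

## The model and the method

Candidate mechanisms form an augmented bipedal spring-loaded inverted
pendulum (SLIP): for each leg `j` in ground contact,

    M(q̈ − g) = Σⱼ ( −[k_L (L − L₀) + c_L L̇] q/L
                     −[k_s θ + c_s θ̇] q/L_s²
                     −[k_f φ + c_f φ̇] q/L_f² )ⱼ

with leg length `L`, sagittal/frontal leg angles `θ, φ` from vertical and
planar projections `L_s, L_f`.  Rewriting per-mechanism with normalized
coefficients gives a 14-column regression library (7 per leg) whose fitted
coefficients are directly the dimensionless signature quantities
`κ_L, κ_L·L̃₀, ζ_L, κ_s, ζ_s, κ_f, ζ_f`.

Identification proceeds by hybrid sparse regression: cluster kinematically
similar samples by a continuous stride phase `ψ`; run sequential thresholded
least squares (STLSQ) over a 40-point sparsity sweep in every cluster;
keep structures found in ≥ 1% of clusters; score them on held-out data with
the small-sample-corrected Akaike Information Criterion (AICc); average all
plausible structures (ΔAICc ≤ 3) with Akaike weights; and quantify
coefficient uncertainty with a 200-draw bootstrap.

A forward simulator of the same augmented SLIP (hybrid event-driven
integration, touchdown/liftoff detection, optional measurement noise)
provides ground-truth synthetic gait for validation.

## Worked example

```r
library(templatesig)

trial <- canonical_trial(n_strides = 40)   # frozen ground-truth SLIP gait
trial
#> Walking trial (synthetic): 4144 samples at 120.0 Hz (34.5 s), 40 strides
#>   M = 70 kg, L_bio = 1 m

cfg <- signature_config(n_test = 1200, n_centroids = 600, k_neighbors = 240,
                        resample_size = NULL, n_boot = 50)
res <- identify_signatures(trial, cfg, seed = 1)
subset(res$signature_table, leg == "R" & gait_phase == "SS_R",
       select = c(coefficient, value, boot_mean, cv))
#>  coefficient     value boot_mean        cv
#>      kappa_L 15.382090 15.384046 5.697e-04
#>     L0_tilde  0.966202  0.966208 2.876e-05
#>       zeta_L -0.001304 -0.001342 2.581e-01
#>      kappa_s -0.070701 -0.072759 2.549e-01
#>       zeta_s        NA        NA        NA
#>      kappa_f 10.452647 10.437759 7.573e-03
#>       zeta_f  4.231684  4.358601 2.550e-01
```

Reading the output: the ground truth of this synthetic walker is a pure leg
spring with `κ_L = 16.7` and `L̃₀ = 0.97`.  The right-leg single-support
signature recovers the resting length to 0.4% and the stiffness to 8%, with
tiny bootstrap CVs for both; the residual terms (`κ_s`, `κ_f`, `ζ_f`) are
selection artifacts of noise-free periodic data — the held-out reconstruction
is exact to `r² = 1.000000`, so the information criterion cannot distinguish
the true structure from supersets (see the vignette's "Known limitations").
`zeta_s` is `NA` because a damping ratio is undefined for a mechanism whose
stiffness was not selected.

The simulator itself:

```r
p <- default_gait_params()        # kappa_L = 16.7, L0_tilde = 0.97
tr <- simulate_slip(p, default_gait_state(), n_strides = 120)
range(slip_energy(tr))            # conservative gait: drift ~1e-7 relative
noisy <- add_noise(tr, sd_pos = 0.001, seed = 1)  # 1 mm marker noise
```

A thin command-line wrapper for the common steps lives in
`inst/cli/templatesig.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/templatesig.R", package="templatesig"))')" \
    simulate --out trial.csv --strides 40
```

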