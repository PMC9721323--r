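# saskit

Tools for analysing one-dimensional small-angle scattering (SAS) curves in R.
The package bundles four method families that practitioners usually have to
assemble from separate codes:

1. **Form-factor models and projected correlations** — the homogeneous
   sphere and the Debye–Anderson–Brumberger (DAB) random two-phase model,
   together with their real-space projected correlation functions `G(r)`
   (the quantity measured by SESANS), in closed form.
2. **Flexible size distributions** — lognormal, bimodal lognormal, and the
   *metalog* quantile-parameterized family. The metalog quantile function is
   a linear combination of logit-polynomial terms,
   `M_k(y) = a1 + a2 L + a3 (y-1/2)L + a4 (y-1/2) + ...` with
   `L = ln[y/(1-y)]`, fitted *linearly* to CDF data and supporting
   unbounded, left-bounded and doubly bounded variants (2–10 terms). Form
   factors are integrated over a metalog in quantile space,
   `I(q) = \int_0^1 P(q, M_k(y)) dy`, which is numerically robust for both
   very sharp and very broad distributions.
3. **Model-free size-distribution retrieval** — the ill-posed Fredholm
   problem `I(q_i) = \int P(q_i, R) x(R) dR` solved by Tikhonov
   regularization (identity/first/second-derivative cost operators) and by
   four expectation-maximization (Richardson–Lucy) schemes: plain, smoothed
   (log-space binomial smoothing composed with each update), and entropy
   regularization with a fixed or adaptive prior. The regularization weight
   is selected at the corner of the L-curve (maximum curvature of the
   log-misfit vs log-cost polyline).
4. **Numerical structure factors** — an Ornstein–Zernike solver
   (`h = c + ρ c*h`) for spherically symmetric pair potentials (hard
   sphere, piecewise-constant shells, two-Yukawa, Lennard-Jones) under the
   Percus–Yevick, hypernetted-chain, MSA and modified-MSA closures, via
   Picard iteration with FFT-based radial Fourier transforms; validated
   against the analytic Wertheim hard-sphere solution. Decoupling and
   local-monodisperse approximations combine `S(q)` with polydisperse form
   factors. A **multiple-scattering** module computes the measured cross
   section at optical depth `τ = Σ_t t` from the real-space kernel
   `e^{-τ}(e^{τ G(r)} - 1)` through numerical Hankel transforms.

Units: `q` in nm⁻¹, lengths in nm, cross sections in cm⁻¹, sample thickness
in cm, wavelength in nm. No implicit conversions are performed.

## Worked example

```r
library(saskit)

# 1. simulate the bimodal benchmark (modes 20 and 80 nm, 1% noise)
curve <- simulate_curve(synthetic_spec(), seed = 42)

# 2. retrieve the volume-weighted size distribution with smoothed EM
R <- default_size_grid(curve$q, 100)
kern <- build_kernel(curve$q, R, weighting = "volume")
fit <- em_iterate(kern, curve, scheme = "smoothed", max_iter = 3000, tol = 1e-9)

# 3. hard-sphere structure factor: numerical OZ vs analytic
sol <- oz_solve(potential_hard_sphere(1), "PY", eta = 0.3,
                grid = oz_grid(2^13, 1/250))

# 4. multiple scattering for the DAB model at optical depth tau = 1
msp <- multiscatter_params(sigma_t = 10, t = 0.1, lam = 0.6)
Im <- multiple_scattering_intensity("dab", list(xi = 10), msp, c(0.02, 0.1, 0.5))
```

This prints:

```
<sas_curve> 100 points, q in [0.02, 2] nm^-1
<inversion_result> scheme = em_smoothed, lambda = 1, chi2 = 10050.4, iterations = 630
recovered modes (nm): 85.8, 21.25
OZ vs Wertheim sup-norm: 4.78e-05 (S(0) = 0.0938)
     q    single  multiple
1 0.02 32273.100 14417.173
2 0.10  8726.646  4816.298
3 0.50    51.637    57.805
```

The two retrieved modes sit within one size bin of the true volume-weighted
modes (21.3 and 81.9 nm on this grid). The numerical structure factor agrees
with the closed-form Percus–Yevick solution to a few parts in 10⁵, and
`S(0) = (1-η)⁴/(1+2η)² ≈ 0.0938` at η = 0.3. At τ = 1 multiple scattering
drains intensity from the forward direction (the beam is redistributed) and
fills in the high-q region — the characteristic flattening of optically
thick SAS measurements.

A thin command-line wrapper is provided at `inst/cli/saskit` with
subcommands `simulate`, `fit-sizedist`, `oz` and `msas`; run it with no
arguments for usage.

## Package layout

- `R/models.R` — sphere/DAB intensities and projected correlations
- `R/distributions.R` — metalog machinery, lognormals, quantile-space integration
- `R/inversion.R` — kernel, Tikhonov, EM schemes, L-curve
- `R/hankel.R`, `R/multiscatter.R` — Hankel transforms, multiple scattering
- `R/oz.R` — potentials, closures, OZ solver, Wertheim reference, polydispersity
- `R/io.R`, `R/cli.R` — ASCII curve I/O, synthetic benchmark, CLI dispatch
- `vignettes/saskit-methods.Rmd` — models, assumptions and numerical choices
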