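---
title: "Models, assumptions and numerical choices in saskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and numerical choices in saskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saskit)
```

This vignette documents the models implemented in saskit, the assumptions
behind them, and the numerical decisions that shape the results — the
material a user needs to judge whether the package is applicable to their
data, and a maintainer needs to understand why the code looks the way it
does.

## Scattering models and units

All functions use `q` in nm⁻¹, lengths in nm, cross sections per unit
volume in cm⁻¹, sample thickness in cm and wavelength in nm. With these
conventions `λ² I q dq` is a cross section per volume, so no hidden unit
conversions are required anywhere.

Two analytic form factors are provided. The homogeneous sphere has
amplitude

$$F(q) = \Delta\rho \tfrac{4\pi}{3}R^3\,
  \frac{3[\sin(qR) - qR\cos(qR)]}{(qR)^3},$$

with the Taylor expansion $1 - (qR)^2/10 + (qR)^4/280$ used below
$qR = 10^{-2}$, where the trigonometric form loses up to half its digits to
cancellation. The DAB model $I_0/(1+q^2\xi^2)^2$ describes a random
two-phase medium with a single correlation length $\xi$.

Both models have closed-form *projected correlation functions* $G(z)$ — the
autocorrelation of the scattering-length-density fluctuations projected
along the beam, normalized so $G(0)=1$. For the sphere, $G$ follows from
the ball overlap function
$\gamma(u) = 1 - \tfrac{3u}{4R} + \tfrac{u^3}{16R^3}$ (support $[0, 2R]$)
via $G(z) \propto \int_0^\infty \gamma(\sqrt{z^2+s^2})\,ds$; the package
evaluates the projection in closed form (the normalization constant is
$3R/4$, and $G$ vanishes identically beyond $2R$). For the DAB model,
projecting $\gamma(u) = e^{-u/\xi}$ gives $G(z) = (z/\xi)K_1(z/\xi)$. The
projection integral is the normative definition; the unit tests check the
closed forms against adaptive quadrature of that integral to $10^{-8}$.

## The metalog size distribution

The metalog is defined through its quantile function (inverse CDF) rather
than its density: $x = Q(y) = M_k(y)$ is a linear combination of the basis

$$1,\; L,\; (y-\tfrac12)L,\; (y-\tfrac12),\; (y-\tfrac12)^2,\;
  (y-\tfrac12)^2L,\; \dots,\; (y-\tfrac12)^4 L,
  \qquad L = \ln\frac{y}{1-y},$$

truncated at $k \in [2, 10]$ terms. Because the basis is linear in the
coefficients, fitting CDF data `(x, y)` is ordinary least squares — no
nonlinear optimization, no starting values. The left-bounded variant
applies $x = b_l + e^{M_k(y)}$ and the doubly bounded one
$x = (b_l + b_u e^{M_k})/(1 + e^{M_k})$; with $k=2$ and $b_l=0$ the family
reduces exactly to the log-logistic distribution, which the tests use as an
independent oracle.

The density is the reciprocal quantile density, $p(x) = 1/(dM_k/dy)$ with
the chain-rule factor for bounded transforms. A coefficient vector is
*feasible* when $dM_k/dy > 0$ throughout $(0,1)$; saskit checks this on a
fixed grid of 10 001 interior points — cheap, deterministic, and adequate
for $k \le 10$ whose quantile densities are smooth low-order
logit-polynomials. Infeasible vectors are rejected at construction; fitted
vectors that come out infeasible carry a warning flag, and the constrained
refitting strategy is deliberately left to the caller.

### Quantile-space integration

Averaging a form factor over a size distribution,
$I(q) = \int P(q,x)\,p(x)\,dx$, becomes
$I(q) = \int_0^1 P(q, M_k(y))\,dy$ after the change of variables — finite
limits, no density factor, and equally well-behaved for near-delta and for
heavy-tailed distributions. Numerically the integral is taken on
$[\epsilon, 1-\epsilon]$ with $\epsilon = 10^{-8}$, in the logit variable
$t = \ln[y/(1-y)]$ on 36 uniform composite Gauss–Legendre panels. The logit
substitution matters: metalog tails are power laws in $1-y$, and a
high-order sphere moment (the forward intensity carries $x^6$) concentrates
a boundary layer near $y = 1$ that uniform-$y$ quadrature of any fixed
order fails to resolve; in $t$ the layer becomes a smooth exponential. With
this choice the quantile-space and $x$-space routes agree to $10^{-11}$
relative for a 10-term metalog fitted to a shape-0.4 lognormal, and the
lognormal quadrature path agrees with a brute-force 10 000-node trapezoid
oracle to $10^{-7}$.

For lognormal-type distributions the package integrates in $x$ over the
$[10^{-11}, 1-10^{-11}]$ quantile range with composite Gauss–Legendre
panels; the wide support is needed precisely because of the $x^6$ weight.

## Size-distribution retrieval

The forward map is discretized as $A_{ij} = P(q_i, R_j)\,w_j\,\Delta R_j$
on (by default) 100 log-spaced bins spanning $\pi/q_\max$ to $\pi/q_\min$ —
the size window to which the measured $q$ range is actually sensitive.
With `weighting = "number"` the solution is a number density ($w = 1$);
with `weighting = "volume"` the solution is the volume-weighted
distribution $D_V = n(R)V(R)$ and the kernel columns carry $1/V(R_j)$. The
volume convention is used for the benchmark because equal-volume bimodal
populations give comparably tall peaks, which is how such results are
usually plotted and judged.

**Tikhonov.** Minimizes $\|\Sigma^{-1}(Ax-y)\|^2 + \lambda\|Lx\|^2$ with
$L$ the identity or a first/second difference operator, by the (ridge)
normal equations; a singular system at $\lambda = 0$ falls back to the
SVD pseudoinverse and is flagged. No positivity constraint is imposed —
negative ringing is visible to the user rather than silently clipped.

**Expectation-maximization.** The plain scheme is the Richardson–Lucy
multiplicative update
$x_j \leftarrow x_j \,[\sum_i A_{ij} y_i/(Ax)_i]/[\sum_i A_{ij}]$, which
keeps iterates positive and increases the Poisson-type likelihood
$\sum_i [y_i \ln(Ax)_i - (Ax)_i]$ at every step. Measurement uncertainties
enter by jointly rescaling the rows of $A$ and $y$ by $1/\sigma_i$, which
preserves the non-negative measure structure the iteration requires.
Because the problem is ill-posed, the plain iteration eventually amplifies
noise; three stabilized variants are provided:

* *smoothed*: each update is composed with linear smoothing of $\ln x$
  by a symmetric binomial kernel (default width 5, reflective boundary),
  blended with weight $w \in (0,1]$ — $w = 1$ is the full
  smoothing-composed iteration, smaller $w$ interpolates toward plain.
* *entropy, fixed prior*: after the RL step the multiplicative correction
  $(\tilde p_j/\tilde x_j)^w$ pulls the (sum-normalized) iterate toward a
  fixed prior, uniform by default.
* *entropy, adaptive prior*: the same correction with the prior replaced
  by the binomially smoothed running iterate.

The entropy corrections are this package's concrete form of
entropy-regularized RL: a damped geometric step toward the prior,
equivalent to one fixed-point sweep on the entropy-penalized objective.
Stopping is by relative L2 change below `tol` (default $10^{-7}$) or
`max_iter` (default $10^5$). Negative data points (possible at high noise)
are floored at a small epsilon and flagged.

**L-curve.** For a ladder of weights (default 15, log-spaced) the corner
of the (log misfit, log cost) polyline is the point of maximal Menger
curvature; ties resolve to the smaller weight, and an (effectively)
collinear curve returns the median weight with a warning — there is no
corner to find. The cost is $\|D_2 x\|^2$ for the linear schemes and the
Kullback–Leibler divergence from the prior for the entropy schemes. The
same machinery accepts a ladder traced over iterations instead of weights,
since it only consumes (weight, misfit, cost) triples.

### The synthetic benchmark

`synthetic_spec()` defines the study conditions used throughout the tests:
spheres from an equal-volume bimodal lognormal population with medians 20
and 80 nm and shape 0.15, observed at 100 log-spaced points in
$q \in [0.02, 2]$ nm⁻¹ with 1% relative Gaussian noise and no background.
The equal-volume constraint fixes the number weight of the small mode at
$m_2^3/(m_1^3+m_2^3) \approx 0.985$. The generator is seeded and
byte-reproducible. It emulates the standard bimodal retrieval benchmark;
it does *not* emulate instrument resolution smearing, incoherent
backgrounds, or counting (Poisson) noise, so passing tests demonstrate the
correctness of the inversion machinery, not robustness to every artifact
of real instruments. On this benchmark all four EM schemes and
L-curve-selected Tikhonov (d2) locate both volume-distribution modes
within one size bin (4.8% on the default grid).

## Multiple scattering

For samples of non-negligible optical depth $\tau = \Sigma_t t$ the
measured cross section contains multiply scattered neutrons/photons. For a
model with known projected correlation $G(r)$ the measured curve is

$$\left(\frac{d\Sigma}{d\Omega}\right)_m(q) =
  \frac{2\pi}{\lambda^2 t}\int_0^\infty
  e^{-\tau}\left(e^{\tau G(r)} - 1\right) J_0(qr)\, r\, dr,$$

whose series expansion
$\sum_{n\ge1} e^{-\tau}\tau^n/n!\,\mathcal H[G^n]$ is the sum over
$n$-fold scattering events ($n$-fold angular self-convolutions become
products under the Hankel transform). The $r = 0$ value of the kernel,
$1 - e^{-\tau}$, is the total multiply-scattered fraction. As
$\tau \to 0$ the expression reduces to a single-scattering curve whose
total cross section is exactly $\Sigma_t$ — this normalization contract,
together with the truncated series as an independent oracle (25 terms,
accurate to machine precision for $\tau \le 3$), pins down all prefactors.
Only models with analytic $G(r)$ are supported (monodisperse and
lognormal-polydisperse spheres, DAB); a fully numerical model would require
three nested transforms per evaluation, which is out of scope. For the
lognormal sphere population, each radius contributes its $G_R$ with weight
$\propto R^4 p(R)$ (volume times forward projection), evaluated on 101
quantile nodes. Optical depths above 50 raise an overflow error.

The Hankel transforms use the symmetric self-reciprocal convention
$g(r) = \int f(q)J_0(qr)\,q\,dq$ with all $2\pi$, $\lambda^2$ and $t$
factors kept explicitly in the physics functions. Numerically the
oscillatory integral is split at half-periods $\pi/x$ of $J_0$, each
segment integrated adaptively, with iterated averaging (Euler-type
acceleration) of the alternating partial sums for slowly decaying tails;
the Gaussian self-transform is reproduced to $5\times10^{-17}$ RMS.
Sampled curves are continued beyond their grid by a power law fitted to
the top quarter of the grid, and the transform refuses inputs whose tail
decays like $q^{-2}$ or slower (the integral diverges). Sampled
real-space functions are interpolated with a natural cubic spline, which
keeps the DAB forward–inverse round trip below $10^{-7}$ RMS. The total
cross section $\Sigma_t = (\lambda^2/2\pi)\int I(q)\,q\,dq$ uses the same
tail model. $\Sigma_t$ is treated as a cross section per volume in cm⁻¹
throughout.

A caveat for sharp monodisperse models: at the zeros of the sphere form
factor the single-scattering intensity vanishes while the two-scattering
term does not, so *relative* deviations between the multiple- and
single-scattering curves are unbounded near those zeros at any $\tau$.
Weak-limit checks therefore use the zero-free DAB model, or restrict the
sphere comparison to $qR \le 4$.

## The Ornstein–Zernike solver

The OZ equation $h = c + \rho\,c * h$ closes with one of four relations
(outside any hard core): Percus–Yevick $c = (e^{-u}-1)(1+\gamma)$, HNC
$c = e^{-u+\gamma}-1-\gamma$, MSA $c = -u$, and modified MSA
$c = e^{-u}-1$, where $\gamma = h - c$. Inside a hard core every closure
enforces the exact condition $g = 0$ via $c = -1-\gamma$; infinite
potential values never enter an exponential. MSA is implemented only for
potentials with a hard core: for a soft $r^{-12}$ core its $c = -u$ tail
is not integrable at the origin, so no grid or parameter choice gives a
meaningful transform — the package raises a typed error for MSA with
Lennard–Jones instead of returning an arbitrary regularization.

The solver Picard-iterates $\gamma$: closure → FFT-based radial Fourier
transform ($\hat f(k) = (4\pi/k)\int rf\sin(kr)dr$ as a discrete sine
transform; inverse normalization $1/(2\pi^2)$) → OZ relation
$\hat\gamma = \rho\hat c^2/(1-\rho\hat c)$ → inverse transform → mixing
$\gamma \leftarrow (1-\alpha)\gamma + \alpha\gamma_{OZ}$ with
$\alpha = 0.2$ by default. Convergence is declared when the pre-mixing
residual $\max|\gamma_{OZ}-\gamma|$ falls below $10^{-8}$; hitting the
iteration cap or $1-\rho\hat c \le 0$ (spinodal/instability region) raises
an error rather than returning an unphysical $S(q)$. Density and volume
fraction are related by $\rho = 6\eta/(\pi\sigma^3)$; for Lennard–Jones,
$\sigma$ is the length parameter and $\eta$ is interpreted through the
same formula.

The default grid is $n = 2^{14} = 16\,384$ points at
$\Delta r = \sigma/500$ (so $\Delta k = \pi/(n \Delta r)$), which resolves
the core discontinuity and reaches $r \approx 33\sigma$. One detail is
worth a paragraph: $c(r)$ jumps at the core edge, and a plain sine-series
sum over grid points treats the edge point one-sidedly, costing
$O(\Delta r)$ accuracy — about $10^{-2}$ in $S(q)$ at $\eta = 0.4$. The
solver therefore assigns the grid point sitting on $r = \sigma$ the mean
of the two one-sided closure limits (the trapezoidal treatment of a jump),
which restores $O(\Delta r^2)$ behavior; the measured sup-norm deviation
from the analytic Wertheim PY solution is then $\le 4\times10^{-5}$ for
$\eta \le 0.4$ over $q\sigma \in [0.2, 40]$. The same half-weight
convention applies to discontinuous test inputs of `radial_fourier`. The
discrete transform's relative error grows as $(\Delta r\,k)^2/12$, so
closed-form checks are asserted on the $k$-range where that model allows
the target accuracy.

Validation conditions chosen by this package (and used by the acceptance
script): the low-density virial identity
$(S(q)-1)/\rho \to \hat f_{\mathrm{Mayer}}$ is checked at $\eta = 10^{-3}$
with deliberately weak tails — piecewise shells at $-0.05/+0.025\,kT$,
two-Yukawa $K_1 = 0.1, Z_1 = 10, K_2 = -0.05, Z_2 = 0.5$, Lennard–Jones
$\epsilon = 0.1\,kT$ — because at this density the inherent second-virial
correction already consumes about half of the 2% tolerance, and MSA's
$O(u^2)$ linearization must fit in the remainder. The qualitative
cluster-peak check (short-range attraction $K_1 = 6, Z_1 = 10$ plus weak
long-range repulsion $K_2 = -0.3, Z_2 = 0.5$ at $\eta = 0.15$) asserts a
local $S(q)$ maximum below the hard-sphere primary peak; the parameters
are package-chosen since only the phenomenon, not its parameters, is
specified in the literature being followed.

Polydispersity enters through the decoupling approximation
$I = n[\langle F^2\rangle + \langle F\rangle^2(S-1)]$ or the local
monodisperse approximation
$I = n\int p(R)F^2(q,R)\,S(q;\sigma(R))\,dR$ with the radius-to-diameter
mapping $\sigma(R) = 2R$ by default (a configurable factor, since
different codes use different conventions).

## Problem sizes and runtimes

The validation suite uses the full $2^{14} \times \sigma/500$ grid for the
hard-sphere comparisons, a $2^{12} \times \sigma/100$ grid for the
16-combination low-density sweep, 100-bin inversions of the 100-point
benchmark curve (3 000 EM iterations per scheme), and 25-term
multiple-scattering series oracles on 30-point $q$ grids; the whole
acceptance script completes in well under a minute on one CPU. These sizes
were chosen as the smallest at which each check is limited by the method
under test rather than by its oracle.

## Known limitations

* Only isotropic (radially symmetric) scattering; no 2D patterns or
  azimuthal fitting.
* Multiple scattering only for models with analytic projected
  correlations; no generalized Gaussian coil.
* The OZ solver is monodisperse; polydispersity only via the two
  approximations above. Thermodynamic self-consistency schemes and the
  larger closure menagerie (Rogers–Young, Verlet, ...) are not included.
* The metalog fit is unconstrained least squares; feasibility is checked
  but not enforced during fitting.
* Instrument resolution smearing is not modeled anywhere.
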