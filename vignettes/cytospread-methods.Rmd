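---
title: "Models and methods: cortex-driven flows and nuclear spreading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cortex-driven flows and nuclear spreading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
```

```{r setup, message = FALSE}
library(cytospread)
```

# The physical problem

Early syncytial *Drosophila* embryos contain many nuclei in one shared
cytoplasm. During cell cycles 4–6 the actomyosin cortex under the
plasma membrane contracts, dragging cytoplasm along the cell wall and
driving bulk cytoplasmic flows that carry the nuclei along the long
(anterior–posterior, AP) axis. Whether the nuclei end up uniformly
spaced along that axis — a requirement for normal development — depends
on how much cumulative cortical motion the embryo produces.

`cytospread` implements the pieces needed to analyse this process
quantitatively:

1. an **exact Stokes-flow solution** inside a prolate spheroidal cell
   driven by an arbitrary axisymmetric tangential slip velocity on its
   boundary;
2. a **long-wavelength (lubrication) solution** valid for any elongated
   axisymmetric shape;
3. a **passive-tracer transport simulator** measuring the axial
   homogeneity of the nuclear distribution as a function of the
   accumulated cortical forcing;
4. an **analytically solvable one-dimensional reduced model** of the
   same transport.

All lengths are in μm, velocities in μm s⁻¹ and angles in radians
throughout.

# Exact flow in a prolate spheroid

The cell is a rigid prolate spheroid with semi-axes $b_x < b_z$
(defaults 110 and 270 μm, the measured embryo dimensions). The
cytoplasm is treated as a Newtonian fluid at zero Reynolds number; over
the time scales of interest this reproduces the large-scale features of
measured cytoplasmic flows, although it cannot capture, e.g., the exact
positions of vorticity extrema, for which two-phase models are needed.
The cortex enters only as a prescribed tangential slip velocity
$v_s(\zeta)$ on the boundary, with $\zeta = z/b_z$ the rescaled axial
position there.

In modified prolate spheroidal coordinates $(\tau, \zeta)$ with
semi-focal distance $c = \sqrt{b_z^2 - b_x^2}$, the boundary is
$\tau = \tau_0 = b_z/c$ and the axisymmetric flow derives from a Stokes
streamfunction expanded in Gegenbauer functions of the first kind:

$$\psi(\tau, \zeta) = \sum_{n \ge 2} g_n(\tau)\, G_n(\zeta),$$

where second-kind functions are excluded because they are singular on
the symmetry axis and the $n = 0, 1$ terms would make the velocity
diverge there. Regularity at the focal segment restricts each $g_n$ to
the combinations

$$g_2 = F_2 G_2 + E_4 G_4, \quad g_3 = F_3 G_3 + E_5 G_5, \quad
  g_{n\ge4} = F_n G_n + E_{n+2} G_{n+2} + E_n G_{n-2}.$$

The slip profile is expanded in associated Legendre functions,
$v_s(\zeta) = \tau_0 (\tau_0^2 - \zeta^2)^{-1/2} \sum_n B_n
P_n^1(\zeta)$, and the boundary conditions (zero normal flow; prescribed
tangential slip) become, per order,

$$g_n(\tau_0) = 0, \qquad g_n'(\tau_0) = c^2 \tau_0\, n(n-1)\, B_{n-1}.$$

Even and odd orders form independent ladders: each order is a 2×2
linear solve that reuses the $E$ coefficient fixed two orders below.
The implementation evaluates $G_n$ through the Legendre representation
$G_n = (P_{n-2} - P_n)/(2n-1)$, which extends analytically to the
$\tau > 1$ side, and all derivatives analytically via
$G_n' = -P_{n-1}$; no finite differences enter the solver.

Two normalization facts are worth recording because they pin the whole
chain and are verified by tests rather than trusted from notation: the
Gegenbauer orthogonality constant is
$\int_{-1}^1 G_n G_m (1-x^2)^{-1}\,dx = \tfrac{2}{n(n-1)(2n-1)}
\delta_{nm}$, and the associated Legendre convention is the
Condon–Shortley one, fixed by requiring
$\sqrt{1-x^2}\,P^1_l = -l(l+1)\,G_{l+1}$ to hold exactly. The ultimate
arbiter is the *slip-reconstruction test*: the tangential boundary
velocity of the assembled solution must reproduce $v_s$ itself, which
it does to the truncation floor of the expansion.

## Truncation

The series is truncated at `nmax = 14` by default. The slip shape
behaves like a square root at the poles when written in the $P^1_n$
basis, so the $B_n$ decay algebraically and the residual truncation
error concentrates in a thin shell at the boundary. On the package's
standard interior evaluation grid (95 % of each semi-axis, excluding
points where the flow is below 1 % of its maximum), moving from
`nmax = 14` to `nmax = 25` changes the velocity field by well under
0.1 % of the maximum flow speed:

```{r truncation}
g <- embryo_geometry(110, 270)
100 * truncation_study(slip_drosophila(), g, n_low = 14, n_high = 25)
```

## The Drosophila slip profile

The measured cortical flow of cell cycle 6 is modelled as a separable
profile $v_s(\zeta, t) = V(t)\,[-\sin(\pi\zeta + \arcsin\tfrac13) -
\tfrac13]$: a shifted sine that vanishes at the poles (no cortical
sources there) and crosses zero at
$\zeta^* = -2\arcsin(1/3)/\pi \approx -0.2163$, the stagnation point
towards which the cortex converges. The amplitude at the cycle-6
contraction peak is about $V = 0.3$ μm s⁻¹. The resulting interior flow
has the observed four-vortex structure (two meridional recirculation
cells mirrored across the axis):

```{r flowplot, eval = requireNamespace("ggplot2", quietly = TRUE)}
fl <- stokes_flow(slip_drosophila(), g)
autoplot(fl)
```

# Long-wavelength solution

For any elongated axisymmetric shape of radius profile $R(z)$ and axial
wall slip $U(z)$, the leading-order lubrication flow is locally
pressure-driven pipe flow with zero net flux through each cross-section:

$$u_z = U(z)\left[2\left(\frac{r}{R}\right)^2 - 1\right], \qquad
  u_r = \tfrac12 U'(z)\, r\left[1 - \left(\frac{r}{R}\right)^2\right] +
        U(z) R'(z) \left(\frac{r}{R}\right)^3 .$$

It satisfies the wall slip, exact no-penetration and zero flux *by
construction*. For the embryo geometry and Drosophila slip it deviates
from the exact solution by less than 5 % of the maximum of each
velocity component — remarkable for an aspect ratio of only
$b_x/b_z \approx 0.41$. The projection factor
$e_\zeta \cdot e_z$ in $U(z)$ is kept exact here; approximating it by 1
is deferred to the reduced model.

Numerical choices: when a closed-form slip or radius profile is
available its derivative is taken analytically (the spheroid default);
otherwise fourth-order central differences with step $10^{-4} b_z$ are
used. Evaluation is restricted to $|z| \le (1 - 10^{-6}) b_z$, and the
5 % comparison grid excludes a pole cap of 1 % of $b_z$, with the error
normalized by the global maximum of each component.

# Transport in rescaled time

Nuclei are modelled as passive tracers (nuclear Brownian motion is
negligible over cell cycles 4–6) advected by the instantaneous flow.
Because Stokes flow has no inertia, the trajectory depends on the
amplitude history $V(t)$ only through
$\chi(t) = \int_0^t V\,dt'$ — a rescaled time with units of length,
roughly the distance travelled by material points on the cortex. The
simulator therefore integrates $dx/d\chi = \hat u(x)$ with the
unit-amplitude flow $\hat u$, using classic RK4 with fixed step
$\Delta\chi = 0.5$ μm (halving the step changes trajectories at the
$10^{-6}$ μm level; requested snapshot values of $\chi$ are hit
exactly). Tracers pushed outside the spheroid by integration error are
projected just inside the wall; with the exact flow this essentially
never triggers.

## Initial condition

The initial nuclear cloud is centred on the axial stagnation point
$z_c = b_z\,\zeta^*$ and has radius 60 μm. The tracers are drawn
**uniformly from a disk** of that radius in a plane containing the AP
axis (each tracer then receives an independent azimuth, which changes
nothing axisymmetric). The axial projection of this cloud is the
semicircular density
$n_0(Z) \propto \sqrt{Z_0^2 - Z^2}$, $Z_0 = 60/b_z$ — precisely the
initial condition the one-dimensional reduced model uses, keeping the
two transport models consistent with one another. This disk geometry
is the study condition under which all the quantitative optima quoted
below are reproduced; a uniform *ball* (parabolic projection) shifts
every optimum upward by roughly 10 % and is inconsistent with the
reduced model's initial density.

## Homogeneity measures and the optimum

Axial homogeneity is measured on the density
$\rho(z) = (N R \sqrt{2\pi})^{-1} \sum_i e^{-(z - z_i)^2/2R^2}$ by the
variance $\Phi(\chi) = \int_{-b_z}^{b_z} (\rho - \bar\rho)^2\,dz$, with
kernel scale $R = 7$ μm (a nuclear diameter) or 28 μm (the
aster-migration separation); a kernel-free alternative divides the
embryo into $N_{\rm strips}$ equal strips and takes the variance of the
occupation counts. An ensemble of 100 simulations (seeds
`base_seed + k`) of $N = 40$ tracers yields the normalized mean curve
$\langle\Phi(\chi)\rangle / \langle\Phi(0)\rangle$, which falls from 1,
attains an interior minimum and rises again as nuclei pile up at the
poles and recirculate. The optimum $\chi^*$ is the argmin over the
2-μm snapshot grid, refined by a quadratic least-squares fit over a
±30 μm window — the curve is locally parabolic there, and for the
noisier strip measure the windowed fit is a visibly lower-variance
estimator of the argmin than the raw grid minimum.

Study-condition results (100 seeds, $N = 40$): $\chi^* \approx
189\text{–}195$ μm for kernel scales 2–7 μm, rising to
$\approx 213$ μm at 28 μm; nearly unchanged at $N = 10$ or $N = 100$
and under the strip measure. The experimentally realized values of
$\chi$ — about 129 μm for wild type and 57 μm for a dampened-flow
mutant, both treated as *inputs* taken from published estimates, since
the underlying flow traces are not reproduced here — sit respectively
about 0.07 and 0.35 of normalized variance above the curve minimum:
wild-type cortical forcing is near-optimal for axial spreading.

```{r transport, eval = FALSE}
# Full study conditions (about 1 minute):
fl <- stokes_flow(slip_drosophila(), g)
ens <- advect_ensemble(fl, n = 40, n_seeds = 100, base_seed = 1)
curve <- homogeneity_curve(ens, g, bandwidth = 7)
chi_star(curve)
autoplot(curve)
```

## Amplitude histories

`chi_from_amplitude()` converts a cortical amplitude history $V(t)$
(tabulated samples or a Gaussian sum fitted with
`fit_amplitude_gaussians()`) into $\chi$. The built-in amplitude
presets are synthetic stand-ins: their Gaussian shapes are plausible
three- and two-peak contraction trains, but only their *total* $\chi$
(129 and 57 μm) is calibrated to the published estimates. Parameter
uncertainty from the fit propagates to $\chi$ by the delta method.

## Cell division

`divide_nuclei()` implements the qualitative division experiment:
duplicating each nucleus and relaxing the doubled population under a
short-range repulsion of range 28 μm lowers the axial variance
(measured with $R = 28$ μm, the scale at which one nucleus and its two
daughters carry comparable density weight). The published description
fixes only the interaction range; the linear-spring force law,
overdamped relaxation and stopping rule (max step < 0.01 μm) are this
package's documented choices, so only the sign and rough size
(≈ 6–7 % decrease per round on the pre-cycle-6 configuration) are
meaningful, not precise magnitudes.

# The reduced one-dimensional model

Replacing the cortical profile by its symmetrized sine
$v_s = -V(t) \sin(\pi\zeta)$ and approximating the axial bulk flow by
$u_{AP} = -v_s$ (the lubrication centreline value with the projection
factor set to 1), the axial density $n(Z, T)$ with $Z = z/b_z$ and
$T = \pi\chi/b_z$ obeys
$\partial_T n + \partial_Z[\sin(\pi Z)\,n/\pi] = 0$, solved exactly by
characteristics:

$$n(Z, T) = e^{-T} n_0\!\left(\tfrac{2}{\pi}\arctan\!\big(e^{-T}
  \tan\tfrac{\pi Z}{2}\big)\right)
  \frac{\tan^2(\pi Z/2) + 1}{e^{-2T}\tan^2(\pi Z/2) + 1}.$$

For $|Z| > 1/2$ the implementation switches to an equivalent
$\cot(\pi Z/2)$ form, which is finite up to the poles (where the
characteristic map fixes $Z = \pm1$ and the density vanishes outside
the advected support).

The initial density is the semicircle
$n_0(Z) = \sqrt{\max(0, Z_0^2 - Z^2)}\,/\,(\pi Z_0^2/2)$ with
$Z_0 = 60/270$; the denominator is exactly the integral of the
numerator, so mass is 1 and the conserved spatial mean is
$\bar n = 1/2$. The homogeneity measure
$\Phi_{1D}(\chi) = \int_{-1}^1 (n - \tfrac12)^2 dZ$ (composite Simpson
on 2001 points; $\chi$ grid 0–400 μm in 1 μm steps with local quadratic
refinement) is minimized at

```{r reduced}
optimal_chi_1d(bz = 270, Z0 = 60 / 270)
```

about 159 μm — between the experimental wild-type estimate (129 μm)
and the full 3-D optima (195–213 μm). Because the argmin of
$\Phi_{1D}$ is invariant under any rescaling or constant offset of the
density, this number is pinned entirely by the initial shape and the
characteristic map; a *parabolic* initial bump of the same half-width,
for instance, moves it to about 174 μm. At large $\chi$ the 1-D curve
overshoots the 3-D ensemble curve: in one dimension nuclei reaching the
poles cannot recirculate back along the cortex.

# What the simulations do and do not show

The synthetic study conditions emulate: the embryo geometry, the
separable cortical forcing with the measured spatial profile, passive
advection in rescaled time, and the published ensemble protocol
(100 seeds, 40 tracers, 60 μm initial cloud at the stagnation point).
They do **not** emulate: nuclear Brownian motion (deliberately
neglected), hydrodynamic or steric interactions between nuclei during
transport, cortical feedback on the flow, time-dependence of the
spatial profile shape, the viscoelastic two-phase character of real
cytoplasm, or the experimental PIV traces behind the 129/57 μm
estimates (used as given inputs). Passing tests therefore demonstrate
internal correctness of the models and reproduction of the published
model predictions, not direct agreement with raw experimental data.

# Numerical and design choices at a glance

| Choice | Value | Why |
|---|---|---|
| Truncation `nmax` | 14 | interior field converged to < 0.1 % vs 25 |
| Slip quadrature | Gauss–Legendre, ≥ 64 nodes | integrand smooth on [−1, 1] since τ₀ > 1 |
| RK4 step Δχ | 0.5 μm | halving changes trajectories < 10⁻⁶ μm |
| Density grid | 1 μm over [−b_z, b_z], trapezoid | kernel scales ≥ 2 μm well resolved |
| χ snapshot grid | 0–400 μm, step 2 μm | brackets all optima with ±1 μm refinement |
| argmin refinement | quadratic LS, ±30 μm window | lower-variance estimator on flat noisy minima |
| Ensemble seeds | `base_seed + k`, k = 0..99 | full determinism given `base_seed` |
| Escape handling | radial projection at τ ≥ τ₀ | exact flow is non-penetrating; projections ≈ 0 |
| Division force law | linear spring, range 28 μm | range is published; the law is a package choice |
| 1-D quadrature | Simpson, 2001 points | Φ₁D stable to < 10⁻⁴ vs 4001 points |

Problem sizes used by the test-suite and the reproduction script —
100-seed ensembles of 10–100 tracers on a 201-point χ grid — are the
published study conditions themselves and run in a few minutes on one
core; the solvers are vectorized across all tracers of all seeds.

# Known limitations

* The exact solver assumes a perfect prolate spheroid; for other
  elongated shapes only the lubrication backend applies.
* Slip profiles with square-root-type endpoint behaviour converge
  algebraically in the mode basis; truncation error then concentrates
  near the boundary (interior accuracy is much better than the
  worst-case boundary shell).
* The vortex counter works on a finite grid and may miss recirculation
  cells thinner than the grid spacing (irrelevant for the low-order
  mode structures studied here).
* Stochastic optima carry seed-to-seed scatter of a few μm even with
  100 seeds; the strip-count measure is noisier than the kernel
  measure.
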