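---
title: "Methods: the forward model, the collapsed nodal-adjoint Jacobian, and the reconstruction loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward model, nodal-adjoint Jacobian, reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mwtomo)
```

This vignette is the package's account of its science: the scattering model
and its assumptions, the sensitivity-matrix construction that is the heart of
the package, the reconstruction loop, the synthetic-data generator, and the
numerical and design choices made where more than one defensible option
existed.

## The scattering model

We solve the 2D transverse-magnetic (TM) problem: the electric field has a
single out-of-plane scalar component obeying the 2D Helmholtz equation. All
media are characterized by the complex squared wavenumber

$$ k^2 = \omega^2 \mu_0 \left( \varepsilon_0 \varepsilon_r - j\,\sigma/\omega \right) \quad [\mathrm{m^{-2}}], $$

under the engineering time convention $e^{+j\omega t}$, so passive media have
$\mathrm{Im}\,k^2 \le 0$, outgoing waves carry Hankel functions of the second
kind, and the 2D Green's function is $G(d) = H_0^{(2)}(k_b d)/4j$. The
imaging problem is posed in $k^2$: one complex number per node carries both
the permittivity and the conductivity image, and the conversion to
$(\varepsilon_r, \sigma)$ is the fixed scaling
$\varepsilon_r = \mathrm{Re}(k^2)/(\omega^2\mu_0\varepsilon_0)$,
$\sigma = -\mathrm{Im}(k^2)/(\omega\mu_0)$ applied at reporting time.

Assumptions worth stating explicitly:

* antennas are ideal 2D line currents (transmit) and point samplers
  (receive); no antenna geometry, mutual coupling, or feed model;
* the background (coupling bath) is homogeneous and known; only the imaging
  zone carries unknowns;
* single frequency, no dispersion model;
* the problem is open-domain: the volume-integral formulation radiates to
  infinity by construction, with no absorbing boundary needed.

## Forward solver: node-collocated discrete dipoles

The total field solves the volume integral (Lippmann–Schwinger) equation
with contrast $\chi = k^2 - k_b^2$ supported on the imaging zone. We
collocate at the nodes of the same uniform grid that carries the image
parameters; each node owns an $h \times h$ square, giving the dense system

$$ E_n = E^{inc}_n + \sum_m C_{nm}\, \chi_m E_m, \qquad
   C_{nm} = h^2 G(p_n, p_m)\ (n \ne m). $$

The diagonal (self) coefficient integrates $G$ over the cell by the
equivalent-circle substitution (radius $a = h/\sqrt{\pi}$), which has the
closed form $C_{nn} = -\frac{j\pi a}{2k_b} H_1^{(2)}(k_b a) - 1/k_b^2$. The
midpoint rule for off-diagonal coupling and the equivalent circle for the
self term are certified jointly by an analytic oracle, not by fancier
quadrature: the scattered field of a homogeneous dielectric cylinder in the
lossy bath, computed independently as a cylindrical-harmonic series via the
addition theorem, must agree with the solver within 2% relative L2 error at
the default cell size (about a tenth of the background wavelength). The test
suite asserts exactly that, plus the exact zero-contrast identity, exact
measurement reciprocity, linearity in source amplitude, and error reduction
under grid refinement.

Because the zone is fixed and the background known, the coupling matrix `C`
is built once per scene (a small offset table of kernel values, gathered by
index differences — the grid's translation invariance) and reused across all
transmitters and all reconstruction iterations. The default solve is one
dense LU factorization shared by all 16 right-hand sides; a matrix-free
BiCGSTAB path over the same kernel coefficients is available
(`method = "iterative"`) and must agree with the dense path to 1e-8, which
the suite checks.

### Cell size, accuracy, and the sub-wavelength guard

`self_term()` warns when $\mathrm{Re}(k_b)\, h > 2\pi/10$, i.e. when fewer
than ten cells sample the background phase wavelength. The guard is
expressed against the *phase* wavelength rather than $|k_b|$ because lossy
baths inflate $|k_b|$ with a decay component that has nothing to do with
sampling; the shipped default (3.90625 mm cells, 1500 MHz, εr = 20.9 bath)
sits just inside the guard. The equivalent-circle substitution error grows
with $k_b h$: well under 0.5% against square-cell quadrature for comfortably
sub-wavelength cells, about half a percent right at the guard. That residual
is immaterial at the solver level (the cylinder oracle passes at 2% with
margin) and cancels to first order in calibrated reconstruction, where
model-predicted and model-fitted data share the same self term.

### Representing smooth scatterers

`make_property_map()` assigns inclusion properties by node-in-disk
membership by default: staircase transitions, consistent with the step-wise
zone philosophy, and what the phantom simulator uses. A staircase disk,
however, carries an $O(h)$ boundary error that dominates the forward
solver's discretization error budget. For verification against smooth-object
references the `membership = "area"` option weights each boundary node's
contrast by the area fraction of its owned square inside the disk (8×8
subsampling), restoring the convergence needed to meet the 2% cylinder
criterion at the default grid. Both options are exact away from the
boundary.

## Geometry: the step-wise circular zone

The imaging zone is the subset of grid cells whose *centres* lie within the
zone radius of the grid centre; the unknowns live on the distinct corner
nodes of those cells, ordered row-major. The paper's printed configuration —
1012 cells and 1085 nodes on the 64-cell, 25 cm grid — pins the radius down
only to a plateau: every radius in [69.72, 69.93) mm selects exactly that
set. The shipped default is `zone_radius_m = 0.0698`. Note that the
*effective* diameter (the diameter of the equal-area circle,
$2\sqrt{1012\,h^2/\pi} = 14.02$ cm) is a different number: it describes the
zone's area, not the selection rule, and quoting it as the selection radius
would grow the zone to 1020 cells. The Euler relation
$|\mathrm{nodes}| = |\mathrm{cells}| + B/2 + 1$ (B = boundary edge count) is
asserted for every zone the generator produces.

Each node's quadrature weight is the area $A_\tau$ of its incident in-zone
cells: $4h^2$ in the interior (the paper's uniform-grid constant, 60.8 mm²
under the nominal rounded 3.9 mm cell), down to $h^2$ at staircase corners.
We keep the true per-node $A_\tau$ at boundary nodes rather than the uniform
constant because the collapsed quadrature holds exactly with per-node areas;
the uniform-constant statement assumes an effectively uniform interior.

## The collapsed nodal-adjoint Jacobian

The adjoint method computes the sensitivity of the measurement for
transmit/receive pair $(s, r)$ to $k^2_\tau$ from the two forward fields —
the one launched by the transmitter and the one that *would be* launched by
the receiver (reciprocity). On dual meshes this requires a quadrature over
the parameter basis function's support. When the forward and parameter
grids coincide and the basis is nodal (value 1 at its node, 0 at all
others), every term with $n \ne \tau$ vanishes and the whole row collapses
to

$$ J[(s,r), \tau] = -\frac{1}{j\omega\mu_0 |J_r|}\, \frac{A_\tau}{M}\,
   E_s(p_\tau)\, E_r(p_\tau), $$

one element-wise vector product per row. The same derivative can be obtained
directly from the discrete collocation system, and it is *exact* for
interior nodes (where $A_\tau/M = h^2$); the test suite verifies adjoint
entries against central finite differences of the received field to 1e-3
relative at interior nodes, second-order step convergence of the finite
differences, and machine-precision agreement (1e-12) between the collapsed
row and an independently coded general dual-mesh quadrature
(`jacobian_row_general()`). The operation-count structure — exactly `ns`
forward solves and `ns*nr` vector products per Jacobian, zero hidden solves —
is instrumented with package counters and asserted, since the complexity
claim is the method's point.

Reciprocal rows ((s,r) vs (r,s)) are bitwise identical: the row kernel
multiplies the two fields in canonical transmitter order because C99 complex
multiplication, though commutative mathematically, is not bit-for-bit
symmetric in its operands.

The log-domain Jacobian divides each row by that row's model-predicted
received field (chain rule for the complex logarithm): real parts become
sensitivities of $\ln|E|$, imaginary parts of phase. No unwrapping happens
inside the Jacobian — phase unwrapping is a measurement-side transformation.

## Reconstruction

Calibration re-bases the measured phantom perturbation onto the model:
$\gamma_{cal} = [\log m_{inh} - \log m_{hom}] + \log \hat m_{hom}$, all in
the log-magnitude/unwrapped-phase domain (1D unwrap along the receiver
sequence of each transmitter). Antenna and system factors common to the two
measured conditions cancel; at the first iteration the model terms cancel
exactly, so unwrap ambiguities cannot leak into the starting residual.

Each Gauss–Newton iteration runs one forward sweep, forms the residual
$\gamma_{cal} - \gamma_{comp}$ and its L2 norm (normalized to the first
iteration, so $e_1 = 1$), reuses the sweep's fields for the Jacobian,
log-transforms it, and solves the Levenberg–Marquardt normal equations
$(J^H J + \lambda \bar d I)\,\Delta k^2 = J^H r$ with $\bar d$ the mean
diagonal of $J^H J$ (so $\lambda$ is relative). Defaults
$\lambda_0 = 0.1$, geometric decay 0.9 per iteration: strong early damping
against the underdetermined 240-equation / 1085-unknown step, relaxing as
the image approaches the data. After each update, images are projected to
the physical cone ($\varepsilon_r \ge 1$, $\sigma \ge 0$). Iteration stops
when $|e_i - e_{i-1}| < 10^{-3}$ (the stopping rule of the tank experiment),
at the iteration cap (default 25), or — with a warning — after three
consecutive error increases. All arithmetic is complex (Hermitian normal
equations); the real-stacked formulation would be equivalent.

The residual tracked is the plain L2 norm of the complex log-domain
residual, magnitude and phase weighted equally; the experimental
error-functional details were not specified more finely than that, and this
is the simplest functional consistent with the log-domain update.

## The synthetic phantom generator

`simulate_measurements()` emulates the tank experiment end to end: both the
homogeneous (bath only) and inhomogeneous (bath + phantom) conditions are
simulated with the same solver on a grid refined by `fine_factor` (default
2), then perturbed by i.i.d. complex Gaussian noise with standard deviation
`noise_level` (default 1%) relative to each measurement's magnitude, under a
fixed seed (byte-identical reruns). Simulating on a refined grid rather
than with a different solver family is the inverse-crime precaution: the
inversion never sees its own discretization, while the repository stays
self-contained.

Defaults mirror the tank experiment: 16 antennas on a 15.2 cm circle,
1500 MHz, bath εr = 20.9 / σ = 1.35 S/m, a 4 cm diameter cylinder with
εr = 16.9 / σ = 1.15 S/m. The experiment's description places the phantom
"in front of antennas #6 and #7" without coordinates; the default puts the
centre at 2/3 of the zone radius along that fixed bisector direction — well
off-centre, inside the zone, clear of the antennas — and `score_recovery()`
measures localization as the distance from the truth to the half-maximum
centroid of the recovered anomaly (thresholding at half peak is the standard
way to keep low-level ringing far from the object from biasing the
centroid).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: antenna modeling and array coupling, cable/system
drift between the two measured conditions, non-Gaussian or correlated noise,
multi-frequency dispersion, and 3D propagation of a real tank. The
generator's role is to validate the mathematics (solver, Jacobian,
calibration, update loop) under controlled conditions, not to certify
instrument performance.

## Numerical choices and degenerate inputs

* **Complex-argument cylinder functions.** Base R's Bessel functions are
  real-only, so the package implements $J_{0,1}$, $Y_{0,1}$, $H^{(2)}_{0,1}$
  for complex argument (ascending series for $|z| \le 12$, Hankel's
  asymptotic expansion beyond) and integer-order sequences by Miller
  downward recurrence ($J_n$) and stable upward recurrence ($H^{(2)}_n$).
  Within the package's regime — loss angles of glycerin–water baths,
  $|\mathrm{Im}\,z| \lesssim 0.35 |z|$ — worst-case relative error is
  ~1e-12; accuracy degrades like $\epsilon\, e^{2|\mathrm{Im} z|}$ for
  strongly evanescent arguments in the series region, outside the intended
  domain. Shipped checks: agreement with base `besselJ`/`besselY` on the
  real axis across the series/asymptotic switch, the cancellation-free
  cross-product Wronskian identity on complex arguments, and recurrence
  consistency of the order sequences.
* **Tie-breaks.** Cell membership uses $\le$ on the centre distance; node
  ordering is row-major; measurement rows are (s ascending, r ascending,
  r ≠ s). All orderings are deterministic and shared by measurements and
  Jacobian rows.
* **Degenerate inputs.** Zero-magnitude measurements are rejected before
  the log transform; a zero received field rejects the Jacobian row with a
  diagnostic; observation points on a source, nodes outside the zone, s = r
  measurement rows, duplicate or missing (s, r) pairs, and unknown
  configuration keys all fail fast with informative errors. A zero
  first-iteration residual (data generated by the starting model) stops the
  reconstruction immediately at the background image.
* **Problem sizes in the shipped tests.** Property and identity tests run
  on a 24-cell grid with 8 antennas (~180 unknowns); accuracy and
  acceptance checks run the full 64-cell / 1085-unknown configuration, with
  the phantom-recovery test simulating its data on the twice-refined
  (128-cell) grid. The whole suite is a sub-minute run on one core.

## Known limitations

* 2D TM only; no 3D extension, no vector fields.
* Ideal antennas; no calibration transfer model beyond homogeneous-tank
  log-domain subtraction.
* The dense LU forward solve is $O(n_p^3)$; ample at ~1000 unknowns,
  but an FFT/Toeplitz-accelerated matvec would be the route to much finer
  grids.
* Phase unwrapping is 1D along receivers per transmitter; pathological
  geometries with inter-receiver phase steps near π could unwrap
  inconsistently between datasets (the calibration structure cancels the
  common part at the homogeneous start).
* The regularizer is plain Levenberg–Marquardt with geometric decay; no
  spatial priors, no line search, no parameter-free stopping beyond the
  stated rule.
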