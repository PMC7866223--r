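# mwtomo

2D microwave tomographic image reconstruction in R: a discrete-dipole
forward solver, an exact nodal-adjoint sensitivity (Jacobian) matrix in its
collapsed one-product-per-row form, and log-magnitude/phase Gauss–Newton
image reconstruction — plus a synthetic phantom simulator so the whole
pipeline runs and is testable without any measured data.

## The problem and who this is for

Microwave tomography recovers the spatial distribution of dielectric
properties (relative permittivity εr and conductivity σ) of an object — in
breast imaging, a tissue target immersed in a lossy glycerin–water coupling
bath — from complex transmission measurements between the elements of a
surrounding antenna array. It is a nonlinear inverse scattering problem
solved iteratively: each Gauss–Newton step needs (a) a forward solution of
the 2D Helmholtz scattering problem for every transmitter and (b) the
Jacobian matrix of all measurements with respect to all image parameters.
The package targets researchers prototyping tomographic reconstruction
algorithms and the numerical methods around them.

## The method at its core

**Forward model.** The 2D TM scattering problem is written as a volume
integral equation and collocated at the nodes of a uniform grid (the
discrete-dipole approximation): with contrast χ(r) = k²(r) − k_b² supported
on a step-wise circular imaging zone,

    E_n = E_inc,n + Σ_m C_nm χ_m E_m ,

where `C_nm = h² G(p_n, p_m)` couples node-owned h×h squares through the
outgoing 2D Green's function `G(d) = H₀⁽²⁾(k_b d) / 4j`, and the diagonal
term is the closed-form integral of G over the equal-area circle of a cell.
Antennas are ideal 2D line sources on a circle surrounding the zone.

**Collapsed nodal-adjoint Jacobian.** Because the forward grid and the
parameter grid are the *same* grid with nodal basis functions, the dual-mesh
adjoint quadrature for the sensitivity of measurement (s, r) to the squared
wavenumber k²_τ at node τ degenerates to a single term:

    J[(s,r), τ] = −(1 / (jωμ₀|Jr|)) · (A_τ / M) · E_s(p_τ) · E_r(p_τ) ,

with A_τ the area of the in-zone cells incident to node τ and M = 4 vertices
per square cell (A_τ/M = h² in the interior). An entire Jacobian row is one
element-wise product of two already-computed field distributions: the whole
240 × 1085 matrix of the default configuration costs 16 forward solves and
240 vector products — no extra solves, which is the point of the method.

**Reconstruction.** Measured phantom data are calibrated against a
homogeneous-tank measurement in the log domain
(γ_cal = log m_inhomog − log m_homog + log m̂_homog, phases unwrapped per
transmitter), and the image is updated by Levenberg–Marquardt-regularized
Gauss–Newton steps on the log-transformed Jacobian until the relative
residual decrease drops below 1×10⁻³.

## Worked example

The shipped default scenario reproduces a tank experiment: 16 monopole
antennas on a 15.2 cm circle, 25 × 25 cm / 64 × 64-cell grid, a 1012-cell /
1085-node circular imaging zone, a 1500 MHz glycerin–water bath
(εr = 20.9, σ = 1.35 S/m), and a 4 cm cylindrical inclusion
(εr = 16.9, σ = 1.15 S/m) placed off-centre. Data are simulated on a
twice-refined grid with 1% complex Gaussian noise (no inverse crime):

```r
library(mwtomo)
scene <- scene_from_config(default_config())
sim   <- simulate_measurements(scene$phantom, scene$grid, scene$zone, scene$array)
comp  <- forward_sweep(property_map(scene$zone, scene$background, scene$frequency),
                       scene$zone, scene$array)$measurements
cal   <- calibrate(sim$inhomog, sim$homog, comp)
fit   <- mwt_reconstruct(cal, scene$zone, scene$array, scene$frequency,
                         scene$background, scene$control)
print(fit)
#> Microwave tomographic reconstruction (log-magnitude/phase Gauss-Newton)
#>   16 antennas, 1085 unknown nodes, 1500 MHz
#>   6 iterations; converged (stopping rule met); relative error 0.04892
#>   eps_r in [15.3, 23.2]; sigma in [0.977, 1.56] S/m
round(fit$errors, 4)
#> [1] 1.0000 0.1331 0.0581 0.0516 0.0496 0.0489
score_recovery(fit, scene$phantom)[c("mean_eps_footprint", "centroid_error_cells")]
#> $mean_eps_footprint
#> [1] 17.46888
#> $centroid_error_cells
#> [1] 0.4590274
```

The relative residual falls monotonically from 1 and the run stops by the
1×10⁻³ rule after 6 iterations (the whole example takes ~20 s). The mean
reconstructed permittivity over the true inclusion footprint is 17.5 against
a truth of 16.9 (+3.4%), and the recovered anomaly's half-maximum centroid
lands 0.46 cells from the true centre. `plot(fit)` draws the εr and σ
images; `coef`, `predict`, `residuals` and `simulate` behave as for any
fitted-model object.

A command-line front end with `simulate`, `forward`, `jacobian`,
`reconstruct` and `validate` subcommands lives at `inst/cli/mwt.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mwt.R",package="mwtomo"))')" \
    simulate --out data/
```

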