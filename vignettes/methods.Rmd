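---
title: "Methods: forward modelling, phantoms, and network reconstruction in eit3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward modelling, phantoms, and network reconstruction in eit3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eit3d` implements a desk-scale pipeline for three-dimensional electrical
impedance tomography (EIT) of a cylindrical domain carrying three rings of
16 boundary electrodes: a complete-electrode-model (CEM) finite element
forward solver, an adjacent stimulation protocol producing 2,160-value
boundary voltage frames, conductivity phantom generators, SNR-controlled
noise injection, a residual bottleneck regression network that maps a
45 x 48 reconfigured feature map to per-element conductivity, a regularized
Gauss-Newton comparator, and a metric suite. This vignette records the
models, the tunable parameters, and the design decisions taken where the
problem was genuinely open.

## Forward model

The domain is a cylinder (default radius 5 cm, height 8 cm) discretized
into first-order tetrahedra. Conductivity is piecewise constant per
element and stored in S/m; configuration surfaces accept uS/cm
(1 uS/cm = 1e-4 S/m), the conventional unit for saline backgrounds.
Current (default 1 mA) is driven through adjacent electrode pairs, and the
potential field solves the conduction equation with CEM boundary
conditions: finite electrode patches with a contact layer between
electrode and medium, and zero net current elsewhere. The linear system is
assembled sparsely; electrode potentials are grounded by a
Lagrange-multiplier constraint enforcing a zero mean, a convention that
leaves differential measurements unchanged. Solves are accepted only when
the relative residual is at most 1e-10 (one iterative-refinement pass is
applied if needed).

**Contact model.** The electrode--medium interface is modelled as a thin
layer of the medium itself: a face owned by element `e` contributes a
surface admittance `sigma_e / l_c` per unit area, with the equivalent gap
`l_c` parameterized by the impedance the interface presents at the nominal
350 uS/cm background (`cem_params(contact_impedance = 1e-4)` ohm m^2 by
default). Physically this treats the contact as electrolyte-dominated; its
admittance scales with the electrolyte conductivity. The payoff is
structural: the assembled system is exactly homogeneous of degree one in
the conductivity vector, so boundary frames satisfy
`v(c * sigma) = v(sigma) / c` and the Euler identity
`J %*% sigma = -v` to solver precision --- properties the test-suite
asserts at 1e-10 and 1e-6 respectively. A fixed, conductivity-independent
contact impedance would break both at roughly the relative magnitude of
the contact term (about 1e-3 at the defaults).

**Jacobian.** Sensitivities are computed by the adjoint-field
formulation. Because every measured pair is also a drive pair in the
adjacent protocol, the measurement fields reuse the 48 drive solutions.
The derivative of the system matrix is exact: the familiar
gradient-dot-gradient volume term plus the (small) interface term for
elements owning electrode faces. The full matrix is validated against
central finite differences on a 336-element mesh.

## Meshing

The built-in mesher is structured: identical fan-plus-annulus disk
triangulations on each z-level, with vertical prisms split into three
tetrahedra each. Diagonal choices follow intrinsic rules (edges oriented
centre-to-rim, inner-to-outer, and counterclockwise), which makes the
tetrahedral decomposition *exactly* equivariant under rotation by one
azimuthal division. With the default `na = 48` azimuthal divisions the
mesh is invariant under the 22.5-degree electrode spacing, which the
package exploits twice: rotational-consistency tests of the solver, and
exact symmetry augmentation during training (below). Axial node levels
always include the rims of the electrode bands, so electrode patches are
resolved by whole boundary faces at any refinement. Electrode patches are
the set of lateral boundary faces whose centroid falls inside the
electrode's angular window and axial band; the discrete electrode is
therefore mesh-quantized, and an empty patch is a validation error rather
than a silent loss. Typical sizes: refinement 1 gives 3,024 elements
(about the "3,000-element" scale used throughout the reduced-scale
experiments), refinement 3 about 11,000.

## Protocol and feature reconfiguration

Drives cycle through ring-adjacent pairs (2,1), (3,2), ..., (1,16) per
ring, rings in order, 48 drives in total. Each drive measures 45 adjacent
pairs: 13 in its own ring (all pairs not sharing an electrode with the
drive, starting two positions past it) and 16 in each other ring
(starting at the local pair aligned with the drive's lower electrode).
The differential sign convention is `v = phi(out1) - phi(out2)` with the
measured pair ordered counterclockwise. A frame is the excitation-major
vector of all 48 x 45 = 2,160 values; the feature map is its 48 x 45
excitation-by-measurement matrix transposed to 45 x 48, the single-channel
image the network consumes. The reconfiguration is a bijection and is
tested bit-exactly.

## Phantoms

*Acrylic-style inclusions*: spheres, axis-aligned cylinders and cubes of
near-insulating material (0.0001 uS/cm) in a 350 uS/cm saline background.
Membership is decided by element centroid --- simple, deterministic, and
consistent with the per-element conductivity model; partial-volume
weighting is deliberately not attempted. The seeded sampler draws shape
parameters uniformly from configured ranges; defaults keep centres within
the central 60% of the cylinder radially and within 20--80% of its
height, with sphere radii 0.6--1.4 cm --- chosen once as a plausible
phantom family for a 10 cm tank. Draws whose discretized field is
constant (an inclusion that captures no centroid) are redrawn: they carry
no reconstruction target.

*Maize-ear gradient fields*: conductivity decays exponentially with
distance from a centre point, with an axially modulated in-plane scale
`s(z) = 1 + a sin(bz + c)` and
`Es = exp(-Dxy s(z)/bs1 - Dxy s(z)/bs2 - Dz/bs3)`; element conductivity
is `sigma_max * Es` (default 350 uS/cm at the centre; the dimensionless
shape leaves the multiplier open, so it is configurable). The in-plane
distance deliberately appears in both of the first two exponent terms,
exactly as the model is stated. `z` is taken as the centroid's axial
offset from the phantom centre, which keeps the field invariant under
rigid translation of mesh and centre together while preserving the
intended axial variation.

These generators emulate the geometry and contrast of tank experiments
and the smooth moisture gradient of an ear; they do not emulate
electrode-contact drift, multi-tissue anatomy (husk/kernel/cob surfaces),
or frequency-dependent admittivity. Passing tests therefore demonstrate
correctness of the simulation-to-reconstruction chain, not performance on
measured produce.

## Noise and the detection limit

SNR is defined frame-wise on RMS amplitude: noise is i.i.d. zero-mean
Gaussian with standard deviation `RMS(frame) * 10^(-SNR/20)`, seeded per
sample. A measurement is deemed usable when its magnitude exceeds the
noise mean plus three standard deviations; for the zero-mean model the
threshold is `3 sigma_noise`. The reported proportion is exactly
`count / 2,160`, and it is non-decreasing in SNR by construction of the
threshold; the suite checks the trend over 20--60 dB rather than any
particular counts, which depend on mesh and phantom.

## Reconstruction network

The architecture is the standard four-stage bottleneck residual design:
7x7/stride-2 stem (64 filters, padding 3) giving 64 x 23 x 24 on a
45 x 48 input, 3x3/stride-2 max pooling to 12 x 12, stages of bottleneck
blocks (projection shortcut at stage entry, identity elsewhere,
rectified-linear activations, batch normalization after every
convolution), global average pooling to a 2,048-long vector at the
default widths (64, 128, 256, 512) x expansion 4, and a single fully
connected regression head sized to the mesh element count. Depths
(3, 4, 6, 3) are the default; reduced variants shrink depths and widths
but keep the same shape grammar. Everything is implemented in R with
compiled im2col convolution, pooling and optimizer kernels; there is no
GPU path.

Training minimizes the amplified mean-squared error
`alpha * mean((pred - target)^2)` (default `alpha = 100`) with Adam
(default base learning rate 1e-4, the reference full-scale value), batch
size 32, and a reduce-on-plateau schedule (factor 0.5, patience 5, on
validation loss). The amplification raises the gradient magnitude on
small-valued conductivity targets; with Adam its practical effect is
mostly on the loss scale reported, and it is kept configurable.

**Normalization.** Feature maps are standardized per position by
training-split mean and standard deviation: boundary frames share a large
phantom-independent background pattern, and position-wise centering is
what exposes the informative anomaly to the convolution stack. Targets
default to per-element standardization (each element z-scored by its own
training-split statistics, floored at 5% of the largest element standard
deviation): this balances the loss between the rare anomaly-bearing
elements and the nearly constant background, which would otherwise
dominate the objective. Global range and z-score scalings are available.
The head bias is initialized at the per-element mean of the normalized
training targets, so optimization starts from the best constant-field
predictor. All statistics come from the training split only and are
stored in the model.

**Symmetry augmentation.** Because mesh, electrodes and protocol are all
exactly equivariant under rotation by one electrode spacing,
`symmetry_permutations()` yields 16 exact (element-permutation,
frame-permutation) pairs. During training each example is presented under
a uniformly drawn rotation whenever it is visited; at prediction time the
estimator can be symmetrized by averaging the 16 back-rotated
predictions. Both are loss-free: no interpolation or resampling error is
introduced.

## Reduced-scale study configuration

The package's experiments run at desk scale, chosen once as a coherent
set: a 3,024-element mesh (refinement 1), 1,000 single-sphere samples at
40 dB split 8:2, a reduced network with stage depths (1, 1, 1, 1) and
widths (32, 64, 128, 512) --- shallow, but keeping the full 2,048-long
pooled vector so the head retains roughly the information capacity of the
2,160-value frame --- 30 epochs at batch size 16 and learning rate 3e-3.
The raised learning rate and reduced batch compensate for having roughly
an order of magnitude fewer optimizer steps than a full-scale schedule;
the package defaults remain the full-scale values. Training this
configuration takes on the order of a quarter hour on one CPU core. The
Gauss-Newton comparator and solver-physics checks use 336- and
2,016-element meshes.

## Gauss-Newton comparator

Absolute imaging by damped, Tikhonov-regularized Gauss-Newton:
initialization at the best-fit homogeneous field (a scalar least-squares
fit that is exact under the solver's conductivity scaling), identity or
graph-Laplacian prior, regularization weight specified relative to
`mean(diag(J'J))` (default 1e-2), step halving until the objective
decreases, Jacobian recomputed at every iterate, conductivity floored at
1e-10 S/m as a numerical guard, stop on `max_iters` (default 10) or a
relative objective change below 1e-6. Wall-clock inverse-problem solving
time (IPST) is recorded and reported but never asserted --- it is
hardware-dependent.

## Metrics

RMSE, Pearson correlation (CC) and SSIM are computed on whole element
vectors; SSIM uses global statistics (fields are unstructured per-element
values, so windowed image SSIM does not apply) with the conventional
constants `(0.01 Lr)^2` and `(0.03 Lr)^2` off the reference's dynamic
range, floored for degenerate references. The distribution-quality
statistics use a Gaussian kernel: MMD is the square root of the unbiased
two-sample estimator (negative estimates clipped at zero) with the median
pairwise-distance bandwidth; KDE-ISE integrates the squared difference of
two kernel density estimates (Silverman bandwidths, 512-point grid
spanning the pooled range plus three bandwidths); LMMD averages MMD over
contiguous equal windows (default 10, remainder dropped); KNNDC averages,
over the first sample set, the mean Euclidean distance to the k nearest
neighbours in the second (default k = 5). Kernel and bandwidth choices
are documented defaults --- the statistics themselves do not prescribe
them.

## Numerical choices and degenerate inputs

Sparse LU with a residual contract of 1e-10; symmetric systems by
construction (asserted to 1e-12). Tetrahedra are orientation-fixed to
positive volume; non-manifold connectivity and empty electrode patches
are validation errors. All-zero frames reject RMS-based SNR scaling.
Constant inputs to CC raise an error (the correlation is undefined);
constant references in SSIM fall back to a positive floor for the
stabilizers. Random draws everywhere go through explicitly seeded,
restored RNG scopes, so sampling, noise, initialization and batch order
are reproducible end to end and independent of the caller's RNG state.

## Known limitations

Real-valued conductivity at a nominal frequency (no complex admittivity),
isotropic media, first-order elements, and a structured mesh whose
electrode patches are quantized to face boundaries. The mesher's
rotational equivariance does not extend to reflections. The network path
is CPU-bound and deliberately small; at desk scale its held-out accuracy
is limited by sample count and optimizer steps rather than by the
architecture's capacity, and small inclusions near the mesh resolution
limit remain the hardest cases for both the network and the Gauss-Newton
comparator.
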