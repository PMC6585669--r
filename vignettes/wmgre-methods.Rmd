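---
title: "Methods: the wmgre white-matter GRE forward model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the wmgre white-matter GRE forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wmgre` predicts the susceptibility-weighted multi-echo gradient-echo (GRE)
signal of white matter from explicit two-dimensional cross-section geometry.
This vignette records the model, its assumptions, the numerical conventions,
and the design decisions taken where the problem was genuinely open — in
enough detail that every number the package produces can be traced to a
stated choice.

## The three-compartment model

A cross-section is a label map: each pixel is extra-axonal water,
intra-axonal water, or myelin. Axons are assumed parallel and infinite along
z, so all fields are computed in 2D on the k_z = 0 plane; axonal undulation
and any 3D structure are out of scope. The compartments do not exchange
magnetization. Default properties (editable via `compartment_properties()`):

| compartment | T2 (ms) | proton density | chi_iso (ppb) | chi_aniso (ppb) |
|---|---|---|---|---|
| extra-axonal | 50 | 1 | 0 | 0 |
| intra-axonal | 50 | 1 | 0 | 0 |
| myelin | 15 | 1/2 | -60 | -120 |

The aqueous compartments are the susceptibility reference (chi = 0). Myelin
carries an isotropic offset plus an anisotropic component from the radial
stacking of its phospholipid bilayers.

## The susceptibility tensor and its convention

In the local bilayer frame the myelin tensor is

    diag(chi_i + chi_a,  chi_i - chi_a/2,  chi_i - chi_a/2),

long axis along the bilayer normal (radial in the sheath), anisotropic part
traceless. This specific split is *pinned by the hollow-cylinder closed
form*: only a traceless anisotropic part of magnitude `(3/2) chi_a` along the
radius yields the intra-axonal shift

    delta_f_intra = (3/4) chi_a ln(1/g) sin^2(theta) * gamma_bar B0 * 1e-9,

which is the analytic anchor (`analytic_hollow_cylinder()`): -9.57 Hz at
g = 0.7, 7 T, theta = pi/2. The superficially simpler convention
`diag(chi_i + chi_a, chi_i, chi_i)` yields a 1/2 coefficient instead of 3/4
and fails the anchor by a third; it is therefore not used. A useful check:
with Table values, the local tensor at azimuth 0 is `diag(-180, 0, 0)` ppb
and its trace, `3 chi_i = -180 ppb`, is rotation invariant.

Per-pixel orientation comes from `orientation_map()`: the azimuth of the
pixel about its fiber's center, either continuous or quantized into
azimuthal wedges (`max(16, perimeter / (2 px))` wedges per fiber, keeping
wedge arcs under ~2 px; the two modes agree in the intra-axonal mean to well
under 0.5 Hz).

## The field solver and its gauge

`forward_field()` evaluates, per Fourier component of the tensor field X,

    bracket(k) = (1/3) H^T X(k) H - (H^T k)(k^T X(k) H) / |k|^2,

with H = [sin(theta), 0, cos(theta)], k_z = 0, inverse-transforms, and
scales by `1e-9 * gamma_bar * B0` (gamma_bar fixed at 42.58 MHz/T) to give
Hz. Implementation notes:

* **DC bin.** `bracket(0)` is set to zero, making the returned field
  zero-mean over the grid. The k = 0 limit of the dipole kernel is
  direction-dependent; zeroing it is the standard resolution and bulk
  (nonlocal) offsets are reinstated explicitly via
  `apply_uniform_offset()`.
* **Periodicity.** No zero-padding. The packed geometries are generated on a
  torus (`pack_circles()` uses minimum-image distances and the rasterizer
  wraps), so the transform's implicit periodicity is exact for them. Bounded
  geometries (single axons, loaded rasters) accept the wrap and exclude edge
  effects with the central `sample_mask()` (default: a disk covering 50% of
  the area).
* **Oracle.** `direct_convolution_oracle()` evaluates the identical operator
  by explicit DFT matrix multiplication on grids up to 128 px; the fast and
  brute-force paths agree to 1e-6 relative, and the operator is linear to
  1e-10.

**Frequency origin.** In a dense periodic medium there is no "far away"
pixel, so the zero of frequency is a gauge choice at the ~1 Hz level: with a
zero-mean field and ~32% myelin (whose own mean frequency is strongly
positive, ~+13 Hz under the defaults), the aqueous compartments necessarily
sit *below* zero. Measured GRE phase is referenced after background-field
removal, and compartment frequency distributions are conventionally drawn
with extra-axonal water at 0 Hz. `reference_field()` therefore subtracts the
extra-axonal *mean* by default. The extra-axonal *mode* was rejected as the
reference after testing: the packed models' extra-axonal distribution has a
flat, roughly 1 Hz wide top, so modal estimates wander by about +-1 Hz from
packing seed to packing seed, whereas the mean is stable to ~0.003 Hz.
Consequences worth knowing: under the mean gauge the extra-axonal modal bin
sits within one 0.5 Hz bin of zero; the packed circular model's intra peak
falls at -10.25 Hz where the isolated-axon value is -9.6 (a ~0.5 Hz
collective offset plus binning); any check phrased against a *mode* inherits
the half-hertz ambiguity.

## Geometry generators

**Packing.** `pack_circles()` draws outer radii from Gamma(shape 5.7,
mean `mean_radius`), inner radius `g * outer` (g = 0.7), and packs by random
placement followed by staged radius growth with collision-resolving
relaxation sweeps (positional noise breaks symmetric deadlocks; toroidal
domain; deterministic per seed). Acceptance of a packing is by achieved
composition, not by contact statistics.

*Radius calibration.* The EM template statistics this generator emulates —
gamma shape 5.7 about a 0.46 µm mean radius, g = 0.7, 1434 fibers on a
37 µm square — are not jointly realizable with the 36% extra-axonal volume
fraction the rendered models carry: at those radii the expected fiber area
fraction is 82% (even a zero-variance draw cannot get the extra-axonal
fraction above 30%). The composition is the quantity the physics depends on
— the 2D field pattern is scale-invariant, so absolute radius only sets the
pixel size, while volume fractions set every signal weight — and the
companion myelin volume fraction (0.32 = 0.64 x (1 - 0.7^2)) corroborates
it. The default therefore calibrates the mean radius to the composition:

    mean_radius = sqrt((1 - evf) L^2 shape / ((shape + 1) n pi)) = 0.4067 um

for evf = 0.36. An explicit `mean_radius` (e.g. the EM value 0.46 µm on a
correspondingly larger domain) overrides the calibration;
`match_fraction = TRUE` additionally rescales the realized draw to the exact
target composition (gamma is a scale family, so the distribution shape is
preserved) — used where two geometries must match fiber density exactly, as
in `run_geometry_comparison()`.

**Warping.** `warp_geometry()` composes axis-aligned sinusoidal shear maps
(`x <- x + A sin(2 pi f y / L + phase)`, axes alternating, incommensurate
frequencies). Every pass has unit Jacobian, so all enclosed areas — hence
per-axon g and map fiber density — are conserved exactly in the continuum
and to better than 2% through the polygon discretization (vertex counts are
chosen to resolve the shortest displacement wavelength with ~32 vertices per
cycle). Integer frequencies keep the map periodic on the torus. Defaults
(amplitude 0.45 µm, wavelength ~6 µm) produce local shear strains of order
0.5-1.3, rendering over 90% of outlines non-circular (circularity
4 pi A / P^2 < 0.95).

**Irregular outlines.** `synthesize_irregular_axons()` is a synthetic
stand-in for hand-segmented electron-microscopy templates: each packed circle
is perturbed by a random radial harmonic series (orders 2-5, total relative
SD 0.15, clamped at +-0.3), the inner boundary scaled with the outer so g is
preserved exactly, each outline rescaled to its original fiber area, and
perturbations damped locally where neighbors would collide. It emulates
outline irregularity and its effect on the field; it does *not* emulate
other features of real tissue — non-axonal inclusions (iron-rich
oligodendrocytes, astrocytes), unmyelinated axons, spatially correlated
shapes, or segmentation noise — so passing tests on it demonstrate
correctness of the forward machinery on irregular geometry, not fidelity to
any particular micrograph.

**Demyelination.** `erode_myelin()` thins the sheath *from the inside out*:
the outer boundary (hence fiber density) is untouched and the removed
innermost myelin becomes intra-axonal water, so A_t is constant while
g = sqrt(A_i / A_t) rises. The alternative reading — removed myelin becoming
extra-axonal space — would shrink the fiber, contradicting constant fiber
density at fixed outer boundaries; reassignment to the lumen is the only
self-consistent choice given that constraint. Circular fibers erode
analytically (r_inner = g r_outer), polygons by rescaling the inner boundary
about its centroid, rasters by relabeling myelin pixels in order of their
BFS distance from the lumen (exact to one pixel layer).

## Signal synthesis

`static_signal()` evaluates, over masked pixels,

    S(t) = sum_n rho_n exp(-t / T2_n) sum_{pixels in n} exp(i s 2 pi df t),

normalizes magnitude by S(0) = sum_n rho_n area_n, and unwraps phase in
time. Choices:

* **Sign.** `sign_convention = +1` by default, so a positive mean frequency
  accrues positive phase (the isotropic-only variant then shows positive
  early phase, as it should); the opposite sign is available, and headline
  phase comparisons use |phase|.
* **Echo grids.** `echo_times("static")` gives 100 samples over 0-55 ms;
  `"cuprizone"` the 3-55 ms, 4 ms-spaced acquisition grid.
* **Compression.** For masks above ~1 Mpixel the per-compartment frequency
  values are binned at 0.01 Hz before the echo loop; the worst-case phase
  error per pixel is pi * 0.01 * 0.055 ~ 1.7e-3 rad, two orders below any
  tolerance used. `freq_bin = 0` forces the exact sum.
* **Unwrapping.** Phase increments are wrapped into (-pi, pi] and summed;
  zero-magnitude samples (the packed circular model's signal passes through
  a beat null near 50-55 ms) get interpolated increments and a message.

`run_diffusion()` adds Monte Carlo diffusion: spins seeded uniformly over
masked pixels, weighted by the proton density of their home compartment;
Gaussian steps with per-axis SD sqrt(2 D dt), D = 2 um^2/ms in water; myelin
is impermeable (steps into it are rejected by default, a reflecting rule is
available) and myelin water is immobile, accruing local phase (an
alternative excludes myelin spins and adds that compartment's static term
analytically). The default step time follows the four-pixel rule
`dt = (4 px)^2 / (4 D)`, coarsened by `time_scale` for scaled-down runs;
per-spin phase is recorded at echo times (linear interpolation between
steps). In the D -> 0 limit the result converges to a Monte Carlo estimate
of the static signal; free diffusion recovers D from the Einstein relation
to a few percent; diffusion through the packed field shows motional
narrowing (slower magnitude decay, less phase accrual than static).

## Problem sizes

The native reference grid is 4454 px over 37 µm (8.3 nm pixels). The package
default for packed experiments is 2227 px over the same domain (16.6 nm
pixels): the sheath is still ~8 px thick, and the quantities of interest are
resolution-converged at this size (the extra-axonal line width changes by
<5% between 2227 and 4454, and peak positions by less than a bin). The
acceptance script rasterizes the composition measurement at the native
4454 px and computes fields at 2227 px; unit tests use geometrically similar
fixtures at 120 fibers / 644 px (identical pixel size and composition).

## Known limitations and honest discrepancies

* **Packed-model phase at 55 ms.** For the g = 0.7 circular packing this
  model computes |phase(55 ms)| of ~3.5-4 rad, not the ~1.5 rad reported for
  this configuration in the literature. The discrepancy is structural, not
  numerical: 1.5 rad equals the two-phasor marginal value omega t / 2 (omega
  = 2 pi x 9.6 Hz), which requires the extra-axonal phasor to stay
  comparable to the intra-axonal one through 55 ms and the beat null to sit
  at the last echo. That in turn requires an extra-axonal line width of
  ~2 Hz, whereas the extra-axonal field of *any* 64%-fiber packing under the
  default susceptibilities disperses with sigma ~3.5 Hz — a value we found
  invariant to raster resolution (2227 vs 4454), to 2x2-supersampled
  susceptibility maps, to the inter-fiber gap (0.02-0.10 µm), and even to a
  jittered hexagonal arrangement. With sigma = 3.5 Hz the extra-axonal
  phasor decoheres by ~45 ms, the signal phase locks onto the -9.6 Hz
  intra-axonal rotation, and the unwrapped phase reaches ~3.5 rad. Every
  anchor that does not depend on this coherence regime is reproduced (the
  -9.6 Hz intra peak, the 36% composition, the beat null near 55 ms, the
  near-zero 55 ms magnitude at g = 0.7 and its ~0.3 maximum at g = 0.98, the
  -6 Hz peak under chi_a = -70 ppb, the sign behavior of the isotropic-only
  variant). The acceptance output reports the computed value.
* **Beat-null non-monotonicity.** Magnitude(55 ms) rises with g across the
  demyelination sweep except possibly between g = 0.70 and ~0.74, where the
  beat null crosses the 55 ms echo and can produce a ~0.005 dip for some
  packing seeds. |phase(55 ms)| decreases strictly with g in every packing
  tested.
* **Isotropic-only phase at long TE.** With chi_a = 0, chi_i = -100 ppb the
  phase accrues positively while the myelin signal is alive (T2 = 15 ms) and
  the overall frequency distribution has a positive mean; by 55 ms a small
  collective intra-axonal offset (~ -0.4 Hz against the extra-axonal mean)
  pulls the unwrapped phase back to within ~0.1 rad of zero. The qualitative
  contrast with the anisotropic model (which accrues several radians of
  negative phase) is unambiguous.
* The model is 2D and exchange-free; oligodendrocytes, iron, unmyelinated
  axons and 3D undulation are not represented. Nonlocal (bulk) fields enter
  only through the uniform-offset hook.
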