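# wmgre

Forward simulation of the susceptibility-weighted multi-echo gradient-echo
(GRE) MR signal from two-dimensional white-matter microstructure.

## The problem

The GRE signal in white matter — both its magnitude decay (T2\*) and its
phase — is shaped by the magnetic susceptibility of myelin. Myelin is
diamagnetic relative to the surrounding water, and because its phospholipid
bilayers stack radially around each axon, its susceptibility is *anisotropic*:
a rank-2 tensor whose long axis points along the local bilayer normal. Models
that invert the GRE signal for microstructural quantities (myelin volume,
g-ratio, myelin susceptibility) have usually assumed axons are nested
circular cylinders. `wmgre` makes the geometric assumptions explicit and
testable: it generates axon cross-section geometries of increasing realism —
single circles and ellipses, random close packings of polydisperse circular
fibers, smoothly warped (elliptical) packings, irregular synthetic outlines,
or loaded segmentation rasters — and predicts the complex three-compartment
GRE signal for each, with and without water diffusion, including
demyelination sweeps in which the sheath is thinned from the inside out.

Intended users: MR physicists and microstructure modelers who want a
transparent, scriptable forward model for susceptibility-weighted white
matter signals.

## The model

1. **Geometry.** A label map assigns each pixel to extra-axonal water,
   intra-axonal water or myelin. The packed model draws outer fiber radii
   from a Gamma distribution (shape 5.7) with g-ratio 0.7 and realizes an
   extra-axonal volume fraction of 36% (myelin 0.32) on a periodic
   37 × 37 µm domain with 1434 fibers.
2. **Susceptibility tensor.** Each myelin pixel carries the hollow-cylinder
   tensor `diag(χi + χa, χi − χa/2, χi − χa/2)` (ppb; anisotropic part
   traceless, long axis radial), rotated about z by the local bilayer azimuth
   φ. Defaults: χi = −60 ppb, χa = −120 ppb; aqueous compartments are the
   zero-susceptibility reference.
3. **Field.** The off-resonance frequency map is the Fourier-domain tensor
   dipole solution on the k_z = 0 plane,

       Δf(r) = FT⁻¹{ (1/3) ĤᵀX(k)Ĥ − (Ĥᵀk)(kᵀX(k)Ĥ)/k² } · γ̄B₀,

   with Ĥ = [sin θ, 0, cos θ] and the DC bin zeroed. For a nested circular
   axon this reproduces the closed form
   `Δf_intra = (3/4) χa ln(1/g) sin²θ · γ̄B₀ · 1e−9` (−9.57 Hz at g = 0.7,
   7 T, θ = π/2).
4. **Signal.** Static magnetization:
   `S(t) = Σₙ ρₙ e^(−t/T2,n) Σ_pixels e^(i·2π·Δf·t)` over a central sampling
   mask, with T2 = 50/50/15 ms and ρ = 1/1/0.5 for extra/intra/myelin;
   magnitude normalized to S(0), phase temporally unwrapped. Diffusion:
   Monte Carlo random walk (D = 2 µm²/ms in water, myelin impermeable and
   immobile) accumulating per-spin phase.

## Worked example

A single myelinated axon (g = 0.7, outer radius 0.5 µm) perpendicular to a
7 T field:

```r
library(wmgre)

grid  <- grid_spec(1000, 6)                    # 1000 px over 6 um
axon  <- make_single_ellipse_axon(ellipse_spec(0), g = 0.7, grid = grid)
map   <- rasterize(axon, grid)
field <- forward_field(build_tensor_map(map, orientation_map(map)),
                       field_config(B0 = 7, theta = pi / 2))

compartment_histograms(field, map, sample_mask(grid, 0.5))$peaks
#> # A tibble: 3 × 4
#>   compartment peak_hz mean_hz n_pixels
#>   <chr>         <dbl>   <dbl>    <int>
#> 1 extra         -0.25 -0.0484   478228
#> 2 intra         -9.75 -9.57      10684
#> 3 myelin        26.2  13.5       11112

analytic_hollow_cylinder(0.7)   # closed-form intra-axonal shift
#> [1] -9.567948

signal <- static_signal(field, map)
glance(signal)
#> # A tibble: 1 × 5
#>   n_echoes t_max_ms magnitude_final phase_final_rad abs_phase_final_rad
#>      <int>    <dbl>           <dbl>           <dbl>               <dbl>
#> 1      100       55           0.297         -0.0128              0.0128
```

The intra-axonal water resonates 9.6 Hz below the extra-axonal reference —
the hollow-cylinder anisotropy shift — while myelin water spreads over a
broad, mostly positive band (humps near 0 and +26 Hz). The signal keeps 30%
of its magnitude at TE = 55 ms and, with only one axon in the field of view,
accrues little net phase. `autoplot(signal)`, `autoplot(field)` and
`autoplot(map)` plot the curves and maps.

Packed-model experiments are one call each:

```r
cfg <- experiment_config(seed = 1)          # 1434 fibers, 37 um, 2227 px
cmp <- run_geometry_comparison(cfg)         # circular / warped / irregular
swp <- run_demyelination_sweep(cfg)         # g = 0.70 ... 0.98
tidy(swp); glance(swp); autoplot(swp)
```

A thin command-line interface over the same functions lives in
`inst/cli/wmgre.R` (`pack`, `ellipse`, `erode`, `measure`, `field`,
`signal`, `sweep` subcommands).

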