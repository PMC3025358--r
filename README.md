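# winding3d

Detection, classification and subpixel localization of critical points in
3D scalar images — minima, 1-saddles, 2-saddles and maxima — via the
three-dimensional **winding number**, plus the two applications built on
it: counting blob-like structures (follicles in 3D ultrasound, labeled
cell bodies in confocal stacks) inside an optional mask, and sparse
critical-point **optic flow** for volume sequences such as tagged cardiac
MR, where tag crossings are intensity maxima and tag fading defeats
brightness-constancy methods.

## The statistic

Around a voxel, integrate over a closed cube surface the solid-angle
2-form of the normalized image-gradient map:

```
nu = ∮_S (∇L_i × ∇L_j) · ∇L / ‖∇L‖³ dxⁱ ∧ dxʲ = 4π k,  k ∈ ℤ
```

`k` is the topological degree of `x ↦ ∇L/‖∇L‖` on `S`: zero at regular
points, `sign(det H)` summed over enclosed nondegenerate critical points
otherwise — surface-independent and additive. The sign splits
{minimum, 2-saddle} (`+4π`) from {1-saddle, maximum} (`−4π`); the Hessian
index (number of negative eigenvalues: 0/1/2/3) completes the
classification. The default integrator normalizes the surface gradients
onto the unit sphere, triangulates the cube surface, and sums signed
spherical-triangle solid angles (stable two-argument arctangent formula),
so `k` is exact to float rounding; a literal 9-point face-sum quadrature is
also provided. Detected points are refined to subpixel accuracy by Newton
iteration `x ← x − H⁻¹∇L` on trilinearly interpolated Gaussian-derivative
jets, and velocities at tracked maxima follow from `V = −H⁻¹ ∂t(∇L)`.

All derivatives live in Gaussian scale space with the diffusion convention
`σ² = 2s` (a printed "scale 9" means `s = 9`, `σ ≈ 4.24` voxels; every
function also takes `sigma` directly).

## A worked example

```r
library(winding3d)

# Table of winding values: a 1-saddle sampled on a grid
v  <- quadratic_volume(c(1, 1, -1), size = 15)
j  <- gaussian_jet(v, s = 0.5)
winding_degree(j, attr(v, "center"))
#> $nu [1] -12.56637   # = -4*pi, exactly quantized
#> $k  [1] -1

# Detect and refine the maximum of an off-grid Gaussian bump
bf    <- blob_volume(matrix(c(11.3, 13.7, 10.5), 1), sigma = 2.5,
                     amplitude = 1, size = 32)
jet   <- gaussian_jet(bf$volume, s = 1)
field <- winding_field(jet)
field
#> <winding_field> 32x32x32 grid, mode = degree
#>   interior voxels: 27000 (ok 20792, flat 2366, unreliable 3842)
#>   candidate voxels (|k| >= threshold): 8
pts <- refine_critical_points(detect_critical_points(field, jet), jet)
subset(as.data.frame(pts), type == "maximum",
       select = c(x, y, z, k, rx, ry, rz, converged))
#>    x  y  z  k    rx    ry   rz converged
#> 1 11 14 10 -1 11.31 13.69 10.5      TRUE
```

The eight triggering voxels merge into one candidate; Newton refinement
recovers the true center (11.3, 13.7, 10.5) to within 0.01 voxels.

Counting and flow are one-liners over the same machinery:

```r
count_blobs(volume, s = 9, polarity = "minima", mask = mask)   # dark blobs
flow <- track_and_flow(read_sequence("frames/"), s = 3.5,
                       frame_range = 9:12, boundary_margin = 10)
```

A thin command-line wrapper with subcommands `detect`, `count`, `flow`,
`phantom` and `eval-aae` lives at `inst/cli/winding3d.R`; volumes are read
and written as NIfTI or multi-page TIFF, tables as CSV with 0-based
coordinates and a JSON sidecar recording the full run configuration.

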