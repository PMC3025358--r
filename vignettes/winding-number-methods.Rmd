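---
title: "Critical points of 3D images by the winding number: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical points of 3D images by the winding number: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winding3d)
```

## The model

A critical point of a smooth intensity function $L(x,y,z)$ is a point where
$\nabla L = 0$; it is nondegenerate when the Hessian $H = (\partial_i
\partial_j L)$ is invertible there. Around any voxel one can integrate, over
a closed oriented surface $S$, the 2-form built from the image gradient

$$\nu \;=\; \oint_S \frac{(\nabla L_i \times \nabla L_j)\cdot \nabla L}
{\lVert\nabla L\rVert^{3}} \; dx^i \wedge dx^j ,$$

where $\nabla L_i$ denotes the gradient of the $i$-th derivative image (the
$i$-th column of $H$). This is the pullback of the solid-angle form of the
unit sphere under the normalized gradient map $x \mapsto \nabla L /
\lVert\nabla L\rVert$, so $\nu = 4\pi k$ where the integer $k$ is the
topological degree of that map on $S$: $0$ when $S$ encloses no critical
point, and otherwise the sum of $\mathrm{sign}(\det H) = \pm 1$ over the
enclosed nondegenerate critical points. The quantity is independent of the
chosen surface and additive over enclosed singularities, which is what makes
it usable as a detector: a voxel is a candidate precisely when the cube
surface around it yields $k \neq 0$.

The four nondegenerate types are classified by the *index* (number of
negative Hessian eigenvalues): minimum (0), 1-saddle (1), 2-saddle (2),
maximum (3), with winding $+4\pi, -4\pi, +4\pi, -4\pi$ respectively. Note
that the winding sign alone separates {minimum, 2-saddle} from {1-saddle,
maximum}; the index (or an intensity comparison) resolves the rest.

**Normalization.** Derivations of the 2-form in the literature sometimes
carry an overall factor 2, under which a minimum would integrate to $8\pi$
while the classification tables and the divide-by-$4\pi$ quantization step
assume $\pm 4\pi$. This package uses the solid-angle normalization (no extra
factor), the unique convention under which the table values, the
$\nu = \mathrm{sign}(\det H)\,4\pi$ identity and the quantization rule are
mutually consistent. The choice is verified in the tests against sampled
quadratic forms.

## The two integrators

`winding_field()` evaluates $\nu$ on the $3^3$ cube around every interior
voxel in one of two modes.

**Degree mode** (default). The gradient vectors at the 26 surface voxels are
normalized onto the unit sphere, each cube face is split into 8 triangles
with consistent outward orientation, and $\nu$ is the sum of the 48 signed
spherical-triangle solid angles of the mapped vertices, each computed with
the numerically stable two-argument arctangent (van Oosterom–Strackee)
formula. The result is *exactly* $4\pi \times$ integer up to float rounding
(the tests require $10^{-9}$ relative accuracy on quadratic fixtures), and
is surface-independent by construction. This is the mode used by all
pipelines.

**Riemann mode.** The literal unit-weight $3\times 3$ sample sum of the full
integrand on the six faces (upper face minus lower face per axis pair), with
the position-dependent $1/\lVert\nabla L\rVert^3$ evaluated at every sample.
The nine unit-weight samples act as a midpoint rule on faces that extend
half a voxel *beyond* the closed cube, so the magnitude at an isolated
critical point systematically exceeds $4\pi$ (about $1.52\times 4\pi$ for an
isotropic quadratic; the tests pin this against a dense quadrature of the
same over-extended faces). The sign is still reliable, and candidates are
taken at $|\nu|/4\pi > 1/2$. The mode is retained for fidelity to the
classical face-sum formulation and as a cross-check.

Voxels whose entire cube surface carries gradients below a floor
($10^{-12}\times$ the volume's maximum gradient magnitude; gradients at the
round-off level of the intensity scale count as zero) are flagged `flat`;
voxels with some sub-floor samples or degenerate mapped triangles are
flagged `unreliable` and never become candidates.

## Scale space

All derivatives are Gaussian-derivative convolutions at a fixed scale. The
scale parameter follows the diffusion convention: kernel variance
$\sigma^2 = 2s$. Printed scales such as "scale 9" are interpreted as $s$
(so $\sigma = \sqrt{18} \approx 4.24$ voxels); every user-facing function
also accepts `sigma` directly for the alternative reading. Kernels are
sampled at integer offsets, truncated at $4\sigma$, and moment-corrected:
unit mass (order 0), zero mass / unit first moment (order 1), zero mass and
first moment / second moment 2 (order 2). With these corrections the jets
are *exact* on quadratic polynomials in the deep interior, which is what
makes the winding table and one-step Newton tests exact rather than
approximate. Boundaries are handled by symmetric reflection; convolution
along an axis is applied as a dense banded operator through BLAS.

The scale-normalized Laplacian used for blob enhancement is
$2s\,(L_{xx}+L_{yy}+L_{zz})$. For a unit-amplitude Gaussian blob of
standard deviation $\sigma_b$ the center response magnitude is maximized at
kernel variance $2s = \tfrac{2}{3}\sigma_b^2$, i.e. $s^* = \sigma_b^2/3$ —
the 3D analogue of the familiar 2D result $t^* = \sigma_b^2$ (the often
quoted $\sigma = \sigma_b$ optimum is the 2D case; the tests assert the 3D
closed form).

## Detection, deduplication, refinement

A nondegenerate critical point typically triggers a small cluster of
adjacent voxels. Candidates are merged by 26-connected clustering, but only
among voxels that agree in winding sign *and* Hessian index: plain
connectivity clustering collapses physically distinct critical points as
soon as their trigger clusters touch (at small scales on noisy data, tens
of thousands of candidate voxels can chain into a single component). The
cluster representative maximizes $|\nu|$ *after rounding to the $4\pi$
quantum* — in degree mode all members tie exactly, deliberately deferring to
the tie-breaks (smallest gradient magnitude, then lexicographic index),
which select the voxel nearest the true zero of the gradient.

Subpixel refinement iterates the Newton update $x \leftarrow x - H^{-1}
\nabla L$ with gradient and Hessian interpolated trilinearly between voxels
(max 10 iterations, step tolerance $10^{-3}$ voxels by default). Trilinear
interpolation is exact for fields that are linear per axis, so on an exactly
quadratic intensity the first step lands on the optimum. Points with a
singular or ill-conditioned Hessian (condition number $> 10^8$) keep their
voxel position with a degenerate flag; points whose total displacement
exceeds 2 voxels are flagged divergent and reset — refinement never walks
into a neighboring basin.

Classification defaults to the eigenvalue rule (index $\to$ type) with the
winding sign cross-checked against $\mathrm{sign}(\det H)$; a mismatch flags
the point rather than dropping it. An alternative intensity mode uses only
the winding sign plus a comparison of the center against the mean of its 26
neighbors; the neighborhood statistic is not canonical, which is why the
eigenvalue rule is the default.

## Blob counting

`count_blobs()` chains enhancement (optional) → jet → degree-mode winding
field → detection → polarity filter → mask filter → refinement. Two
properties matter in practice:

* **Scale trade-off.** Too small a scale detects intensity grains: on the
  15-blob noisy test volume, $s = 1.5$ yields over a thousand minima while
  the matched scale $s = \sigma_b^2/2$ yields each true blob exactly once.
  Matching the smoothing sigma to the blob sigma is a good default.
* **False positives outside structures are expected.** With no contrast
  threshold (none is applied by default), genuine minima of the smoothed
  noise field appear in structure-free regions — on the noisy fixture, the
  unmasked count at matched scale is ~24 for 15 true blobs, all 15 of which
  are recovered to within 0.03 voxels. This is precisely why the pipeline
  takes a mask: restricting to the tissue of interest removes them, and the
  masked count equals the number of masked blobs exactly in the tests. An
  optional `min_contrast` filter is available for maskless use.

With `enhance = TRUE` the polarity refers to the *enhanced* volume: bright
blobs give negative Laplacian response and are counted as minima. Detection
after enhancement runs at the same scale as the enhancement itself (the
operation order is not canonical; one scale for both is this package's
choice).

The 26-neighbor strict-comparison extremum detector (`local_extrema_26()`)
is included as the classical baseline; on clean, well-separated blobs it
selects exactly the same voxels as the winding detector (asserted in the
tests), but it cannot see saddles and offers no reliability flags.

## Critical-point optic flow

For an image sequence, differentiating $\nabla L(x(t), t) = 0$ along the
trajectory of a tracked critical point gives

$$V = -H^{-1}\,\partial_t(\nabla L),$$

evaluated here with central temporal differences
$(\nabla L(t{+}1) - \nabla L(t{-}1))/2$ and trilinear interpolation at the
refined maxima of each frame; the linear system is solved directly. The
estimator needs no brightness constancy: a global intensity modulation
$A(t)$ (tag fading under $T_1$ relaxation) scales $H$ by $A(t)$ and adds
$A'(t)\nabla L$ to the temporal term, which vanishes at a critical point.
With discrete central differences the cancellation is exact only to first
order — a residual factor $\cosh(\Delta t/T_1)$ remains on the speed, below
$10^{-3}$ for physiological ratios ($T_1 \approx 25$ frame intervals for
30 ms frames), and the tests assert invariance at that level. A related
discretization limit: for a tag pattern of period $\lambda$ translating at
$v$ voxels/frame, the central difference attenuates the estimate by exactly
$\operatorname{sinc}(2\pi v/\lambda)$ — negligible at $v \lesssim 0.5$
(error 0.013 at $v = 0.5$, $\lambda = 8$), but ~10% at a full voxel per
frame. The tests assert sub-0.05 recovery at moderate speeds and the exact
attenuation factor at $v = 1$.

Frames at the sequence ends have no central difference and are excluded;
samples within a boundary margin (default 10 voxels) of any face are
discarded because the reflected boundary distorts the jets there.

## The phantom

The accuracy benchmark is a fully synthetic expanding-contracting tag
phantom: base pattern $P(u) = \sum_i \cos(2\pi u_i/\lambda)$ (a 3D
chessboard whose maxima are the tag crossings, on the lattice
$c + \lambda\mathbb{Z}^3$), radially scaled about the center $c = (l,l,l)$
by $\sigma(t) = (l + mt - nt^2)/l$. This scaling is the unique radial warp
whose material velocity field equals the closed form

$$V_{GT}(x,t) = \frac{m - 2nt}{l + (m - nt)t}\,(x - c),$$

(solve $\dot r = \frac{m-2nt}{l+mt-nt^2}\, r$), so the ground truth is
exact by construction, and the scaled pattern is evaluated analytically per
frame — no interpolation error enters the generation. Defaults: $79^3$
voxels, 19 frames, $\lambda = 9$ (the printed tag width read as the pattern
period; pass $2\times$ for the half-period reading), $l, m, n = 40, 4, 0.2$.
Times run $t = 0..18$; the field is zero everywhere at $t = m/2n = 10$, so
that frame contributes only excluded samples to angular-error statistics.

**What passing this benchmark does and does not show.** Because the phantom
is exactly self-consistent and smoothing a cosine is again a cosine (maxima
do not shift), the only remaining error sources are trilinear interpolation
and the $O(\Delta t^2)$ temporal differencing. The measured accuracy of the
flow pipeline on this phantom (scale $s = 3.5$, frames $t = 8..11$,
10-voxel margin; run by `scripts/acceptance.R`) is a mean angular error of
about $0.02°$ (sd $\approx 0.03°$, $n = 372$). Published results for this
kind of experiment report angular errors of a few degrees; those numbers
include phantom-generation error from resampled or interpolated intensity
patterns, which this generator deliberately avoids. The benchmark therefore
validates the estimator, not the difficulty of any particular historical
phantom. Conversely, none of this exercises real tagged-MRI effects —
noise, through-plane inconsistency, tag fading beyond a global exponential,
non-polynomial motion — so phantom accuracy is an upper bound on real-data
accuracy.

Angular error between estimate and truth is
$\arccos(\hat V_{GT}\cdot\hat V)$ in degrees, aggregated as mean (AAE) and
standard deviation over all valid samples; vectors with norm below
$10^{-8}$ are excluded and counted.

## Numerical choices, in one place

| Quantity | Default | Rationale |
|---|---|---|
| kernel truncation | $4\sigma$ | $<10^{-7}$ tail mass |
| gradient floor | $10^{-12} \max\lVert\nabla L\rVert$ | division guard only; round-off gradients treated as zero |
| candidate rule | $|k| \geq 1$ (degree), $|\nu|/4\pi > 1/2$ (Riemann) | degree is exactly quantized |
| Newton | 10 iterations, tol $10^{-3}$ vox, cap 2 vox | converges in 1–3 steps in practice |
| Hessian condition cap | $10^8$ | beyond this the velocity solve is meaningless |
| degenerate eigenvalue | $|\lambda| < 10^{-6} \max|\lambda|$ | relative, scale-free |
| boundary margin (flow) | 10 voxels | kernel halfwidth at $s = 3.5$ is 11 |

Problem sizes used by the test-suite and the acceptance script: quadratic
fixtures $7^3$–$21^3$, blob volumes $64^3$ with 15 blobs, flow sequences
$40^3\times 5$, and one full $79^3\times 19$ phantom run; together they
complete in a few minutes on one CPU.

## Known limitations

* Isotropic voxels are assumed throughout; anisotropic spacing must be
  resampled beforehand.
* Degenerate (catastrophe) critical points are flagged, not analyzed.
* The flow is sparse (velocities only at maxima); no interpolation to a
  dense field is provided.
* Plateaus produce no detection in the 26-neighbor baseline (strict
  comparisons) and `flat` flags in the winding field.
* The intensity-mode classifier's 26-neighbor-mean statistic is a
  pragmatic choice; prefer the default eigenvalue rule.

## A worked example

```{r example}
bf <- blob_volume(matrix(c(11.3, 13.7, 10.5), 1), sigma = 2.5,
                  amplitude = 1, size = 32L)
jet <- gaussian_jet(bf$volume, s = 1)
field <- winding_field(jet)
pts <- refine_critical_points(detect_critical_points(field, jet), jet)
subset(as.data.frame(pts), type == "maximum",
       select = c(x, y, z, k, rx, ry, rz, converged))
```

The detected voxel is (11, 14, 10) (1-based); refinement returns the
continuum optimum to within $10^{-2}$ voxels of the true center
(11.3, 13.7, 10.5).
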