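---
title: "Blurred palmprint verification with structure-layer WRHOG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blurred palmprint verification with structure-layer WRHOG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vowrhog)
```

## The problem

Palmprints captured by non-contact devices are routinely defocused, and
defocus destroys exactly the fine ridge texture that most palmprint
matchers rely on. `vowrhog` implements a verification pipeline built
around the observation that an image's *structure layer* — the
cartoon-like component of a Meyer-type structure/texture decomposition —
is far less sensitive to blur than the raw pixels, so features extracted
from it remain comparable across blur levels.

The pipeline is:

1. (optionally) simulate defocus with a Gaussian point-spread function,
2. split the ROI into structure layer $u$ and texture layer $v$ with a
   Vese–Osher (VO) decomposition,
3. describe $u$ with a blockwise, rotation-invariant, magnitude-weighted
   orientation histogram whose blocks are re-weighted by their fractal
   dimension (the WRHOG feature),
4. match feature vectors with the normalized correlation coefficient
   (NCC) and evaluate FAR/FRR/EER and the decidability index.

Everything runs on synthetic ridge-textured ROIs produced by the
package's own generator, so no external database is needed.

## Blur model and sharpness

Defocus is modeled as $g = h_\sigma * f + n$ with an isotropic Gaussian
$h_\sigma$ (`gaussian_psf()`, `apply_gddm()`). The kernel is truncated at
radius $\lceil 3\sigma\rceil$ and renormalized (less than 0.3% of mass is
lost before renormalization); convolution uses mirrored edges so the
frame of the image does not darken. Sharpness is quantified by the
Roberts gradient energy (`rge()`), the sum of squared Roberts-cross
differences over all $2\times2$ neighborhoods. RGE decreases
monotonically in $\sigma$; because Gaussian blur keeps attenuating every
non-constant component, RGE tends to zero rather than to a positive
constant, so the well-known "plateau" past $\sigma \approx 10$ is a
statement about the RGE *curve plotted at the scale of the sharp image*:
between $\sigma = 10$ and $\sigma = 15$ the change is below 1% of the
sharp image's RGE, although the self-relative change remains large. The
package's tests encode the plateau in that curve-scale form.

## The Vese–Osher decomposition

With $p = 1$ the VO energy minimized here is

$$E(u, g_1, g_2) = \sum \sqrt{|\nabla u|^2 + \varepsilon^2}
  \;+\; \lambda \lVert f - u - \operatorname{div} g\rVert_2^2
  \;+\; \mu \sum \sqrt{g_1^2 + g_2^2 + \varepsilon^2},$$

where the texture layer is $v = \operatorname{div} g$. Gradients use
forward differences with replicated edges (homogeneous Neumann), the
divergence uses the matching backward differences, and
$\varepsilon = 10^{-4}$ regularizes both square roots — including the
$\mu$-term, which makes the half-quadratic majorization argument exact:
each outer iteration (one Gauss–Seidel sweep for $u$ with the TV
diffusivity lagged, then coordinate-descent sweeps for $g_1$ and $g_2$
with the $|g|$ weight lagged) minimizes a convex majorizer, so the energy
trace is non-increasing by construction, and the tests assert it.
Iteration stops when the relative $L_2$ change of $u$ falls below `tol`
(default $10^{-3}$) or after `max_outer` (default 100) iterations; a
non-converged run is flagged, not an error.

**Parameter defaults.** The image is normalized to $[0,1]$ internally.
On that scale the defaults are $\lambda = 5$ and $\mu = 0.01$. $\lambda$
controls how tightly $f \approx u + v$ must hold: with a weak fidelity
term most of the signal lands in the residual and the decomposition
separates nothing, whereas $\lambda = 5$ recovers more than half of a
period-4, amplitude-20 sinusoidal texture into $v$ while leaving a
piecewise-constant cartoon in $u$. $\mu$ prices oscillation in $g$:
ridge-scale texture (a few pixels period) is much cheaper to represent
in $g$ than in $u$'s total variation, while step edges are much cheaper
in $u$, which is precisely the structure/texture split. Both parameters
are exposed in `vo_params()`.

Degenerate inputs behave sensibly: a constant image is returned exactly
as its own structure layer with $v \equiv 0$, and adding a constant gray
offset shifts $u$ and leaves $v$ unchanged (the update equations are
shift-equivariant; with a fixed iteration count the equivariance is
exact to machine precision).

## The WRHOG descriptor

**HOG.** Gradients come from the $[-1, 0, 1]$ mask; orientation is the
full-circle gradient vector orientation $\operatorname{atan2}(G_y, G_x)$
mapped to $[0, 2\pi)$, with $+x$ = increasing column, $+y$ = increasing
row. Histograms have $N$ hard-assigned half-open bins (no vote
interpolation), each pixel voting its magnitude; histograms are
$L_1$-normalized, with all-zero accumulations left at zero. Vote mass
below $10^{-9}$ gray levels is treated as interpolation round-off from
flat patches and also left at zero.

**RIGO/RIHOG.** Around each pixel, $K = 8$ points are sampled on a
radius-$r = 2$ circle. At each sample point a local frame is set with
its $x$-axis along the outward ray, and the gradient there is estimated
by unit-step central differences of bilinearly interpolated gray values
along the local axes. Each pixel therefore contributes $K$
(magnitude, local-angle) votes. Because the frames are carried along
with any rotation about the pixel, the histogram is exactly invariant to
$90°/180°/270°$ grid rotations and approximately invariant to small
continuous rotations of band-limited textures.

A limitation worth stating plainly: measuring angles *relative to the
radial direction* discards the block's absolute ridge orientation. For a
perfectly oriented sinusoidal texture the $K$ votes are rotated copies
of one another, so a small rotation shifts the whole histogram exactly
as it shifts a plain HOG, and the descriptor's robustness advantage
comes instead from the angular smearing contributed by orientation
diversity inside the block. On isotropic band-limited textures RIHOG is
more stable than HOG on essentially every fixture; on strongly oriented
ridge textures the advantage holds at the blockwise-descriptor level
(where it is tested) but the loss of absolute orientation also costs
discriminability — see "Known limitations" below.

**RHOG and WRHOG.** The image is tiled by non-overlapping $b \times b$
blocks ($b = 16$ by default, $N = 12$ bins; trailing remainder
rows/columns are dropped so all blocks are full-sized). Each block's
RIHOG is computed from the block's own pixels only (votes whose sampling
neighborhood crosses the block edge are dropped), so blocks are
independent and permuting input blocks permutes feature segments. WRHOG
multiplies each block's normalized histogram by the block's differential
box-counting (DBC) fractal dimension computed on the same layer, giving
rough, texture-rich blocks more weight in the match.

**DBC fractal dimension.** At grid scale $s$ (defaults: the power-of-two
divisors of $b$ in $[2, b/2]$, i.e. $\{2, 4, 8\}$ for $b = 16$), the
gray surface over each $s \times s$ cell is covered by boxes of height
$s \cdot G / M$ ($G = 256$ gray levels), counting
$\lfloor l_{\max}/s'\rfloor - \lfloor l_{\min}/s'\rfloor + 1$ boxes per
cell; $D$ is the least-squares slope of $\log N_s$ against
$\log(M/s)$. A flat block gives exactly $D = 2$; i.i.d. noise
approaches 3. $D$ is computed on the descriptor's input layer (the
structure layer in the full pipeline), consistent with the pipeline
order.

## Matching and evaluation

NCC is the Pearson correlation with population (divide-by-$n$) standard
deviations; the decidability index
$d = |\mu_g - \mu_i| / \sqrt{(\sigma_g^2 + \sigma_i^2)/2}$ uses the same
convention. A zero-variance feature vector scores 0 with a warning.
Verification accepts a comparison when its score is at least the
threshold (ties accept). The threshold grid for FAR/FRR curves is every
distinct observed score plus $\pm\infty$ sentinels, so the curves hit
every attainable operating point; the EER is read off at the FAR/FRR
crossing by linear interpolation between the two bracketing thresholds.

## The synthetic ROI generator

`make_identity()` builds an identity as a quasi-periodic ridge pattern
$\cos(2\pi f \psi)$ whose phase field $\psi$ is a random base direction
plus a smooth warp (low-pass filtered white noise, a few pixels of phase
displacement), darkened by 2–3 principal lines drawn as quadratic Bézier
curves with Gaussian cross-profiles (depth 40–80 gray levels, width 3–5
px). Ridge frequency is drawn from $[0.1, 0.25]$ cycles/pixel, amplitude
from $[25, 45]$. Templates render on a padded canvas so sample rotation
never imports border artifacts into the cropped ROI.

`render_sample()` models residual capture misalignment (rotation within
$\pm3°$, integer shifts within $\pm2$ px) plus Gaussian defocus and
optional noise. `make_database()` mirrors a two-session protocol:
gallery samples are mildly degraded (blur $\sigma \sim U[0.5, 1.5]$,
rotation $U[-1.5, 1.5]°$, shifts in $[-1, 1]$ — chosen once as a
realistic first-session capture), probe samples carry the test
degradation (blur $\sigma \sim U[1, 7]$ by default, the full
misalignment ranges). Everything is bit-reproducible from the master
seed.

What the generator does *not* emulate: real palm anatomy (creases,
minutiae, pore texture), illumination variation, perspective distortion,
or sensor noise statistics. Passing tests on this data demonstrate that
the pipeline's mathematics behaves as designed — blur stability of the
structure layer, rotation invariance of the descriptor, the ranking of
descriptor variants under controlled degradation — not that the specific
error rates would transfer to any real database.

## Experiment sizes and numerical choices

The test suite and the acceptance script run the full experiment at desk
scale: 50 identities with 5 gallery + 5 probe images each (62 500
matches per descriptor arm), structure-stability sweeps over 10–20
identities at blur $\sigma \in \{1,\dots,7\}$, and 50-fixture
rotation-robustness panels — sizes chosen so the whole suite runs in
minutes while keeping the score distributions dense enough for stable
EER estimates. Solver tolerances and the histogram round-off floor are
stated above; ties in the accept decision count as accepts; degenerate
regressions (a single DBC scale) and empty score sets raise validation
errors rather than returning NaN.

## Known limitations

* The RIGO realization is one canonical reading of a construction whose
  defining equations are not fully recoverable; it satisfies exact
  90°-rotation invariance and the radial-frame symmetry properties, but
  its relative-angle histogram trades absolute orientation information
  for that invariance. On blur-dominated synthetic probes this costs
  RHOG discriminability relative to plain HOG even though it is the more
  rotation-robust descriptor; the structure-layer and fractal-weighting
  stages still improve every variant they are added to, and the full
  VO–WRHOG pipeline remains the strongest VO arm.
* EER estimates on small synthetic databases carry Monte-Carlo noise of
  a few tenths of a percent; ordering claims are therefore evaluated
  across several master seeds by majority.
* The CLI is a thin wrapper (`inst/cli/vowrhog.R`) intended for batch
  use of the exported functions, not a daemonized verification service.
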