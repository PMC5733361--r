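---
title: "Pointwise stimulus synthesis: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pointwise stimulus synthesis: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimsyn)
```

`stimsyn` renders visual stimulus movies by evaluating formulas at every
pixel of every frame.  This vignette records the models behind each
component family, the conventions the package fixes where several were
defensible, and the numerical choices a careful user should know about.

## Coordinates, time, and the frame model

A frame is an `height_px x width_px x 3` array of linear-light RGB
intensities, nominally in the unit interval (filtering may push values
outside it; tone mapping brings them back before quantization).  Pixel
`(i, j)` (1-based row/column) samples the continuous point
`((j - 0.5) * um_per_px, (i - 0.5) * um_per_px)` with the origin at the
field's top-left — pixel *centers*, one sample per pixel.  Anti-aliasing is
provided only through soft shape edges (below), never by supersampling.

The frame at index `t` represents the interval beginning at
`t / frame_rate_hz` seconds; all time-dependent components are evaluated
at that onset time.  Whether a frame should be sampled at its onset or
midpoint is a genuinely open convention; onset sampling was chosen because
it makes event-log times (`frame / rate`) and modulation values coincide
exactly, which matters when aligning spike trains to stimulus phase.

Intensities stay in double precision through the whole pipeline;
quantization (to 16 bits, round-half-away-from-zero) happens only at file
write.

## Shapes and soft membership

Shapes are implicit regions.  Each has a signed distance `d` (negative
inside), and membership is

* `edge_width = 0`: hard, `m = [d <= 0]`;
* `edge_width = e > 0`: a cubic smoothstep ramp of total width `e`
  centered on the contour, so `m = 0.5` exactly on the boundary.

`edge_width` shares the coordinate units (micrometers when `um_per_px`
is physical).  Polygons use the even-odd rule on pixel centers, which
resolves self-intersections without error; Bezier regions are flattened to
polygons at a fixed chord tolerance of 0.25 px before testing.  The
rectangle distance is the standard exact box SDF, so soft edges remain
round at corners.  Fuzzy set operations on memberships (`pmax`, `pmin`,
`1 - m`) satisfy the De Morgan identities exactly because they never leave
`[0, 1]`.

`grid_points` repeats a base shape at lattice, random, or explicit
vertices and combines overlapping copies by maximum — the natural
combinator for memberships (union).  Hexagonal lattices put odd rows
(0-based) at a half-spacing offset with vertical pitch
`spacing * sqrt(3) / 2`.

## Patterns

Gratings follow `mean + amplitude * sin(2π f (x cosθ + y sinθ) + phase)`;
square gratings threshold the same phase, with the tie `sin = 0` assigned
to the high level so the output is deterministic.  The constructor rejects
`amplitude > min(mean, 1 - mean)`, keeping gratings displayable without
clipping.

The frequency/contrast chart interpolates its spatial frequency
geometrically (log-linearly) along `x` using the *integrated* phase of the
sweep — so the pattern is a smooth spatial chirp, not a sequence of
locally-resampled gratings — and its contrast geometrically along `y`.
A zero contrast endpoint makes the geometric form undefined, so the
contrast gradient falls back to linear interpolation when an endpoint is
non-positive; the zero-contrast edge is then exactly mid-gray.

Image primers map container integers linearly to `[0, 1]` and sample
bilinearly.  No sRGB decoding is applied: assets are assumed linear-light,
which is the correct convention when the display chain is gamma-compensated
by the package itself.  Supplying display-referred (sRGB) images without
accounting for this is the user's responsibility.

## Motion, modulation, warps

Linear motion takes either a velocity or a crossing time; in the latter
case speed is `(field extent along the direction + shape_extent) /
crossing_time`, so the shape enters on one side and has fully left on the
other when the time elapses.  Free-form paths are piecewise cubic Hermite
through `(time, position, velocity)` control points — they pass through
every control point exactly — and clamp to the endpoint positions outside
the time range.  Random shake superimposes per-frame uniform offsets in
`[-A, A]^2` from a dedicated xorshift stream; uniform (not Gaussian) was
chosen for bounded excursions, and the stream is separate from checkerboard
noise so decorating a stimulus with shake never changes its noise sequence.
Amplitude zero is special-cased to exact zeros.

Modulations multiply a primer's intensity (they do not interpolate toward
a background color; mixing under a mask covers that use case).  The sine
and square modulations sweep amplitude linearly and frequency as a
continuous-phase linear chirp, `φ(t) = 2π (f₀ t + (f₁ − f₀) t² / 2D)` over
duration `D` — integrated phase, so the waveform has no discontinuities as
the frequency changes.  Multi-component synthesis normalizes by the sum of
amplitudes and shifts into `[0, 1]`.  All modulation outputs are clamped.

Warps remap coordinates *before* motion is applied (evaluation order:
warp, then motion offset, then primer, then modulation scaling — fixed and
documented, since permuting it changes output).  The pinch-twist warp is
this package's construction: inside radius `R`, rotation by
`twist · (1 − r/R)²` and radial rescaling `r → (r/R)^strength · R`,
identity at and beyond the rim (continuous).  Custom warps accept a
function or a coarse rectangular lookup table interpolated bilinearly.

## Grid noise

The xorshift128 generator uses the classic reference companion constants,
so `seed_state(123456789)` reproduces the published test state and any
independent transliteration can verify the stream word-for-word (the test
suite does exactly that).  A zero seed remaps to 1 to respect the
never-all-zero invariant.  Grids fill row-major — a deliberately
unambiguous sequential contract, in place of the original idea of
generating cells in parallel, so the same stream can be regenerated by
analysis code in any language.  Shifted grids translate the existing words
and draw fresh ones only for the vacated border cells, again in row-major
order over the vacated region; the draw count equals the vacated area
exactly, which the tests assert by stream-position accounting.

Words map to the unit interval as `u = word / 2^32` (half-open).  Binary
checkerboards threshold at `u >= 0.5`, grayscale maps linearly, color uses
three independent streams seeded `seed`, `seed + 1`, `seed + 2`.  Exported
text (`frame k rows r cols c` header plus one line per row) round-trips
losslessly.

## Spatial filtering

Spatial kernels are materialized at a 4-sigma truncation radius (odd
sizes).  The Gaussian is normalized to unit sum.  The
difference-of-Gaussians subtracts a surround Gaussian rescaled so the
discrete sum is *exactly* zero, making it a true zero-integral band-pass:
homogeneous regions map to zero, and values beyond `[0, 1]` around edges
are expected and handled by renorm tone mapping.

Boundary handling is zero padding for linear convolution.  This is a
choice, not a theorem — it means a DoG output is nonzero within one kernel
radius of the frame border even on constant input; tests and measurements
therefore distinguish interior from rim.  `convolve_fft` computes the
mathematically identical zero-padded linear convolution via a padded FFT
(oracle-tested against the direct path at 1e-10), while
frequency-*specified* kernels (low/high/band-pass, custom transfer
functions of signed frequency in cycles/pixel) multiply the frame's
spectrum directly and therefore have cyclic boundary semantics — there is
no spatial support to pad with.  The two semantics are intentionally not
hidden from the user.  Filtering acts per RGB channel, not on luminance,
so colored inputs stay colored.

Median filtering (odd windows, edge-replicated borders) is the one
nonlinear spatial filter shipped.

## Temporal filtering

Pixel values across frames are discrete-time signals; only past frames
enter a filter (a filter that "needs" future frames is realized by adding
a presentation delay).  Frames before the stimulus start are zeros by
default; a `hold` option replicates the first frame instead, for filters
that should start in steady state.  Window kernels (rectangular,
triangular, Hamming, Hann) are unit-sum; exponential attenuation `a^k` is
left unnormalized so a unit step converges to `1/(1-a)`; the biphasic
"cell" kernel (difference of two temporal Gaussians, a positive lobe then
a negative lobe — the usual coarse model of a retinal cell's impulse
response) is rescaled to exactly zero sum.

The recursive LTI form keeps per-pixel complex states `s_j` with
`y = d·x + Σ Re(s_j)`, `s_j ← z_j (s_j + c_j x)` — constant memory per
pixel regardless of effective kernel length.  Its impulse response is
`h₀ = d` and `h_k = Σ Re(c_j z_j^k)` for `k ≥ 1`; `fit_exponentials`
accordingly fits taps 1 onward by Prony's method (least-squares linear
prediction for the poles, a linear solve for the coefficients) and absorbs
tap 0 into the direct term, so representable kernels are reproduced
exactly.  Fitted poles on or outside the unit circle are rejected with an
error rather than silently stabilized: a constant (rectangular) kernel,
for instance, drives the prediction pole to exactly 1, and shipping an
unstable recursion would corrupt long renders.

## Tone mapping, statistics, gamma

Histogram measurement covers at least `[0, 1]` and reports mass below 0
and above 1 separately, since post-filtering frames legitimately exceed
the displayable range.  Tone maps are monotone:

* stretch `(v − lo)/(hi − lo)` clamped (bounds explicit or measured);
* sigmoid `1/(1 + exp(−slope (v − center)))`;
* equalization through an *interpolated* (piecewise-linear) CDF.  The
  classic per-bin staircase quantizes output to at most `n_bins` levels,
  which cannot flatten a histogram at the same resolution; the continuous
  CDF reduces to the discrete formula at bin edges and maps a strictly
  increasing ramp to an exactly uniform output.  A single occupied bin
  degenerates to the identity (avoiding 0/0);
* renorm, the unique affine map sending the measured `[min, max]` to
  `[0, 1]` — after zero-integral filtering this is what turns flat (zero)
  regions into mid-gray.

Every tone map can be dynamic (re-measured per frame) or static (one
global mapping).  Static mapping requires global statistics, which
`run_sequence` obtains with a measurement prepass: the stimulus is
rendered once up to the static stage, measured, then rendered for real.
On a single-frame stimulus the two modes coincide exactly.

Frame statistics use luminance = unweighted channel mean (computation is
in linear RGB; Rec. 709 weighting can be applied by the caller to the
channels first if desired).  Michelson contrast `(Lmax − Lmin)/(Lmax +
Lmin)` and RMS contrast `sd(L)/mean(L)` use the population standard
deviation (a frame is the full pixel population); entropy uses 256 equal
luminance bins.  Per-frame values are reported individually and can be
averaged over a stimulus by the caller; the package does not presume which
summary an analysis wants.

Gamma compensation interpolates the measured (input, luminance) photometer
samples piecewise-linearly and tabulates the compensation at the
device-curve values of a uniform *input* grid (plus the sample nodes).
This makes the tabulated compensation the exact functional inverse of the
interpolated device curve — composing the two is the identity to float
precision — whereas a table uniform in luminance loses accuracy badly where
power-law curves are steep near zero.  Accuracy against the *true* device
curve is then limited only by the photometer sampling density (256 samples
of a square-law device give ~3e-4 worst-case error).

## Sequences, events, determinism

A sequence concatenates stimuli under one geometry and one global seed.
Each stimulus gets a fresh render context (PRNG state, temporal state,
frame cursor); stateful stimuli must be rendered sequentially from frame 0,
which the context enforces.  The `stim` channel rises on each stimulus's
first frame and falls on its last; one `stop` pulse marks the final frame.
Event times are computed as `frame / rate` directly from the index — no
accumulation, hence no drift.  The per-frame render-time budget report
(wall time vs `1/rate`) is informational only and never alters output.

Determinism is a contract: identical configuration + seed produce
byte-identical outputs, verified end-to-end by double-rendering the
shipped demo configuration and comparing file checksums.  All randomness
(grid noise, shake, random layouts) flows from explicit seeds through the
package's own generator; nothing touches R's global RNG at render time.

## What the built-in test material does and does not show

The test and acceptance material is synthetic by design — constant frames,
ramps, random fields from seeded generators, closed-form kernels — because
the engine's claims are exact mathematical properties (oracle equivalence,
zero integrals, frame-index arithmetic, bit-reproducibility), not
statistical fits.  Problem sizes were chosen to exercise every code path
at comfortable margins: 1e5-word PRNG cross-checks against an independent
transliteration (1e6 for distributional sanity), 50 random frame/kernel
pairs up to 48x48 with kernels up to 11x11 for the FFT oracle, 100 frames
of 16x16 for LTI equivalence, 256x256 ramps for equalization, a 45-frame
demo sequence for the checksum test, and 5,000 shapes on a 256x256 field
for the many-shape stress case.  Passing them demonstrates correctness of
the machinery, not perceptual adequacy of any particular stimulus on any
particular display — gamma samples, physical pixel pitch and frame rate
must still describe the real apparatus.

## Known limitations

* Real-time display, vertical-sync/frame-drop hardware detection, GPU
  execution, 3D/VR content and hardware voltage output are out of scope.
* Frequency-domain kernels are cyclic; spatial kernels are zero-padded —
  mixing the two on the same stimulus produces (documented) different rim
  behavior.
* Median filtering is O(window²) per pixel in plain R; very large windows
  on large fields are slow.
* Vector-graphics shape import is limited to explicit vertex / Bezier
  control-point lists.
* Video containers are not decoded; natural-movie primers take directories
  of numbered PNG frames (pre-conversion is assumed).
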