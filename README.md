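# stimsyn

Offline, deterministic synthesis of visual stimulus movies for retina
physiology, optogenetics, and psychophysics.

Experiments on the visual system need light patterns with precise spatial
and temporal structure: drifting bars and gratings, flickering random
checkerboards for white-noise receptive-field mapping, filtered natural
images, intensity ramps with frame-accurate onset markers.  `stimsyn`
builds such movies from small, composable **stimulus building components
(SBCs)** — shapes, patterns, motions, modulations, warps, filters, tone
maps — and renders them *pointwise*: every pixel of every frame is the
value of a formula evaluated at that pixel's center, rather than a
rasterized polygon.  That makes set operations on shapes, soft (fuzzy)
edges, per-pixel masking and nonlinear coordinate warps all trivial to
combine, and makes output bit-reproducible from a seed.

## The model in brief

A stimulus is an ordered component list.  Each frame at index `t`
(time `t / f` seconds at frame rate `f`) is produced in three phases:

1. **Prerequisites** — the xorshift128 grid generator advances: a
   `rows x cols` array of 32-bit words is refreshed (or translated, with
   fresh draws only in the vacated border cells) per frame.  The update is
   `t = x ^ (x << 11); t ^= t >> 8; (x,y,z,w) <- (y, z, w, (w ^ (w >> 19)) ^ t)`,
   so the whole noise stream is a pure function of the seed and can be
   exported as text for system-identification analysis (spike-triggered
   averaging etc.).
2. **Core rendering** — shape primers evaluate a membership
   `m(x, y) ∈ [0, 1]` (smoothstep of the signed distance across an
   `edge_width` band); pattern primers evaluate e.g.
   `mean + A sin(2π f (x cosθ + y sinθ) + φ)`.  Warps remap coordinates
   first, then motion offsets (`v t`, Hermite paths, seeded shake), then the
   primer is evaluated and scaled by a modulation `m(t)` (linear ramps,
   constant-phase chirps, multi-sine synthesis).  A `mix` composition
   interpolates foreground/background primers under a mask primer:
   `out = mask · fg + (1 − mask) · bg`.
3. **Post-processing** — spatial filtering (direct or FFT-domain
   convolution with Gaussian / zero-integral difference-of-Gaussians /
   Gabor kernels, frequency-specified transfer functions, median), causal
   temporal filtering (windowed convolution or a recursive LTI state system
   `y = d·x + Σ Re(s_j)`, `s_j ← z_j (s_j + c_j x)` fitted by Prony's
   method), tone mapping (contrast stretch, sigmoid, interpolated-CDF
   histogram equalization, renorm of out-of-range intensities back into
   `[0, 1]`), and gamma compensation from measured photometer samples.

Sequences of stimuli render to 16-bit PNG frames or a raw float stack,
together with a frame-accurate event log (`stim` rise/fall per stimulus,
one `stop` pulse) standing in for hardware synchronization voltages.

## Worked example

Binary checkerboard noise confined to a soft-edged disc over gray,
edge-enhanced by a difference-of-Gaussians filter and renormed:

```r
library(stimsyn)
geo <- field_geometry(64, 64, frame_rate_hz = 60)
stim <- stimulus(list(
  component("prng", "xorshift128", list(rows = 16, cols = 16)),
  component("primer", "checkerboard", list(mode = "binary")),
  component("primer", "fullfield", list(intensity = 0.5)),
  component("primer", "disc",
            list(radius = 20, edge_width = 4,
                 fill_color = 1, background_color = 0)),
  component("composition", "mix",
            list(foreground = 1, background = 2, mask = 3)),
  component("spatial_filter", "dog",
            list(sigma_center = 1, sigma_surround = 2)),
  component("tonemap", "renorm")), duration_frames = 30,
  label = "masked_noise")

ctx <- render_context(geo, seed = 42)
frame0 <- render_frame(stim, 0, ctx)
str(frame0)
#>  num [1:64, 1:64, 1:3] 0.581 0.622 0.599 0.576 0.566 ...
s <- frame_stats(frame0)
cat(sprintf("michelson %.3f | rms %.3f | entropy %.2f bits\n",
            s$michelson, s$rms_contrast, s$entropy_bits))
#> michelson 1.000 | rms 0.244 | entropy 5.63 bits
```

The filtered frame uses the full dynamic range (Michelson contrast 1
after renorming), the flat gray surround sits at the mid-gray the
zero-integral filter maps it to, and the entropy quantifies how much of
the 8-bit luminance range the noise occupies.  Rendering the same stimulus
with the same seed again reproduces `frame0` bit for bit.

Whole sequences are declarative YAML (see
`inst/extdata/demo_sequence.yaml`) and can be run from the shell:

```sh
Rscript inst/cli/stimsyn render inst/extdata/demo_sequence.yaml -o out --seed 7
Rscript inst/cli/stimsyn validate inst/extdata/demo_sequence.yaml
Rscript inst/cli/stimsyn randoms --seed 5 --rows 16 --cols 16 --frames 10 -o randoms.txt
```

`out/` then holds `frame_%06d.png` (16-bit), `events.tsv`,
`resolved_config.yaml` (every default made explicit, for provenance) and
optionally the exported random grids.

## Scope

The engine is deliberately offline: real-time display, vertical-sync and
frame-drop hardware handling, GPU shader generation, 3D/VR rendering, and
voltage output on serial ports are out of scope.  Timing is expressed as
exact frame indices (`time = frame / rate`) in the event log; a per-frame
render-time budget report is informational only.  See the methods
vignette (`vignettes/stimulus-synthesis.Rmd`) for the modeling choices,
parameter conventions and known limitations.
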