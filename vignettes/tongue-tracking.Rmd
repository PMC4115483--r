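---
title: "Tracking the tongue in midsagittal vocal-tract images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the tongue in midsagittal vocal-tract images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguetrack)
```

## Overview

`tonguetrack` implements a complete articulatory–acoustic analysis chain for
sustained-vowel studies of the vocal tract:

1. **Preprocessing** — a midsagittal grayscale frame is thresholded to find
   the dark air-filled cavities, cleaned morphologically, and the oral cavity
   is isolated; its boundary seeds an active contour.
2. **Tracking** — a greedy snake refines the movable boundary points onto the
   tongue surface.
3. **Measurement** — tongue tip constriction location (TTCL), tongue body
   constriction location (TBCL) and lip aperture (LA) are measured in
   millimetres relative to the palate and lip landmarks.
4. **Acoustics** — vowel recordings (or synthesized vowels) are analyzed by
   linear-predictive coding (LPC) to recover formant frequencies.
5. **Correlation** — the per-vowel articulatory means are correlated with the
   per-vowel formant means: tongue body height against F1, tongue tip
   location against F2.

A synthetic midsagittal *phantom* with exactly known geometry, and a
source–filter vowel synthesizer with exactly known formants, make every stage
testable without scanner data.

## Preprocessing

Air images near-black, so the cavity threshold is a small fraction of the
frame's dynamic range above its minimum:

$$T = f\,(I_{\max} - I_{\min}) + I_{\min}, \qquad f = 0.06 .$$

Pixels at or below $T$ form the raw cavity mask, which is *opened* with a
disc (radius 2 px by default) to drop specks and hair-thin bridges.
Connected components are labelled with 8-connectivity, components smaller
than 50 px or adjacent to the (dilated) jaw are discarded, and the oral
cavity is chosen as the largest remaining component that does not touch the
image border and whose centroid lies below the palatal (ANS–PNS) plane — the
nasal cavity lies above it.

The selected component is closed (radius 3 px) and its boundary split into
an upper trace (smallest row per column) and a lower trace (largest row per
column). The upper trace is resampled to 30 movable snake points, the lower
to 15 fixed points; both run anterior → posterior.

For low-SNR data the configuration option `median_radius` applies an
edge-preserving median filter before thresholding. Gaussian pre-smoothing is
deliberately *not* used there: it bleeds bright tissue intensity into the
thin dark airway and fragments the mask, while the median filter preserves
the band.

## The greedy snake

The contour is the open polyline of the 30 movable upper points followed by
the 15 fixed lower points (reversed, so consecutive points are spatial
neighbours). Each sweep visits the movable points in order; every point
moves to the pixel of its 3×3 neighbourhood minimizing

$$E = \alpha E_{ela} + \beta E_{curv} + \gamma E_{img}$$

with

* $E_{ela} = \bar d - \lVert v_i - v_{i-1}\rVert$, the signed difference
  between the contour's mean inter-point spacing $\bar d$ (recomputed once
  per sweep) and the candidate's distance to its predecessor;
* $E_{curv} = \lVert v_{i+1} - 2 v_i + v_{i-1}\rVert^2$, the squared second
  difference (endpoints duplicate their single interior neighbour);
* $E_{img} = -\lVert \nabla (G_\sigma * I)\rVert^2$, the negative squared
  gradient magnitude of the Gaussian-blurred frame.

Defaults are $\alpha = 1.2$, $\beta = 1$, $\gamma = 5.2$, $\sigma = 5$.
Points are updated serially (later points see earlier moves), candidates are
scanned current-position-first so a point moves only on a *strict*
improvement, and the run stops when fewer than 10 % of the points move in a
sweep (`stop_fraction = 0.1`), or after 200 sweeps. An alternative rule
stops on mean per-sweep displacement (`stop_rule = "displacement"`).

The blur radius sets the capture range: a blurred step edge of contrast $C$
has peak gradient $C/(\sigma\sqrt{2\pi})$ and attracts from roughly
$2\sigma \approx 10$ px. Every sweep is deterministic, and the test suite
replays each one against a brute-force serial-greedy oracle.

## Articulatory measurements

With the tracked tongue contour, the palate trace and the lip landmarks
(1-based pixel coordinates, `(x, y)` = (column, row), anterior = smaller
column):

* **TTCL** — distance from the tongue tip (the anterior-most contour point)
  to the nearest palate-trace point;
* **TBCL** — minimum distance from the posterior half of the contour (by arc
  length) to the palate trace;
* **LA** — distance between the upper- and lower-lip landmarks.

Distances are divided by the resolution (1.057 px/mm by default) to give
millimetres. A `"perpendicular"` mode measures orthogonally to the ANS–PNS
line instead of to the nearest trace point. Per-vowel summaries use the
sample ($n-1$) variance and its square root; single-frame summaries are
flagged degenerate.

## Acoustics

`average_formants` cuts a recording into $\lfloor \text{duration} / 0.025\,
\text{s}\rfloor$ consecutive non-overlapping 25 ms windows, gates out windows
more than 30 dB below the loudest, and averages per-window LPC formant
estimates. Each window is resampled to twice the maximum formant frequency
(5000 Hz for male, 5500 Hz for female voices), pre-emphasized (coefficient
0.98), Hann-windowed, and fitted with an autocorrelation LPC model of order
$2 \times 5 + 2 = 12$ via Levinson–Durbin. Complex pole pairs with
$0 < f < f_{\max}$ and bandwidth $< 400$ Hz are kept, ascending.

The synthesizer drives a cascade of two-pole resonators with an impulse
train shaped by a leaky integrator (−6 dB/oct glottal roll-off); a seeded
noise floor keeps the spectrum full-rank. When only F1/F2 targets are given,
`neutral_upper_formants()` supplies nominal F3–F5 so the spectrum matches a
full vocal tract — without them the surplus LPC poles bias F1 by up to ~10 %.
The residual error (≈2 % mean absolute relative error on F1/F2) is dominated
by harmonic sampling at high fundamental frequency, a known limit of LPC.

## The phantom

`generate_midsagittal_frame` renders a 256×256 frame with bright tissue
(200), near-black air (2), a thin intermediate-intensity palate strip (120)
between the dark oral airway and the dark nasal cavity, a dark jaw blob, a
dark lip pocket, and a bright fat marker pinning the intensity maximum.
The tongue surface is a natural spline through the archetype's control
points; Gaussian blur and additive noise emulate acquisition degradation.

Two deliberate design choices:

* the thin bright palate between two dark cavities creates opposing
  gradients whose blurred fields largely cancel, so the movable points are
  pulled *across* the airway onto the tongue edge rather than sticking to
  the airway top;
* airway gaps stay within 6–10 px (≈5.7–9.5 mm), i.e. near-closed sustained
  articulation, matching the snake's capture range.

**Known limit:** the open vowel /a/ reaches a 10 px posterior gap — exactly
the capture boundary. In a perfectly noiseless rendering its posterior
points can remain near the palate; realistic noise perturbs the energy
landscape enough to converge. The phantom validates the *mechanism*; it is
not a substitute for real imaging data.

Six archetypes encode the qualitative vowel contrasts (widest cavity and
lips for /a/, highest front tongue for /i/, narrowest lips for /u/, back
raising for /o/ and /u/), so the expected orderings of TTCL, TBCL and LA are
known analytically per frame.

## Reproducibility

Every random step (phantom noise, frame jitter, synthesis noise floor)
derives a sub-seed from one master seed; `run_pipeline` with the same
configuration is bitwise reproducible. The reference per-frame measurement
and formant tables ship as CSV fixtures (`articulatory_table()`,
`formant_table()`), and the test suite checks that every summary cell is
reproduced from its per-frame values, that the correlation signs and vowel
orderings hold, and that tracking, energies, morphology and formant recovery
match independent oracles.

```{r example, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1))
res$correlations
```
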