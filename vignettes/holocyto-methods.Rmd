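---
title: "Methods: holographic cytometry phase processing in holocyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: holographic cytometry phase processing in holocyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocyto)
```

holocyto implements the complete processing chain of a high-throughput
off-axis quantitative phase microscope for flowing cells, from the raw
interferogram to per-cell morphology, together with a synthetic-data
generator that serves as the oracle for every stage. This vignette explains
the model each stage assumes, the numerical conventions we fixed where the
mathematics leaves a choice, the tunable parameters and their defaults, and
what the synthetic tests do and do not demonstrate about instrument data.

## Imaging model and geometry

A pulsed 640 nm source is split into a sample arm crossing a microfluidic
channel and a tilted reference arm; their interference is recorded by a
line-scan camera as 96 × 4096 intensity frames at 300 fps, 0.203 µm object
pixels, NA 0.4. Frames are stored rows × columns with the long axis ("x")
as the lateral position across the channel and the short axis ("y") along
the flow. The Rayleigh resolution 0.61·λ/NA = 0.976 µm spans about 5 pixels.
All of this lives in `optics_config()`; no other function carries physical
constants of its own.

## Phase retrieval

The interferogram intensity is $|r + s|^2$ with a reference
$r \propto e^{-i2\pi(f_y y + f_x x)}$. In the Fourier domain the information
about the sample field $s = e^{i\varphi}$ sits on the carrier $(f_y, f_x)$.
`calibrate_carrier()` locates that sideband on the first frame as the
magnitude maximum over the positive-$f_x$ half-plane, excluding a ±8 row ×
±64 column rectangle around DC; searching one half-plane picks one of the
two conjugate sidebands deterministically, and argmax ties resolve to the
lowest (row, column). The peak must exceed 10× the median magnitude of the
search region, otherwise there is no off-axis carrier to demodulate.

`demodulate()` crops a 20 × 874 window centred on the peak, embeds it at the
centre of an otherwise zero spectrum of 48 × 2048 (half resolution, used for
unwrapping and detection) and 96 × 4096 (full resolution, kept for
refocusing) and inverse transforms. The inverse FFT is normalised by the
*input frame* size rather than the output size, so zero-padding does not
change amplitudes and a unit-contrast fringe gives a unit-amplitude field at
both resolutions — a pure bookkeeping convention, since any global scale
cancels in the later complex division, but a fixed one keeps results
deterministic. The wrapped phase convention is $(-\pi, \pi]$ throughout,
with the boundary $-\pi$ remapped to $+\pi$.

A consequence worth stating explicitly: the 20-row crop limits the vertical
bandwidth to about ±0.10 cycles/pixel, so even a perfect pipeline can only
recover the *band-limited* true phase. `bandlimited_truth()` computes that
reachable reference directly from a synthetic scene's ground truth (no
carrier, no interference, no unwrapping), and the round-trip tests compare
against it; against the raw ground truth, hard-edged objects keep a
rasterisation/ringing residual of ~0.1 rad RMS near their edges that no
demodulator could remove.

## Block-parallel Goldstein unwrapping

Residues are computed on 2 × 2 plaquettes as the sign of the closed-loop sum
of wrapped differences. We fixed the loop orientation to a consistent
counter-clockwise cycle (right, down, left, up in array coordinates); with
any consistent orientation the loop sum is always in $\{-2\pi, 0, 2\pi\}$,
which the tests verify, whereas an inconsistent term order would not form a
closed loop at all. Branch cuts use Goldstein's growing-box pairing: each
unbalanced residue searches boxes of increasing radius (up to 8) for an
opposite unbalanced residue or the frame edge, whichever is nearer, with
opposite charges preferred at equal radius; segments are rasterised with
Bresenham lines. Flood fill is breadth-first with 4-connectivity and a fixed
neighbour order (up, down, left, right), seeded at the first non-cut pixel
in row-major order at its wrapped value; cut pixels are assigned last and
never serve as references. The fill is implemented in C++ (`src/`), since a
per-pixel BFS over millions of pixels is the one place where interpreted R
is the wrong tool.

The parallel scheme unwraps each 48 × 2048 frame in 128 blocks of 20
columns, consecutive blocks sharing 4 columns. (A literal 20/4 schedule
covers 2052 columns, so the final block is clipped at the frame edge —
still 128 blocks.) Blocks are merged left to right by the mode of the
overlap phase difference rounded to multiples of $2\pi$, ties toward the
smallest offset; overlap pixels keep the left block's values. Residues and
cuts are computed once per frame *before* splitting: recomputing them per
block would lose cross-block consistency. On residue-free fields the merged
result equals the single-region flood fill up to one global $2\pi$ multiple
— the central exactness property, tested over 100 seeded fields.

## Background removal

Three backgrounds are removed from each 40-frame batch, in this order:

* **Temporal wrap errors.** Any pixel deviating more than $2\pi$ from its
  temporal median over the batch is shifted by the whole number of wraps
  bringing it nearest the median. The median is our choice of reference
  (the estimator is otherwise unspecified); it is robust to a transient
  cell occupying a pixel in a few frames of 40.
* **Smooth optical background.** A cubic polynomial is fitted per row and
  subtracted — the frame is 40× wider than tall, so per-row curves stand in
  for a 2D cubic surface at a fraction of the cost. By default one masked
  re-fit excludes pixels whose residual exceeds 0.5 rad so cells do not
  lift the curve; the direct single-pass fit (which produces faint side
  lobes beside bright cells) is available with `robust = FALSE`.
* **Static structure.** The pixel-wise temporal median of the batch —
  channel walls, dust, and any *persistent* unwrap error — is subtracted
  from every frame. We chose the median as the simplest statistic that
  keeps transient cells out of the background while capturing everything
  persistent.

The default synthetic channel walls step the phase by 4 rad (> π) exactly so
that block unwrapping genuinely errs at the walls and this stage has real
errors to remove.

## Cell detection

Cleaned frames are binarised at 0.3 rad. The detection kernel is as tall as
the frame (48 rows): a +1 disk of 20 half-resolution pixels (≈ one RBC) in
the centre and −8 bands over the top and bottom 4 rows, zeros elsewhere.
The kernel's published form is qualitative (a centre-positive,
edge-negative template), so the exact values are configuration; the defaults
are the mildest structure that makes a fully centred cell score above half
the disk mass while any cell overlapping the edge bands scores below
threshold. Correlation along x is computed per 80-frame batch by
zero-padded FFT (scores rounded at 10⁻⁶ so symmetric plateaus tie exactly)
and verified against the brute-force sliding dot product. Local maxima of
the 80 × 2048 map above threshold, greedily accepted in descending score
with an exclusion window of 24 columns × 5 frames, yield one detection per
cell — the frame where the flowing cell crosses the centre of the short
axis — without any motion tracking. Frames whose best column score stays
under a tenth of the threshold are recorded as empty backgrounds, and each
detection is assigned the temporally nearest one.

## Digital refocusing

For each detection, 96 × 96 full-resolution crops of the cell frame and its
background frame are taken at the same columns (cells whose window would
cross the lateral frame edge are discarded). Complex division removes the
common background; for thin objects (phase below $2\pi$) the quotient's
argument is the cell phase directly, with no unwrapping.

Propagation uses the exact angular spectrum with the transfer function
$H = \exp\!\big(i2\pi d(\sqrt{1/\lambda^2 - f_x^2 - f_y^2} - 1/\lambda)\big)$
and evanescent components zeroed. The $-1/\lambda$ term references the phase
to the co-propagating plane wave: interferometric phase is measured against
the reference beam, so numerical propagation must not add the
distance-dependent piston $e^{ikd}$ (with the piston left in, a refocused
crop acquires a spurious ~rad-scale offset against its unpropagated
surroundings). At $d = 0$ the kernel is identically 1 — no propagation, no
filtering — so zero-distance propagation is the exact identity.

The focus metric is the population variance of the amplitude: a pure phase
object has flat amplitude exactly in focus. Coarse autofocus evaluates 32
distances from −24 to 24 µm (grid step 48/31 ≈ 1.55 µm; ties toward the
smaller |d|); the stored distance is the one *passed to the propagator to
restore focus*, so a cell defocused by $+d$ is recorded at $-d$ — the sign
convention is ours and used consistently, including by the simulator's
ground truth. A quadratic $d(x)$ is fitted to the first 128 cells (fewer
with a warning below 8, an error below 3); its residual standard deviation
sets the spread of the three-depth refinement $\{d(x)-s, d(x), d(x)+s\}$,
from which the minimum-variance candidate is returned ("minimised
amplitude" is read as the amplitude-variance criterion defined alongside
it). Candidates are continuous values, not snapped back to the 32-point
grid. We divide first and propagate the quotient once; the published order
(propagate both, then divide) is available via `propagate_before_divide`.
The two orders commute exactly for uniform backgrounds and agree below 0.01
rad for the tilt scale a real background crop carries — they are *not*
equivalent to machine precision for curved backgrounds, which the tests
state honestly rather than assert away.

## Morphology

The refocused phase has the mean of its four 8 × 8 corner blocks
subtracted, is thresholded (0.3 rad by default, the same value as
detection, since no separate value is published), opened with a radius-1
disk, and reduced to its largest 4-connected component. From mask and
phase: area $A = N\,dA$; $\mathrm{OPL} = \varphi\lambda/2\pi$ per pixel;
$\mathrm{OV} = dA \sum \mathrm{OPL}$; eccentricity
$\sqrt{1-\lambda_\text{minor}/\lambda_\text{major}}$ from the second
central moments; circularity $4\pi A/C^2$ with a Crofton 4-direction
perimeter (robust to rasterisation; validated against analytic circles).
The inverted circularity variant $4\pi C^2/A$ — which evaluates to ≈158 for
a circle and is not a bounded descriptor — is available behind
`circularity_printed_form` for literal comparison only. The RBC filter
bounds are pure configuration; the defaults bracket healthy cells
(area 20–90 µm²; optical volume 2–20 µm³, i.e. refractive-index contrast
~0.06 times a 70–120 fL cell volume; eccentricity ≤ 0.8;
circularity ≥ 0.7), with closed intervals so a value exactly on a bound
passes.

## Evaluation harness

The reference for quality assessment is exhaustive amplitude-variance
refocusing on a 0.1 µm grid over the full ±24 µm range. Seven metrics
compare each cell before (background-divided, unpropagated) and after
real-time refocusing against that reference: percent errors of OV, area and
mean OPL (denominator: the reference value), absolute differences of
eccentricity and circularity, RMSE of the OPL map in µm, and the global
SSIM with $c_1 = 2.22\times10^{-3}$, $c_2 = 2.00\times10^{-2}$, computed on
the phase scale (the published formula is global, not sliding-window, and
does not name a scale; phase is the natural one here). Reports give the
population mean and the 95th percentile (linear-interpolation quantile) with
before/after improvement factors, factors being undefined for SSIM.

`evaluate_refocusing_population()` wires the harness to the simulator: cells
with a quadratic defocus tilt across the field of view (defaults spanning
2–15 µm) plus 0.8 µm Gaussian scatter, calibration on the first 128, then
three-depth versus fine refocusing for all. On 200 such cells every error
metric improves in the mean and SSIM rises from ~0.88 to ~0.997 — a
directional, not numerical, reproduction: the exact factors depend on the
defocus distribution of the acquisition.

## The simulator, and what the tests do not show

`synthesize_frames()` builds each frame's true phase (cells in their flow
positions + per-row cubic background + wall steps), forms
$s = e^{i\varphi}$, applies each cell's true defocus by propagating the
96-column sub-field around it, interferes with the tilted reference, and
adds clipped Gaussian intensity noise; ground truth (detections, focused
cell crops, defocus, static phase, per-frame phase) is recorded before
noise. Identical scene + seed is bit-identical. Cell profiles are a uniform
disk, a spherical-cap "bead", and a biconcave RBC-like profile
$\varphi_0(1 - 0.5 e^{-r^2/(0.25R^2)})$ cosine-tapered to zero over the
outer 15% of the radius (the taper width is our choice; the profile needs
*some* smooth edge to be band-limited enough to image). Default cell radius
3.4 µm and peak phase 1.8 rad match face-on RBC scale at 640 nm.

What this exercises: every numerical contract of every stage, end to end,
with exact oracles. What it does not emulate: partial coherence, speckle,
camera noise statistics, flow dynamics beyond constant displacement,
out-of-plane cell rotation, refractive-index heterogeneity inside cells, or
overlapping cells. Passing tests therefore demonstrate algorithmic
correctness under the stated model, not instrument-level performance; the
evaluation factors on real data will differ with the real defocus and noise
distributions.

## Problem sizes and determinism

The shipped tests run the full pipeline on acquisitions of 20–84 frames and
populations of 200 crop-level cells — sizes chosen so the whole suite
exercises every batch boundary (20-frame unwrap, 40-frame post-processing,
80-frame detection batches) while staying comfortable on a single CPU. All
randomness is seeded; the pipeline itself is deterministic given input and
configuration, batch results are bit-identical to per-frame processing, and
re-running an acquisition reproduces its CSVs byte for byte.

## Known limitations

* Residues trapped in regions fully enclosed by branch cuts unwrap against
  their own seed; persistent $2\pi$ offsets there are removed later by the
  static background stage, matching the pipeline's overall contract, but
  transient ones in a single frame can survive as artifacts.
* The per-row cubic cannot represent background curvature along the short
  axis; for the 48-row frames this is negligible by construction.
* The three-depth refinement assumes the calibration curve is stable over
  an acquisition; drifting optics would need re-calibration.
* Detection assumes one cell per exclusion window; touching or overlapping
  cells merge into single detections by design (no splitting).
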