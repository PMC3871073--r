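---
title: "ROI localization for NIR finger-vein images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI localization for NIR finger-vein images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinroi)
```

## The problem

A finger-vein scanner transilluminates a finger with ~850 nm near-infrared
light. Soft tissue transmits, hemoglobin absorbs: the captured frame shows a
bright elongated finger band on a dark background, with dark curvilinear
veins inside it and a locally brighter vertical stripe at each knuckle,
where articular cartilage lets the light through. Before any vein matching
can happen, a fixed-geometry region of interest (ROI) must be cut from the
finger region — and captures are routinely degraded by translation, tilt,
scale, scattering haze, uneven illumination, fingers that partially leave
the frame, and light stolen by the neighboring finger. A wrong ROI inflates
within-subject distance and sinks recognition accuracy, so the segmentation
and ROI steps have to be robust to all of the above.

`veinroi` implements a complete localization pipeline: coarse segmentation
with directional edge operators, a variance-gated repair path for broken
contours, least-squares orientation correction, and knuckle-anchored ROI
detection, plus a seedable synthetic image generator that provides analytic
ground truth for every branch of the pipeline.

## Pipeline model

All processing happens on a 120 × 160 working frame (`work_size`): native
480 × 640 captures are reduced 4× with bicubic interpolation, which costs
nothing in contour accuracy and an order of magnitude in runtime. Rows are
indexed top to bottom, columns left to right, 1-based; column `x` runs along
the finger axis.

### Coarse binarization

The finger's upper and lower contours are the only two long horizontal
edges in the frame. The image is split at the horizontal center line;
each half is correlated with a directional edge operator — a Prewitt
horizontal kernel extended to `kernel_cols = 11` columns, with the sign
arranged so that the contour (scanning from the center toward the boundary)
yields a positive ridge. Widening the operator along the finger axis
averages out vein texture that a 3 × 3 kernel would mistake for an edge;
11 columns is the widest the operator can be before genuinely sloped
contours (a few tenths of a row per column after orientation errors)
decohere across the window. Correlation uses replicate borders, so the
frame edge itself never generates a spurious ridge. Each filtered half is
min–max normalized to [0, 255] and the per-column argmax gives the contour
rows `up_j` and `low_j`; ties break toward the center line, where the
finger sits by device design. The mask is filled between the two contours,
one contiguous run per column.

For databases captured with the reverse polarity (bright background, dark
finger), `bright_background = TRUE` complements the intensities on load,
which is exactly equivalent to swapping the two operators.

### The variance gate and boundary padding

When a contour is washed out (scattering, uneven illumination) or leaves the
frame (improper placement), the argmax in the affected columns lands on vein
texture or noise, and the traced contour jumps. Each trace is split into a
left and a right half and the sample variance of each half's row values is
computed; any of the four variances exceeding `Thr = 38` px² routes the
image to the repair path, with the upper test taking precedence. 38 px²
(on the 120 × 160 scale) sits an order of magnitude above clean-trace
jitter (≲ 1 px²) and well below what a jumped trace produces (typically
hundreds). Half-size captures need a proportionally larger threshold — a
per-database profile (e.g. `Thr = 150`) handles that.

The first repair assumes the finger genuinely left the frame: `t = 3` zero
rows are padded onto the offending side, giving the filter a clean
dark-to-bright transition at the old boundary, the coarse pass is re-run on
the padded (m + t) × n image, and the padded rows are discarded. On truly
truncated columns the recovered contour is the frame boundary, which is the
best available answer. Three rows suffice for the 3-row-high operator and
keep the extra filtering negligible.

### Midpoint clustering and line-guided removal of false background

Breaks caused by scattering rather than truncation survive re-binarization.
Those are caught in midline space: the per-column midpoints
`y_i = (up_i + low_i)/2` of a correct segmentation form one smooth chain,
while a residual error displaces a run of midpoints far off that chain.
Single-linkage agglomerative clustering on the (x, y) midpoints (Euclidean
distance, `stats::hclust`) is cut where the smallest inter-cluster link
exceeds `link_dist`; the largest cluster is kept and everything else is
flagged. Size ties go to the cluster with the smaller y-variance (the
flatter chain is the midline).

The cut distance trades off two failure modes. Error plateaus displace
midpoints by at least ~9 px in y (half the intensity-collapse depth that is
needed to fire the variance gate in the first place), so the cut must stay
below that. But a short run of w hijacked columns inside an otherwise
correct chain opens an x-gap of w + 1 between correct segments; a cut at
5 px disconnects the chain behind a 4-column hijack, and the disconnected —
perfectly correct — tail would then be flagged and "repaired". The default
is `link_dist = 7`: bridges hijack gaps up to 5 columns, still separates
every plateau the gate can produce.

The midline of the correct points is then fit by least squares
(`y = kx + b`, closed form), and each flagged column is reconstructed by
midpoint symmetry: the corrected midpoint is `y_c = kx + b`, the broken
contour is `round(2 y_c − low)` (or the mirror formula), with the broken
side decided per column by comparing both contours against the line ± the
median half-width. Two guards matter in practice:

* a flagged column whose midpoint already lies within `link_dist / 2` of the
  line is left untouched. Cluster fragmentation can flag whole runs of good
  columns (when a plateau splits the chain, only one side can be the largest
  cluster); rewriting them would replace exact contours with the fit's
  extrapolation error, doubled by the symmetry formula.
* if every midpoint is flagged, the segmentation is unrecoverable and the
  image is reported as a failure rather than silently "repaired".

Both sides broken is handled sequentially: upper repair first, then the
lower test is re-run on the repaired trace.

### Orientation correction

With the midline fit in hand, the orientation angle is `θ = atan(k)`,
converted to degrees. The signed angle (positive = rotate counterclockwise)
drives the correction; the magnitude is what gets logged. If |θ| exceeds
the 1° gate (`min_angle_deg`), image and mask are rotated about the frame
center by the angle that makes the midline horizontal — bicubic for
intensities, nearest-neighbor for the mask so it stays strictly {0, 1},
zero fill, frame size preserved so the downstream geometry is unchanged.
Below the gate, interpolation blur would cost more than the residual tilt.

### ROI detection

The ROI is anchored on the second knuckle. The finger extent (y₁, y₂) is
read off the mask at anchor column 150 (near the fingertip, where fingers
are narrowest; if that column is empty the nearest nonempty column is used
with a warning). The block spanning rows y₁..y₂ and columns 21..80 of the
segmented (rotation-corrected) image is projected vertically,
`V_j = Σᵢ w(i, j)`; the knuckle transmits the most light, so
`c = argmax V_j` marks it, and `ref = c + 20` maps it back to frame
columns. The ROI rectangle is rows (y₁+2)..(y₂−2) and columns
[ref − 15, ref + 80) — half-open, hence exactly 95 columns — clamped to
the frame with a warning when the knuckle sits close to the left edge.
Finally the crop is normalized to 60 × 128 by bicubic resampling, so every
downstream feature extractor sees a constant geometry.

## The synthetic generator

`generate_finger_image()` renders the geometry the scanner produces: dark
background (20 ± noise), bright band (160 ± noise) with a 1.5 px edge
rolloff, tilted by φ about the frame center; three roughly parallel dark
vein curves (a shared base wave plus small per-vein wiggle, offsets spaced
so veins neither stack on each other nor come within ~7 px of a contour —
stacked veins would imitate a contour-strength edge, which real parallel
veins rarely do for long runs); a brighter knuckle stripe (Gaussian,
σ = 3.5 px, gain 1.3); additive Gaussian noise (sd 4). Ground truth —
mask, tilt, knuckle column, expected routing — falls out of the geometry.

Artifact classes map to pipeline branches: `truncated_top`/`_bottom` drive
one contour out of the frame with a monotone smooth-hinge ramp toward one
end (slope ~0.35–0.6 rows/col, the regime where a real finger slides off
the sensor window; steeper synthetic ramps defeat any width-11 operator and
test nothing the method claims); `scatter_wedge` collapses a sharp-sided
run of one contour toward background, the residual-error case that only
clustering can fix — placements are rejection-sampled (seeded, hence still
deterministic) so the displaced trace stays inside its half-frame and its
predicted variance clears the gate, since sub-gate haze is an unrepairable
degradation this class does not model; `uneven_illum` and
`neighbor_finger` must *not* fire
the gate; `parasitic_blob` is a bright background spot that hijacks the
trace. The generator is seeded end-to-end: a master seed determines every
sample bit-exactly.

What it does not emulate: real vein topology (branching), scattering as a
contrast-loss field rather than a localized wedge, sensor fixed-pattern
noise, finger pressure, or rotation about the finger axis. Passing the
suite therefore demonstrates that the pipeline's decision logic and
geometry are correct under the stated image-formation model — not
performance on any particular camera.

## Numerical choices

* Intensities are floating point on the 0–255 scale internally; quantized
  to 8 bits only on write.
* Bicubic interpolation is the Keys cubic-convolution kernel (a = −0.5),
  separable; when shrinking, the kernel is widened by the scale factor
  (antialiasing). Resampling weights are renormalized at replicated borders.
* Odd frame heights split at ⌊m/2⌋ with the extra row in the lower half.
* Trace splits for the variance test give the extra column to the first
  half; variances are sample variances (divisor n − 1), which is what the
  threshold was calibrated against.
* Argmax ties: toward the center line (contours), smallest index
  (projection).
* Reconstruction rows are clamped to [1, m] and `low ≥ up` is enforced.
* RGB convenience inputs collapse via 0.299/0.587/0.114 luminance weights.

## Evaluation harness

A segmentation is "correct" when it contains no appreciable false
background or false foreground: IoU with the truth mask ≥ 0.98 *and* no
connected mismatch component (8-connectivity, `EBImage::bwlabel`) larger
than 1% of the finger area. The second clause catches compact bites that
IoU alone would forgive. Accuracy is the correct fraction.

The test and acceptance workloads, chosen to exercise every branch at a
size a laptop runs in seconds: a 200-image suite (50% clean, 10% each
truncated-top/bottom, scattering wedge, uneven illumination, neighbor
finger), an orientation sweep φ ∈ {−8, −6, …, 8}° × 10 seeds, and 100
random instances per brute-force oracle comparison. The post-rotation
residual angle is measured from the rotation-corrected mask's own midline
(`mask_midline_angle`): re-running edge detection on a rotated frame
instead would measure its zero-filled corners (which can clip the contour
at the outermost columns) rather than the rotation.

## Known limitations

* The straight-midline model breaks for heavily truncated fingers, whose
  clipped midline is kinked; the deviation guard keeps the repair from
  making things worse, but the estimated angle for such images reflects the
  clipped band, not the anatomical axis.
* One finger band per image is assumed; a second full band would need
  multi-object reasoning the method does not attempt.
* Bright-background support is the polarity complement only; database
  quirks like tag strips are handled by the CLI's generic `--crop-rows`.
* Rotation about the finger axis and pressure-induced deformation are out
  of scope.
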