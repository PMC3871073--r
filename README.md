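# veinroi

Robust region-of-interest (ROI) localization for near-infrared finger-vein
images, for people building finger-vein biometric pipelines: the stage that
turns a raw transillumination capture — a bright finger band on a dark
background, degraded by tilt, translation, scattering haze, uneven
illumination, truncated contours, or a neighboring finger — into a fixed
60 × 128 sub-image of the finger, aligned and anchored on the second
knuckle, ready for vein feature extraction.

## Method

On a 120 × 160 working frame (native captures are reduced with bicubic
interpolation):

1. **Coarse binarization.** The frame is split at the horizontal center
   line; each half is correlated with a directional edge operator (a
   Prewitt horizontal kernel extended to 11 columns, signed so the finger
   contour yields a bright ridge). Per-column argmax gives the contour rows
   `up_j`, `low_j`; the mask is filled between them.
2. **Variance-gated repair.** Each contour trace is split in half; a sample
   variance above `Thr = 38` px² flags a broken contour. The repair pads
   `t = 3` zero rows onto the broken side and re-binarizes (truncated
   fingers adopt the frame boundary as contour). Residual errors are caught
   in midline space: midpoints `y_i = (up_i + low_i)/2` are clustered by
   single linkage (cut 7 px); the largest cluster is the finger chain, and
   flagged columns are reconstructed from the least-squares midline
   `y = kx + b` by midpoint symmetry, `up = round(2(kx + b) − low)`.
3. **Orientation correction.** `θ = atan(k)`; if |θ| > 1°, image and mask
   are rotated about the frame center (bicubic / nearest-neighbor) so the
   midline is horizontal.
4. **ROI detection.** Finger extent (y₁, y₂) is read at anchor column 150;
   the block rows y₁..y₂ × columns 21..80 is projected vertically,
   `V_j = Σᵢ w(i, j)`; the knuckle column is `c = argmax V_j`,
   `ref = c + 20`. The ROI is rows (y₁+2)..(y₂−2) × columns
   [ref−15, ref+80) — exactly 95 wide — normalized to 60 × 128.

Segmentation quality is scored as accuracy = correct / total, where
"correct" means mask IoU with ground truth ≥ 0.98 and no connected
mismatch component above 1% of the finger area.

A seedable synthetic generator (`generate_finger_image`,
`generate_suite`) renders NIR-like fingers with analytic ground truth
(mask, tilt, knuckle column, expected routing) and artifact classes for
every pipeline branch — the validation substrate for the whole package.

## Worked example

```r
library(veinroi)

# a clean synthetic finger, tilted 4 degrees
s <- generate_finger_image(synthetic_params(seed = 7, tilt_deg = 4))
r <- run_pipeline(s$image)
print(r)
#> finger ROI 60x128 | case: normal | theta +3.95 deg (rotated) | ref col 45 | rows 33..87

v <- segmentation_verdict(r$mask, s$truth_mask)
sprintf("IoU vs truth: %.4f  correct: %s", v$iou, v$correct)
#> "IoU vs truth: 0.9992  correct: TRUE"
```

The pipeline estimated the tilt at +3.95° (true: 4°), rotated, located the
knuckle at column 45 (where the generator put it), and produced a 60 × 128
ROI; the segmentation matches the analytic truth mask to IoU 0.999.

Batch evaluation over a ground-truthed suite:

```r
su <- generate_suite(n = 50, seed = 1)
verd <- vapply(seq_len(50), function(i)
  segmentation_verdict(run_pipeline(su$samples[[i]]$image)$mask,
                       su$samples[[i]]$truth_mask)$correct, logical(1))
evaluate_segmentation(verd)
#> segmentation accuracy: 50 / 50 = 1.0000
```

A command-line front end with `run`, `synth`, `eval` and `inspect`
subcommands lives in `inst/cli/veinroi.R`; YAML profiles (e.g.
`Thr: 150` for half-size captures) feed `--config`.

## Documentation

`vignette("veinroi-methods")` describes the model, every tunable parameter
with its default and rationale, what the synthetic generator does and does
not emulate, numerical choices, and known limitations.
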