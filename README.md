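# patchdsa

Motion-artifact-reduced digital subtraction angiography (DSA) for mask and
contrast fluoroscopy series acquired under **natural breathing**, by
patch-based respiratory phase matching.

DSA subtracts a pre-contrast (*mask*) X-ray frame from a contrast-enhanced
frame to isolate vessels. In the abdomen, breathing, heartbeat and
peristalsis move the anatomy between the two acquisitions, and the residual
structure (motion artifact) can obscure vessels or be mistaken for them.
Whole-image phase matching picks, for each contrast frame, the mask frame at
the most similar breathing phase — but one frame cannot serve organs that
move independently of the diaphragm. `patchdsa` matches **per patch**
instead. For each contrast frame `C` and mask series `M_1..M_T`, each
divided into an N x N grid of patches (N = 10):

1. **Phase matching** — each contrast patch `c^(i,j)` selects the mask frame
   `t*` maximizing the zero-normalized cross-correlation
   `ZNCC(a,b) = sum((a-ā)(b-b̄)) / sqrt(sum((a-ā)²) sum((b-b̄)²))`
   against the co-located mask patch, exhaustively over all T frames.
2. **Subpixel refinement** — the selected patch is translated within the
   whole mask frame by continuous `(t_x, t_y)` (bilinear resampling) to
   maximize ZNCC, via a downhill simplex search with a bounded step.
3. **Brightness-corrected subtraction** — the refined mask patch is shifted
   by `μ_c − μ_m` (means over pixels not flagged as contrast-enhanced on the
   preliminary subtraction) and subtracted; patches are reassembled with no
   blending. An over-exclusion guard falls back to using every pixel when a
   poor threshold would mark nearly the whole patch as vessel.

The package also ships the two reference baselines (whole-image phase
matching; first-frame simple subtraction), a histogram-entropy quality
metric with an exact Wilcoxon signed-rank comparison, a synthetic breathing
phantom with ground-truth motion and vessel maps, and a command-line
interface (`inst/cli/patchdsa.R`) with `simulate` / `run` / `evaluate`
commands. It is aimed at researchers in interventional imaging who want a
reproducible, fully inspectable reference implementation of patch-based
phase matching.

## Worked example

Generate a two-case synthetic breathing suite and compare the three methods:

```r
library(patchdsa)
study <- run_phantom_study(n_cases = 2, seed = 7)
print(study)
#> <phantom_study> 2 case(s), seed 7
#>    method median_entropy  mean_rms
#>   ohnishi       2.648319  3.967274
#>  patchdsa       2.521711  3.527031
#>    simple       3.903315 10.729004
#>   vessel depth recovery (patchdsa): 94.2% (mean)
#>   patchdsa_vs_ohnishi: p = 0.5, lower entropy: patchdsa
#>   patchdsa_vs_simple: p = 0.5, lower entropy: patchdsa
```

Reading the output: `median_entropy` is the Shannon entropy of the DSA
intensity histogram (nats), averaged over cases — lower is better, a clean
DSA image concentrates its histogram around background and vessel levels.
The patch-based method (`patchdsa`) beats whole-image phase matching
(`ohnishi`), and both beat first-frame subtraction (`simple`). `mean_rms` is
the background residual RMS outside the true vessel (intensity units;
artifact energy against ground truth). Vessel depth recovery says the mean
DSA value inside the true vessel core reached 94% of the planted contrast
depth. With only 2 cases the exact signed-rank p-value cannot go below 0.5;
the 10-case study in `scripts/acceptance.R` yields p ≈ 0.002.

Processing real series:

```r
mask     <- read_series("mask.tif", role = "mask")
contrast <- read_series("contrast.tif", role = "contrast")
frames   <- generate_dsa_sequence(contrast, mask)        # list of dsa_frame
entropies <- evaluate_sequence(frames)
write_series(image_series(lapply(frames, `[[`, "image"), role = "contrast"),
             "dsa.tif")   # signed values: offset-encoded + JSON sidecar
```

or from a shell:

```sh
Rscript inst/cli/patchdsa.R simulate --out sim --cases 3 --seed 1
Rscript inst/cli/patchdsa.R run --mask sim/case_01/mask.tif \
    --contrast sim/case_01/contrast.tif --method patchdsa --out runs/case_01
Rscript inst/cli/patchdsa.R evaluate --runs runs --out report
```

## Package layout

- `R/` — series I/O and cropping, patch grid, ZNCC matching, simplex
  refinement, brightness-corrected assembly, entropy + signed-rank
  evaluation, synthetic phantom, study orchestration.
- `vignettes/patchdsa-methods.Rmd` — the model, parameter rationale, phantom
  design and its limitations.
- `tests/testthat/` — unit, property and end-to-end tests.
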