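---
title: "Patch-based phase-matched DSA: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based phase-matched DSA: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Digital subtraction angiography (DSA) visualizes vessels by subtracting a
pre-contrast *mask* frame from a contrast-enhanced frame of the same field of
view. In the abdomen under natural breathing, anatomy moves between the two
acquisitions — respiration displaces the diaphragm and every organ coupled to
it, the heart pulsates on its own clock, and bowel gas drifts with
peristalsis — so a plain subtraction leaves motion artifacts that can obscure
or mimic vessels. Whole-image respiratory phase matching (selecting, for each
contrast frame, the single mask frame at the most similar breathing phase)
removes the respiratory component but cannot serve organs whose motion is
uncorrelated with the diaphragm.

`patchdsa` implements a per-patch alternative: each contrast frame is divided
into an N x N grid, and *each patch independently* selects, refines and
subtracts its own mask content.

## The method

For mask series $M_1, \dots, M_T$ and one target contrast frame $C$, each
divided into patches indexed $(i, j)$:

**Step A — phase matching.** For every contrast patch $c^{i,j}$, compute the
zero-normalized cross-correlation (ZNCC)

$$\mathrm{ZNCC}(a, b) \;=\;
\frac{\sum (a - \bar a)(b - \bar b)}
     {\sqrt{\sum (a - \bar a)^2 \,\sum (b - \bar b)^2}}$$

against the co-located patch $m_t^{i,j}$ of every mask frame, and keep the
frame $t^\*$ with the highest score. ZNCC is invariant to positive affine
intensity maps, so gain and offset drifts between the series do not bias the
selection. The search is exhaustive over all $T$ frames (about 30; no
pruning), and ties break to the earliest frame. A zero-variance patch cannot
be scored; it gets the sentinel score 0, is flagged, and skips refinement.

**Step B — subpixel refinement.** Organs also shift in directions unrelated
to the diaphragm. The selected patch is therefore translated within the whole
mask frame $M_{t^\*}$ by continuous offsets $(t_x, t_y)$, resampled
bilinearly, and the translation maximizing ZNCC is found by a 2-D downhill
simplex (Nelder–Mead) search started at $(0,0)$.

**Step C — brightness-corrected subtraction.** Because adjacent cells may
subtract different mask frames (and subpixel resampling shifts local means),
uncorrected patches would produce visible tiling at the seams. Each refined
mask patch is shifted by the scalar $\mu_c - \mu_m$ before subtraction, where
both means are taken over the pixels *not* flagged as contrast-enhanced.
Contrast-enhanced pixels exist only in the contrast patch and are dark, so
including them would drag $\mu_c$ down and over-darken the corrected mask.
Enhanced pixels are detected on the preliminary subtraction patch (contrast
minus refined mask, before correction) by thresholding. The corrected patches
are subtracted and written into the output at their grid positions with no
blending; seam consistency rests entirely on the brightness correction,
which is exact in the sense that after correction the mask and contrast
patches have identical means over the non-excluded set.

Two baselines are provided: `global_phase_match()` (one ZNCC-best mask frame
per contrast frame, whole-image subtraction, optionally restricted to an ROI
— the classical whole-image phase-matching strategy with the contrast frame
as the target) and `simple_subtraction()` (every contrast frame minus the
first mask frame).

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_divisions` | 10 | – | Balance between patch structure content and locality; smaller patches lack matchable structure, larger ones average over independently moving organs. |
| `initial_step` | 1.0 | px | Initial simplex edge; residual motion after phase matching is on the order of a pixel. |
| `xtol` / `ftol` | 0.01 / 1e-5 | px / ZNCC | Stop when the simplex collapses below a hundredth of a pixel or the score spread is negligible. |
| `max_iter` | 200 | – | Ample for a 2-D simplex at these tolerances. |
| `max_shift` | half the smaller patch edge, capped at 10 | px | Penalty bound on the translation; keeps the search off repetitive structures (ribs one period away). |
| `exclusion_mode` | `robust_sigma` | – | Threshold at median − k·1.4826·MAD of the preliminary patch; removes the operator dependence of a manually chosen threshold while `fixed_threshold` reproduces the manual workflow. |
| `sigma_k` | 2 | robust SD | On pure noise excludes only the ~2% lower tail; a planted vessel many SDs deep is excluded essentially completely. |
| `max_excluded_fraction` | 0.9 | – | Over-exclusion guard: if thresholding marks more than 90% of a patch as contrast-enhanced, the threshold is distrusted and every pixel is used. Protects against the failure where a poor threshold classifies most of an artifact-bearing patch as vessel and then mis-corrects it. Note the robust mode can never exclude more than ~50% of a patch (the threshold sits below the median by construction), so this guard is effectively a safety net for the fixed-threshold workflow. |
| `bin_width` | 1.0 | intensity | Entropy histogram bin; reproduces a per-integer-level histogram on integer data. Values are binned anchored at the image minimum, making the metric shift-invariant. |
| `log_base` | natural | – | Rescales entropies uniformly; never changes method orderings. |

Design choices where the design was genuinely open:

* **Simplex details.** The initial simplex is the right triangle (0,0),
  (s,0), (0,s); out-of-bounds and out-of-frame shifts are penalized (score
  −2) rather than clamped so the simplex can recover from an excursion; the
  returned translation is the **best feasible point ever evaluated**, not the
  final simplex state. This enforces the monotonicity contract
  `refined_score >= coarse_score` exactly, independent of where the simplex
  happens to terminate. The optimizer is implemented in-package because
  these three behaviors (fixed initial simplex, penalty handling,
  best-ever-point return) are part of the method's contract;
  `stats::optim`'s Nelder–Mead serves as an independent cross-check in the
  tests.
* **Interpolation.** Bilinear. A closed-form oracle exists (a half-pixel
  shift of a linear ramp adds exactly half a unit), integer shifts reproduce
  exact pixel copies, and bilinear cannot overshoot on noisy fluoroscopy the
  way bicubic can.
* **Support of the correction means.** Both $\mu_m$ and $\mu_c$ are computed
  over the same non-excluded pixel set. Computing $\mu_m$ over all pixels
  while excluding vessel pixels from $\mu_c$ would leave a residual offset
  whenever the excluded region's mask intensities differ from the patch
  mean; a common support makes the correction offset-free by construction.
* **Step order.** The preliminary patch used for exclusion is computed
  *after* subpixel refinement, so motion residuals contaminate the threshold
  as little as possible.
* **Step B does not revisit $t^\*$.** The frame choice from step A is final;
  refinement only translates within that frame.
* **Tie-breaking** everywhere is "smallest index": deterministic and
  reproducible across evaluation orders.
* **Whole-frame entropy.** The quality metric is computed on the full frame;
  no masking is applied by default.
* **Exact Wilcoxon with ties.** Per-case median entropies are compared with
  a two-sided signed-rank test whose null distribution is computed exactly
  (generating-function convolution over all sign assignments) for up to 25
  nonzero pairs, with zeros dropped and average ranks for ties;
  `stats::wilcox.test` declines exact computation under ties, so it is used
  as the cross-check on tie-free data only.

## The synthetic phantom

No clinical angiograms ship with the package, so validation runs on a
generated phantom (`generate_phantom()`, `make_case_suite()`) that emulates
the acquisition the method targets: one mask series (30 frames) followed by
one contrast series (50 frames) at 6 frames/s, sharing background anatomy
and one continuous motion clock.

* **Background**: intensity gradient, rib-like periodic bands, three octaves
  of smooth random texture (coarse anatomy to fine detail), and a soft
  diaphragm edge. The whole background translates vertically by
  $A\sin(2\pi t / (\text{period} \cdot \text{rate}))$ with $A = 6$ px and a
  4 s period — quiet-breathing scale motion sampled over 1.25 respiratory
  cycles by the mask series, so every contrast-frame phase has a usable
  counterpart.
* **Independent motions**: a pulsating cardiac disk (1 s period) and three
  bowel gas pockets drifting with a random walk. These are deliberately
  *uncorrelated* with respiration; they are what separates the patch-based
  method from whole-image matching.
* **Vessel**: a branching tree of line segments, planted only in the
  contrast series, with a flat-core profile (full depth out to
  width − 0.5 px, 1 px linear falloff), depth −50 intensity units, and an
  inflow ramp over the first 12 frames. Contrast agent attenuates X-rays,
  so the vessel is *darker* than background — the sign convention the
  exclusion threshold relies on.
* **Noise**: i.i.d. Gaussian, SD 2, drawn independently for the two series.
* **Scale**: 240 x 312 px frames. At N = 10 this gives 24 x 31 px patches,
  which reproduces the *proportions* of clinically cropped frames
  (~370 x 490 px, 37 x 49 px patches) — in particular the fraction of a
  patch a vessel can cover, which controls both how much the vessel biases
  ZNCC selection and how far it can inflate the MAD of the exclusion
  statistic. The texture amplitudes (14/9/5 over three scales) and vessel
  depth were chosen together so that vessel and background contribute
  comparable variance within a vessel-crossing patch, as they do clinically.
* **Truth**: per-frame diaphragm displacement and respiratory phase, cardiac
  phase, bowel centers, per-frame vessel masks, and the planted depth map
  (`planted_depth_map()`) — the displaced, inflow-scaled profile a perfect
  subtraction would recover.

The validation study (`run_phantom_study()`) generates 10 cases with
jittered motion parameters, runs all three methods, and scores per-frame
entropy, background residual RMS against the true vessel support, and vessel
depth recovery relative to the planted depth map. Sample sizes were chosen
as the package's desk-scale stand-in for a multi-patient evaluation.

### What the phantom does and does not show

The phantom's respiratory motion is a rigid vertical translation. That makes
ground truth exact and matching well-posed, but it means a *translation*
refinement can in principle compensate any respiratory mismatch within its
search bound — including mismatches a clinically deforming abdomen would not
permit. The consequence is visible in the deep-breathing stress test
(`respiration$amplitude_ratio = 2`, emulating a patient who breathed deeper
during contrast acquisition): the patch method degrades (its entropy rises,
genuinely unmatchable content appears at the field edges, and with a manual
fixed threshold the over-exclusion guard fires on many patches — the
tiling-artifact pathway), yet its *advantage over whole-image matching
grows* rather than shrinks, because the whole-image baseline cannot
compensate at all while per-patch translation absorbs most of the mismatch.
On clinical data, deformation, through-plane motion and content changes
would limit the refinement in ways this phantom cannot express. Passing the
phantom study therefore demonstrates correct mechanics and the expected
method ordering under independent organ motion; it does not bound
performance on real angiograms.

Other realism gaps: no X-ray physics (scatter, beam hardening), no detector
lag, vessels do not pulsate, and noise is Gaussian rather than Poisson-
dominated.

## Numerical choices and degenerate inputs

* Grid partition: axis length $L = qN + r$ gives $r$ patches of $q{+}1$
  pixels then $N{-}r$ of $q$; patches tile the frame exactly and differ by
  at most one pixel per axis.
* Degenerate (zero-variance) patches: score 0, select frame 1 by the tie
  rule, skip refinement, but are still subtracted and brightness-corrected.
* Infeasible subpixel samples (outside the frame) signal the optimizer with
  a penalty score of −2 rather than raising an error.
* The entropy histogram anchors at the observed minimum, so entropy is
  invariant under adding a constant; an empty or non-finite image is an
  error, a constant image has entropy 0.
* All-zero paired differences make the signed-rank test undefined; the
  comparison reports that state instead of a p-value.
* Signed DSA frames are written as offset/scale-encoded 16-bit TIFF with a
  JSON sidecar recording the exact decode (the installed TIFF writer does
  not support arbitrary-range float samples); integer-valued series in
  range are written verbatim and round-trip exactly.

## Problem sizes used by the shipped studies

The test suite exercises unit properties on 80 x 104 px phantoms (10 mask /
6 contrast frames) and the full study on 10 default-scale cases; the
acceptance script reruns the same 10-case study from scratch. These sizes
are the package's chosen desk-scale study conditions.

## Known limitations

* DICOM input is not supported in this build; convert to multi-page TIFF or
  PNG frames first.
* The refinement model is pure translation — no rotation, scaling or
  deformation — matching the method's design, and it shares the method's
  known failure modes: structures that genuinely changed between series
  (deep-breathing mismatch) and threshold-driven brightness errors
  (tiling). The over-exclusion guard mitigates, not eliminates, the latter.
* Entropy is a no-reference proxy: it rewards concentrated histograms, not
  anatomical correctness. The phantom study therefore also checks residuals
  and depth recovery against ground truth.
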