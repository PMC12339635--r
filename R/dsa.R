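# Step C — brightness-corrected patch subtraction and method orchestration.

#' Brightness-correction parameter set
#'
#' Because each grid cell may subtract a *different* mask frame (and a
#' subpixel-resampled one), per-patch brightness offsets would otherwise
#' produce visible tiling artifacts at patch seams. Each mask patch is
#' therefore shifted by the scalar `mean(contrast) - mean(mask)` computed
#' over pixels that are *not* contrast-enhanced; enhanced pixels exist only
#' in the contrast patch and would bias the contrast mean downward
#' (contrast agent is dark), causing over-correction.
#'
#' @param exclusion_mode `"robust_sigma"` (default): a pixel of the
#'   preliminary subtraction patch is contrast-enhanced when it lies below
#'   `median - sigma_k * 1.4826 * MAD`; or `"fixed_threshold"`: below a
#'   user-chosen signed intensity, reproducing a manually tuned workflow.
#' @param fixed_threshold signed intensity threshold (fixed_threshold mode).
#' @param sigma_k robust-sigma multiplier (default 2).
#' @param max_excluded_fraction if thresholding would exclude more than this
#'   fraction of a patch, the exclusion is abandoned for that patch and every
#'   pixel is used — a guard against poorly chosen thresholds marking nearly
#'   a whole artifact-bearing patch as "contrast-enhanced" and then
#'   mis-correcting it.
#' @return An object of class `brightness_params`.
#' @export
brightness_params <- function(exclusion_mode = c("robust_sigma",
                                                 "fixed_threshold"),
                              fixed_threshold = NULL, sigma_k = 2,
                              max_excluded_fraction = 0.9) {
  exclusion_mode <- match.arg(exclusion_mode)
  if (exclusion_mode == "fixed_threshold" &&
      (is.null(fixed_threshold) || !is.finite(fixed_threshold)))
    stop("fixed_threshold mode requires a finite `fixed_threshold`",
         call. = FALSE)
  stopifnot(sigma_k > 0, max_excluded_fraction > 0,
            max_excluded_fraction <= 1)
  structure(list(exclusion_mode = exclusion_mode,
                 fixed_threshold = fixed_threshold,
                 sigma_k = sigma_k,
                 max_excluded_fraction = max_excluded_fraction),
            class = "brightness_params")
}

#' Mark contrast-enhanced pixels of a preliminary subtraction patch
#'
#' Operates on the preliminary DSA patch (contrast minus refined mask, before
#' any brightness correction), where contrast-enhanced pixels are strongly
#' negative. Pixels below the threshold are marked enhanced. If the marked
#' fraction exceeds `max_excluded_fraction` the mask is reset to all-`FALSE`
#' (use every pixel) and the patch is flagged via the `"fallback"` attribute,
#' with a warning.
#'
#' @param preliminary_dsa_patch signed numeric matrix.
#' @param params a [brightness_params()].
#' @return Logical matrix (`TRUE` = excluded), with attributes
#'   `excluded_fraction` (the fraction actually excluded after any fallback)
#'   and `fallback`.
#' @export
estimate_exclusion_mask <- function(preliminary_dsa_patch,
                                    params = brightness_params()) {
  stopifnot(inherits(params, "brightness_params"))
  x <- preliminary_dsa_patch
  thr <- if (params$exclusion_mode == "fixed_threshold") {
    params$fixed_threshold
  } else {
    med <- stats::median(x)
    med - params$sigma_k * 1.4826 * stats::median(abs(x - med))
  }
  mask <- x < thr
  fallback <- FALSE
  if (mean(mask) > params$max_excluded_fraction) {
    warning(sprintf(
      "exclusion threshold marked %.0f%% of the patch as contrast-enhanced (> %.0f%%); falling back to using every pixel",
      100 * mean(mask), 100 * params$max_excluded_fraction), call. = FALSE)
    mask[] <- FALSE
    fallback <- TRUE
  }
  attr(mask, "excluded_fraction") <- mean(mask)
  attr(mask, "fallback") <- fallback
  mask
}

#' Brightness-correct a mask patch against its contrast patch
#'
#' Adds the scalar `mu_c - mu_m` to every pixel of the mask patch, where both
#' means are taken over the non-excluded pixel set. Using the same support
#' for both means makes the correction exact: afterwards the corrected mask
#' patch and the contrast patch have identical means over the non-excluded
#' pixels, so the subtraction is offset-free outside vessels.
#'
#' @param mask_patch,contrast_patch numeric matrices of identical shape.
#' @param exclusion logical matrix (`TRUE` = excluded from the means); must
#'   not be all-`TRUE`.
#' @return The corrected mask patch.
#' @export
correct_brightness <- function(mask_patch, contrast_patch, exclusion) {
  stopifnot(identical(dim(mask_patch), dim(contrast_patch)),
            identical(dim(exclusion), dim(mask_patch)))
  keep <- !exclusion
  if (!any(keep))
    stop("all pixels excluded; the over-exclusion fallback should have ",
         "prevented this", call. = FALSE)
  mask_patch + (mean(contrast_patch[keep]) - mean(mask_patch[keep]))
}

new_dsa_frame <- function(image, match_map, method) {
  structure(list(image = image, match_map = match_map, method = method),
            class = "dsa_frame")
}

#' @export
print.dsa_frame <- function(x, ...) {
  cat(sprintf("<dsa_frame> %d x %d px, method=%s, value range [%.3g, %.3g]\n",
              nrow(x$image), ncol(x$image), x$method,
              min(x$image), max(x$image)))
  invisible(x)
}

#' Generate one patch-based DSA frame
#'
#' The full per-frame pipeline: for every grid cell, (A) select the
#' phase-matched mask frame by ZNCC ([match_patch()]), (B) refine the mask
#' patch by subpixel translation ([refine_match()]), then (C) compute the
#' preliminary subtraction, estimate the contrast-enhanced exclusion mask,
#' brightness-correct the mask patch and subtract. Patches are written into
#' the output at their grid positions with no blending — seam consistency is
#' handled entirely by the brightness correction.
#'
#' @param contrast_frame numeric matrix (one target contrast frame).
#' @param mask_series the mask [image_series()].
#' @param grid a [build_grid()] for the shared frame shape.
#' @param refine_params a [refinement_params()], or `NULL` to skip step B.
#' @param brightness a [brightness_params()].
#' @return A `dsa_frame`: signed subtraction `image`, the per-patch
#'   `match_map` (with refined offsets, scores and exclusion diagnostics) and
#'   `method = "patchdsa"`.
#' @export
generate_dsa_frame <- function(contrast_frame, mask_series,
                               grid = build_grid(nrow(contrast_frame),
                                                 ncol(contrast_frame), 10),
                               refine_params = refinement_params(),
                               brightness = brightness_params()) {
  mm <- phase_match_frame(contrast_frame, mask_series, grid)
  out <- matrix(0, nrow(contrast_frame), ncol(contrast_frame))
  for (k in seq_len(nrow(mm))) {
    i <- mm$i[k]; j <- mm$j[k]
    b <- patch_bounds(grid, i, j)
    rows <- (b$row + 1L):(b$row + b$height)
    cols <- (b$col + 1L):(b$col + b$width)
    cpatch <- contrast_frame[rows, cols, drop = FALSE]
    mframe <- mask_series$frames[[mm$t_star[k]]]
    if (!is.null(refine_params) && !mm$degenerate[k]) {
      rf <- refine_match(cpatch, mframe, c(b$row, b$col), refine_params)
      mm$tx[k] <- rf$tx; mm$ty[k] <- rf$ty; mm$refined_score[k] <- rf$score
      mpatch <- sample_shifted_patch(mframe, c(b$row, b$col),
                                     c(b$height, b$width), c(rf$tx, rf$ty))
    } else {
      mpatch <- mframe[rows, cols, drop = FALSE]
    }
    prelim <- cpatch - mpatch
    excl <- estimate_exclusion_mask(prelim, brightness)
    mm$excluded_fraction[k] <- attr(excl, "excluded_fraction")
    mm$fallback[k] <- attr(excl, "fallback")
    out[rows, cols] <- cpatch - correct_brightness(mpatch, cpatch, excl)
  }
  new_dsa_frame(out, mm, "patchdsa")
}

#' Generate the full patch-based DSA sequence
#'
#' Applies [generate_dsa_frame()] to every contrast frame in order. Frames
#' are processed independently, so the t-th output depends only on the t-th
#' contrast frame and the mask series.
#'
#' @param contrast_series,mask_series [image_series()] objects of identical
#'   frame shape.
#' @param n_divisions grid divisions per axis (default 10).
#' @param refine_params a [refinement_params()], or `NULL` to skip step B.
#' @param brightness a [brightness_params()].
#' @return List of `dsa_frame` objects, one per contrast frame.
#' @export
generate_dsa_sequence <- function(contrast_series, mask_series,
                                  n_divisions = 10,
                                  refine_params = refinement_params(),
                                  brightness = brightness_params()) {
  check_series_pair(contrast_series, mask_series)
  d <- frame_dim(contrast_series)
  grid <- build_grid(d[1], d[2], n_divisions)
  lapply(contrast_series$frames, generate_dsa_frame, mask_series = mask_series,
         grid = grid, refine_params = refine_params, brightness = brightness)
}

#' First-frame simple subtraction baseline
#'
#' The naive DSA: every contrast frame minus the *first* mask frame, whole
#' image, no matching and no brightness correction. Any respiratory
#' displacement between the first mask frame and a given contrast frame
#' appears directly as a motion artifact.
#'
#' @inheritParams generate_dsa_sequence
#' @return List of `dsa_frame` objects with `method = "simple"`.
#' @export
simple_subtraction <- function(contrast_series, mask_series) {
  check_series_pair(contrast_series, mask_series)
  m1 <- mask_series$frames[[1]]
  lapply(seq_len(n_frames(contrast_series)), function(t) {
    mm <- data.frame(i = 1L, j = 1L, t_star = 1L, coarse_score = NA_real_,
                     tx = 0, ty = 0, refined_score = NA_real_,
                     excluded_fraction = NA_real_, fallback = FALSE,
                     degenerate = FALSE)
    class(mm) <- c("match_map", "data.frame")
    new_dsa_frame(contrast_series$frames[[t]] - m1, mm, "simple")
  })
}

#' Whole-image phase matching baseline
#'
#' For each contrast frame, selects the *single* mask frame with the highest
#' whole-image (or ROI) ZNCC and subtracts it globally. This is the
#' respiratory phase-matching strategy of Ohnishi et al., with the selection
#' direction reversed so that the contrast frame is the target — the same
#' orientation as the patch-based method. The ROI stands in for a
#' diaphragm-region box; by default the whole frame is used. Because one
#' frame must serve the entire field of view, organs moving independently of
#' the diaphragm (heart, bowel) remain misaligned.
#'
#' @inheritParams generate_dsa_sequence
#' @param roi optional [crop_rect()]: restrict the similarity evaluation to
#'   this region (the subtraction is always whole-image).
#' @param brightness optional [brightness_params()]: when supplied, one
#'   global brightness offset (with contrast-region exclusion) is applied per
#'   frame; `NULL` (default) subtracts without correction.
#' @return List of `dsa_frame` objects with `method = "ohnishi"`.
#' @export
global_phase_match <- function(contrast_series, mask_series, roi = NULL,
                               brightness = NULL) {
  check_series_pair(contrast_series, mask_series)
  d <- frame_dim(contrast_series)
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "crop_rect"))
    if (roi$top + roi$height > d[1] || roi$left + roi$width > d[2])
      stop("roi exceeds frame bounds", call. = FALSE)
    rows <- (roi$top + 1L):(roi$top + roi$height)
    cols <- (roi$left + 1L):(roi$left + roi$width)
  } else {
    rows <- seq_len(d[1]); cols <- seq_len(d[2])
  }
  lapply(contrast_series$frames, function(cf) {
    target <- cf[rows, cols, drop = FALSE]
    scores <- vapply(mask_series$frames, function(m)
      zncc(target, m[rows, cols, drop = FALSE]), numeric(1))
    t_star <- which.max(scores)
    mframe <- mask_series$frames[[t_star]]
    img <- cf - mframe
    fallback <- FALSE; efrac <- NA_real_
    if (!is.null(brightness)) {
      excl <- estimate_exclusion_mask(img, brightness)
      efrac <- attr(excl, "excluded_fraction")
      fallback <- attr(excl, "fallback")
      img <- cf - correct_brightness(mframe, cf, excl)
    }
    mm <- data.frame(i = 1L, j = 1L, t_star = t_star,
                     coarse_score = scores[t_star], tx = 0, ty = 0,
                     refined_score = scores[t_star],
                     excluded_fraction = efrac, fallback = fallback,
                     degenerate = FALSE)
    class(mm) <- c("match_map", "data.frame")
    new_dsa_frame(img, mm, "ohnishi")
  })
}

check_series_pair <- function(contrast_series, mask_series) {
  stopifnot(inherits(contrast_series, "image_series"),
            inherits(mask_series, "image_series"))
  if (!identical(frame_dim(contrast_series), frame_dim(mask_series)))
    stop("contrast and mask series have different frame shapes (",
         paste(frame_dim(contrast_series), collapse = "x"), " vs ",
         paste(frame_dim(mask_series), collapse = "x"), ")", call. = FALSE)
  invisible(TRUE)
}

#' Stack the match maps of a DSA sequence into one table
#'
#' @param frames list of `dsa_frame` objects.
#' @return A `match_map` data.frame with a leading `frame` column.
#' @export
sequence_match_map <- function(frames) {
  mm <- do.call(rbind, lapply(seq_along(frames), function(t)
    cbind(frame = t, as.data.frame(frames[[t]]$match_map))))
  class(mm) <- c("match_map", "data.frame")
  mm
}
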