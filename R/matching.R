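# Step A — patch-based respiratory phase matching.

#' Zero-normalized cross-correlation of two equal-size patches
#'
#' ZNCC subtracts each patch's mean and normalizes by the standard
#' deviations, so the score is invariant to positive affine intensity maps of
#' either argument and lies in \[-1, 1\]. It is the similarity metric used
#' both for phase matching across mask frames and for the subpixel
#' refinement objective. A patch with zero variance carries no structure to
#' correlate; such comparisons return the sentinel 0 (see
#' [patch_is_degenerate()]).
#'
#' @param a,b numeric matrices of identical shape with at least 2 pixels.
#' @return `sum((a - mean(a)) * (b - mean(b))) /
#'   sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))`, or 0 if either patch
#'   has zero variance.
#' @export
zncc <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("zncc: patch shapes differ (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")", call. = FALSE)
  if (length(a) < 2L)
    stop("zncc: patches must have at least 2 pixels", call. = FALSE)
  da <- a - mean(a)
  db <- b - mean(b)
  va <- sum(da * da)
  vb <- sum(db * db)
  if (va == 0 || vb == 0) return(0)
  sum(da * db) / sqrt(va * vb)
}

#' Is a patch degenerate for matching?
#'
#' A constant (zero-variance) patch cannot be scored by ZNCC; matching falls
#' back to the sentinel score 0 and the earliest mask frame, and such cells
#' are flagged so downstream steps can skip refinement while still
#' subtracting them.
#'
#' @param x numeric matrix.
#' @export
patch_is_degenerate <- function(x) {
  d <- x - mean(x)
  sum(d * d) == 0
}

#' Select the phase-matched mask frame for one patch
#'
#' Scores the contrast patch against the co-located patch of every mask frame
#' by ZNCC and returns the frame attaining the maximum — the mask frame whose
#' local respiratory (or cardiac/peristaltic) phase best matches the contrast
#' frame at this grid cell. The search is exhaustive over all T mask frames;
#' ties break to the smallest frame index.
#'
#' @param contrast_patch numeric matrix (the patch of the target contrast
#'   frame at cell (i, j)).
#' @param mask_series the mask [image_series()].
#' @param cell integer pair (i, j).
#' @param grid the [build_grid()] consistent with the mask frame shape.
#' @return list with `t_star` (selected mask frame, 1-based), `score`
#'   (attained ZNCC), `degenerate` (TRUE if the contrast patch, or every mask
#'   patch, had zero variance).
#' @export
match_patch <- function(contrast_patch, mask_series, cell, grid) {
  stopifnot(inherits(mask_series, "image_series"))
  if (n_frames(mask_series) == 0L)
    stop("empty mask series", call. = FALSE)
  i <- cell[1]; j <- cell[2]
  dc <- contrast_patch - mean(contrast_patch)    # hoisted out of the T loop
  vc <- sum(dc * dc)
  any_ok <- FALSE
  scores <- vapply(mask_series$frames, function(m) {
    b <- extract_patch(m, grid, i, j)
    db <- b - mean(b)
    vb <- sum(db * db)
    if (vc == 0 || vb == 0) return(0)
    any_ok <<- TRUE
    sum(dc * db) / sqrt(vc * vb)
  }, numeric(1))
  t_star <- which.max(scores)            # which.max takes the first maximum
  list(t_star = t_star, score = scores[t_star], degenerate = !any_ok)
}

#' Phase-match every patch of one contrast frame
#'
#' Runs [match_patch()] independently for all N^2 grid cells and collects the
#' result in a match map: one row per cell with the selected mask frame, the
#' coarse ZNCC, the (not yet refined) subpixel offset and the degeneracy
#' flag. Cells are independent, so any evaluation order gives the same map.
#'
#' @param contrast_frame numeric matrix.
#' @param mask_series the mask [image_series()].
#' @param grid a [build_grid()] for the shared frame shape.
#' @return A `match_map` data.frame with columns `i`, `j`, `t_star`,
#'   `coarse_score`, `tx`, `ty`, `refined_score`, `excluded_fraction`,
#'   `fallback`, `degenerate`; `tx`/`ty` are 0 and `refined_score` equals
#'   `coarse_score` until refinement.
#' @export
phase_match_frame <- function(contrast_frame, mask_series, grid) {
  stopifnot(is.matrix(contrast_frame))
  if (!identical(dim(contrast_frame), frame_dim(mask_series)))
    stop("contrast frame shape ", paste(dim(contrast_frame), collapse = "x"),
         " does not match mask series shape ",
         paste(frame_dim(mask_series), collapse = "x"), call. = FALSE)
  n <- grid$n
  cells <- expand.grid(j = seq_len(n), i = seq_len(n))[, c("i", "j")]
  res <- mapply(function(i, j) {
    m <- match_patch(extract_patch(contrast_frame, grid, i, j),
                     mask_series, c(i, j), grid)
    c(m$t_star, m$score, m$degenerate)
  }, cells$i, cells$j)
  mm <- data.frame(i = cells$i, j = cells$j,
                   t_star = as.integer(res[1, ]),
                   coarse_score = res[2, ],
                   tx = 0, ty = 0,
                   refined_score = res[2, ],
                   excluded_fraction = NA_real_,
                   fallback = FALSE,
                   degenerate = as.logical(res[3, ]))
  class(mm) <- c("match_map", "data.frame")
  mm
}

#' Write / read a match map as CSV
#'
#' The per-patch provenance of a DSA frame (selected mask frame, ZNCC before
#' and after refinement, subpixel offset, exclusion diagnostics) serialized
#' for audit.
#'
#' @param match_map a `match_map` data.frame (optionally with a `frame`
#'   column when several frames are stacked).
#' @param path CSV file path.
#' @export
write_match_map <- function(match_map, path) {
  utils::write.csv(as.data.frame(match_map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_match_map
#' @export
read_match_map <- function(path) {
  mm <- utils::read.csv(path)
  class(mm) <- c("match_map", "data.frame")
  mm
}
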