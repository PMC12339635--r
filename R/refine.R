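# Step B — subpixel refinement of the selected mask patch.
#
# After phase matching, residual motion within the selected mask frame is
# typically well under a pixel to a few pixels. The selected patch is
# translated inside the whole mask frame by continuous offsets (t_x, t_y),
# resampled bilinearly, and the translation maximizing ZNCC against the
# contrast patch is found with a 2-D downhill simplex (Nelder-Mead) search.

#' Refinement parameter set
#'
#' @param initial_step initial simplex edge length in pixels. The initial
#'   simplex has vertices (0,0), (`initial_step`, 0), (0, `initial_step`).
#' @param xtol stop when the simplex has collapsed to this size in pixels.
#' @param ftol stop when the ZNCC spread across the simplex is below this.
#' @param max_iter maximum simplex iterations.
#' @param max_shift search bound per axis in pixels; `NULL` (default) means
#'   half the smaller patch edge, capped at 10 px. A tight bound keeps the
#'   search from locking onto repetitive structures such as ribs one period
#'   away.
#' @return An object of class `refinement_params`.
#' @export
refinement_params <- function(initial_step = 1.0, xtol = 0.01, ftol = 1e-5,
                              max_iter = 200L, max_shift = NULL) {
  stopifnot(initial_step > 0, xtol > 0, ftol > 0, max_iter >= 1)
  if (!is.null(max_shift)) {
    stopifnot(max_shift > 0)
    if (max_shift < initial_step)
      stop("max_shift must be >= initial_step", call. = FALSE)
  }
  structure(list(initial_step = initial_step, xtol = xtol, ftol = ftol,
                 max_iter = as.integer(max_iter), max_shift = max_shift),
            class = "refinement_params")
}

#' Sample a translated patch from a mask frame at subpixel resolution
#'
#' Returns the h x w patch whose pixel (u, v) is the bilinear interpolation
#' of `mask_frame` at position (`cell_origin[1] + u + t_y`,
#' `cell_origin[2] + v + t_x`) (0-based pixel coordinates; `t_x` shifts along
#' columns, `t_y` along rows). Integer shifts reproduce exact pixel copies.
#' If any required sample position falls outside the frame the shift is
#' infeasible and `NULL` is returned; the optimizer treats that as a penalty
#' rather than an error so the simplex can recover from an excursion.
#'
#' @param mask_frame numeric matrix (the whole selected mask frame).
#' @param cell_origin 0-based (row, col) of the patch's upper-left corner.
#' @param patch_shape (h, w) of the patch.
#' @param shift (t_x, t_y) translation in pixels.
#' @return h x w numeric matrix, or `NULL` if the shift is infeasible.
#' @export
sample_shifted_patch <- function(mask_frame, cell_origin, patch_shape, shift) {
  h <- patch_shape[1]; w <- patch_shape[2]
  H <- nrow(mask_frame); W <- ncol(mask_frame)
  rows <- cell_origin[1] + 0:(h - 1) + shift[2]
  cols <- cell_origin[2] + 0:(w - 1) + shift[1]
  if (rows[1] < 0 || rows[h] > H - 1 || cols[1] < 0 || cols[w] > W - 1)
    return(NULL)
  fr <- pmin(floor(rows), H - 2); wr <- rows - fr
  fc <- pmin(floor(cols), W - 2); wc <- cols - fc
  a11 <- mask_frame[fr + 1, fc + 1, drop = FALSE]
  a21 <- mask_frame[fr + 2, fc + 1, drop = FALSE]
  a12 <- mask_frame[fr + 1, fc + 2, drop = FALSE]
  a22 <- mask_frame[fr + 2, fc + 2, drop = FALSE]
  a11 * ((1 - wr) %o% (1 - wc)) + a21 * (wr %o% (1 - wc)) +
    a12 * ((1 - wr) %o% wc)     + a22 * (wr %o% wc)
}

# Compact 2-D Nelder-Mead with the standard coefficients (reflection 1,
# expansion 2, contraction 0.5, shrink 0.5), a fixed right-angle initial
# simplex, and best-ever bookkeeping done by the caller's objective. Entirely
# deterministic.
nelder_mead_2d <- function(fn, x0, step, xtol, ftol, max_iter) {
  verts <- list(x0, x0 + c(step, 0), x0 + c(0, step))
  fv <- vapply(verts, fn, numeric(1))
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    ord <- order(fv)
    verts <- verts[ord]; fv <- fv[ord]
    size <- max(abs(verts[[2]] - verts[[1]]), abs(verts[[3]] - verts[[1]]))
    if (size < xtol && (fv[3] - fv[1]) < ftol) { converged <- TRUE; break }
    iter <- iter + 1L
    centroid <- (verts[[1]] + verts[[2]]) / 2
    xr <- centroid + (centroid - verts[[3]])
    fr <- fn(xr)
    if (fr < fv[1]) {                       # try expansion
      xe <- centroid + 2 * (centroid - verts[[3]])
      fe <- fn(xe)
      if (fe < fr) { verts[[3]] <- xe; fv[3] <- fe }
      else         { verts[[3]] <- xr; fv[3] <- fr }
    } else if (fr < fv[2]) {
      verts[[3]] <- xr; fv[3] <- fr
    } else {
      if (fr < fv[3]) {                     # outside contraction
        xc <- centroid + 0.5 * (xr - centroid)
        fc_ <- fn(xc)
        if (fc_ <= fr) { verts[[3]] <- xc; fv[3] <- fc_; next }
      } else {                              # inside contraction
        xc <- centroid - 0.5 * (centroid - verts[[3]])
        fc_ <- fn(xc)
        if (fc_ < fv[3]) { verts[[3]] <- xc; fv[3] <- fc_; next }
      }
      for (k in 2:3) {                      # shrink toward the best vertex
        verts[[k]] <- verts[[1]] + 0.5 * (verts[[k]] - verts[[1]])
        fv[k] <- fn(verts[[k]])
      }
    }
  }
  list(converged = converged, iterations = iter)
}

#' Refine a phase-matched patch by subpixel translation
#'
#' Maximizes `zncc(contrast_patch, sample_shifted_patch(mask_frame, ...))`
#' over the translation (t_x, t_y), starting from (0, 0) — the position
#' selected by phase matching — with a downhill simplex search. Shifts that
#' sample outside the frame or exceed `max_shift` are penalized (score -2)
#' instead of clamped. The returned translation is the best *feasible* point
#' ever evaluated, not the final simplex state, so the refined score can
#' never fall below the coarse score at (0, 0).
#'
#' @param contrast_patch numeric matrix.
#' @param mask_frame the whole selected mask frame M_t*.
#' @param cell_origin 0-based (row, col) of the patch in the frame.
#' @param params a [refinement_params()].
#' @return list with `tx`, `ty`, `score`, `converged`, `degenerate`,
#'   `evaluations`.
#' @export
refine_match <- function(contrast_patch, mask_frame, cell_origin,
                         params = refinement_params()) {
  stopifnot(inherits(params, "refinement_params"))
  shape <- dim(contrast_patch)
  if (patch_is_degenerate(contrast_patch))
    return(list(tx = 0, ty = 0, score = 0, converged = FALSE,
                degenerate = TRUE, evaluations = 0L))
  max_shift <- params$max_shift
  if (is.null(max_shift)) max_shift <- min(min(shape) / 2, 10)
  dc <- contrast_patch - mean(contrast_patch)   # constant across evaluations
  vc <- sum(dc * dc)
  env <- new.env(parent = emptyenv())
  env$best_f <- Inf; env$best_x <- c(0, 0); env$n <- 0L
  fn <- function(x) {
    env$n <- env$n + 1L
    if (abs(x[1]) > max_shift || abs(x[2]) > max_shift) return(2)
    p <- sample_shifted_patch(mask_frame, cell_origin, shape, x)
    if (is.null(p)) return(2)
    dp <- p - mean(p)
    vp <- sum(dp * dp)
    f <- if (vp == 0) 0 else -sum(dc * dp) / sqrt(vc * vp)
    if (f < env$best_f) { env$best_f <- f; env$best_x <- x }
    f
  }
  f0 <- fn(c(0, 0))   # seed best-ever with the unshifted position
  nm <- nelder_mead_2d(fn, c(0, 0), params$initial_step,
                       params$xtol, params$ftol, params$max_iter)
  list(tx = env$best_x[1], ty = env$best_x[2], score = -env$best_f,
       converged = nm$converged, degenerate = FALSE, evaluations = env$n)
}
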