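#' Build the N x N patch grid
#'
#' Partitions an H x W frame into `n_divisions` near-equal intervals per axis.
#' When the axis length is not divisible by N, the remainder r is distributed
#' as one extra pixel to the first r intervals, so patch edge lengths differ
#' by at most one pixel and the patches tile the frame exactly. N = 10 is the
#' working default for clinical-scale frames: smaller patches carry too little
#' structure for reliable matching, larger ones average over locally
#' independent organ motion.
#'
#' @param height,width frame dimensions in pixels.
#' @param n_divisions number of grid divisions per axis (>= 1). Each patch
#'   must be at least 2 x 2 px, so `height` and `width` must both be at least
#'   `2 * n_divisions`.
#' @return An object of class `patch_grid` with fields `n`, `row_cuts`,
#'   `col_cuts` (0-based cut positions, length n+1, covering `[0, height]` and
#'   `[0, width]`); patch (i, j) spans rows `[row_cuts[i], row_cuts[i+1])` and
#'   columns `[col_cuts[j], col_cuts[j+1])`.
#' @examples
#' g <- build_grid(370, 490, 10)
#' diff(g$row_cuts)  # ten 37s
#' @export
build_grid <- function(height, width, n_divisions) {
  stopifnot(n_divisions >= 1, n_divisions == round(n_divisions))
  n <- as.integer(n_divisions)
  if (height < 2L * n || width < 2L * n)
    stop(sprintf(
      "frame %d x %d too small for a %d x %d grid: every patch needs >= 2 px per axis (minimum frame %d x %d)",
      height, width, n, n, 2L * n, 2L * n), call. = FALSE)
  structure(list(n = n,
                 row_cuts = axis_cuts(as.integer(height), n),
                 col_cuts = axis_cuts(as.integer(width), n),
                 height = as.integer(height), width = as.integer(width)),
            class = "patch_grid")
}

axis_cuts <- function(len, n) {
  base <- len %/% n
  r <- len %% n
  lengths <- rep.int(base, n)
  if (r > 0) lengths[seq_len(r)] <- base + 1L
  c(0L, cumsum(lengths))
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d cells over %d x %d px\n",
              x$n, x$n, x$height, x$width))
  invisible(x)
}

# 0-based origin and shape of patch (i, j).
patch_bounds <- function(grid, i, j) {
  stopifnot(i >= 1, i <= grid$n, j >= 1, j <= grid$n)
  list(row = grid$row_cuts[i], col = grid$col_cuts[j],
       height = grid$row_cuts[i + 1L] - grid$row_cuts[i],
       width = grid$col_cuts[j + 1L] - grid$col_cuts[j])
}

# Extract patch (i, j) from a frame matrix.
extract_patch <- function(frame, grid, i, j) {
  b <- patch_bounds(grid, i, j)
  frame[(b$row + 1L):(b$row + b$height),
        (b$col + 1L):(b$col + b$width), drop = FALSE]
}
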