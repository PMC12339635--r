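#' Construct an image series
#'
#' An `image_series` is the in-memory representation of one fluoroscopy
#' acquisition: an ordered list of grayscale frames of identical shape, tagged
#' with its role in DSA generation (`"mask"` = pre-contrast, `"contrast"` =
#' during/after contrast injection). Pixel values are stored as doubles in
#' detector units; by convention a higher value is a brighter pixel, so
#' iodinated contrast agent (which attenuates X-rays) appears *darker* in
#' contrast frames and preliminary subtractions contrast - mask are negative
#' inside vessels.
#'
#' @param frames list of numeric matrices, all with identical dimensions, or a
#'   single matrix (treated as a one-frame series). All values must be finite.
#' @param role `"mask"` or `"contrast"`.
#' @param pixel_spacing optional numeric length-2, (row, col) spacing in mm.
#' @param frame_rate optional frames per second.
#' @param source_id free-text identifier of the source.
#' @return An object of class `image_series` with fields `frames`, `role`,
#'   `pixel_spacing`, `frame_rate`, `source_id`.
#' @examples
#' s <- image_series(list(matrix(0, 4, 4), matrix(1, 4, 4)), role = "mask")
#' n_frames(s)
#' @export
image_series <- function(frames, role = c("mask", "contrast"),
                         pixel_spacing = NULL, frame_rate = NULL,
                         source_id = "") {
  role <- match.arg(role)
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f))
      stop("every frame must be a numeric matrix", call. = FALSE)
    dim(f)
  }, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop("inconsistent frame shapes at frame indices: ",
         paste(bad, collapse = ", "), call. = FALSE)
  nonfinite <- which(!vapply(frames, function(f) all(is.finite(f)), logical(1)))
  if (length(nonfinite))
    stop("non-finite pixel values in frames: ",
         paste(nonfinite, collapse = ", "), call. = FALSE)
  if (!is.null(pixel_spacing)) {
    stopifnot(is.numeric(pixel_spacing), length(pixel_spacing) == 2L,
              all(pixel_spacing > 0))
    pixel_spacing <- as.numeric(pixel_spacing)
  }
  if (!is.null(frame_rate)) {
    stopifnot(is.numeric(frame_rate), length(frame_rate) == 1L, frame_rate > 0)
    frame_rate <- as.numeric(frame_rate)
  }
  structure(
    list(frames = lapply(frames, function(f) {storage.mode(f) <- "double"; f}),
         role = role, pixel_spacing = pixel_spacing,
         frame_rate = frame_rate, source_id = as.character(source_id)),
    class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf("<image_series> role=%s, T=%d frames of %d x %d px\n",
              x$role, n_frames(x), d[1], d[2]))
  if (!is.null(x$frame_rate))
    cat(sprintf("  frame rate: %g /s\n", x$frame_rate))
  if (!is.null(x$pixel_spacing))
    cat(sprintf("  pixel spacing: %g x %g mm\n",
                x$pixel_spacing[1], x$pixel_spacing[2]))
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Number of frames in a series
#' @param series an `image_series`.
#' @export
n_frames <- function(series) length(series$frames)

#' Frame dimensions (rows, cols) of a series
#' @param series an `image_series`.
#' @export
frame_dim <- function(series) dim(series$frames[[1]])

#' Define a crop rectangle
#'
#' Rectangles are 0-based and half-open: `crop_rect(top, left, height, width)`
#' selects pixel rows `[top, top + height)` and columns `[left, left + width)`.
#' This row-major, 0-based, half-open convention is used throughout the
#' package.
#'
#' @param top,left 0-based offsets of the upper-left corner.
#' @param height,width extent in pixels (>= 1).
#' @return An object of class `crop_rect`.
#' @export
crop_rect <- function(top, left, height, width) {
  vals <- c(top = top, left = left, height = height, width = width)
  if (any(vals != round(vals)))
    stop("crop_rect fields must be integers", call. = FALSE)
  if (top < 0 || left < 0 || height < 1 || width < 1)
    stop("crop_rect requires top, left >= 0 and height, width >= 1",
         call. = FALSE)
  vals <- as.integer(round(vals))
  structure(list(top = vals[1], left = vals[2],
                 height = vals[3], width = vals[4]), class = "crop_rect")
}

#' Crop every frame of a series to a field-of-view rectangle
#'
#' Clinical fluoroscopy frames carry collimator borders and burned-in
#' annotation outside the fluoroscopic field; those regions are cropped away
#' before matching. All frames are cropped identically and the input series is
#' left unmodified.
#'
#' @param series an `image_series`.
#' @param rect a [crop_rect()] lying fully inside the frame.
#' @return A new `image_series` of cropped frames with metadata preserved.
#' @export
crop_series <- function(series, rect) {
  stopifnot(inherits(series, "image_series"), inherits(rect, "crop_rect"))
  d <- frame_dim(series)
  over_r <- rect$top + rect$height - d[1]
  over_c <- rect$left + rect$width - d[2]
  if (over_r > 0 || over_c > 0)
    stop(sprintf(
      "crop rectangle exceeds frame bounds by %d row(s) and %d column(s)",
      max(over_r, 0L), max(over_c, 0L)), call. = FALSE)
  rows <- (rect$top + 1L):(rect$top + rect$height)
  cols <- (rect$left + 1L):(rect$left + rect$width)
  out <- series
  out$frames <- lapply(series$frames, function(f) f[rows, cols, drop = FALSE])
  out
}
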