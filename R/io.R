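# Series I/O.
#
# Two on-disk layouts are supported: multi-page TIFF (8/16-bit unsigned
# samples) and a directory of PNG frames. Signed or non-integer data (DSA
# frames are signed by construction) cannot be stored in unsigned integer
# samples directly, so write_series() encodes such series affinely
# (stored = round((value - offset) * scale)) and records the decode in a JSON
# sidecar next to the image file; read_series() applies the sidecar
# transparently. Integer-valued series already within the sample range are
# stored verbatim and round-trip exactly.

#' Read an image series from disk
#'
#' Reads a multi-page TIFF or a directory of PNG frames into an
#' [image_series()]. PNG frames are ordered by natural sort of their file
#' names (`f2.png` before `f10.png`); TIFF pages keep their page order.
#' Multi-channel images whose channels are identical (gray stored as RGB) are
#' collapsed to one channel. If a JSON sidecar written by [write_series()] is
#' present, its affine decode and series metadata are applied.
#'
#' @param path a TIFF file or a directory of `.png` frames.
#' @param role `"mask"` or `"contrast"`.
#' @param format_hint optional, one of `"tiff"`, `"png_dir"`; inferred from
#'   `path` when omitted. (`"dicom"` is recognized but not supported by this
#'   build and raises an error.)
#' @param invert if `TRUE`, negate intensities on read. Use for sources whose
#'   lookup table is inverted relative to the package convention that
#'   brighter = higher value and contrast agent is dark.
#' @return An [image_series()].
#' @export
read_series <- function(path, role = c("mask", "contrast"),
                        format_hint = NULL, invert = FALSE) {
  role <- match.arg(role)
  fmt <- infer_format(path, format_hint)
  if (fmt == "dicom")
    stop("DICOM input is not supported by this build; ",
         "convert to multi-page TIFF or PNG frames first", call. = FALSE)
  if (fmt == "tiff") {
    if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                                 call. = FALSE)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("cannot read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    if (is.array(pages) || is.matrix(pages)) pages <- list(pages)
    frames <- lapply(pages, collapse_gray)
    sidecar <- sidecar_path(path)
  } else {
    if (!dir.exists(path)) stop("cannot read '", path, "': no such directory",
                                call. = FALSE)
    files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
    if (length(files) == 0L)
      stop("no .png frames found in '", path, "'", call. = FALSE)
    files <- files[natural_order(basename(files))]
    frames <- lapply(files, function(f) {
      img <- png::readPNG(f, info = TRUE)
      depth <- attr(img, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      collapse_gray(img) * (2^depth - 1)
    })
    sidecar <- file.path(path, "series.json")
  }
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (!is.null(meta) && identical(meta$encoding, "affine")) {
    frames <- lapply(frames, function(f) f / meta$scale + meta$offset)
  }
  if (invert) frames <- lapply(frames, function(f) -f)
  image_series(
    frames, role = role,
    pixel_spacing = if (!is.null(meta$pixel_spacing))
      unlist(meta$pixel_spacing),
    frame_rate = meta$frame_rate,
    source_id = if (!is.null(meta$source_id)) meta$source_id else path)
}

#' Write an image series to disk
#'
#' Writes a multi-page TIFF or a directory of PNG frames. Series whose values
#' are non-negative integers within the sample range are stored verbatim
#' (exact round trip). Anything else — signed DSA output in particular — is
#' offset/scale-encoded into the unsigned sample range and the decode is
#' recorded in a JSON sidecar (`<file>.json`, or `series.json` inside a PNG
#' directory) together with the series metadata, so sign and scale survive a
#' read/write cycle up to the declared bit depth.
#'
#' @param series an [image_series()].
#' @param path output TIFF file or PNG directory.
#' @param format `"tiff"` (default) or `"png_dir"`.
#' @param bits_per_sample 8 or 16 (PNG directories are always written 16-bit).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("tiff", "png_dir"),
                         bits_per_sample = 16L) {
  stopifnot(inherits(series, "image_series"))
  format <- match.arg(format)
  if (!bits_per_sample %in% c(8L, 16L))
    stop("bits_per_sample must be 8 or 16", call. = FALSE)
  if (format == "png_dir") bits_per_sample <- 16L
  maxval <- 2^bits_per_sample - 1
  v <- unlist(series$frames, use.names = FALSE)
  exact <- all(v >= 0) && all(v <= maxval) && all(v == round(v))
  if (exact) {
    offset <- 0; scale <- 1
  } else {
    offset <- min(v)
    rng <- max(v) - offset
    scale <- if (rng > 0) maxval / rng else 1
  }
  stored <- lapply(series$frames,
                   function(f) round((f - offset) * scale) / maxval)
  meta <- list(encoding = if (exact) "identity" else "affine",
               offset = offset, scale = scale,
               bits_per_sample = bits_per_sample,
               role = series$role, source_id = series$source_id,
               pixel_spacing = series$pixel_spacing,
               frame_rate = series$frame_rate)
  if (format == "tiff") {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(stored, path, bits.per.sample = bits_per_sample)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_along(stored))
      png::writePNG(stored[[t]],
                    file.path(path, sprintf("frame_%04d.png", t)))
    jsonlite::write_json(meta, file.path(path, "series.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

infer_format <- function(path, format_hint) {
  if (!is.null(format_hint))
    return(match.arg(format_hint, c("tiff", "png_dir", "dicom")))
  if (dir.exists(path)) return("png_dir")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("dcm", "dicom")) return("dicom")
  stop("cannot infer format of '", path,
       "'; pass format_hint = \"tiff\" or \"png_dir\"", call. = FALSE)
}

sidecar_path <- function(path) paste0(path, ".json")

# Collapse an H x W x C array whose channels agree to a single H x W matrix.
collapse_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    for (k in seq_len(ch - 1L))
      if (!isTRUE(all.equal(img[, , k], img[, , k + 1L], tolerance = 0)))
        stop("multi-channel frame with unequal channels; ",
             "expected single-channel grayscale", call. = FALSE)
    return(img[, , 1L])
  }
  stop("unsupported frame dimensionality: ",
       paste(dim(img), collapse = " x "), call. = FALSE)
}

# Order file names treating digit runs numerically ("f2" < "f10").
natural_order <- function(x) {
  padded <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), formatC,
                               width = 20, flag = "0")
    s
  }, character(1), USE.NAMES = FALSE)
  order(padded, x)
}
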