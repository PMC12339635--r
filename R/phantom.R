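# Synthetic breathing phantom.
#
# Emulates one fluoroscopic acquisition pair: a mask series and a contrast
# series that share background anatomy (intensity gradient, rib-like bands,
# smooth texture, a soft diaphragm edge), all displaced vertically by a
# sinusoidal respiratory motion, plus two motions *independent* of
# respiration — a pulsating cardiac disk and drifting bowel gas pockets —
# and, in the contrast series only, a dark branching vessel tree whose depth
# ramps in over the first frames (contrast inflow). Detector noise is added
# last. The generator also emits the ground truth (trajectories, per-frame
# vessel masks) that the validation suite scores against.

#' Phantom configuration
#'
#' Defaults mirror the clinical acquisition protocol the package targets —
#' 30 mask frames and 50 contrast frames at 6 frames/s — at a desk-scale
#' frame of 240 x 312 px (patches at N = 10 then have the same
#' vessel-to-patch proportions as clinically cropped frames). The vessel depth is negative: contrast agent
#' attenuates X-rays, so vessels are darker than background, matching the
#' package-wide intensity convention.
#'
#' @param height,width frame shape in pixels.
#' @param t_mask,t_contrast frame counts of the two series.
#' @param frame_rate frames per second.
#' @param respiration list: `amplitude` (px, peak diaphragm displacement),
#'   `period` (s), `amplitude_ratio` (contrast:mask amplitude; > 1 emulates
#'   deeper breathing during contrast acquisition, the classic
#'   phase-matching failure mode).
#' @param cardiac list: `center` (row, col as fractions of the frame),
#'   `radius` (px), `amplitude` (px radius pulsation), `period` (s), `depth`
#'   (intensity of the cardiac disk, negative = darker).
#' @param bowel list: `centers` (list of (row, col) fractions), `radius` (px),
#'   `amplitude` (intensity of the gas pockets, positive = brighter),
#'   `drift_speed` (px/frame), `walk_sd` (random-walk step SD, px/frame).
#' @param vessel list: `tree` (list of segments, each (r1, c1, r2, c2) in
#'   fractions of the frame), `width` (px half-width), `depth` (negative
#'   intensity), `inflow_frames` (frames over which depth ramps to full).
#' @param noise list: `gaussian_sd` (detector noise SD, intensity units).
#' @param seed integer; fixes every random component.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 240, width = 312,
                           t_mask = 30, t_contrast = 50, frame_rate = 6,
                           respiration = list(),
                           cardiac = list(),
                           bowel = list(),
                           vessel = list(),
                           noise = list(),
                           seed = 1L) {
  # shallow merge: user keys replace defaults wholesale (modifyList would
  # silently skip unnamed nested lists such as the vessel tree)
  merge_opts <- function(def, user) {
    for (nm in names(user)) def[[nm]] <- user[[nm]]
    def
  }
  cfg <- list(
    height = as.integer(height), width = as.integer(width),
    t_mask = as.integer(t_mask), t_contrast = as.integer(t_contrast),
    frame_rate = frame_rate,
    respiration = merge_opts(
      list(amplitude = 6, period = 4, amplitude_ratio = 1), respiration),
    cardiac = merge_opts(
      list(center = c(0.27, 0.27), radius = 28, amplitude = 2, period = 1,
           depth = -20), cardiac),
    bowel = merge_opts(
      list(centers = list(c(0.73, 0.25), c(0.80, 0.65), c(0.62, 0.85)),
           radius = 13, amplitude = 18, drift_speed = 0.25, walk_sd = 0.15),
      bowel),
    vessel = merge_opts(
      list(tree = list(c(0.15, 0.45, 0.45, 0.50),
                       c(0.45, 0.50, 0.78, 0.40),
                       c(0.45, 0.50, 0.62, 0.70),
                       c(0.28, 0.47, 0.40, 0.28)),
           width = 1.5, depth = -50, inflow_frames = 12), vessel),
    noise = merge_opts(list(gaussian_sd = 2), noise),
    seed = as.integer(seed))
  stopifnot(cfg$height >= 20, cfg$width >= 20, cfg$t_mask >= 1,
            cfg$t_contrast >= 1, cfg$frame_rate > 0,
            cfg$respiration$amplitude > 0, cfg$respiration$period > 0,
            cfg$respiration$amplitude_ratio > 0,
            cfg$cardiac$period > 0, cfg$cardiac$radius > 0,
            cfg$vessel$width > 0, cfg$vessel$inflow_frames >= 1,
            cfg$noise$gaussian_sd >= 0)
  if (cfg$vessel$depth >= 0)
    stop("vessel depth must be negative (contrast agent is dark)",
         call. = FALSE)
  for (s in cfg$vessel$tree)
    if (length(s) != 4 || any(s < 0) || any(s > 1))
      stop("vessel tree segments must be (r1, c1, r2, c2) within [0, 1] ",
           "fractions of the frame", call. = FALSE)
  structure(cfg, class = "phantom_config")
}

# Bilinear translate with edge replication (used for the global respiratory
# shift, where out-of-frame samples clamp to the nearest edge row/column).
translate_clamped <- function(img, tx, ty) {
  H <- nrow(img); W <- ncol(img)
  rows <- pmin(pmax(0:(H - 1) + ty, 0), H - 1)
  cols <- pmin(pmax(0:(W - 1) + tx, 0), W - 1)
  fr <- pmin(floor(rows), H - 2); wr <- rows - fr
  fc <- pmin(floor(cols), W - 2); wc <- cols - fc
  img[fr + 1, fc + 1] * ((1 - wr) %o% (1 - wc)) +
    img[fr + 2, fc + 1] * (wr %o% (1 - wc)) +
    img[fr + 1, fc + 2] * ((1 - wr) %o% wc) +
    img[fr + 2, fc + 2] * (wr %o% wc)
}

# Smooth random texture: low-resolution normal field upsampled bilinearly.
smooth_texture <- function(H, W, amp, n_low = c(9, 12)) {
  low <- matrix(stats::rnorm(prod(n_low)), n_low[1], n_low[2])
  ri <- seq(1, n_low[1], length.out = H)
  ci <- seq(1, n_low[2], length.out = W)
  fr <- pmin(floor(ri), n_low[1] - 1); wr <- ri - fr
  fc <- pmin(floor(ci), n_low[2] - 1); wc <- ci - fc
  amp * (low[fr, fc] * ((1 - wr) %o% (1 - wc)) +
         low[fr + 1, fc] * (wr %o% (1 - wc)) +
         low[fr, fc + 1] * ((1 - wr) %o% wc) +
         low[fr + 1, fc + 1] * (wr %o% wc))
}

# Minimum distance from every pixel to a set of line segments (px coords).
segment_distance_map <- function(H, W, segments) {
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d <- matrix(Inf, H, W)
  for (s in segments) {
    p1 <- c(s[1] * (H - 1), s[2] * (W - 1))
    p2 <- c(s[3] * (H - 1), s[4] * (W - 1))
    v <- p2 - p1
    len2 <- sum(v^2)
    tt <- if (len2 == 0) 0 else
      pmin(pmax(((rr - p1[1]) * v[1] + (cc - p1[2]) * v[2]) / len2, 0), 1)
    d <- pmin(d, sqrt((rr - (p1[1] + tt * v[1]))^2 +
                      (cc - (p1[2] + tt * v[2]))^2))
  }
  d
}

#' Generate one phantom case
#'
#' Builds the mask and contrast series plus the ground truth record. The two
#' series share the same anatomy and motion model; the time index runs
#' continuously from the mask series (t = 0, ..., T_m - 1) into the contrast
#' series (t = T_m, ...), so the respiratory phase continues across the
#' acquisition boundary as it would clinically. Noise draws are independent
#' between series; the same seed reproduces the output bit for bit.
#'
#' @param config a [phantom_config()].
#' @return list with `mask` and `contrast` ([image_series()]) and `truth`, a
#'   `phantom_truth` list holding: `time` (per-frame series, frame, global
#'   time index, respiratory phase \[0, 2pi), diaphragm displacement in px,
#'   cardiac phase, inflow scale), `bowel` (per-frame pocket centers),
#'   `vessel_profile` (static depth map, un-displaced), `vessel_core`
#'   (static logical core mask), `vessel_masks` (per contrast frame, the
#'   displaced core mask), `vessel_depth`, and the `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$height; W <- config$width
  Tm <- config$t_mask; Tc <- config$t_contrast
  set.seed(config$seed)

  r01 <- matrix(seq(0, 1, length.out = H), H, W)
  c01 <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
  rpx <- r01 * (H - 1); cpx <- c01 * (W - 1)
  background <- 150 - 20 * r01 + 6 * c01 +
    9 * sin(2 * pi * (rpx + 0.15 * cpx) / 18) +          # rib-like bands
    smooth_texture(H, W, amp = 14) +                     # coarse anatomy
    smooth_texture(H, W, amp = 9, n_low = c(27, 35)) +   # organ detail
    smooth_texture(H, W, amp = 5, n_low = c(54, 70)) -   # fine detail
    35 * stats::plogis((rpx - 0.55 * (H - 1)) / 2.5)     # diaphragm edge

  vd <- segment_distance_map(H, W, config$vessel$tree)
  wv <- config$vessel$width
  # full depth out to width - 0.5 px, linear edge falloff over 1 px
  coverage <- pmin(1, pmax(0, (wv + 0.5 - vd) / 1.0))
  dim(coverage) <- c(H, W)   # pmin with a scalar first arg drops dim
  vessel_profile <- config$vessel$depth * coverage
  vessel_core <- vd <= max(wv - 0.5, 0.5)

  bw <- config$bowel
  bw$centers <- lapply(bw$centers,
                       function(p) p * c(H - 1, W - 1))   # fractions -> px
  n_pockets <- length(bw$centers)
  drift_dir <- lapply(seq_len(n_pockets), function(k) {
    a <- stats::runif(1, 0, 2 * pi); c(sin(a), cos(a))
  })
  Ttot <- Tm + Tc
  walk <- lapply(seq_len(n_pockets), function(k)
    cbind(cumsum(stats::rnorm(Ttot, 0, bw$walk_sd)),
          cumsum(stats::rnorm(Ttot, 0, bw$walk_sd))))

  ccen <- config$cardiac$center * c(H - 1, W - 1)
  cdist <- sqrt((rpx - ccen[1])^2 + (cpx - ccen[2])^2)

  resp_omega <- 2 * pi / (config$respiration$period * config$frame_rate)
  card_omega <- 2 * pi / (config$cardiac$period * config$frame_rate)

  render <- function(t_idx, resp_amp, inflow_scale) {
    disp <- resp_amp * sin(resp_omega * t_idx)
    frame <- translate_clamped(background, 0, disp)
    if (inflow_scale > 0)
      frame <- frame + inflow_scale * translate_clamped(vessel_profile, 0, disp)
    rad <- config$cardiac$radius +
      config$cardiac$amplitude * sin(card_omega * t_idx)
    frame <- frame + config$cardiac$depth * stats::plogis((rad - cdist) / 2)
    centers <- vector("list", n_pockets)
    for (k in seq_len(n_pockets)) {
      ctr <- bw$centers[[k]] + drift_dir[[k]] * bw$drift_speed * t_idx +
        walk[[k]][t_idx + 1L, ]
      centers[[k]] <- ctr
      pd2 <- (rpx - ctr[1])^2 + (cpx - ctr[2])^2
      frame <- frame + bw$amplitude * exp(-pd2 / (2 * (bw$radius / 2)^2))
    }
    if (config$noise$gaussian_sd > 0)
      frame <- frame + matrix(stats::rnorm(H * W, 0, config$noise$gaussian_sd),
                              H, W)
    list(frame = frame, disp = disp, centers = centers)
  }

  amp_m <- config$respiration$amplitude
  amp_c <- amp_m * config$respiration$amplitude_ratio
  rows_time <- list(); rows_bowel <- list()
  mask_frames <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    ti <- t - 1L
    out <- render(ti, amp_m, 0)
    mask_frames[[t]] <- out$frame
    rows_time[[length(rows_time) + 1L]] <- data.frame(
      series = "mask", frame = t, t_index = ti,
      resp_phase = (resp_omega * ti) %% (2 * pi), resp_disp = out$disp,
      cardiac_phase = (card_omega * ti) %% (2 * pi), inflow_scale = NA_real_)
    for (k in seq_len(n_pockets))
      rows_bowel[[length(rows_bowel) + 1L]] <- data.frame(
        series = "mask", frame = t, pocket = k,
        row = out$centers[[k]][1], col = out$centers[[k]][2])
  }
  contrast_frames <- vector("list", Tc)
  vessel_masks <- vector("list", Tc)
  for (t in seq_len(Tc)) {
    ti <- Tm + t - 1L
    s <- min(1, t / config$vessel$inflow_frames)
    out <- render(ti, amp_c, s)
    contrast_frames[[t]] <- out$frame
    vessel_masks[[t]] <-
      translate_clamped(vessel_core + 0, 0, out$disp) > 0.5
    rows_time[[length(rows_time) + 1L]] <- data.frame(
      series = "contrast", frame = t, t_index = ti,
      resp_phase = (resp_omega * ti) %% (2 * pi), resp_disp = out$disp,
      cardiac_phase = (card_omega * ti) %% (2 * pi), inflow_scale = s)
    for (k in seq_len(n_pockets))
      rows_bowel[[length(rows_bowel) + 1L]] <- data.frame(
        series = "contrast", frame = t, pocket = k,
        row = out$centers[[k]][1], col = out$centers[[k]][2])
  }

  truth <- structure(list(
    time = do.call(rbind, rows_time),
    bowel = do.call(rbind, rows_bowel),
    vessel_profile = vessel_profile, vessel_core = vessel_core,
    vessel_masks = vessel_masks, vessel_depth = config$vessel$depth,
    config = config), class = "phantom_truth")

  list(mask = image_series(mask_frames, role = "mask",
                           frame_rate = config$frame_rate,
                           source_id = sprintf("phantom seed %d", config$seed)),
       contrast = image_series(contrast_frames, role = "contrast",
                               frame_rate = config$frame_rate,
                               source_id = sprintf("phantom seed %d",
                                                   config$seed)),
       truth = truth)
}

#' Generate a suite of phantom cases
#'
#' Produces `n_cases` phantoms whose motion parameters are jittered around
#' `base_config` (respiratory amplitude and period, cardiac period, bowel
#' drift), emulating between-patient variability. Everything is
#' deterministic in `seed`. Optionally writes each case to
#' `out_dir/case_NN/` as TIFF series plus a JSON truth record, the layout
#' the command-line `run`/`evaluate` commands consume.
#'
#' @param n_cases number of cases.
#' @param base_config a [phantom_config()]; per-case seeds and jitters are
#'   derived from `seed`, overriding `base_config$seed`.
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return (Invisibly when writing) a list of cases, each a
#'   `list(config, mask, contrast, truth)`.
#' @export
make_case_suite <- function(n_cases, base_config = phantom_config(),
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_cases >= 1)
  set.seed(seed)
  jit <- matrix(stats::runif(n_cases * 4, 0.85, 1.15), n_cases, 4)
  case_seeds <- sample.int(.Machine$integer.max %/% 2, n_cases)
  cases <- vector("list", n_cases)
  for (k in seq_len(n_cases)) {
    cfg <- base_config
    cfg$respiration$amplitude <- cfg$respiration$amplitude * jit[k, 1]
    cfg$respiration$period <- cfg$respiration$period * jit[k, 2]
    cfg$cardiac$period <- cfg$cardiac$period * jit[k, 3]
    cfg$bowel$drift_speed <- cfg$bowel$drift_speed * jit[k, 4]
    cfg$seed <- case_seeds[k]
    ph <- generate_phantom(cfg)
    cases[[k]] <- list(config = cfg, mask = ph$mask,
                       contrast = ph$contrast, truth = ph$truth)
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, sprintf("case_%02d", k))
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_series(ph$mask, file.path(cdir, "mask.tif"))
      write_series(ph$contrast, file.path(cdir, "contrast.tif"))
      write_series(image_series(lapply(ph$truth$vessel_masks,
                                       function(m) m + 0),
                                role = "contrast"),
                   file.path(cdir, "vessel_masks.tif"))
      tr <- ph$truth
      jsonlite::write_json(
        list(time = tr$time, bowel = tr$bowel,
             vessel_depth = tr$vessel_depth,
             config = unclass(cfg)),
        file.path(cdir, "truth.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }
  if (is.null(out_dir)) cases else invisible(cases)
}

#' Planted vessel depth map for one contrast frame
#'
#' Reconstructs from the truth record the contrast-agent signal the
#' generator actually added to a given contrast frame: the static vessel
#' depth profile, displaced by that frame's respiratory shift and scaled by
#' its inflow factor. This is the reference a subtraction method should
#' recover inside the vessel.
#'
#' @param truth a `phantom_truth`.
#' @param frame contrast frame index (1-based).
#' @return Numeric matrix of planted (negative) vessel intensities.
#' @export
planted_depth_map <- function(truth, frame) {
  stopifnot(inherits(truth, "phantom_truth"))
  tc <- truth$time[truth$time$series == "contrast", ]
  stopifnot(frame >= 1, frame <= nrow(tc))
  tc$inflow_scale[frame] *
    translate_clamped(truth$vessel_profile, 0, tc$resp_disp[frame])
}
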