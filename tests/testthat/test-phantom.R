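test_that("a motionless, noiseless phantom is static outside the vessel", {
  cfg <- small_phantom_config(
    seed = 71,
    respiration = list(amplitude = 1e-9),   # amplitudes must be positive
    cardiac = list(amplitude = 1e-9, depth = 0),
    bowel = list(drift_speed = 0, walk_sd = 0, amplitude = 0),
    noise = list(gaussian_sd = 0))
  ph <- generate_phantom(cfg)
  for (t in 2:n_frames(ph$mask))
    expect_equal(ph$mask$frames[[t]], ph$mask$frames[[1]], tolerance = 1e-7)
  # contrast frames differ from mask frames only where vessel was planted
  last <- n_frames(ph$contrast)   # past the inflow ramp
  diffmap <- ph$contrast$frames[[last]] - ph$mask$frames[[1]]
  outside <- abs(ph$truth$vessel_profile) < 1e-12
  expect_lt(max(abs(diffmap[outside])), 1e-6)
  expect_lt(mean(diffmap[ph$truth$vessel_core]), -30)
})

test_that("the diaphragm trajectory follows the configured sinusoid", {
  cfg <- small_phantom_config(seed = 72,
                              respiration = list(amplitude = 6, period = 4))
  ph <- generate_phantom(cfg)
  tm <- ph$truth$time[ph$truth$time$series == "mask", ]
  expect_equal(tm$resp_disp, 6 * sin(2 * pi * (0:9) / 24))
  expect_true(all(tm$resp_phase >= 0 & tm$resp_phase < 2 * pi))
  # contrast series continues the same clock
  tc <- ph$truth$time[ph$truth$time$series == "contrast", ]
  expect_equal(tc$t_index, 10:15)
  expect_equal(tc$resp_disp, 6 * sin(2 * pi * (10:15) / 24))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_phantom(small_phantom_config(seed = 73))
  b <- generate_phantom(small_phantom_config(seed = 73))
  expect_identical(a$mask$frames, b$mask$frames)
  expect_identical(a$contrast$frames, b$contrast$frames)
  expect_identical(a$truth$time, b$truth$time)
  c <- generate_phantom(small_phantom_config(seed = 74))
  expect_false(identical(a$mask$frames, c$mask$frames))
})

test_that("mask series carries no vessel signal", {
  ph <- generate_phantom(small_phantom_config(seed = 75))
  # the mask series must be untouched by the vessel model: doubling the
  # planted depth changes contrast frames but not a single mask pixel
  ph2 <- generate_phantom(small_phantom_config(seed = 75,
                                               vessel = list(depth = -90)))
  expect_identical(ph$mask$frames, ph2$mask$frames)
  expect_false(identical(ph$contrast$frames, ph2$contrast$frames))
  # contrast frames past inflow are clearly darker in the vessel core
  tc <- ph$truth$time[ph$truth$time$series == "contrast", ]
  full <- which(tc$inflow_scale >= 1)
  depth <- vapply(full, function(t) {
    m <- ph$truth$vessel_masks[[t]]
    mean(ph$contrast$frames[[t]][m]) - mean(ph$mask$frames[[1]][m])
  }, numeric(1))
  expect_true(all(depth < -20))
})

test_that("whole-frame similarity tracks the respiratory displacement", {
  ph <- generate_phantom(phantom_config(t_contrast = 12, seed = 76))
  tm <- ph$truth$time[ph$truth$time$series == "mask", ]
  tc <- ph$truth$time[ph$truth$time$series == "contrast", ]
  hits <- 0L
  for (t in seq_len(12)) {
    scores <- vapply(ph$mask$frames, zncc, numeric(1),
                     a = ph$contrast$frames[[t]])
    best_disp_err <- min(abs(tm$resp_disp - tc$resp_disp[t]))
    got_disp_err <- abs(tm$resp_disp[which.max(scores)] - tc$resp_disp[t])
    if (got_disp_err <= best_disp_err + 0.5) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * 12))
})

test_that("case suites are deterministic, jittered, and written to disk", {
  cfg <- small_phantom_config()
  s1 <- make_case_suite(3, cfg, seed = 77)
  s2 <- make_case_suite(3, cfg, seed = 77)
  expect_equal(s1[[2]]$mask$frames, s2[[2]]$mask$frames)
  amps <- vapply(s1, function(cs) cs$config$respiration$amplitude, numeric(1))
  expect_gt(stats::sd(amps), 0)   # jitter is applied
  dir <- withr::local_tempdir()
  make_case_suite(2, cfg, seed = 78, out_dir = dir)
  expect_true(file.exists(file.path(dir, "case_01", "mask.tif")))
  expect_true(file.exists(file.path(dir, "case_02", "truth.json")))
  back <- read_series(file.path(dir, "case_01", "mask.tif"), role = "mask")
  expect_equal(n_frames(back), cfg$t_mask)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(vessel = list(depth = 10)), "negative")
  expect_error(phantom_config(vessel = list(tree = list(c(0, 0, 2, 1)))),
               "within \\[0, 1\\]")
  expect_error(phantom_config(respiration = list(amplitude = -1)))
})

test_that("planted_depth_map reproduces the injected vessel signal", {
  cfg <- small_phantom_config(seed = 79, noise = list(gaussian_sd = 0))
  ph <- generate_phantom(cfg)
  t <- n_frames(ph$contrast)
  pl <- planted_depth_map(ph$truth, t)
  vm <- ph$truth$vessel_masks[[t]]
  expect_lt(max(pl), 1e-12)
  expect_lt(mean(pl[vm]), -30)
  # mask-region values agree with direct translation of the profile
  tc <- ph$truth$time[ph$truth$time$series == "contrast", ]
  expect_equal(pl, tc$inflow_scale[t] *
                 patchdsa:::translate_clamped(ph$truth$vessel_profile, 0,
                                              tc$resp_disp[t]))
})
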