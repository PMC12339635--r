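test_that("robust-sigma exclusion marks the lower tail, never everything", {
  # pure noise: excluded fraction ~ lower tail beyond 2 robust SDs
  set.seed(41)
  fracs <- replicate(40, {
    x <- matrix(rnorm(30 * 40, 0, 5), 30, 40)
    m <- estimate_exclusion_mask(x, brightness_params(sigma_k = 2))
    expect_false(attr(m, "fallback"))
    mean(m)
  })
  expect_equal(mean(fracs), pnorm(-2), tolerance = 0.2)
  expect_true(all(fracs < 0.1))
})

test_that("a planted vessel is excluded while background is retained", {
  set.seed(42)
  x <- matrix(rnorm(40 * 40, 0, 5), 40, 40)
  vessel <- matrix(FALSE, 40, 40); vessel[, 18:21] <- TRUE
  x[vessel] <- x[vessel] - 200
  m <- estimate_exclusion_mask(x, brightness_params(sigma_k = 2))
  expect_true(all(m[vessel]))
  expect_gt(mean(!m[!vessel]), 0.99)
})

test_that("over-exclusion falls back to using every pixel, with a warning", {
  x <- matrix(rnorm(100, 0, 1), 10, 10)
  # a fixed threshold above nearly all values would exclude ~everything
  p <- brightness_params(exclusion_mode = "fixed_threshold",
                         fixed_threshold = 10, max_excluded_fraction = 0.9)
  expect_warning(m <- estimate_exclusion_mask(x, p), "falling back")
  expect_false(any(m))
  expect_true(attr(m, "fallback"))
  expect_identical(attr(m, "excluded_fraction"), 0)
})

test_that("brightness correction equalizes non-excluded means exactly", {
  set.seed(43)
  cp <- matrix(rnorm(200, 100, 8), 10, 20)
  # pure offset, no exclusions: corrected mask equals the contrast patch
  mp <- cp + 12
  none <- matrix(FALSE, 10, 20)
  expect_equal(correct_brightness(mp, cp, none), cp)
  # identical patches: identity
  expect_equal(correct_brightness(cp, cp, none), cp)
  # vessel-excluded correction is not biased by the vessel
  cp2 <- cp; cp2[, 9:11] <- cp2[, 9:11] - 150   # vessel region
  mp2 <- cp + 5                                  # mask is 5 brighter
  excl <- matrix(FALSE, 10, 20); excl[, 9:11] <- TRUE
  corrected <- correct_brightness(mp2, cp2, excl)
  expect_equal(corrected, mp2 - 5)               # correction term is -5
  expect_equal(mean(corrected[!excl]), mean(cp2[!excl]))
  expect_error(correct_brightness(mp, cp, !none), "excluded")
})

test_that("a reordered mask series subtracts to zero everywhere", {
  set.seed(44)
  frames <- replicate(6, matrix(rnorm(60 * 80, 100, 15), 60, 80),
                      simplify = FALSE)
  mask <- image_series(frames, role = "mask")
  contrast <- image_series(frames[c(4, 2, 6)], role = "contrast")
  out <- generate_dsa_sequence(contrast, mask, n_divisions = 5)
  for (f in out) expect_lt(max(abs(f$image)), 1e-6)
})

test_that("a static phantom with a planted vessel recovers its depth", {
  # pixel-level texture anchors the refinement: any nonzero shift
  # decorrelates it, so the ZNCC optimum for static anatomy is (0, 0)
  set.seed(45)
  bg <- textured_field(60, 80, seed = 45) + matrix(rnorm(60 * 80, 0, 10),
                                                   60, 80)
  vessel <- matrix(FALSE, 60, 80); vessel[20:40, 38:41] <- TRUE
  cf <- bg; cf[vessel] <- cf[vessel] - 100
  mask <- image_series(replicate(3, bg, simplify = FALSE), role = "mask")
  # without refinement the aligned anatomy cancels exactly
  f0 <- generate_dsa_frame(cf, mask, build_grid(60, 80, 5),
                           refine_params = NULL)
  expect_equal(mean(f0$image[vessel]), -100, tolerance = 1e-9)
  expect_lt(max(abs(f0$image[!vessel])), 1e-9)
  # with refinement, vessel-crossing patches may accept sub-pixel shifts
  # that trade a little background residual for vessel correlation; the
  # depth estimate stays accurate and the background stays near zero
  f <- generate_dsa_frame(cf, mask, build_grid(60, 80, 5))
  expect_equal(mean(f$image[vessel]), -100, tolerance = 3)
  expect_lt(mean(abs(f$image[!vessel])), 1)
})

test_that("output patches partition the frame: provenance covers all cells", {
  ph <- generate_phantom(small_phantom_config(seed = 46))
  f <- generate_dsa_frame(ph$contrast$frames[[2]], ph$mask,
                          build_grid(80, 104, 4))
  expect_equal(nrow(f$match_map), 16L)
  expect_true(all(is.finite(f$image)))
  expect_identical(dim(f$image), c(80L, 104L))
})

test_that("sequence generation is per-frame independent and order-preserving", {
  ph <- generate_phantom(small_phantom_config(seed = 47))
  sub <- image_series(ph$contrast$frames[1:3], role = "contrast")
  perm <- image_series(ph$contrast$frames[c(3, 1, 2)], role = "contrast")
  out <- generate_dsa_sequence(sub, ph$mask, n_divisions = 4,
                               refine_params = NULL)
  out_perm <- generate_dsa_sequence(perm, ph$mask, n_divisions = 4,
                                    refine_params = NULL)
  expect_equal(out_perm[[2]]$image, out[[1]]$image)
  expect_equal(out_perm[[1]]$image, out[[3]]$image)
  one <- generate_dsa_frame(ph$contrast$frames[[2]], ph$mask,
                            build_grid(80, 104, 4), refine_params = NULL)
  expect_equal(out[[2]]$image, one$image)
})

test_that("simple subtraction uses the first mask frame verbatim", {
  ph <- generate_phantom(small_phantom_config(seed = 48))
  m1 <- ph$mask$frames[[1]]
  contrast <- image_series(list(m1, m1 + 10), role = "contrast")
  out <- simple_subtraction(contrast, ph$mask)
  expect_equal(out[[1]]$image, matrix(0, 80, 104))
  expect_equal(out[[2]]$image, matrix(10, 80, 104))
  expect_identical(out[[1]]$method, "simple")
})

test_that("global matching selects the planted frame and honors the ROI", {
  set.seed(49)
  frames <- replicate(8, matrix(rnorm(60 * 60, 100, 10), 60, 60),
                      simplify = FALSE)
  mask <- image_series(frames, role = "mask")
  contrast <- image_series(frames[[7]], role = "contrast")
  out <- global_phase_match(contrast, mask)
  expect_equal(out[[1]]$match_map$t_star, 7L)
  expect_lt(max(abs(out[[1]]$image)), 1e-9)
  expect_identical(out[[1]]$method, "ohnishi")
  roi_out <- global_phase_match(contrast, mask, roi = crop_rect(40, 0, 20, 60))
  expect_equal(roi_out[[1]]$match_map$t_star, 7L)
  expect_error(global_phase_match(contrast, mask,
                                  roi = crop_rect(50, 50, 20, 20)),
               "exceeds frame bounds")
})

test_that("shape mismatches between series are rejected", {
  a <- image_series(matrix(0, 10, 10), role = "contrast")
  b <- image_series(matrix(0, 12, 10), role = "mask")
  expect_error(generate_dsa_sequence(a, b), "different frame shapes")
})
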