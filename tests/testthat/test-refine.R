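test_that("zero shift reproduces the grid patch exactly", {
  set.seed(31)
  img <- matrix(rnorm(400), 20, 20)
  p <- sample_shifted_patch(img, c(4, 6), c(8, 8), c(0, 0))
  expect_identical(p, img[5:12, 7:14])
})

test_that("integer shifts reproduce integer-indexed patches", {
  set.seed(32)
  img <- matrix(rnorm(400), 20, 20)
  expect_equal(sample_shifted_patch(img, c(4, 6), c(8, 8), c(1, 0)),
               img[5:12, 8:15])
  expect_equal(sample_shifted_patch(img, c(4, 6), c(8, 8), c(-2, 3)),
               img[8:15, 5:12])
})

test_that("half-pixel shift on a column ramp adds exactly 0.5", {
  img <- matrix(0:19, 20, 20, byrow = TRUE)    # f(r, c) = c (0-based)
  p <- sample_shifted_patch(img, c(5, 5), c(6, 6), c(0.5, 0))
  expect_equal(p, img[6:11, 6:11] + 0.5)
  # and on the row axis with a row ramp
  imgr <- matrix(0:19, 20, 20)
  pr <- sample_shifted_patch(imgr, c(5, 5), c(6, 6), c(0, 0.5))
  expect_equal(pr, imgr[6:11, 6:11] + 0.5)
})

test_that("subpixel samples agree with an independent scalar bilinear", {
  set.seed(33)
  img <- matrix(rnorm(400), 20, 20)
  for (shift in list(c(0.3, -1.7), c(-2.25, 0.6), c(1.5, 1.5))) {
    p <- sample_shifted_patch(img, c(6, 6), c(5, 5), shift)
    for (u in c(0, 2, 4)) for (v in c(0, 2, 4)) {
      expect_equal(p[u + 1, v + 1],
                   bilinear_at(img, 6 + u + shift[2], 6 + v + shift[1]))
    }
  }
})

test_that("shifts sampling outside the frame are infeasible", {
  img <- matrix(1, 10, 10)
  expect_null(sample_shifted_patch(img, c(0, 0), c(5, 5), c(-0.5, 0)))
  expect_null(sample_shifted_patch(img, c(5, 5), c(5, 5), c(0, 0.5)))
  expect_false(is.null(sample_shifted_patch(img, c(5, 5), c(5, 5), c(0, 0))))
})

test_that("refinement of an already-optimal match stays at the origin", {
  img <- textured_field(40, 40, seed = 34)
  rf <- refine_match(img[11:26, 11:26], img, c(10, 10))
  expect_lt(abs(rf$tx), 0.02)
  expect_lt(abs(rf$ty), 0.02)
  expect_gt(rf$score, 1 - 1e-9)
})

test_that("planted subpixel translations are recovered", {
  img <- textured_field(60, 60, seed = 35)
  for (planted in list(c(2.3, -1.6), c(-0.7, 0.4), c(1.1, 2.2))) {
    cp <- sample_shifted_patch(img, c(20, 20), c(16, 16), planted)
    rf <- refine_match(cp, img, c(20, 20))
    expect_lt(abs(rf$tx - planted[1]), 0.25)
    expect_lt(abs(rf$ty - planted[2]), 0.25)
    expect_gt(rf$score, 0.99)
  }
})

test_that("the search respects max_shift and still returns a feasible point", {
  img <- textured_field(60, 60, seed = 36)
  cp <- sample_shifted_patch(img, c(20, 20), c(12, 12), c(8, 0))
  rf <- refine_match(cp, img, c(20, 20),
                     refinement_params(max_shift = 4))
  expect_lte(abs(rf$tx), 4)
  expect_lte(abs(rf$ty), 4)
  expect_gte(rf$score, -1)
})

test_that("refined score never falls below the unshifted score", {
  ph <- generate_phantom(small_phantom_config(seed = 37))
  grid <- build_grid(80, 104, 5)
  cf <- ph$contrast$frames[[4]]
  mm <- phase_match_frame(cf, ph$mask, grid)
  for (k in c(1, 7, 13, 20, 25)) {
    b <- patchdsa:::patch_bounds(grid, mm$i[k], mm$j[k])
    cp <- cf[(b$row + 1):(b$row + b$height), (b$col + 1):(b$col + b$width)]
    rf <- refine_match(cp, ph$mask$frames[[mm$t_star[k]]], c(b$row, b$col))
    expect_gte(rf$score, mm$coarse_score[k] - 1e-9)
  }
})

test_that("refinement is deterministic and skips degenerate patches", {
  img <- textured_field(40, 40, seed = 38)
  cp <- sample_shifted_patch(img, c(12, 12), c(10, 10), c(0.8, -0.4))
  r1 <- refine_match(cp, img, c(12, 12))
  r2 <- refine_match(cp, img, c(12, 12))
  expect_identical(r1, r2)
  rd <- refine_match(matrix(5, 10, 10), img, c(12, 12))
  expect_true(rd$degenerate)
  expect_identical(c(rd$tx, rd$ty, rd$score), c(0, 0, 0))
})

test_that("the simplex search agrees with stats::optim Nelder-Mead", {
  # independent optimizer on the same objective, small planted shifts
  img <- textured_field(50, 50, seed = 39)
  for (planted in list(c(0.9, -0.6), c(-1.2, 0.3))) {
    cp <- sample_shifted_patch(img, c(16, 16), c(14, 14), planted)
    rf <- refine_match(cp, img, c(16, 16))
    obj <- function(x) {
      p <- sample_shifted_patch(img, c(16, 16), c(14, 14), x)
      if (is.null(p)) return(2)
      -zncc(cp, p)
    }
    ref <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10))
    expect_equal(rf$score, -ref$value, tolerance = 1e-3)
  }
})
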