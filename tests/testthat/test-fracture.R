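test_that("crop_top_curvature crops at the fitted vertex or the band edge", {
  rows <- 1:100
  # hook: quadratic with vertex at row 10, inside the top-20% band (rows 1:20)
  cols <- 30 + 0.05 * (rows - 10)^2
  cropped <- crop_top_curvature(make_line(rows, cols))
  expect_true(min(cropped$rows) %in% c(10L, 11L))  # vertex 10 +/- fit epsilon

  # straight top: degenerate parabola, crop at the band's lower boundary
  straight <- make_line(rows, rep(25, 100))
  cs <- crop_top_curvature(straight)
  expect_equal(min(cs$rows), 21L)

  expect_error(crop_top_curvature(make_line(1:10, rep(1, 10))), "too short")
})

test_that("fit_ideal_contour recovers polynomial contours", {
  rows <- 1:120
  coefs <- c(40, 0.05, -0.003, 1e-5)
  cols <- coefs[1] + coefs[2] * rows + coefs[3] * rows^2 + coefs[4] * rows^3
  fit <- fit_ideal_contour(make_line(rows, cols), 3)
  expect_equal(fit, coefs, tolerance = 1e-6)

  vert <- fit_ideal_contour(make_line(rows, rep(55, 120)), 3)
  expect_equal(vert[1], 55, tolerance = 1e-6)
  expect_true(all(abs(vert[2:4]) < 1e-6))

  expect_error(fit_ideal_contour(make_line(1:3, 1:3), 3), "underdetermined")
})

test_that("noisy cubic coefficients are recovered within 3 standard errors", {
  set.seed(99)
  rows <- 1:200
  coefs <- c(50, 0.1, -1e-3, 4e-6)
  cols <- coefs[1] + coefs[2] * rows + coefs[3] * rows^2 + coefs[4] * rows^3 +
    rnorm(200, 0, 0.5)
  fit <- fit_ideal_contour(make_line(rows, cols), 3)
  se <- summary(lm(cols ~ rows + I(rows^2) + I(rows^3)))$coefficients[, 2]
  expect_true(all(abs(fit - coefs) < 3 * se))
})

test_that("score_deviation reports mse and strict excess runs", {
  rows <- 1:50
  cols <- rep(20, 50)
  fit <- c(20, 0, 0, 0)
  sc <- score_deviation(make_line(rows, cols), fit, 3)
  expect_equal(sc$mse, 0)
  expect_identical(nrow(sc$excess_runs), 0L)

  # a deviation of exactly 3.0 is not an excess (strict inequality)
  cols2 <- cols; cols2[25] <- 23
  expect_identical(nrow(score_deviation(make_line(rows, cols2), fit, 3)$excess_runs), 0L)

  cols3 <- cols; cols3[20:26] <- 20 + c(4, 5, 6, 7, 6, 5, 4)
  sc3 <- score_deviation(make_line(rows, cols3), fit, 3)
  expect_identical(nrow(sc3$excess_runs), 1L)
  expect_identical(sc3$excess_runs$start_row, 20L)
  expect_identical(sc3$excess_runs$end_row, 26L)
  expect_identical(sc3$excess_runs$peak_row, 23L)
  expect_equal(sc3$excess_runs$peak_dev, 7)
  # brute-force mse oracle
  expect_equal(sc3$mse, mean((cols3 - 20)^2))
})

test_that("detect_fracture flags multi-row excess areas with circles", {
  rows <- 1:150
  cols <- rep(30, 150)
  cols[90:110] <- 38  # 8-px lateral step segment
  rpt <- detect_fracture(list(make_line(rows, cols)), fit_config())
  expect_true(rpt$fractured)
  expect_identical(nrow(rpt$detections), 1L)
  expect_true(rpt$detections$row >= 85 && rpt$detections$row <= 115)
  expect_gt(rpt$detections$radius, 0)

  expect_error(detect_fracture(list()), "no bone lines")
  expect_error(detect_fracture(rep(list(make_line(rows, cols)), 5)), "at most 4")
})

test_that("tolerance scaling removes or floods detections", {
  set.seed(7)
  rows <- 1:150
  cols <- 30 + rnorm(150, 0, 1.2)
  line <- make_line(rows, cols)
  huge <- detect_fracture(list(line), fit_config(tolerance = 1e6))
  expect_false(huge$fractured)
  tiny_cfg <- fit_config(tolerance = 0)
  cropped <- crop_top_curvature(line, tiny_cfg)
  fit <- fit_ideal_contour(cropped, 3)
  sc <- score_deviation(cropped, fit, 0)
  expect_identical(sum(sc$excess_runs$n_rows), length(cropped$rows))
})

test_that("peak deviation grows with step magnitude on phantoms", {
  peaks <- vapply(c(2, 4, 6, 8, 10), function(m) {
    ph <- generate_phantom(phantom_spec(
      rng_seed = 77, fracture = fracture_truth(1, "step", m, 0.55)))
    rep <- suppressWarnings(run_pipeline(ph$image))
    max(vapply(rep$residual_trace[3:4], function(tr)
      max(abs(tr$residuals$residual)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(peaks) > -0.25))  # non-decreasing up to contour jitter
  expect_gt(peaks[5], peaks[1])
})

test_that("gap fractures sever the traced contour", {
  # the 9x9 entropy window bleeds the edge ridge ~4 rows into the gap from
  # each side, so only gaps wider than window + search reach sever the trace
  ph <- generate_phantom(phantom_spec(
    rng_seed = 78, fracture = fracture_truth(0, "gap", 16, 0.5)))
  rep <- suppressWarnings(run_pipeline(ph$image))
  expect_lt(rep$n_lines, 4L)
})
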