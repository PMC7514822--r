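test_that("shannon_entropy matches hand-computed distributions", {
  expect_equal(shannon_entropy(rep(17, 81)), 0)
  expect_equal(shannon_entropy(c(rep(0, 40), rep(255, 40))), 1)
  expect_equal(shannon_entropy(c(rep(0, 4), rep(100, 2), rep(200, 2))), 1.5)
  expect_equal(shannon_entropy(c(0, 0, 255, 255), log_base = 4), 0.5)
  expect_error(shannon_entropy(numeric()), "nonempty")
})

test_that("local_entropy_map equals the brute-force oracle", {
  set.seed(10)
  img <- as_gray_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  expect_lt(max(abs(local_entropy_map(img) - brute_entropy_map(img))), 1e-9)

  step <- as_gray_image(matrix(rep(c(0, 200), each = 200), 20, 20))
  m <- local_entropy_map(step)
  expect_lt(max(abs(m - brute_entropy_map(step))), 1e-9)
  # maximal along the step edge, zero far away
  expect_equal(which.max(m[10, ]) %in% 10:11, TRUE)
  expect_equal(m[10, 2], 0)
  expect_equal(m[10, 19], 0)
})

test_that("entropy map is zero on constant input and local around a defect", {
  expect_true(all(local_entropy_map(matrix(40L, 15, 15)) == 0))
  img <- matrix(40L, 21, 21); img[11, 11] <- 200L
  m <- local_entropy_map(img)
  nz <- which(m > 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 11) <= 4 & all(abs(nz[, 2] - 11) <= 4)))
  expect_error(local_entropy_map(matrix(1L, 5, 5)), "smaller than")
})

test_that("sigma weighting is sensitive to scale, entropy alone is not", {
  a <- as_gray_image(matrix(rep(c(10, 20), each = 150), 15, 20))
  b <- as_gray_image(matrix(rep(c(10, 210), each = 150), 15, 20))
  ea <- local_entropy_map(a); eb <- local_entropy_map(b)
  # same two-value histograms row-wise => same entropy, larger sigma for b
  expect_true(max(eb) > max(ea))
})

test_that("normalise_rows subtracts the global mean and clips at zero", {
  m <- matrix(c(0, 10), 4, 4)
  out <- normalise_rows(m)
  expect_true(all(out %in% c(0, 5)))
  expect_true(all(normalise_rows(matrix(3, 4, 4)) == 0))
  set.seed(3)
  r <- matrix(runif(100), 10, 10)
  out2 <- normalise_rows(r)
  expect_true(all(out2 >= 0))
  expect_lt(mean(out2), mean(r))
})

test_that("detect_row_peaks collapses plateaus and applies the 20% rule", {
  pk <- detect_row_peaks(c(0, 0, 5, 9, 9, 9, 5, 0, 0))
  expect_identical(pk$columns, 5L)     # mean of plateau columns 4:6
  expect_equal(pk$values, 9)

  expect_length(detect_row_peaks(rep(0, 12))$columns, 0L)

  row <- c(0, 100, 0, 0, 0, 0, 15, 0, 0)
  pk2 <- detect_row_peaks(row, 0.2)
  expect_identical(pk2$columns, 2L)    # 15 <= 0.2 * 100 is discarded

  # strictly-greater comparison at the threshold boundary
  row3 <- c(0, 100, 0, 0, 20, 0)
  expect_identical(detect_row_peaks(row3, 0.2)$columns, 2L)
  expect_error(detect_row_peaks(row, 0), "in \\(0, 1\\)")
})

test_that("nearby marked maxima merge into one representative", {
  row <- c(0, 0, 8, 7, 9, 0, 0, 0, 0, 6, 0)
  pk <- detect_row_peaks(row, 0.2, merge_gap = 2)
  # maxima at 3 and 5 merge (gap 1), peak at 10 stays
  expect_identical(pk$columns, c(4L, 10L))
  expect_equal(pk$values[1], 9)
})

test_that("line_edge_image is binary with sparse rows", {
  ph <- generate_phantom(phantom_spec(rng_seed = 12))
  emap <- local_entropy_map(crop_to_content(ph$image))
  edges <- line_edge_image(emap)
  expect_true(all(edges %in% c(0L, 255L)))
  expect_true(all(rowSums(edges > 0) <= ncol(edges) / 2))

  expect_true(all(line_edge_image(matrix(0, 10, 10)) == 0L))
  one_col <- matrix(0, 12, 12); one_col[, 6] <- 5
  expect_identical(which(line_edge_image(one_col)[4, ] > 0), 6L)
})

test_that("line edges land on ground-truth bone edges", {
  ph <- generate_phantom(phantom_spec(rng_seed = 13))
  img <- crop_to_content(ph$image)
  off <- attr(img, "offset")
  edges <- line_edge_image(local_entropy_map(img))
  gt <- ph$truth$edges
  rows <- seq(ph$truth$bone_end_row + 10L, ph$truth$bottom_row - 10L, by = 4L)
  hit <- vapply(rows, function(r) {
    cols <- which(edges[r - off[["row"]], ] > 0) + off[["col"]]
    g <- gt$col[gt$row == r]
    all(vapply(g, function(x) min(abs(cols - x)) <= 2, logical(1)))
  }, logical(1))
  expect_gt(mean(hit), 0.9)
})

test_that("segmentation entropy follows its tile decomposition", {
  img <- matrix(0L, 16, 16); img[1:8, ] <- 255L
  # window >= image: a single tile equal to the image => E(S) = 0
  expect_equal(segmentation_entropy(img, 16), 0)

  # two 4x8 tiles: one mixed (1 bit), one constant (0 bits)
  img2 <- matrix(0L, 4, 16)
  img2[, 5:8] <- 255L
  eh <- shannon_entropy(img2)
  expected <- (1 - eh) / eh + (0 - eh) / eh
  expect_equal(segmentation_entropy(img2, 8), expected)
  expect_error(segmentation_entropy(matrix(0L, 8, 8), 4), "constant image")
})

test_that("global entropy score combines H(X) and scaled E(S)", {
  img <- matrix(0L, 16, 16); img[1:8, ] <- 255L
  sc <- global_entropy_score(img, 16)
  expect_equal(sc$global_entropy, sc$image_entropy)  # single matching tile
  expect_equal(sc$n_windows, 1L)

  img2 <- matrix(0L, 4, 16); img2[, 5:8] <- 255L
  sc2 <- global_entropy_score(img2, 8)
  es <- segmentation_entropy(img2, 8)
  expect_equal(sc2$segmentation_entropy, es)
  expect_equal(sc2$global_entropy, sc2$image_entropy + es / sc2$n_windows)
})

test_that("baseline edge detectors behave on degenerate and step inputs", {
  flat <- matrix(100L, 32, 32)
  for (m in c("canny", "laplacian", "sobel_v", "sobel_h"))
    expect_true(all(baseline_edges(flat, m) == 0L))

  step <- as_gray_image(matrix(rep(c(0, 200), each = 32 * 16), 32, 32))
  can <- baseline_edges(step, "canny")
  cols <- unique(which(can > 0, arr.ind = TRUE)[, 2])
  expect_true(all(abs(cols - 16.5) <= 2))
  expect_error(baseline_edges(step, "prewitt"))
})
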