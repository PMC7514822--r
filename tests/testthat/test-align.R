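test_that("pad_border adds a black frame of the requested width", {
  img <- as_gray_image(matrix(7L, 100, 80))
  out <- pad_border(img, 10)
  expect_identical(dim(out), c(120L, 100L))
  expect_true(all(out[1:10, ] == 0L) && all(out[, 1:10] == 0L))
  expect_identical(out[11:110, 11:90], img)
  expect_identical(pad_border(img, 0), img)
  z <- pad_border(matrix(0L, 100, 80), 5)
  expect_identical(dim(z), c(110L, 90L))
  expect_true(all(z == 0L))
  expect_error(pad_border(img, -1), ">= 0")
})

test_that("binarise maps positive to 255 and is idempotent", {
  img <- matrix(c(0L, 1L, 128L, 255L), 2, 2)
  b <- binarise(img)
  expect_identical(as.vector(b), c(0L, 255L, 255L, 255L))
  expect_identical(binarise(b), b)
  expect_true(all(binarise(matrix(0L, 5, 5)) == 0L))
  expect_true(all(binarise(matrix(255L, 5, 5)) == 255L))
})

test_that("close_artifacts matches a brute-force closing and fills small holes", {
  bin <- matrix(0L, 50, 50)
  bin[6:45, 6:45] <- 255L
  bin[20:23, 20:23] <- 0L   # 4x4 hole, smaller than the 10x10 kernel
  closed <- close_artifacts(bin, 10)
  expect_identical(closed, brute_closing(bin, 10L))
  expect_true(all(closed[20:23, 20:23] == 255L))
  expect_identical(close_artifacts(closed, 10), closed)  # idempotent
  full <- matrix(255L, 30, 30)
  expect_identical(close_artifacts(full, 10), full)
  expect_error(close_artifacts(matrix(3L, 5, 5)), "not binary")
})

test_that("pca_orientation recovers analytic axes", {
  tall <- matrix(0L, 60, 20)
  tall[10:50, 5:15] <- 255L
  ori <- pca_orientation(tall)
  expect_equal(ori$alpha, 90)
  expect_equal(ori$rotation, 0)

  # rectangle of points rotated 30 deg from vertical: analytic axis at 60 deg
  h <- seq(-40, 40, by = 0.5); w <- seq(-10, 10, by = 0.5)
  pts <- expand.grid(y = h, x = w)
  th <- -30 * pi / 180
  xr <- pts$x * cos(th) - pts$y * sin(th)
  yr <- pts$x * sin(th) + pts$y * cos(th)
  img <- matrix(0L, 160, 160)
  img[cbind(round(80 - yr), round(80 + xr))] <- 255L
  ori2 <- pca_orientation(img)
  expect_lt(abs(ori2$alpha - 60), 1)

  sq <- matrix(0L, 40, 40); sq[10:30, 10:30] <- 255L
  expect_warning(ori3 <- pca_orientation(sq), "degenerate")
  expect_equal(ori3$alpha, 90)
  expect_equal(ori3$rotation, 0)
  expect_true(ori3$degenerate)

  expect_error(pca_orientation(matrix(0L, 5, 5)), "no box found")
})

test_that("pca_orientation is invariant to the white encoding", {
  img <- matrix(0L, 60, 40); img[10:50, 15:25] <- 255L
  a <- pca_orientation(img)
  b <- pca_orientation((img > 0) * 1L)
  expect_equal(a$alpha, b$alpha)
  expect_equal(a$center, b$center)
})

test_that("rotate_image at 0 degrees is the identity", {
  set.seed(2)
  img <- as_gray_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  expect_identical(rotate_image(img, 0), img)
})

test_that("align_image uprights rotated phantoms and is idempotent", {
  ph0 <- generate_phantom(phantom_spec(rng_seed = 2))
  al0 <- align_image(ph0$image)
  expect_lt(abs(al0$orientation$rotation), 1)

  ph <- generate_phantom(phantom_spec(rng_seed = 2, box_angle = 20))
  al <- align_image(ph$image)
  expect_lt(abs(al$orientation$rotation - (-20)), 2)
  re <- align_image(al$image)
  expect_lt(abs(re$orientation$rotation), 2)  # already upright
})

test_that("alignment output agrees with the unrotated phantom's", {
  ph0 <- generate_phantom(phantom_spec(rng_seed = 8))
  ph1 <- generate_phantom(phantom_spec(rng_seed = 8, box_angle = 25))
  # anchor both outputs on the collimation field, ignoring the faint
  # interpolation penumbra (< 17) the rotated copy spills past the boundary
  field_crop <- function(img) {
    rows <- range(which(rowSums(img > 16) > 0))
    cols <- range(which(colSums(img > 16) > 0))
    img[rows[1]:rows[2], cols[1]:cols[2]]
  }
  a0 <- field_crop(align_image(ph0$image)$image)
  a1 <- field_crop(align_image(ph1$image)$image)
  h <- min(nrow(a0), nrow(a1)); w <- min(ncol(a0), ncol(a1))
  expect_lt(abs(nrow(a0) - nrow(a1)) + abs(ncol(a0) - ncol(a1)), 6)
  expect_lt(mean(abs(a0[1:h, 1:w] - a1[1:h, 1:w])), 5)
})
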