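# Rotation-invariant preprocessing: pad, binarise, close, PCA orientation of
# the collimation box, rotation upright with Lanczos resampling.

#' Pad an image with a black border
#'
#' Enhances the boundary between the collimation box and the image frame
#' before binarisation; the default border of 10 pixels guarantees the box
#' never touches the frame.
#'
#' @param img grayscale image matrix.
#' @param pad border width in pixels (>= 0).
#' @return the padded image.
#' @export
pad_border <- function(img, pad = 10L) {
  assert_gray(img)
  pad <- as.integer(pad)
  if (pad < 0) stop("pad must be >= 0")
  if (pad == 0L) return(as_gray_image(img))
  out <- matrix(0L, nrow(img) + 2L * pad, ncol(img) + 2L * pad)
  out[pad + seq_len(nrow(img)), pad + seq_len(ncol(img))] <- img
  as_gray_image(out)
}

#' Binarise on the exposed/unexposed boundary
#'
#' Every strictly positive pixel becomes 255; exact zeros (the unexposed
#' detector outside the collimation field) stay 0.
#'
#' @param img grayscale image matrix.
#' @return a 0/255 image.
#' @export
binarise <- function(img) {
  assert_gray(img)
  out <- matrix(0L, nrow(img), ncol(img))
  out[img > 0] <- 255L
  out
}

#' Morphological closing of binarisation artifacts
#'
#' Closing (dilation then erosion) with a `kernel` x `kernel` all-ones
#' structuring element fills black holes inside the white box that are
#' smaller than the kernel. For even kernel sizes the anchor sits at
#' `floor((kernel-1)/2)`, with the erosion window reflected so that the
#' operation is a true (idempotent) closing. Outside the image, dilation
#' sees black and erosion sees white (the usual neutral border values), so
#' foreground touching the frame is not eroded away.
#'
#' @param binary a 0/255 image.
#' @param kernel structuring element side length in pixels.
#' @return the closed 0/255 image.
#' @export
close_artifacts <- function(binary, kernel = 10L) {
  assert_binary(binary, "binary")
  k <- as.integer(kernel)
  if (k < 1L) stop("kernel must be >= 1")
  a <- (k - 1L) %/% 2L
  d <- cpp_dilate_rect(binary, -a, k - 1L - a, 0L)
  cpp_erode_rect(d, -(k - 1L - a), a, 255L)
}

#' Principal-axis orientation of the collimation box
#'
#' Treats the white pixels as data points `(x = column, y = -row)` and takes
#' the eigenvector of their covariance matrix with the largest eigenvalue.
#' `alpha` is the angle of this axis measured from the horizontal image axis
#' and normalised to `(-90, 90]` (the eigenvector's sign is arbitrary).
#' `rotation` is the upright correction `90 - alpha`, wrapped into
#' `(-90, 90]`. A square box has no defined orientation: both eigenvalues
#' tie, `alpha = 90` is returned with `degenerate = TRUE` and a warning, and
#' no rotation is applied.
#'
#' @param binary a 0/255 image (encoding with white = 1 also accepted).
#' @return an object of class `orientation` with fields `alpha`, `rotation`
#'   (degrees), `center` (mean white-pixel coordinate, `c(row, col)`), and
#'   `degenerate`.
#' @export
pca_orientation <- function(binary) {
  idx <- which(binary > 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("no box found: fewer than 2 white pixels")
  x <- idx[, 2L]
  y <- -idx[, 1L]
  cv <- stats::cov(cbind(x, y))
  eg <- eigen(cv, symmetric = TRUE)
  degenerate <- FALSE
  if (abs(eg$values[1] - eg$values[2]) <=
      1e-9 * max(eg$values[1], .Machine$double.eps)) {
    warning("degenerate box: equal principal variances, orientation undefined")
    degenerate <- TRUE
    alpha <- 90
  } else {
    v <- eg$vectors[, 1L]
    alpha <- atan2(v[2L], v[1L]) * 180 / pi
    if (alpha <= -90) alpha <- alpha + 180
    if (alpha > 90) alpha <- alpha - 180
  }
  rotation <- if (degenerate) 0 else {
    rot <- 90 - alpha
    if (rot > 90) rot <- rot - 180
    rot
  }
  structure(list(alpha = alpha, rotation = rotation,
                 center = c(row = mean(idx[, 1L]), col = mean(x)),
                 degenerate = degenerate),
            class = "orientation")
}

#' @export
print.orientation <- function(x, ...) {
  cat(sprintf("<orientation> alpha %.2f deg, rotation %.2f deg%s\n",
              x$alpha, x$rotation, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Rotate an image about its centre with Lanczos resampling
#'
#' Rotates the content by `angle` degrees counter-clockwise (standard x/y
#' orientation, x = column, y = -row) about the image centre, interpolating
#' with a Lanczos kernel over an 8x8 neighbourhood. The output canvas is
#' enlarged to the rotated bounding box (`expand = TRUE`) so no content is
#' clipped; new pixels are 0.
#'
#' @param img grayscale image matrix.
#' @param angle rotation in degrees.
#' @param expand enlarge the canvas to the rotated bounding box.
#' @return the rotated image.
#' @export
rotate_image <- function(img, angle, expand = TRUE) {
  assert_gray(img)
  if (abs(angle) < 1e-9) return(as_gray_image(img))
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  if (expand) {
    outH <- ceiling(H * abs(cos(th)) + W * abs(sin(th)))
    outW <- ceiling(H * abs(sin(th)) + W * abs(cos(th)))
  } else {
    outH <- H; outW <- W
  }
  out <- cpp_rotate_lanczos(matrix(as.numeric(img), H, W), angle,
                            outH, outW,
                            (H - 1) / 2, (W - 1) / 2,
                            (outH - 1) / 2, (outW - 1) / 2)
  as_gray_image(out)
}

#' Align a radiograph upright
#'
#' Full alignment pipeline: pad with a black border, binarise on the
#' exposed/unexposed boundary, close artifacts, estimate the collimation
#' box's principal axis by PCA, and rotate the padded image by `90 - alpha`
#' about its centre so the box axis becomes vertical.
#'
#' @param img grayscale image matrix containing a nonzero region.
#' @param pad border width (px).
#' @param kernel closing kernel side (px).
#' @return a list with `image` (the aligned image) and `orientation`
#'   (see [pca_orientation()]).
#' @export
align_image <- function(img, pad = 10L, kernel = 10L) {
  padded <- pad_border(img, pad)
  bin <- close_artifacts(binarise(padded), kernel)
  ori <- pca_orientation(bin)
  aligned <- rotate_image(padded, ori$rotation)
  list(image = aligned, orientation = ori)
}
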