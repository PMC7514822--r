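# Classical edge-detector baselines for the segmentation comparison harness.
# No pre-installed R package provides these detectors, so compact standard
# implementations are bundled; hyperparameters follow the tuned comparison
# settings: Canny with hysteresis thresholds (1 +/- 0.66) * mean intensity,
# a 3x3 Laplacian, and 11x11 extended Sobel kernels.

binomial_kernel <- function(n) choose(n - 1L, 0:(n - 1L))

sobel_kernels <- function(size = 11L) {
  smooth <- binomial_kernel(size)
  # integer kernel; round away the FFT residue of convolve()
  deriv <- round(convolve(binomial_kernel(size - 2L), rev(c(-1, 0, 1)),
                          type = "open"))
  list(smooth = smooth, deriv = deriv)
}

canny_edges <- function(img, sigma_frac = 0.66, blur_sigma = 1) {
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  sm <- cpp_filter2d(x, gauss_kernel(blur_sigma))
  kx <- outer(c(1, 2, 1), c(-1, 0, 1))   # 3x3 Sobel, x derivative
  gx <- cpp_filter2d(sm, kx)
  gy <- cpp_filter2d(sm, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  # non-maximum suppression along the quantised gradient direction
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  H <- nrow(mag); W <- ncol(mag)
  padm <- matrix(0, H + 2L, W + 2L)
  padm[2:(H + 1L), 2:(W + 1L)] <- mag
  shift <- function(dr, dc) padm[2:(H + 1L) + dr, 2:(W + 1L) + dc]
  dir0 <- (ang < 22.5 | ang >= 157.5)              # horizontal gradient
  dir45 <- (ang >= 22.5 & ang < 67.5)
  dir90 <- (ang >= 67.5 & ang < 112.5)
  dir135 <- (ang >= 112.5 & ang < 157.5)
  keep <- (dir0 & mag >= shift(0, -1) & mag >= shift(0, 1)) |
    (dir45 & mag >= shift(-1, 1) & mag >= shift(1, -1)) |
    (dir90 & mag >= shift(-1, 0) & mag >= shift(1, 0)) |
    (dir135 & mag >= shift(-1, -1) & mag >= shift(1, 1))
  nms <- mag
  nms[!keep] <- 0
  mu <- mean(img)
  lo <- max((1 - sigma_frac) * mu, .Machine$double.eps)
  hi <- (1 + sigma_frac) * mu
  cpp_hysteresis(nms, lo, hi)
}

#' Baseline edge detectors
#'
#' Runs one of the classical detectors used as comparison baselines for the
#' entropy-based segmentation: Canny (hysteresis thresholds
#' `(1 +/- 0.66) * mean intensity`), a 3x3 Laplacian, or 11x11 vertical /
#' horizontal Sobel operators. Laplacian and Sobel responses carry no
#' published binarisation rule, so they are thresholded at 20% of the
#' maximum absolute response (a package choice, documented here).
#'
#' @param img grayscale image matrix.
#' @param method one of `"canny"`, `"laplacian"`, `"sobel_v"`, `"sobel_h"`.
#' @return a 0/255 edge image.
#' @export
baseline_edges <- function(img,
                           method = c("canny", "laplacian", "sobel_v", "sobel_h")) {
  assert_gray(img)
  method <- match.arg(method)
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (method == "canny") return(canny_edges(img))
  resp <- switch(method,
    laplacian = cpp_filter2d(x, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)),
    sobel_v = {  # vertical edges: derivative along columns
      k <- sobel_kernels(11L)
      cpp_filter2d(x, outer(k$smooth, k$deriv))
    },
    sobel_h = {
      k <- sobel_kernels(11L)
      cpp_filter2d(x, outer(k$deriv, k$smooth))
    })
  resp <- abs(resp)
  m <- max(resp)
  out <- matrix(0L, nrow(img), ncol(img))
  if (m > 0) out[resp > 0.2 * m] <- 255L
  out
}
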