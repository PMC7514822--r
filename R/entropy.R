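# Sigma-weighted local Shannon entropy, row-wise line-edge detection, and
# entropy-based segmentation quality metrics.

#' Sliding-window settings for the local entropy map
#'
#' @param size odd window side length in pixels (>= 3); 9 is the tuned value
#'   for forearm radiographs.
#' @param log_base logarithm base for the entropy (2 = bits).
#' @return an object of class `entropy_window`.
#' @export
entropy_window <- function(size = 9L, log_base = 2) {
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L) stop("window size must be odd and >= 3")
  if (log_base <= 0 || log_base == 1) stop("log_base must be positive and != 1")
  structure(list(size = size, log_base = log_base, boundary = "mirror"),
            class = "entropy_window")
}

#' Shannon entropy of an intensity sample
#'
#' Entropy of the empirical distribution of the values (probability =
#' count / total over distinct values), with `0 * log 0 = 0`.
#'
#' @param values nonempty vector of intensities.
#' @param log_base logarithm base (2 = bits).
#' @return entropy in `log_base` units.
#' @examples
#' shannon_entropy(c(rep(0, 40), rep(255, 40)))  # 1 bit
#' @export
shannon_entropy <- function(values, log_base = 2) {
  values <- as.vector(values)
  if (length(values) == 0L) stop("values must be nonempty")
  p <- tabulate(match(values, unique(values)))
  p <- p / sum(p)
  -sum(p * log(p, base = log_base))
}

#' Sigma-weighted local entropy map
#'
#' For every pixel, the Shannon entropy of the 8-bit intensity histogram in
#' an `n x n` window centred on it, multiplied by the population standard
#' deviation of the window. Windows straddling the border are filled by
#' mirror reflection (edge pixel included). High values mark bone edges,
#' where the window mixes two well-separated intensity populations; flat
#' tissue and background score near 0.
#'
#' @param img grayscale image matrix, at least as large as the window.
#' @param win an [entropy_window()].
#' @return a nonnegative numeric matrix of the same size as `img`.
#' @export
local_entropy_map <- function(img, win = entropy_window()) {
  assert_gray(img)
  if (nrow(img) < win$size || ncol(img) < win$size)
    stop("image smaller than the entropy window")
  storage.mode(img) <- "integer"
  cpp_local_entropy(img, win$size, win$log_base)
}

#' Global-mean normalisation of an entropy map
#'
#' Subtracts the global mean of the map from every value and clips negatives
#' to 0, suppressing the diffuse blur halo around bones before peak
#' extraction.
#'
#' @param emap numeric matrix (an entropy map).
#' @return the normalised map.
#' @export
normalise_rows <- function(emap) {
  out <- emap - mean(emap)
  out[out < 0] <- 0
  out
}

# Collapse local-maximum plateaus of a 1D nonnegative signal to single
# representatives. Returns columns (rounded mean position of each merged
# region, round-half-to-even) and the region's maximum value. Regions of
# marked maxima closer than merge_gap columns are merged.
collapse_maxima <- function(v, merge_gap = 2L) {
  n <- length(v)
  if (n == 0L || all(v <= 0)) return(list(columns = integer(), values = numeric()))
  # plateau-aware local maxima: scan runs of equal value; a plateau touching
  # the sequence boundary has no lower neighbour on that side and is not a
  # maximum (so constant sequences yield no peaks)
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nb_left <- c(Inf, runs$values[-length(runs$values)])
  nb_right <- c(runs$values[-1L], Inf)
  is_max <- runs$values > 0 & runs$values > nb_left & runs$values > nb_right
  if (!any(is_max)) return(list(columns = integer(), values = numeric()))
  regions <- data.frame(start = starts[is_max], end = ends[is_max],
                        value = runs$values[is_max])
  # merge regions whose gap is within merge_gap columns
  grp <- cumsum(c(1L, as.integer(
    regions$start[-1L] - regions$end[-nrow(regions)] > merge_gap)))
  cols <- numeric(0); vals <- numeric(0)
  for (g in unique(grp)) {
    rg <- regions[grp == g, , drop = FALSE]
    members <- unlist(mapply(seq, rg$start, rg$end, SIMPLIFY = FALSE))
    cols <- c(cols, round(mean(members)))
    vals <- c(vals, max(rg$value))
  }
  list(columns = as.integer(cols), values = vals)
}

#' Detect bone-edge peaks in one row of a normalised entropy map
#'
#' Finds local-maximum plateaus, collapses each region of equal-or-nearby
#' marked maxima to one representative at the (round-half-to-even) mean
#' column, then discards peaks whose value is at most `threshold_frac` times
#' the row's maximum positive value.
#'
#' @param row numeric vector (one image row).
#' @param threshold_frac relative threshold in `(0, 1)`; 0.2 is the tuned
#'   value.
#' @param merge_gap maximum column gap between marked maxima merged into one
#'   peak region.
#' @return an object of class `row_peaks` with `columns` (strictly
#'   increasing) and `values`. An all-zero row yields no peaks.
#' @export
detect_row_peaks <- function(row, threshold_frac = 0.2, merge_gap = 2L) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  pk <- collapse_maxima(row, merge_gap)
  if (length(pk$columns)) {
    cut <- threshold_frac * max(row[row > 0])
    keep <- pk$values > cut
    pk$columns <- pk$columns[keep]
    pk$values <- pk$values[keep]
  }
  structure(pk, class = "row_peaks")
}

#' Line-edge image from an entropy map
#'
#' Normalises the map ([normalise_rows()]) and, for every row, sets white
#' pixels exactly at the [detect_row_peaks()] columns. The result is a binary
#' image in which white near-vertical lines trace the bone edges.
#'
#' @param emap numeric entropy map.
#' @param threshold_frac relative peak threshold.
#' @return a 0/255 image of the same size.
#' @export
line_edge_image <- function(emap, threshold_frac = 0.2) {
  norm <- normalise_rows(emap)
  out <- matrix(0L, nrow(norm), ncol(norm))
  for (r in seq_len(nrow(norm))) {
    cols <- detect_row_peaks(norm[r, ], threshold_frac)$columns
    if (length(cols)) out[r, cols] <- 255L
  }
  out
}

# Tile an image into non-overlapping square windows (partial edge tiles
# included) and return the per-tile pixel vectors.
image_tiles <- function(img, window) {
  rs <- split(seq_len(nrow(img)), (seq_len(nrow(img)) - 1L) %/% window)
  cs <- split(seq_len(ncol(img)), (seq_len(ncol(img)) - 1L) %/% window)
  tiles <- list()
  for (ri in rs) for (ci in cs) tiles[[length(tiles) + 1L]] <- img[ri, ci]
  tiles
}

#' Segmentation entropy
#'
#' Tiles the image into non-overlapping `window x window` squares (partial
#' edge tiles included) and sums the relative deviation of each tile's
#' entropy from the whole-image entropy:
#' `E(S) = sum_i (E(r_i) - E(H)) / E(H)`. Small isolated white fragments
#' left after segmentation raise this score.
#'
#' @param img image matrix (typically a binary segmentation).
#' @param window tile side length in pixels.
#' @return the (dimensionless) segmentation entropy.
#' @export
segmentation_entropy <- function(img, window = 32L) {
  eh <- shannon_entropy(as.vector(img))
  if (eh == 0) stop("undefined segmentation entropy: constant image")
  er <- vapply(image_tiles(img, window), shannon_entropy, numeric(1))
  sum(er - eh) / eh
}

#' Global entropy score of a segmentation
#'
#' Combines the image entropy `H(X)` (information left after segmentation)
#' with the segmentation entropy scaled by the number of tiles:
#' `N = H(X) + sum_i (E(r_i) - E(H)) / (n_windows * E(H))`. Lower is better.
#' Both the unscaled segmentation entropy (`E(S)`) and the tile count are
#' reported alongside.
#'
#' @param img image matrix (typically a binary segmentation).
#' @param window tile side length in pixels.
#' @return an object of class `noise_score` with `image_entropy` (bits),
#'   `segmentation_entropy`, `global_entropy` and `n_windows`.
#' @export
global_entropy_score <- function(img, window = 32L) {
  eh <- shannon_entropy(as.vector(img))
  if (eh == 0) stop("undefined segmentation entropy: constant image")
  er <- vapply(image_tiles(img, window), shannon_entropy, numeric(1))
  es <- sum(er - eh) / eh
  nw <- length(er)
  structure(list(image_entropy = eh,
                 segmentation_entropy = es,
                 global_entropy = eh + es / nw,
                 n_windows = nw,
                 window = window),
            class = "noise_score")
}

#' @export
print.noise_score <- function(x, ...) {
  cat(sprintf(
    "<noise_score> H(X) = %.5f bits, E(S) = %.5f, N = %.5f (%d windows of %d px)\n",
    x$image_entropy, x$segmentation_entropy, x$global_entropy, x$n_windows,
    x$window))
  invisible(x)
}
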