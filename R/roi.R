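# Region-of-interest extraction: top boundary from the jump in per-row peak
# counts at the distal bone ends, lateral boundaries from the four highest
# peaks per row.

#' Region-of-interest box
#'
#' 1-based, inclusive bounds `[top_row, bottom_row] x [left_col, right_col]`.
#'
#' @param top_row,bottom_row,left_col,right_col box bounds in pixels.
#' @return an object of class `roi_box`.
#' @export
roi_box <- function(top_row, bottom_row, left_col, right_col) {
  stopifnot(top_row >= 1, top_row < bottom_row,
            left_col >= 1, left_col < right_col)
  structure(list(top_row = as.integer(top_row),
                 bottom_row = as.integer(bottom_row),
                 left_col = as.integer(left_col),
                 right_col = as.integer(right_col)),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> rows %d..%d, cols %d..%d\n",
              x$top_row, x$bottom_row, x$left_col, x$right_col))
  invisible(x)
}

#' Top boundary of the forearm region
#'
#' The number of line-edge peaks per row jumps where the ulna and radius end
#' (carpal structures produce many more peaks than the four bone contours).
#' Within the central band of the image (the bones of a valid study do not
#' end in the top or bottom quarter), local-maximum regions of the peak-count
#' sequence are collapsed to single representatives, those at or above
#' `retain_frac` of the band maximum are retained, and the largest retained
#' row index — the peak closest to the wrist-side bone ends — is returned.
#'
#' @param peaks_per_row integer vector of per-row peak counts.
#' @param search_band fraction pair: band of rows searched.
#' @param retain_frac retain peaks at or above this fraction of the maximum.
#' @return the top-boundary row index.
#' @export
find_top_boundary <- function(peaks_per_row, search_band = c(0.25, 0.75),
                              retain_frac = 0.95) {
  n <- length(peaks_per_row)
  lo <- max(1L, floor(search_band[1] * n))
  hi <- min(n, ceiling(search_band[2] * n))
  band <- peaks_per_row[lo:hi]
  pk <- collapse_maxima(as.numeric(band))
  if (!length(pk$columns))
    stop("invalid image: bones end outside central band")
  keep <- pk$values >= retain_frac * max(pk$values)
  as.integer(lo) - 1L + max(pk$columns[keep])
}

#' Lateral boundaries of the bone region
#'
#' Per row of the (height-cropped) line-edge image, the four peaks with the
#' highest normalised-entropy values are taken — two bones contribute four
#' contours, and bone-edge peaks dominate tissue and collimation edges. The
#' four columns of each row are sorted, averaged position-wise across rows,
#' and the outermost means are expanded outwards by `expand_frac` of their
#' span. Rows with fewer than four peaks are skipped; if more than half of
#' the rows lack four peaks the image carries too little bone evidence.
#'
#' @param peak_image 0/255 line-edge image, already cropped to the bone rows.
#' @param emap normalised entropy map of the same region (peak magnitudes).
#' @param expand_frac outward expansion as a fraction of the bone span.
#' @return `c(left_col, right_col)` (integer, clamped to the image).
#' @export
find_width_box <- function(peak_image, emap, expand_frac = 0.2) {
  stopifnot(all(dim(peak_image) == dim(emap)))
  quads <- matrix(NA_real_, nrow(peak_image), 4L)
  for (r in seq_len(nrow(peak_image))) {
    cols <- which(peak_image[r, ] > 0)
    if (length(cols) < 4L) next
    vals <- emap[r, cols]
    top4 <- cols[order(vals, decreasing = TRUE)[1:4]]
    quads[r, ] <- sort(top4)
  }
  ok <- !is.na(quads[, 1L])
  if (sum(ok) < nrow(peak_image) / 2)
    stop("insufficient bone evidence: fewer than 4 peaks in most rows")
  mean_cols <- colMeans(quads[ok, , drop = FALSE])
  left <- mean_cols[1L]; right <- mean_cols[4L]
  span <- right - left
  left <- max(1L, as.integer(round(left - expand_frac * span)))
  right <- min(ncol(peak_image), as.integer(round(right + expand_frac * span)))
  c(left = left, right = right)
}

#' Extract the region of interest around the ulna and radius
#'
#' Composition of the boundary searches: the top boundary is found from the
#' per-row peak counts of the full line-edge image, the image is cropped
#' from that row to the bottom (the bottom boundary of a forearm study is
#' the image bottom), and the lateral boundaries are found on the cropped
#' region.
#'
#' @param peak_image 0/255 line-edge image (aligned).
#' @param emap normalised entropy map (aligned, same size).
#' @param search_band,retain_frac see [find_top_boundary()].
#' @param expand_frac see [find_width_box()].
#' @return a list with `image` (the cropped line-edge image) and `box`
#'   (an [roi_box()]).
#' @export
extract_roi <- function(peak_image, emap, search_band = c(0.25, 0.75),
                        retain_frac = 0.95, expand_frac = 0.2) {
  stopifnot(all(dim(peak_image) == dim(emap)))
  counts <- rowSums(peak_image > 0)
  top <- find_top_boundary(counts, search_band, retain_frac)
  bottom <- nrow(peak_image)
  cropped <- peak_image[top:bottom, , drop = FALSE]
  lr <- find_width_box(cropped, emap[top:bottom, , drop = FALSE], expand_frac)
  box <- roi_box(top, bottom, lr["left"], lr["right"])
  list(image = cropped[, lr["left"]:lr["right"], drop = FALSE], box = box)
}
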