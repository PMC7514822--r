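# Fracture detection: per bone line, remove the noisy top curvature, fit the
# ideal healthy contour by polynomial regression, and track residual runs
# beyond a pixel tolerance.

#' Fracture-detection fit settings
#'
#' @param ideal_degree degree of the ideal-contour polynomial (3 matches the
#'   gentle S-shape of healthy long-bone contours).
#' @param curvature_degree degree of the top-curvature fit (2).
#' @param top_frac fraction of rows at the top of the bone line examined for
#'   curvature removal (0.20).
#' @param tolerance residual tolerance in pixels; deviations strictly above
#'   it count as excess (3, absorbing merge and segmentation jitter).
#' @param min_run minimum number of consecutive excess rows that triggers a
#'   fracture flag (2: single-row spikes are segmentation noise).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(ideal_degree = 3L, curvature_degree = 2L,
                       top_frac = 0.20, tolerance = 3, min_run = 2L) {
  stopifnot(ideal_degree >= 1L, top_frac > 0, top_frac < 1, tolerance >= 0,
            min_run >= 1L)
  structure(list(ideal_degree = as.integer(ideal_degree),
                 curvature_degree = as.integer(curvature_degree),
                 top_frac = top_frac, tolerance = tolerance,
                 min_run = as.integer(min_run)),
            class = "fit_config")
}

poly_fit <- function(rows, cols, degree) {
  X <- outer(rows, 0:degree, `^`)
  fit <- stats::lm.fit(X, cols)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  unname(coefs)
}

poly_eval <- function(coefs, rows) {
  drop(outer(rows, seq_along(coefs) - 1L, `^`) %*% coefs)
}

#' Remove the top curvature of a bone line
#'
#' The distal end of a traced contour hooks towards the joint and would
#' corrupt the ideal-contour regression. A quadratic `col = q(row)` is
#' fitted to the top `top_frac` of the rows; if its vertex row falls inside
#' that band the line is cropped there, otherwise at the band's lower
#' boundary.
#'
#' @param line a `bone_line`.
#' @param cfg a [fit_config()].
#' @return the cropped `bone_line`.
#' @export
crop_top_curvature <- function(line, cfg = fit_config()) {
  n <- length(line$rows)
  if (n < 20L) stop("bone line too short to crop (need >= 20 rows)")
  k <- max(cfg$curvature_degree + 1L, ceiling(cfg$top_frac * n))
  band <- seq_len(k)  # rows are increasing: the top of the bone comes first
  coefs <- poly_fit(line$rows[band], line$cols[band], cfg$curvature_degree)
  band_lo <- line$rows[1L]; band_hi <- line$rows[k]
  crop_row <- band_hi
  if (abs(coefs[3L]) > 1e-12) {
    vertex <- -coefs[2L] / (2 * coefs[3L])
    if (vertex >= band_lo && vertex <= band_hi) crop_row <- vertex
  }
  keep <- line$rows > crop_row
  structure(list(rows = line$rows[keep], cols = line$cols[keep]),
            class = "bone_line")
}

#' Fit the ideal healthy bone contour
#'
#' Least-squares polynomial `col = p(row)` of the given degree; the fitted
#' curve is the fracture-free reference against which residuals are scored.
#'
#' @param line a `bone_line`.
#' @param degree polynomial degree.
#' @return numeric coefficient vector, lowest order first.
#' @export
fit_ideal_contour <- function(line, degree = 3L) {
  if (length(line$rows) <= degree)
    stop("underdetermined fit: need more rows than the polynomial degree")
  poly_fit(line$rows, line$cols, degree)
}

#' Score contour deviation from the ideal fit
#'
#' Residuals are `col - p(row)` at matching rows. Reports the mean squared
#' error and every maximal run of consecutive entries whose absolute
#' residual strictly exceeds the tolerance, with the location and size of
#' each run's peak.
#'
#' @param line a `bone_line` (the cropped line used for the fit).
#' @param fit coefficients from [fit_ideal_contour()].
#' @param tolerance pixel tolerance (strict inequality).
#' @return a list with `mse`, `residuals` (per-row data frame) and
#'   `excess_runs` (data frame: `start_row`, `end_row`, `peak_row`,
#'   `peak_dev`, `n_rows`).
#' @export
score_deviation <- function(line, fit, tolerance = 3) {
  res <- line$cols - poly_eval(fit, line$rows)
  excess <- abs(res) > tolerance
  runs <- rle(excess)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  excess_runs <- do.call(rbind, lapply(sel, function(k) {
    span <- starts[k]:ends[k]
    pk <- span[which.max(abs(res[span]))]
    data.frame(start_row = line$rows[starts[k]], end_row = line$rows[ends[k]],
               peak_row = line$rows[pk], peak_dev = abs(res[pk]),
               peak_sign = sign(res[pk]), n_rows = length(span))
  }))
  if (is.null(excess_runs))
    excess_runs <- data.frame(start_row = integer(), end_row = integer(),
                              peak_row = integer(), peak_dev = numeric(),
                              peak_sign = numeric(), n_rows = integer())
  list(mse = mean(res^2),
       residuals = data.frame(row = line$rows, col = line$cols,
                              fitted = poly_eval(fit, line$rows),
                              residual = res),
       excess_runs = excess_runs)
}

#' Detect fractures from traced bone lines
#'
#' Per line: [crop_top_curvature()] -> [fit_ideal_contour()] ->
#' [score_deviation()]. The image is flagged as fractured if any line shows
#' a deviation area of at least `min_run` excess rows; each qualifying area
#' becomes a localisation circle centred at the area's peak (row, contour
#' column) with radius equal to the width of the area (floored at the
#' tolerance).
#'
#' @param lines list of `bone_line` objects (1-4).
#' @param cfg a [fit_config()].
#' @return an object of class `fracture_report`: `fractured` (logical),
#'   `detections` (data frame: `row`, `col`, `radius`, `bone_line`,
#'   `peak_dev`) and `residual_trace` (per-line deviation scores).
#' @export
detect_fracture <- function(lines, cfg = fit_config()) {
  if (!length(lines)) stop("no bone lines supplied")
  if (length(lines) > 4L) stop("at most 4 bone lines expected")
  detections <- list()
  traces <- list()
  for (i in seq_along(lines)) {
    cropped <- crop_top_curvature(lines[[i]], cfg)
    fit <- fit_ideal_contour(cropped, cfg$ideal_degree)
    sc <- score_deviation(cropped, fit, cfg$tolerance)
    traces[[i]] <- sc
    # A lateral step produces two adjacent excess runs of opposite residual
    # sign, separated by the zero-crossing band of the fitted contour; with
    # the cubic's smoothing the residual slope there is ~0.5 px/row, so the
    # band is up to about 4 * tolerance rows wide. Such a pair is one
    # fracture area and gets a single localisation circle.
    runs <- sc$excess_runs
    if (nrow(runs)) {
      runs <- runs[order(runs$start_row), , drop = FALSE]
      if (nrow(runs) > 1L) {
        gap <- runs$start_row[-1L] - runs$end_row[-nrow(runs)] - 1L
        flip <- runs$peak_sign[-1L] != runs$peak_sign[-nrow(runs)]
        new_area <- !(flip & gap <= 4 * cfg$tolerance)
        grp <- cumsum(c(1L, as.integer(new_area)))
      } else grp <- 1L
      areas <- do.call(rbind, lapply(split(runs, grp), function(g) {
        pk <- which.max(g$peak_dev)
        data.frame(start_row = min(g$start_row), end_row = max(g$end_row),
                   peak_row = g$peak_row[pk], peak_dev = g$peak_dev[pk],
                   n_rows = sum(g$n_rows))
      }))
      qr <- areas[areas$n_rows >= cfg$min_run, , drop = FALSE]
    } else qr <- runs
    if (nrow(qr)) {
      col_at <- function(r) cropped$cols[match(r, cropped$rows)]
      detections[[length(detections) + 1L]] <- data.frame(
        row = qr$peak_row,
        col = vapply(qr$peak_row, col_at, numeric(1)),
        # the circle radius is the width of the deviation area (floored at
        # the tolerance so minimal detections stay visible)
        radius = pmax(qr$end_row - qr$start_row + 1, cfg$tolerance),
        bone_line = i,
        peak_dev = qr$peak_dev)
    }
  }
  detections <- if (length(detections)) do.call(rbind, detections) else
    data.frame(row = numeric(), col = numeric(), radius = numeric(),
               bone_line = integer(), peak_dev = numeric())
  structure(list(fractured = nrow(detections) > 0L,
                 detections = detections,
                 residual_trace = traces),
            class = "fracture_report")
}

#' @export
print.fracture_report <- function(x, ...) {
  if (x$fractured) {
    cat(sprintf("<fracture_report> FRACTURED: %d detection(s)\n",
                nrow(x$detections)))
    print(x$detections)
  } else {
    cat("<fracture_report> no fracture detected\n")
  }
  invisible(x)
}
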