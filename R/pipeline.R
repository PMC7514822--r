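# End-to-end pipeline: align -> entropy segmentation -> ROI -> contour
# tracing -> fracture detection, with a serialisable configuration.

#' Pipeline configuration
#'
#' Collects every tunable hyperparameter of the pipeline with its tuned
#' default: border pad 10 px, closing kernel 10, entropy window 9 with log
#' base 2, peak threshold 0.20, ROI search band (0.25, 0.75) with 0.95 peak
#' retention and 20% width expansion, contour search window 5 up / 5 aside,
#' minimum path fraction 0.60, contour merge window 15 px, ideal-contour
#' degree 3, top-curvature fraction 0.20, residual tolerance 3 px, entropy
#' metric tile 32 px, and minimum excess run 2 rows.
#'
#' @param ... named overrides of the defaults.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(pad = 10L, close_kernel = 10L,
              entropy_window = 9L, log_base = 2,
              peak_threshold = 0.20,
              roi_band = c(0.25, 0.75), peak_retention = 0.95,
              width_expansion = 0.20,
              search_up = 5L, search_side = 5L,
              min_path_frac = 0.60, merge_window = 15L,
              ideal_degree = 3L, curvature_top_frac = 0.20,
              tolerance = 3, metric_window = 32L, min_run = 2L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$pad >= 0, cfg$close_kernel >= 1,
            cfg$entropy_window >= 3, cfg$entropy_window %% 2 == 1,
            cfg$peak_threshold > 0, cfg$peak_threshold < 1,
            length(cfg$roi_band) == 2, cfg$roi_band[1] < cfg$roi_band[2],
            cfg$peak_retention > 0, cfg$peak_retention <= 1,
            cfg$width_expansion >= 0, cfg$search_up >= 1, cfg$search_side >= 0,
            cfg$min_path_frac > 0, cfg$min_path_frac < 1,
            cfg$merge_window >= 0, cfg$ideal_degree >= 1,
            cfg$curvature_top_frac > 0, cfg$curvature_top_frac < 1,
            cfg$tolerance >= 0, cfg$metric_window >= 2, cfg$min_run >= 1)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full fracture-detection pipeline
#'
#' Executes, in order: alignment (pad, binarise, close, PCA, rotate),
#' sigma-weighted local entropy, line-edge detection, ROI extraction,
#' trimming of the empty canvas rows below the collimation box (the rotation
#' canvas adds black margins that clinical images do not have), graph-based
#' contour tracing, and polynomial-deviation fracture detection. Detection
#' coordinates are reported in the aligned-image frame.
#'
#' @param image grayscale image matrix or a file path readable by
#'   [read_gray()].
#' @param config a [pipeline_config()].
#' @param save_intermediate optional directory for per-stage images.
#' @param verbose log per-stage statistics with `message()`.
#' @return a `fracture_report` with additional fields: `orientation`,
#'   `roi` (the [roi_box()], in cropped-aligned coordinates), `frame` (the
#'   `c(row, col)` offset of the cropped-aligned frame inside the aligned
#'   image), `noise_score` (entropy metrics of the segmentation), and
#'   `n_lines`. Detection coordinates refer to the cropped-aligned frame.
#' @export
run_pipeline <- function(image, config = pipeline_config(),
                         save_intermediate = NULL, verbose = FALSE) {
  if (is.character(image)) image <- read_gray(image)
  assert_gray(image, "image")
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  t0 <- proc.time()[3]
  al <- stage_call("align", align_image(image, config$pad, config$close_kernel))
  say("align: rotation %.2f deg (%.2fs)", al$orientation$rotation,
      proc.time()[3] - t0)

  # crop back to the exposed field: the pad exists only for orientation
  # estimation, and the entropy stage's mirror boundary assumes the limb
  # runs to the image border. The extra half-window trim removes the
  # collimation penumbra (interpolation leaves partially exposed border
  # pixels after rotation) which would otherwise fabricate an entropy ridge
  # along the field boundary.
  aligned <- stage_call("align", crop_to_content(al$image))
  frame <- attr(aligned, "offset")
  k <- config$entropy_window %/% 2L
  if (nrow(aligned) > 4L * k && ncol(aligned) > 4L * k) {
    aligned <- aligned[(k + 1L):(nrow(aligned) - k),
                       (k + 1L):(ncol(aligned) - k), drop = FALSE]
    frame <- frame + k
  }

  emap <- stage_call("segment", local_entropy_map(
    aligned, entropy_window(config$entropy_window, config$log_base)))
  norm <- normalise_rows(emap)
  edges <- stage_call("segment", line_edge_image(emap, config$peak_threshold))
  say("segment: entropy-map mean %.3f, %d edge pixels", mean(emap),
      sum(edges > 0))

  roi <- stage_call("roi", extract_roi(edges, norm, config$roi_band,
                                       config$peak_retention,
                                       config$width_expansion))
  roi_img <- roi$image
  say("roi: rows %d..%d, cols %d..%d", roi$box$top_row, roi$box$bottom_row,
      roi$box$left_col, roi$box$right_col)

  lines <- stage_call("trace", trace_bones(
    roi_img, config$search_up, config$search_side,
    config$min_path_frac, config$merge_window))
  say("trace: %d bone line(s)", length(lines))

  cfg_fit <- fit_config(config$ideal_degree, 2L, config$curvature_top_frac,
                        config$tolerance, config$min_run)
  report <- stage_call("detect", detect_fracture(lines, cfg_fit))

  # map detections from ROI coordinates to the cropped-aligned frame
  if (nrow(report$detections)) {
    report$detections$row <- report$detections$row + roi$box$top_row - 1L
    report$detections$col <- report$detections$col + roi$box$left_col - 1L
  }
  report$orientation <- al$orientation
  report$roi <- roi$box
  report$frame <- frame
  report$noise_score <- global_entropy_score(edges, config$metric_window)
  report$n_lines <- length(lines)

  if (!is.null(save_intermediate)) {
    dir.create(save_intermediate, recursive = TRUE, showWarnings = FALSE)
    write_gray(aligned, file.path(save_intermediate, "aligned.png"))
    write_gray(round(255 * emap / max(max(emap), 1e-12)),
               file.path(save_intermediate, "entropy.png"))
    write_gray(edges, file.path(save_intermediate, "edges.png"))
    write_gray(roi_img, file.path(save_intermediate, "roi.png"))
  }
  report
}

#' Serialise a fracture report to JSON
#'
#' @param report a `fracture_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  out <- list(fractured = report$fractured,
              detections = report$detections,
              rotation = if (!is.null(report$orientation))
                report$orientation$rotation,
              roi = if (!is.null(report$roi)) unclass(report$roi),
              n_lines = report$n_lines)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
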