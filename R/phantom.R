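# Synthetic forearm-radiograph phantoms with exact ground truth.
#
# The phantom emulates the features the pipeline relies on: a bright
# collimation box on an unexposed (exactly zero) background, two near-vertical
# long bones with gentle quadratic bow inside a soft-tissue halo, a cluster of
# carpal-like blobs where the bones end (so the row-peak-count jump used for
# ROI cropping exists), additive Gaussian noise, optional blur, and optional
# fracture perturbations of one bone contour.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Describe a synthetic forearm phantom
#'
#' A `phantom_spec` fixes every parameter of the rendered scene. Geometry is
#' laid out in an upright frame and (for `box_angle != 0`) rotated
#' analytically, so rendering needs no interpolation and a given spec is
#' bit-reproducible. The defaults describe a realistic paediatric forearm
#' study: two high-intensity long bones (half-width 9 px, gentle quadratic
#' bow) inside an intermediate-intensity soft-tissue halo, carpal-like blobs
#' at the distal bone ends, mild quantum noise (sd 2) and slight blur.
#'
#' @param image_height,image_width canvas size in pixels (the canvas is
#'   enlarged automatically when a rotated collimation box would not fit).
#' @param box_angle rotation of the collimation box from vertical, in degrees
#'   (positive = counter-clockwise in standard x/y orientation).
#' @param bone_offset horizontal distance of each bone centreline from the
#'   box centre (px).
#' @param bone_half_width bone half-width (px); bone pixels satisfy
#'   `|col - centreline| <= bone_half_width + 0.5`.
#' @param bone_bow amplitude (px) of the quadratic bow of each centreline;
#'   a quadratic is captured exactly by the cubic ideal-contour fit, so
#'   fracture-free phantoms are a well-posed null case.
#' @param bone_intensity,tissue_intensity,box_intensity 8-bit intensities of
#'   bone, soft tissue and bare collimation field; must be strictly
#'   decreasing and positive.
#' @param tissue_half_width half-width (px) of the soft-tissue halo.
#' @param bone_top_frac vertical position of the distal bone ends as a
#'   fraction of the canvas height (the ROI stage expects it in the central
#'   band of the image).
#' @param noise_sigma additive Gaussian noise sd, in intensity units.
#' @param blur_sigma Gaussian blur sd in pixels (0 = none).
#' @param texture_sigma sd (intensity units) of the spatially correlated
#'   soft-tissue mottle projected over the limb; radiographs superimpose
#'   fat/muscle structure over bone, and edge detectors respond to it.
#' @param texture_scale correlation length of the mottle in pixels.
#' @param fracture `NULL` or a [fracture_truth()] object.
#' @param rng_seed integer seed; identical specs render identical images.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [fracture_truth()]
#' @export
phantom_spec <- function(image_height = 256L, image_width = 192L,
                         box_angle = 0, bone_offset = 22, bone_half_width = 9,
                         bone_bow = 3, bone_intensity = 200,
                         tissue_intensity = 100, box_intensity = 30,
                         tissue_half_width = 54, bone_top_frac = 0.44,
                         noise_sigma = 2, blur_sigma = 0.6,
                         texture_sigma = 6, texture_scale = 2.5,
                         fracture = NULL, rng_seed = 1L) {
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               box_angle = box_angle, bone_offset = bone_offset,
               bone_half_width = bone_half_width, bone_bow = bone_bow,
               bone_intensity = bone_intensity,
               tissue_intensity = tissue_intensity,
               box_intensity = box_intensity,
               tissue_half_width = tissue_half_width,
               bone_top_frac = bone_top_frac,
               noise_sigma = noise_sigma, blur_sigma = blur_sigma,
               texture_sigma = texture_sigma, texture_scale = texture_scale,
               fracture = fracture, rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Fracture ground truth for a phantom
#'
#' @param bone_index which bone carries the fracture (0 = left, 1 = right).
#' @param kind one of `"step"` (lateral offset of the centreline below the
#'   fracture row), `"gap"` (bone absent for `magnitude` rows) or `"bump"`
#'   (Gaussian lateral bulge of the centreline).
#' @param magnitude lateral displacement or gap height in pixels.
#' @param row_frac fracture row as a fraction of the bone extent measured
#'   from the distal (top) end; must stay out of the top 20% that the
#'   curvature-cropping step removes.
#' @return an object of class `fracture_truth`.
#' @export
fracture_truth <- function(bone_index = 1L, kind = c("step", "gap", "bump"),
                           magnitude = 6, row_frac = 0.55) {
  kind <- match.arg(kind)
  if (!bone_index %in% c(0L, 1L)) stop("bone_index must be 0 or 1")
  if (magnitude <= 0) stop("magnitude must be positive")
  if (row_frac <= 0.2 || row_frac >= 0.95)
    stop("row_frac must lie in (0.2, 0.95): the top 20% of the bone line is cropped")
  structure(list(bone_index = as.integer(bone_index), kind = kind,
                 magnitude = magnitude, row_frac = row_frac),
            class = "fracture_truth")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(bone_intensity > tissue_intensity && tissue_intensity > box_intensity &&
          box_intensity > 0))
      stop("intensities must satisfy bone > tissue > box > 0")
    if (image_height < 64L || image_width < 64L)
      stop("canvas too small (minimum 64x64)")
    bw <- round(0.72 * image_width)
    reach <- bone_offset + bone_bow + bone_half_width + 0.5
    if (reach > tissue_half_width - 2 || tissue_half_width > bw / 2 - 4)
      stop("bone centrelines do not lie fully inside the tissue/box region")
    if (!is.null(fracture) && fracture$kind != "gap" &&
        fracture$magnitude > bone_offset - bone_half_width - 0.5)
      stop("fracture magnitude too large: displaced fragment would cross the midline")
    if (bone_top_frac <= 0.3 || bone_top_frac >= 0.7)
      stop("bone_top_frac must keep the bone ends in the central band")
  })
  invisible(spec)
}

# Continuous bone centreline column offset at row offset u (upright frame).
bone_centreline <- function(spec, bone, u, top_off, bottom_off) {
  sgn <- if (bone == 0L) -1 else 1
  mid <- (top_off + bottom_off) / 2
  half <- (bottom_off - top_off) / 2
  t <- pmin(pmax((u - mid) / half, -1), 1)
  cb <- sgn * spec$bone_offset + sgn * spec$bone_bow * t^2
  fr <- spec$fracture
  if (!is.null(fr) && fr$bone_index == bone) {
    # lateral displacement is medial (towards the midline) so the displaced
    # fragment stays inside the soft-tissue halo
    f_off <- top_off + fr$row_frac * (bottom_off - top_off)
    if (fr$kind == "step") cb <- cb - sgn * fr$magnitude * (u > f_off)
    if (fr$kind == "bump") cb <- cb - sgn * fr$magnitude * exp(-((u - f_off) / 5)^2)
  }
  cb
}

#' Render a phantom radiograph and its ground truth
#'
#' Renders the scene described by a [phantom_spec()]: each output pixel is
#' mapped back into the upright scene frame (an exact inverse rotation, no
#' resampling), classified as background / collimation field / tissue /
#' carpal blob / bone, then blurred, degraded with Gaussian noise, quantised
#' to 8 bits and clamped. Pixels outside the collimation box are forced back
#' to exactly 0 afterwards, as on a real unexposed detector.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements `image` (integer matrix)
#'   and `truth`: the true box angle, the distal bone-end row, a data frame
#'   of per-row ground-truth edge columns for the four bone contours
#'   (`line` 1-4 left to right, `bone` 0/1), and fracture information with
#'   the absolute fracture `row`. Ground-truth coordinates refer to the
#'   upright (unrotated) base canvas; they coincide with image coordinates
#'   when `box_angle == 0`.
#' @examples
#' ph <- generate_phantom(phantom_spec(rng_seed = 7))
#' dim(ph$image)
#' head(ph$truth$edges)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  validate_phantom_spec(spec)
  H <- spec$image_height; W <- spec$image_width
  bh <- round(0.90 * H); bw <- round(0.72 * W)
  th <- spec$box_angle * pi / 180
  ct <- cos(th); st <- sin(th)
  outH <- max(H, ceiling(bh * abs(ct) + bw * abs(st)) + 24L)
  outW <- max(W, ceiling(bh * abs(st) + bw * abs(ct)) + 24L)
  cy <- (outH + 1) / 2; cx <- (outW + 1) / 2
  cyb <- (H + 1) / 2; cxb <- (W + 1) / 2

  # the forearm enters from the bottom of the exposed field: the collimation
  # box touches the bottom canvas edge and bones run to the very last row
  r_top <- round(spec$bone_top_frac * H)
  top_off <- r_top - cyb
  bottom_off <- H - cyb
  box_top_off <- H - bh + 1 - cyb

  with_seed(spec$rng_seed, {
    # carpal-like blobs just above the distal bone ends
    nblob <- 8L
    blob_dr <- top_off - seq(3, 15, length.out = nblob) + runif(nblob, -2, 2)
    blob_dc <- seq(-spec$bone_offset - 14, spec$bone_offset + 14,
                   length.out = nblob) + runif(nblob, -3, 3)
    blob_rx <- runif(nblob, 4, 7)
    blob_ry <- runif(nblob, 3, 5)

    rr <- matrix(seq_len(outH), outH, outW)
    cc <- matrix(seq_len(outW), outH, outW, byrow = TRUE)
    dx <- cc - cx
    dy <- -(rr - cy)
    # inverse-rotate into the upright scene frame
    dc_u <- ct * dx + st * dy
    dr_u <- -(-st * dx + ct * dy)

    in_box <- abs(dc_u) <= bw / 2 & dr_u >= box_top_off & dr_u <= bottom_off
    img <- matrix(0, outH, outW)
    img[in_box] <- spec$box_intensity
    # the limb's soft tissue crosses the whole radiation field vertically
    in_tissue <- in_box & abs(dc_u) <= spec$tissue_half_width
    img[in_tissue] <- spec$tissue_intensity
    for (k in seq_len(nblob)) {
      in_blob <- in_box &
        ((dr_u - blob_dr[k]) / blob_ry[k])^2 +
        ((dc_u - blob_dc[k]) / blob_rx[k])^2 <= 1
      img[in_blob] <- 180
    }
    fr <- spec$fracture
    gap_rows <- NULL
    if (!is.null(fr) && fr$kind == "gap") {
      f_off <- top_off + fr$row_frac * (bottom_off - top_off)
      gap_rows <- c(f_off, f_off + fr$magnitude)
    }
    for (b in 0:1) {
      cb <- bone_centreline(spec, b, dr_u, top_off, bottom_off)
      in_bone <- in_box & dr_u >= top_off & dr_u <= bottom_off &
        abs(dc_u - cb) <= spec$bone_half_width + 0.5
      if (!is.null(gap_rows) && fr$bone_index == b)
        in_bone <- in_bone & !(dr_u > gap_rows[1] & dr_u <= gap_rows[2])
      img[in_bone] <- spec$bone_intensity
    }

    if (spec$texture_sigma > 0) {
      # projected soft-tissue mottle: a band-limited random field defined in
      # the upright scene frame (sum of random-phase cosines with Gaussian
      # spectral sampling), so it rotates rigidly with the anatomy and the
      # same seed yields the same tissue at any box angle
      K <- 48L
      fr <- rnorm(K, 0, 1 / (2 * pi * spec$texture_scale))
      fc <- rnorm(K, 0, 1 / (2 * pi * spec$texture_scale))
      phase <- runif(K, 0, 2 * pi)
      tex <- matrix(0, outH, outW)
      for (k in seq_len(K))
        tex <- tex + cos(2 * pi * (fr[k] * dr_u + fc[k] * dc_u) + phase[k])
      tex <- tex * sqrt(2 / K) * spec$texture_sigma
      img <- img + tex * in_tissue
    }
    if (spec$blur_sigma > 0)
      img <- cpp_filter2d(img, gauss_kernel(spec$blur_sigma))
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma), outH, outW)
    img <- as_gray_image(img)
    img[!in_box] <- 0L
  })

  # ground truth in the upright base frame
  rb <- H
  rows <- r_top:rb
  edges <- do.call(rbind, lapply(0:1, function(b) {
    u <- rows - cyb
    cb <- bone_centreline(spec, b, u, top_off, bottom_off)
    keep <- rep(TRUE, length(rows))
    if (!is.null(gap_rows) && spec$fracture$bone_index == b)
      keep <- !(u > gap_rows[1] & u <= gap_rows[2])
    data.frame(
      row = rep(rows[keep], 2L),
      bone = b,
      line = rep(2L * b + c(1L, 2L), each = sum(keep)),
      col = c(cxb + cb[keep] - spec$bone_half_width - 0.5,
              cxb + cb[keep] + spec$bone_half_width + 0.5))
  }))
  truth <- list(
    box_angle = spec$box_angle,
    bone_end_row = r_top,
    bottom_row = rb,
    box_rows = as.integer(c(H - bh + 1, H)),
    box_cols = as.integer(c(ceiling(cxb - bw / 2), floor(cxb + bw / 2))),
    center = c(row = cy, col = cx),
    edges = edges,
    fracture = if (!is.null(spec$fracture)) {
      fr <- spec$fracture
      c(fr, list(row = round(r_top + fr$row_frac * (rb - r_top))))
    })
  structure(list(image = img, truth = truth, spec = spec), class = "phantom")
}

#' Generate a batch of phantoms
#'
#' Per-image seeds are drawn reproducibly from `seed`; a `fracture_rate`
#' fraction of the batch receives a fracture of the given kind with
#' magnitude drawn uniformly from `magnitudes`.
#'
#' @param n number of phantoms.
#' @param seed master seed for the batch.
#' @param fracture_rate fraction of phantoms carrying a fracture.
#' @param kind fracture kind passed to [fracture_truth()].
#' @param magnitudes integer vector of candidate fracture magnitudes (px).
#' @param out_dir if non-`NULL`, each phantom is written as `phantom_###.png`
#'   with a JSON ground-truth sidecar.
#' @param ... further arguments to [phantom_spec()].
#' @return invisibly, a list of `phantom` objects.
#' @export
generate_phantom_batch <- function(n, seed = 1L, fracture_rate = 0,
                                   kind = "step", magnitudes = 6:10,
                                   out_dir = NULL, ...) {
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    has_fr = runif(n) < fracture_rate,
    mags = sample(rep(magnitudes, length.out = max(n, length(magnitudes))), n),
    bones = sample(0:1, n, replace = TRUE),
    row_fracs = runif(n, 0.35, 0.8)))
  phantoms <- lapply(seq_len(n), function(i) {
    fr <- if (draws$has_fr[i])
      fracture_truth(bone_index = draws$bones[i], kind = kind,
                     magnitude = draws$mags[i], row_frac = draws$row_fracs[i])
    generate_phantom(phantom_spec(rng_seed = draws$seeds[i], fracture = fr, ...))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      stem <- file.path(out_dir, sprintf("phantom_%03d", i))
      write_gray(phantoms[[i]]$image, paste0(stem, ".png"))
      tr <- phantoms[[i]]$truth
      tr$edges <- NULL  # keep sidecars small; edges are recomputable
      jsonlite::write_json(tr, paste0(stem, ".json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  invisible(phantoms)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d, box angle %.1f deg, %s\n",
              nrow(x$image), ncol(x$image), x$truth$box_angle,
              if (is.null(x$truth$fracture)) "fracture-free"
              else sprintf("%s fracture (bone %d, row %d, %.1f px)",
                           x$truth$fracture$kind, x$truth$fracture$bone_index,
                           x$truth$fracture$row, x$truth$fracture$magnitude)))
  invisible(x)
}
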