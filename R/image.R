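#' Grayscale image helpers
#'
#' Images in bonetrace are plain integer matrices with values in `[0, 255]`,
#' origin top-left, first index = row (vertical), second index = column
#' (horizontal). `as_gray_image()` coerces and validates; `read_gray()` /
#' `write_gray()` handle 8-bit grayscale PNG and plain (ASCII) PGM files.
#'
#' @param x a numeric or integer matrix.
#' @return `as_gray_image()` returns an integer matrix with intensities
#'   clamped to `[0, 255]`.
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x)) stop("image must be a matrix")
  if (!is.numeric(x)) stop("image must be numeric")
  x <- round(x)
  x[x < 0] <- 0L
  x[x > 255] <- 255L
  storage.mode(x) <- "integer"
  x
}

assert_gray <- function(x, arg = "img") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", arg))
  if (anyNA(x)) stop(sprintf("%s contains NA", arg))
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 255)
    stop(sprintf("%s has intensities outside [0, 255]", arg))
  invisible(TRUE)
}

assert_binary <- function(x, arg = "img") {
  assert_gray(x, arg)
  if (!all(x %in% c(0L, 255L)))
    stop(sprintf("%s is not binary (values must be 0 or 255)", arg))
  invisible(TRUE)
}

#' @rdname as_gray_image
#' @param path file path; format chosen by extension (`.png`, `.pgm`).
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]  # drop extra channels
    return(as_gray_image(a * 255))
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: ", ext)
}

#' @rdname as_gray_image
#' @param img an image matrix.
#' @export
write_gray <- function(img, path) {
  img <- as_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Crop an image to its nonzero bounding box
#'
#' Removes the unexposed border (alignment padding and rotation canvas)
#' around the collimation field. Returns the cropped image with an
#' `offset` attribute `c(row, col)`: the position of the crop origin minus
#' one, so `cropped[r, c]` corresponds to `img[r + offset[1], c + offset[2]]`.
#'
#' @param img grayscale image matrix with at least one nonzero pixel.
#' @return the cropped image (attribute `offset`).
#' @export
crop_to_content <- function(img) {
  rows <- which(rowSums(img > 0) > 0)
  cols <- which(colSums(img > 0) > 0)
  if (!length(rows)) stop("image has no nonzero content")
  out <- img[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
  attr(out, "offset") <- c(row = min(rows) - 1L, col = min(cols) - 1L)
  out
}

# Plain (P2) portable graymap, used for text-only fixtures.
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only plain (P2) PGM supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply(img, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
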