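# Independent brute-force oracles used to cross-check the implementation.

# mirror reflection including the edge pixel, 1-based
reflect1 <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# per-pixel sigma-weighted entropy, recomputed naively
brute_entropy_map <- function(img, size = 9L, log_base = 2) {
  h <- size %/% 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      win <- numeric(size * size)
      k <- 0L
      for (dr in -h:h) for (dc in -h:h) {
        k <- k + 1L
        win[k] <- img[reflect1(r + dr, nrow(img)), reflect1(c + dc, ncol(img))]
      }
      p <- table(win) / length(win)
      H <- -sum(p * log(p, base = log_base))
      sig <- sqrt(mean((win - mean(win))^2))
      out[r, c] <- H * sig
    }
  }
  out
}

# naive binary closing with a k x k all-ones kernel (same anchor convention
# as close_artifacts), border treated as black
brute_closing <- function(bin, k = 10L) {
  a <- (k - 1L) %/% 2L
  H <- nrow(bin); W <- ncol(bin)
  val <- function(m, r, c, fill)
    if (r >= 1 && r <= H && c >= 1 && c <= W) m[r, c] else fill
  dil <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    v <- 0L
    for (dr in -a:(k - 1L - a)) for (dc in -a:(k - 1L - a))
      v <- max(v, val(bin, r + dr, c + dc, 0L))
    dil[r, c] <- v
  }
  ero <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    v <- 255L
    for (dr in -(k - 1L - a):a) for (dc in -(k - 1L - a):a)
      v <- min(v, val(dil, r + dr, c + dc, 255L))
    ero[r, c] <- v
  }
  ero
}

# map base-frame phantom coordinates into run_pipeline's reporting frame
# (valid for box_angle = 0: the aligned image is the padded base image)
to_pipeline_row <- function(r, report, pad = 10L) r + pad - report$frame[["row"]]
to_pipeline_col <- function(c, report, pad = 10L) c + pad - report$frame[["col"]]

# straight-line bone_line constructor for fracture unit tests
make_line <- function(rows, cols) {
  structure(list(rows = rows, cols = cols), class = "bone_line")
}
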