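# Graph-based bone contour tracing through the binary ROI image: root
# selection on the bottom row, upward nearest-pixel expansion, path-length
# filtering, and merging of duplicate (blurred) contours.

#' Select root pixels for contour growth
#'
#' Bones run to the very bottom of the forearm ROI, so every white pixel in
#' the bottom row is taken as a root node. In the ideal case there are
#' exactly four (two contours per bone); noise and blur may produce more,
#' and all are kept — spurious roots grow short paths that the length filter
#' removes.
#'
#' @param binary 0/255 ROI image.
#' @return a matrix with columns `row`, `col`, one root per row.
#' @export
select_roots <- function(binary) {
  assert_binary(binary, "binary")
  cols <- which(binary[nrow(binary), ] > 0)
  if (!length(cols)) stop("no bone roots found: empty bottom row")
  cbind(row = rep(nrow(binary), length(cols)), col = cols)
}

#' Next contour pixels above the current one
#'
#' Searches the window `up` rows above and `side` columns to either side of
#' the current pixel for white pixels and returns all at minimum Euclidean
#' distance (ties are all returned). An empty result marks a dead end.
#'
#' @param binary 0/255 image.
#' @param current `c(row, col)` of the current pixel.
#' @param up,side search window extents in pixels.
#' @return a matrix with columns `row`, `col` (possibly 0 rows).
#' @export
next_pixels <- function(binary, current, up = 5L, side = 5L) {
  r <- current[[1L]]; c <- current[[2L]]
  rows <- max(1L, r - up):(r - 1L)
  if (r <= 1L) return(cbind(row = integer(), col = integer()))
  cols <- max(1L, c - side):min(ncol(binary), c + side)
  sub <- binary[rows, cols, drop = FALSE]
  idx <- which(sub > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(cbind(row = integer(), col = integer()))
  rr <- rows[idx[, 1L]]; cc <- cols[idx[, 2L]]
  d2 <- (rr - r)^2 + (cc - c)^2
  best <- d2 == min(d2)
  ord <- order(cc[best])
  cbind(row = rr[best][ord], col = cc[best][ord])
}

#' Build the bone contour graph
#'
#' From each root, pixels are expanded breadth-first: the nearest white
#' pixels above the current node ([next_pixels()]) become its children.
#' Every edge points strictly upward, and a pixel joins each root's tree at
#' most once (ties that would re-converge dead-end instead), so the per-root
#' structure is a tree whose root-to-leaf chains are the candidate contours.
#'
#' @param binary 0/255 ROI image.
#' @param roots root matrix from [select_roots()].
#' @param up,side search window extents.
#' @return an object of class `contour_graph`: a list of per-root trees,
#'   each a data frame with `row`, `col`, `parent` (0 for the root).
#' @export
build_graph <- function(binary, roots, up = 5L, side = 5L) {
  if (is.null(dim(roots)) || nrow(roots) == 0L) stop("roots must be nonempty")
  W <- ncol(binary)
  trees <- lapply(seq_len(nrow(roots)), function(i) {
    rows <- integer(4096L); cols <- integer(4096L); parent <- integer(4096L)
    rows[1L] <- roots[i, 1L]; cols[1L] <- roots[i, 2L]; parent[1L] <- 0L
    n <- 1L
    visited <- new.env(hash = TRUE, parent = emptyenv())
    assign(as.character((rows[1L] - 1L) * W + cols[1L]), TRUE, envir = visited)
    head <- 1L
    while (head <= n) {
      nx <- next_pixels(binary, c(rows[head], cols[head]), up, side)
      if (nrow(nx)) {
        for (j in seq_len(nrow(nx))) {
          key <- as.character((nx[j, 1L] - 1L) * W + nx[j, 2L])
          if (!is.null(get0(key, envir = visited))) next
          assign(key, TRUE, envir = visited)
          n <- n + 1L
          if (n > length(rows)) {
            rows <- c(rows, integer(length(rows)))
            cols <- c(cols, integer(length(cols)))
            parent <- c(parent, integer(length(parent)))
          }
          rows[n] <- nx[j, 1L]; cols[n] <- nx[j, 2L]; parent[n] <- head
        }
      }
      head <- head + 1L
    }
    data.frame(row = rows[seq_len(n)], col = cols[seq_len(n)],
               parent = parent[seq_len(n)])
  })
  structure(list(trees = trees, roots = roots), class = "contour_graph")
}

#' @export
print.contour_graph <- function(x, ...) {
  cat(sprintf("<contour_graph> %d roots, %s nodes\n", length(x$trees),
              sum(vapply(x$trees, nrow, integer(1)))))
  invisible(x)
}

#' Filter candidate contours by vertical extent
#'
#' Enumerates every root-to-leaf chain of the graph and keeps those whose
#' row extent (root row minus leaf row) exceeds `min_path_frac` of the image
#' height. The extent rule uses rows, not node counts, so diagonal or tied
#' chains are not inflated. The fraction is a patient-age-dependent
#' hyperparameter; 0.60 is the tuned default.
#'
#' @param graph a [build_graph()] result.
#' @param img_height height of the ROI image in pixels.
#' @param min_path_frac minimum extent as a fraction of `img_height`.
#' @return a list of paths, each a matrix with columns `row`, `col` ordered
#'   bottom-up.
#' @export
filter_paths <- function(graph, img_height, min_path_frac = 0.6) {
  min_extent <- min_path_frac * img_height
  paths <- list()
  for (tree in graph$trees) {
    leaves <- setdiff(seq_len(nrow(tree)), tree$parent)
    for (lf in leaves) {
      if (tree$row[1L] - tree$row[lf] <= min_extent) next
      chain <- integer(0)
      k <- lf
      while (k != 0L) {
        chain <- c(chain, k)
        k <- tree$parent[k]
      }
      chain <- rev(chain)  # bottom-up: root first
      paths[[length(paths) + 1L]] <-
        cbind(row = tree$row[chain], col = tree$col[chain])
    }
  }
  if (!length(paths)) stop("no bone contour found: all paths too short")
  paths
}

#' Merge duplicate blurred contours into bone lines
#'
#' Blurred bones produce several parallel contours for one true edge. Paths
#' lying within `merge_window` columns of each other on at least half of
#' their shared rows are grouped, and each group is reduced to one bone line
#' whose per-row column is the mean of the member columns present at that
#' row. At most four lines are returned (the four longest if more survive),
#' sorted left to right; fewer than four triggers a warning.
#'
#' @param paths list of path matrices from [filter_paths()].
#' @param merge_window column window for grouping (px).
#' @return a list of `bone_line` objects (fields `rows`, increasing, and
#'   `cols`, possibly fractional).
#' @export
merge_contours <- function(paths, merge_window = 15L) {
  np <- length(paths)
  if (!np) stop("no paths to merge")
  cols_by_row <- lapply(paths, function(p) {
    stats::setNames(as.numeric(p[, "col"]), p[, "row"])
  })
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    shared <- intersect(names(cols_by_row[[i]]), names(cols_by_row[[j]]))
    if (!length(shared)) next
    near <- abs(cols_by_row[[i]][shared] - cols_by_row[[j]][shared]) <= merge_window
    if (mean(near) >= 0.5) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  groups <- split(seq_len(np), vapply(seq_len(np), find, integer(1)))
  lines <- lapply(groups, function(g) {
    all_rows <- sort(unique(as.integer(unlist(lapply(g, function(i)
      names(cols_by_row[[i]]))))))
    cols <- vapply(all_rows, function(r) {
      vals <- unlist(lapply(g, function(i) cols_by_row[[i]][as.character(r)]))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
    structure(list(rows = all_rows, cols = cols), class = "bone_line")
  })
  if (length(lines) > 4L) {
    extent <- vapply(lines, function(l) diff(range(l$rows)), numeric(1))
    lines <- lines[order(extent, decreasing = TRUE)[1:4]]
  }
  if (length(lines) < 4L)
    warning(sprintf("only %d bone line(s) recovered (expected 4)", length(lines)))
  lines[order(vapply(lines, function(l) mean(l$cols), numeric(1)))]
}

#' @export
print.bone_line <- function(x, ...) {
  cat(sprintf("<bone_line> rows %d..%d, mean col %.1f\n",
              min(x$rows), max(x$rows), mean(x$cols)))
  invisible(x)
}

#' Trace bone lines through a binary ROI image
#'
#' Convenience wrapper: [select_roots()] -> [build_graph()] ->
#' [filter_paths()] -> [merge_contours()].
#'
#' @param binary 0/255 ROI image.
#' @param up,side search window extents.
#' @param min_path_frac minimum path extent fraction.
#' @param merge_window contour merge window (px).
#' @return a list of `bone_line` objects.
#' @export
trace_bones <- function(binary, up = 5L, side = 5L, min_path_frac = 0.6,
                        merge_window = 15L) {
  roots <- select_roots(binary)
  graph <- build_graph(binary, roots, up, side)
  paths <- filter_paths(graph, nrow(binary), min_path_frac)
  merge_contours(paths, merge_window)
}
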