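#' Signed shoelace area of a polygon
#'
#' Vertices are an n x 2 matrix of (x, y) coordinates; the polygon is closed
#' implicitly. The absolute value is returned (pixel^2 units).
#'
#' @param poly n x 2 numeric matrix, columns x and y.
#' @return non-negative area.
#' @export
shoelace_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Rasterize a polygon to a binary mask
#'
#' Pixel (row i, column j) has its center at 0-based coordinates
#' (x = j - 1, y = i - 1) with x rightward and y downward. A pixel is
#' foreground when its center lies inside the polygon under the nonzero
#' winding rule; centers lying exactly on an edge count as inside.
#'
#' @param poly n x 2 matrix of (x, y) vertex coordinates, 0-based, closed
#'   implicitly.
#' @param height,width raster size in pixels.
#' @return integer matrix (height x width) of 0/1.
#' @export
polygon_fill <- function(poly, height, width) {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3)
    stop("polygon needs at least 3 (x, y) vertices")
  height <- as.integer(height); width <- as.integer(width)
  px <- rep(seq_len(width) - 1, each = height)   # x per pixel, column-major
  py <- rep(seq_len(height) - 1, times = width)  # y per pixel
  wn <- integer(height * width)
  on_edge <- logical(height * width)
  n <- nrow(poly)
  eps <- 1e-9
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    e2 <- if (e == n) 1L else e + 1L
    x2 <- poly[e2, 1]; y2 <- poly[e2, 2]
    cr <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- (y1 <= py) & (py < y2) & (cr > 0)
    dn <- (y2 <= py) & (py < y1) & (cr < 0)
    wn <- wn + up - dn
    # on-segment test: zero cross product and within the bounding box
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (seg_len2 > 0) {
      t <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / seg_len2
      d2 <- (px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2
      on_edge <- on_edge | (t >= -eps & t <= 1 + eps & d2 <= eps)
    }
  }
  matrix(as.integer(wn != 0L | on_edge), height, width)
}

#' Largest 4-connected foreground component
#'
#' Two-pass union-find labelling with 4-connectivity; returns a mask retaining
#' only the largest component (ties broken by the smallest label, i.e. the
#' component encountered first in column-major order).
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix with only the largest component kept.
#' @export
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 0) next
    up <- if (i > 1 && mask[i - 1, j] != 0) lab[i - 1, j] else 0L
    lf <- if (j > 1 && mask[i, j - 1] != 0) lab[i, j - 1] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      r <- min(ru, rl)
      parent[ru] <- r; parent[rl] <- r
      lab[i, j] <- r
    } else {
      lab[i, j] <- max(up, lf)
    }
  }
  if (nxt == 0L) return(matrix(0L, h, w))
  roots <- vapply(seq_len(nxt), find, integer(1))
  fg <- lab != 0L
  lab[fg] <- roots[lab[fg]]
  sizes <- tabulate(lab[fg], nbins = nxt)
  keep <- which.max(sizes)
  matrix(as.integer(lab == keep), h, w)
}
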