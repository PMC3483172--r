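# Small planar-geometry helpers shared by the shape-extraction and
# morphometry code. Polygons are data.frames/lists with numeric x, y;
# they may be open (first point not repeated) or closed.

#' Signed polygon area (shoelace formula)
#'
#' @param x,y vertex coordinates; the closing vertex may be repeated or not.
#' @return Absolute enclosed area.
#' @keywords internal
polygon_area <- function(x, y) {
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) return(0)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' @param px,py query point(s).
#' @param x,y polygon vertices (closure optional).
#' @return Logical vector, TRUE where the point lies inside.
#' @keywords internal
point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Minimum width of a band containing a polygon
#'
#' The minimal width over all orientations of a pair of parallel lines
#' enclosing the polygon equals the width of its convex hull, attained with
#' one line flush against a hull edge (rotating calipers).
#'
#' @param x,y polygon vertices.
#' @return Minimal band width.
#' @keywords internal
polygon_min_width <- function(x, y) {
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 2) return(0)
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(h)
  if (m < 3) return(0)  # collinear
  widths <- vapply(seq_len(m), function(i) {
    j <- if (i == m) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) return(Inf)
    # distance of all hull points from the line through edge i
    max(abs((hx - hx[i]) * ey - (hy - hy[i]) * ex) / len)
  }, numeric(1))
  min(widths)
}

# Bilinear interpolation of matrix M (M[y+1, x+1], 0-based coords) at (px, py)
bilinear_at <- function(M, px, py) {
  h <- nrow(M); w <- ncol(M)
  px <- pmin(pmax(px, 0), w - 1)
  py <- pmin(pmax(py, 0), h - 1)
  x0 <- pmin(floor(px), w - 2); y0 <- pmin(floor(py), h - 2)
  fx <- px - x0; fy <- py - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  M[i00] * (1 - fx) * (1 - fy) + M[i01] * fx * (1 - fy) +
    M[i10] * (1 - fx) * fy + M[i11] * fx * fy
}
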