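# Small geometry helpers shared across modules.

#' Signed area of a polygon
#'
#' Shoelace formula; positive for counter-clockwise orientation in a frame
#' with y increasing upwards.
#'
#' @param xy two-column matrix of vertex coordinates, in order.
#' @return signed area (numeric scalar).
#' @keywords internal
poly_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Centroid of a simple polygon
#' @param xy two-column coordinate matrix, in order.
#' @return length-2 numeric vector.
#' @keywords internal
poly_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# TRUE where a polygon is simple (no two non-adjacent edges intersect).
# O(n^2) segment test; polygons here have < 15 vertices.
poly_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  seg <- cbind(xy, xy[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

# Points-in-polygon by even-odd ray crossing; px, py vectors.
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Fold an undirected angle (radians) into [0, pi/2]: acute angle to the x axis.
axis_angle <- function(dx, dy) {
  a <- atan2(dy, dx) %% pi
  pmin(a, pi - a)
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
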