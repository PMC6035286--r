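# Static morphometrics: triangulation of the cell-center network, the
# nematic cell-elongation tensor per triangle, tissue-scale averages,
# natural-strain tissue shape, junctional polarity, apico-basal intensity
# profiles, and surface (ECM) coverage.

# Reference equilateral triangle: unit area, one side along +x.
# Any other fixed reference differs by a rotation/scaling of the linear map
# M, which cancels in M M^T / det M.
ref_triangle_inv <- local({
  s <- 2 / 3^0.25                      # side length of the unit-area equilateral
  E <- cbind(c(s, 0), c(s / 2, s * sqrt(3) / 2))
  solve(E)
})

#' Triangulate a cell mesh at its tricellular vertices
#'
#' Builds one triangle per interior vertex by connecting the cell centers
#' (centroids) of the cells meeting at that vertex. Vertices with four or
#' more incident cells are fanned into triangles in counter-clockwise cell
#' order around the vertex; vertices with fewer than three incident cells
#' (tile corners on the clipped hull) are skipped, so boundary cells
#' contribute only through interior vertices.
#'
#' @param mesh a `cell_mesh` (polygon outlines not required; centroids and
#'   vertex incidence suffice).
#' @return an object of class `triangulation`: a data.frame with one row per
#'   triangle (cell ids `a`, `b`, `c`, the six centroid coordinates, `area`),
#'   plus the source mesh as an attribute.
#' @export
triangulate <- function(mesh) {
  stopifnot(inherits(mesh, "cell_mesh"))
  deg <- lengths(mesh$vertex_cells)
  vin <- which(deg >= 3L)
  rows <- list()
  for (v in vin) {
    cc <- mesh$vertex_cells[[v]]
    if (length(cc) > 3L) {
      # order cells counter-clockwise around the vertex, then fan
      ctr <- mesh$centroids[match(cc, mesh$cell_ids), , drop = FALSE]
      ang <- atan2(ctr[, 2] - mesh$vertices[v, 2], ctr[, 1] - mesh$vertices[v, 1])
      cc <- cc[order(ang)]
      tri <- lapply(seq_len(length(cc) - 2L), function(k) cc[c(1L, k + 1L, k + 2L)])
    } else {
      tri <- list(cc)
    }
    rows <- c(rows, tri)
  }
  if (!length(rows)) {
    warning("mesh has no interior tricellular vertex; empty triangulation")
    tr <- data.frame(a = integer(0), b = integer(0), c = integer(0),
                     ax = numeric(0), ay = numeric(0), bx = numeric(0),
                     by = numeric(0), cx = numeric(0), cy = numeric(0),
                     area = numeric(0))
    return(structure(tr, class = c("triangulation", "data.frame"), mesh = mesh))
  }
  tri <- do.call(rbind, rows)
  P <- function(i) mesh$centroids[match(tri[, i], mesh$cell_ids), , drop = FALSE]
  p1 <- P(1); p2 <- P(2); p3 <- P(3)
  ar2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  # normalize orientation: swap b and c where clockwise
  cw <- ar2 < 0
  if (any(cw)) {
    tmp <- tri[cw, 2]; tri[cw, 2] <- tri[cw, 3]; tri[cw, 3] <- tmp
    tmp <- p2[cw, , drop = FALSE]; p2[cw, ] <- p3[cw, , drop = FALSE]; p3[cw, ] <- tmp
    ar2 <- abs(ar2)
  }
  tr <- data.frame(a = tri[, 1], b = tri[, 2], c = tri[, 3],
                   ax = p1[, 1], ay = p1[, 2], bx = p2[, 1], by = p2[, 2],
                   cx = p3[, 1], cy = p3[, 2], area = ar2 / 2)
  structure(tr, class = c("triangulation", "data.frame"), mesh = mesh)
}

# Vectorized nematic elongation for triangle coordinate columns.
# Returns a two-column matrix (qxx, qxy).
triangle_q_components <- function(ax, ay, bx, by, cx, cy) {
  # M maps the reference equilateral onto the observed triangle
  e1x <- bx - ax; e1y <- by - ay
  e2x <- cx - ax; e2y <- cy - ay
  S <- ref_triangle_inv
  m11 <- e1x * S[1, 1] + e2x * S[2, 1]
  m12 <- e1x * S[1, 2] + e2x * S[2, 2]
  m21 <- e1y * S[1, 1] + e2y * S[2, 1]
  m22 <- e1y * S[1, 2] + e2y * S[2, 2]
  dM <- m11 * m22 - m12 * m21
  if (any(dM <= 0)) stop("degenerate (zero-area) triangle")
  # A = M M^T / det M is symmetric positive definite with det 1;
  # its matrix log is traceless symmetric: Q = (1/2) log A.
  a <- (m11^2 + m12^2) / dM
  b <- (m11 * m21 + m12 * m22) / dM
  c <- (m21^2 + m22^2) / dM
  tr2 <- pmax((a + c) / 2, 1)
  m <- acosh(tr2)
  f <- ifelse(m < 1e-8, 1, m / sinh(m))   # m/sinh(m) -> 1 as m -> 0
  cbind(qxx = f * (a - c) / 4, qxy = f * b / 2)
}

#' Nematic elongation tensor of one triangle
#'
#' Compares a triangle with the reference equilateral triangle: let M be the
#' linear map sending the reference (unit area, one side along +x) to the
#' observed triangle; the elongation tensor is `Q = 1/2 logm(M M^T / det M)`,
#' a symmetric traceless 2 x 2 tensor reported by its two independent
#' components (qxx, qxy). The result does not depend on which vertex is
#' listed first nor on rigid rotations of the reference, and rotating the
#' observed triangle by theta rotates (qxx, qxy) by 2 theta.
#'
#' @param triangle 3 x 2 matrix of vertex coordinates, or a one-row subset of
#'   a [triangulate()] result.
#' @return named numeric vector `c(qxx, qxy)`.
#' @export
triangle_elongation <- function(triangle) {
  if (is.data.frame(triangle)) {
    stopifnot(nrow(triangle) == 1L)
    q <- triangle_q_components(triangle$ax, triangle$ay, triangle$bx,
                               triangle$by, triangle$cx, triangle$cy)
    return(c(qxx = q[1, 1], qxy = q[1, 2]))
  }
  P <- as.matrix(triangle)
  stopifnot(all(dim(P) == c(3L, 2L)))
  ar2 <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
         (P[2, 2] - P[1, 2]) * (P[3, 1] - P[1, 1])
  if (ar2 == 0) stop("degenerate (zero-area) triangle")
  if (ar2 < 0) P <- P[c(1, 3, 2), ]
  q <- triangle_q_components(P[1, 1], P[1, 2], P[2, 1], P[2, 2], P[3, 1], P[3, 2])
  c(qxx = q[1, 1], qxy = q[1, 2])
}

#' Per-triangle elongation components
#'
#' @param tri a [triangulate()] result.
#' @return matrix with columns `qxx`, `qxy`, one row per triangle.
#' @export
triangle_elongations <- function(tri) {
  stopifnot(inherits(tri, "triangulation"))
  triangle_q_components(tri$ax, tri$ay, tri$bx, tri$by, tri$cx, tri$cy)
}

#' Mean cell-elongation tensor over a triangulation
#'
#' Component-wise average of the per-triangle nematic tensors, uniform by
#' default or weighted by triangle area.
#'
#' @param tri a [triangulate()] result with at least one triangle.
#' @param weighting `"uniform"` (default) or `"area"`.
#' @return named numeric vector `c(qxx, qxy)`.
#' @export
mean_elongation <- function(tri, weighting = c("uniform", "area")) {
  weighting <- match.arg(weighting)
  if (!nrow(tri)) stop("empty triangulation")
  q <- triangle_elongations(tri)
  w <- if (weighting == "area") tri$area / sum(tri$area) else rep(1 / nrow(q), nrow(q))
  c(qxx = sum(w * q[, 1]), qxy = sum(w * q[, 2]))
}

#' Mean cell-shape anisotropy over a triangulation
#'
#' Average of per-triangle magnitudes `|Q| = sqrt(qxx^2 + qxy^2)`. Note this
#' is the mean of magnitudes, which bounds the magnitude of the mean tensor
#' from above; both statistics are useful and they differ on disordered
#' tissue.
#'
#' @param tri a [triangulate()] result with at least one triangle.
#' @return scalar mean anisotropy.
#' @export
mean_anisotropy <- function(tri) {
  if (!nrow(tri)) stop("empty triangulation")
  q <- triangle_elongations(tri)
  mean(sqrt(q[, 1]^2 + q[, 2]^2))
}

#' Tissue shape: extents, area and natural strains
#'
#' Measures the maximal PD (x) length `l`, maximal AP (y) width `h` and the
#' tissue area (sum of cell polygon areas when outlines are present,
#' bounding-box area otherwise). Given a reference shape, also the natural
#' strains `L = log(l/l0)`, `H = log(h/h0)` and their difference `L - H`,
#' the tissue elongation.
#'
#' @param mesh a `cell_mesh`.
#' @param reference optional `tissue_shape` (or list with `l` and `h`)
#'   supplying `l0`, `h0`.
#' @param height optional scalar epithelial height (not computed from 2-D
#'   meshes; accepted as measured input).
#' @return object of class `tissue_shape`: list with `l`, `h`, `area`,
#'   `height`, and (with a reference) `L`, `H`, `LmH`.
#' @export
tissue_shape <- function(mesh, reference = NULL, height = NA_real_) {
  stopifnot(inherits(mesh, "cell_mesh"))
  bb <- unname(apply(mesh$vertices, 2, range))
  l <- bb[2, 1] - bb[1, 1]
  h <- bb[2, 2] - bb[1, 2]
  area <- if (!is.null(mesh$cells)) sum(mesh$areas) else l * h
  out <- list(l = l, h = h, area = area, height = height,
              L = NA_real_, H = NA_real_, LmH = NA_real_)
  if (!is.null(reference)) {
    out$L <- log(l / reference$l)
    out$H <- log(h / reference$h)
    out$LmH <- out$L - out$H
  }
  structure(out, class = "tissue_shape")
}

#' @export
print.tissue_shape <- function(x, ...) {
  cat(sprintf("<tissue_shape> l = %.4g, h = %.4g, area = %.4g", x$l, x$h, x$area))
  if (is.finite(x$LmH)) cat(sprintf(", L-H = %.4g", x$LmH))
  cat("\n"); invisible(x)
}

#' Junctional polarity ratio
#'
#' Classifies cell-cell junctions by orientation: junctions whose axis lies
#' within `angle_threshold_deg` of the AP (y) axis are "AP-oriented" (in the
#' wing these carry the PD-polarized myosin signal), within the threshold of
#' the PD (x) axis are "PD-oriented". Returns the ratio of mean intensity on
#' the AP-oriented class to mean intensity on the PD-oriented class.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param intensities numeric vector of per-junction intensities aligned with
#'   the rows of [mesh_junctions()] (as produced by
#'   [synth_junction_intensities()]).
#' @param angle_threshold_deg half-width of each orientation class (degrees).
#' @return scalar polarity ratio.
#' @export
junction_polarity_ratio <- function(mesh, intensities, angle_threshold_deg = 30) {
  jn <- mesh_junctions(mesh)
  if (length(intensities) != nrow(jn))
    stop("`intensities` must align with mesh_junctions(mesh) rows")
  pd <- jn$angle_deg <= angle_threshold_deg
  ap <- jn$angle_deg >= 90 - angle_threshold_deg
  if (!any(pd) || !any(ap)) stop("empty junction orientation class")
  mean(intensities[ap]) / mean(intensities[pd])
}

#' Normalized apico-basal intensity profile
#'
#' Each line scan is divided by its own mean intensity, then the normalized
#' lines are averaged position-wise; the output profile has mean 1, so
#' profiles from samples with different absolute brightness are comparable.
#'
#' @param line_samples list of equal-length numeric vectors (or a matrix with
#'   one line per row).
#' @return numeric vector: the mean normalized profile.
#' @export
apicobasal_profile <- function(line_samples) {
  if (is.matrix(line_samples)) line_samples <- asplit(line_samples, 1)
  if (!length(line_samples)) stop("need at least one line sample")
  len <- unique(lengths(line_samples))
  if (length(len) != 1L) stop("line samples must have equal resampled length")
  norm <- lapply(line_samples, function(v) v / mean(v))
  colMeans(do.call(rbind, norm))
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based between-class variance maximization on `nbins` equal-width
#' bins spanning the data range.
#'
#' @param x numeric vector.
#' @param nbins number of histogram bins.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

#' Surface coverage percentage
#'
#' Fraction of profile samples above an intensity threshold, as a percent;
#' quantifies e.g. what share of an epithelial surface is covered by an ECM
#' marker.
#'
#' @param profile numeric intensity profile along the surface.
#' @param threshold numeric threshold, or `"otsu"` to pick it by between-class
#'   variance maximization.
#' @return coverage in percent (0--100).
#' @export
ecm_coverage <- function(profile, threshold = "otsu") {
  if (!length(profile)) stop("empty profile")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(profile) else threshold
  100 * mean(profile > thr)
}
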