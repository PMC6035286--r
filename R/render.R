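# Rendering synthetic membrane-marker images from a cell mesh, with a
# ground-truth label raster. Raster convention: row-major, origin top-left,
# pixel centers at integer-minus-half coordinates; mesh y increases downward
# to match raster space.

#' Render a membrane image and ground-truth labels from a mesh
#'
#' Draws a bright, anti-aliased membrane skeleton (Gaussian cross-section of
#' full width `membrane_width_px`) over dark cell interiors, applies a small
#' Gaussian blur, and adds Poisson shot noise plus Gaussian read noise.
#' `snr` is defined as membrane mean intensity over total noise sd at the
#' membrane; `Inf` disables noise, in which case the output is a
#' deterministic function of the mesh alone. The label raster assigns each
#' pixel its cell id, with 0 on the membrane skeleton.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param px_per_unit raster resolution (pixels per tissue unit, > 0).
#' @param membrane_width_px membrane thickness in pixels (>= 1).
#' @param snr signal-to-noise ratio at the membrane; `Inf` for noiseless.
#' @param seed integer seed for the noise.
#' @param blur_sigma_px optical blur sd in pixels.
#' @param max_pixels size cap; an error is raised if width x height exceeds it.
#' @return list with `image` (numeric matrix, rows = y), `labels` (integer
#'   matrix), and `px_per_unit`.
#' @export
render_membrane_image <- function(mesh, px_per_unit = 45, membrane_width_px = 2,
                                  snr = Inf, seed = 1L, blur_sigma_px = 0.7,
                                  max_pixels = 4e6) {
  if (is.null(mesh$cells)) stop("mesh carries no polygon outlines")
  if (px_per_unit <= 0) stop("`px_per_unit` must be > 0")
  if (membrane_width_px < 1) stop("`membrane_width_px` must be >= 1")
  bb <- apply(mesh$vertices, 2, range)
  pad <- membrane_width_px / px_per_unit
  x0 <- bb[1, 1] - pad; y0 <- bb[1, 2] - pad
  W <- ceiling((bb[2, 1] - bb[1, 1] + 2 * pad) * px_per_unit)
  H <- ceiling((bb[2, 2] - bb[1, 2] + 2 * pad) * px_per_unit)
  if (as.numeric(W) * H > max_pixels)
    stop(sprintf("raster %d x %d exceeds max_pixels = %g", W, H, max_pixels))

  # pixel-center coordinates in tissue units
  px_x <- x0 + (seq_len(W) - 0.5) / px_per_unit
  px_y <- y0 + (seq_len(H) - 0.5) / px_per_unit

  labels <- matrix(0L, H, W)
  for (k in seq_along(mesh$cells)) {
    xy <- mesh$vertices[mesh$cells[[k]], , drop = FALSE]
    jr <- which(px_x >= min(xy[, 1]) - 1e-9 & px_x <= max(xy[, 1]) + 1e-9)
    ir <- which(px_y >= min(xy[, 2]) - 1e-9 & px_y <= max(xy[, 2]) + 1e-9)
    if (!length(jr) || !length(ir)) next
    gx <- rep(px_x[jr], each = length(ir))
    gy <- rep(px_y[ir], times = length(jr))
    inside <- points_in_polygon(gx, gy, xy)
    if (any(inside)) {
      sub <- labels[ir, jr, drop = FALSE]
      sub[matrix(inside, length(ir))] <- mesh$cell_ids[k]
      labels[ir, jr] <- sub
    }
  }

  # membrane: distance-to-skeleton field over all cell edges
  half_w <- membrane_width_px / 2
  sigma_m <- pmax(membrane_width_px / 2.355, 0.5)   # FWHM = membrane width
  reach <- (half_w + 3 * sigma_m) / px_per_unit
  mem <- matrix(0, H, W)
  edges <- unique_mesh_edges(mesh)
  for (r in seq_len(nrow(edges))) {
    p <- mesh$vertices[edges[r, 1], ]; q <- mesh$vertices[edges[r, 2], ]
    jr <- which(px_x >= min(p[1], q[1]) - reach & px_x <= max(p[1], q[1]) + reach)
    ir <- which(px_y >= min(p[2], q[2]) - reach & px_y <= max(p[2], q[2]) + reach)
    if (!length(jr) || !length(ir)) next
    gx <- rep(px_x[jr], each = length(ir))
    gy <- rep(px_y[ir], times = length(jr))
    d <- dist_point_segment(gx, gy, p, q) * px_per_unit
    contrib <- matrix(exp(-0.5 * (d / sigma_m)^2), length(ir))
    mem[ir, jr] <- pmax(mem[ir, jr], contrib)
    on_line <- matrix(d <= half_w, length(ir))
    if (any(on_line)) {
      sub <- labels[ir, jr, drop = FALSE]
      sub[on_line] <- 0L
      labels[ir, jr] <- sub
    }
  }

  img <- 0.1 + 0.9 * mem
  img <- gaussian_blur(img, blur_sigma_px)
  if (is.finite(snr)) {
    if (snr <= 0) stop("`snr` must be > 0")
    set.seed(seed)
    gain <- 2 * snr^2             # shot noise sd at the membrane: 1/(snr sqrt 2)
    img <- stats::rpois(length(img), lambda = pmax(img, 0) * gain) / gain +
      stats::rnorm(length(img), sd = 1 / (snr * sqrt(2)))
    img <- matrix(img, H, W)
  }
  list(image = img, labels = labels, px_per_unit = px_per_unit)
}

# All unique polygon edges of a mesh as a 2-column matrix of vertex ids.
unique_mesh_edges <- function(mesh) {
  v1 <- integer(0); v2 <- integer(0)
  for (vv in mesh$cells) {
    nx <- c(vv[-1], vv[1])
    v1 <- c(v1, pmin(vv, nx)); v2 <- c(v2, pmax(vv, nx))
  }
  unique(cbind(v1, v2))
}

# Distance from points (px, py) to segment p-q.
dist_point_segment <- function(px, py, p, q) {
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  l2 <- dx^2 + dy^2
  if (l2 == 0) return(sqrt((px - p[1])^2 + (py - p[2])^2))
  t <- pmin(1, pmax(0, ((px - p[1]) * dx + (py - p[2]) * dy) / l2))
  sqrt((px - (p[1] + t * dx))^2 + (py - (p[2] + t * dy))^2)
}

# Separable Gaussian blur with reflected boundaries (exactly symmetric, so
# ridge responses are rotation-equivariant under 90-degree rotations).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    padded <- m[c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * padded[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(m))))
}
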