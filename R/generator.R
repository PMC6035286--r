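# Synthetic epithelium generator: Voronoi tessellations of a perturbed
# hexagonal lattice, clipped to a rectangle. At disorder 0 every interior
# cell is a regular hexagon, so the triangulation elongation tensor is
# exactly zero -- the isotropic reference state of all closed-loop tests.

#' Generate a synthetic epithelial cell mesh
#'
#' Seeds a hexagonal point lattice (unit spacing), perturbs each site by a
#' uniform displacement in a disk of radius `disorder / 2`, and tessellates
#' with a Voronoi diagram clipped to the lattice rectangle (via
#' \code{deldir}). The shared vertex table is rebuilt from the tile corners
#' so that neighboring cells reference identical vertex ids, which gives the
#' tricellular-vertex incidence needed for triangulation and for topological
#' surgery (T1/T2/rosette planting).
#'
#' @param n_cells number of cells (>= 4).
#' @param disorder site perturbation as a fraction of half the lattice
#'   spacing, in `[0, 1]`. 0 gives a perfect honeycomb.
#' @param seed integer seed; output is fully reproducible.
#' @param frame_time optional frame time (hours APF).
#' @return a [new_cell_mesh()] object.
#' @export
make_cell_mesh <- function(n_cells, disorder = 0.3, seed = 1L, frame_time = NA_real_) {
  if (!is.numeric(n_cells) || n_cells < 4) stop("`n_cells` must be >= 4")
  n_cells <- as.integer(n_cells)
  if (disorder < 0 || disorder > 1) stop("`disorder` must be in [0, 1]")

  # Hexagonal lattice, unit spacing within rows, rows sqrt(3)/2 apart.
  # A one-site buffer ring surrounds the kept cells so every kept tile is a
  # complete Voronoi cell (regular hexagon at disorder 0), never clipped by
  # the enclosing rectangle.
  ny <- max(2L, as.integer(round(sqrt(n_cells / (sqrt(3) / 2)))))
  nx <- as.integer(ceiling(n_cells / ny))
  ij <- expand.grid(i = seq_len(nx + 2L), j = seq_len(ny + 2L))
  inner <- which(ij$i >= 2L & ij$i <= nx + 1L & ij$j >= 2L & ij$j <= ny + 1L)
  inner <- inner[seq_len(n_cells)]
  x <- ij$i - 1 + ifelse(ij$j %% 2 == 0, 0.5, 0)
  y <- (ij$j - 1) * sqrt(3) / 2

  if (disorder > 0) {
    np <- length(x)
    rng <- local({ set.seed(seed); list(r = sqrt(runif(np)), a = runif(np, 0, 2 * pi)) })
    rad <- 0.5 * disorder * rng$r
    x <- x + rad * cos(rng$a)
    y <- y + rad * sin(rng$a)
  }

  rw <- c(min(x) - 1, max(x) + 1, min(y) - 1, max(y) + 1)
  dd <- deldir::deldir(x, y, rw = rw, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)[inner]

  # Build the shared vertex table by exact-coordinate dedup (deldir computes
  # each Voronoi vertex once, so shared corners agree to rounding noise).
  allx <- unlist(lapply(tiles, `[[`, "x"), use.names = FALSE)
  ally <- unlist(lapply(tiles, `[[`, "y"), use.names = FALSE)
  key <- paste(round(allx, 6), round(ally, 6))
  uid <- match(key, unique(key))
  verts <- cbind(allx, ally)[!duplicated(key), , drop = FALSE]
  colnames(verts) <- c("x", "y")

  nv <- vapply(tiles, function(t) length(t$x), integer(1))
  cells <- split(uid, rep.int(seq_along(tiles), nv))
  names(cells) <- as.character(seq_along(tiles))

  new_cell_mesh(verts, cells, frame_time = frame_time)
}

#' Jitter mesh vertex positions
#'
#' Adds i.i.d. Gaussian noise to every vertex position (topology untouched).
#' Used to emulate imprecise outlines/centroids when stress-testing event
#' detection and morphometrics.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param sd_frac noise sd as a fraction of the mean cell diameter
#'   (diameter of the equal-area circle).
#' @param seed integer seed.
#' @return the jittered `cell_mesh`.
#' @export
jitter_mesh <- function(mesh, sd_frac = 0.02, seed = 1L) {
  if (is.null(mesh$cells)) stop("mesh carries no polygon outlines")
  diam <- 2 * sqrt(mean(mesh$areas) / pi)
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(mesh$vertices), sd = sd_frac * diam),
                  nrow(mesh$vertices), 2)
  new_cell_mesh(mesh$vertices + noise, mesh$cells, frame_time = mesh$frame_time)
}
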