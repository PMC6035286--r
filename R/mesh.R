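# The cell-mesh container: planar polygonal cells with a shared vertex table,
# neighbor adjacency, and tricellular-vertex incidence. All morphometric and
# kinematic operations run on this structure.

#' Construct a cell mesh
#'
#' A `cell_mesh` holds a planar epithelium: a shared table of vertex
#' positions, one polygon per cell given as a cyclic sequence of vertex ids
#' (counter-clockwise), and derived topology (cell adjacency, per-vertex cell
#' incidence, centroids and areas). Coordinates are in tissue units with
#' x along the proximal--distal (PD) axis and y along the anterior--posterior
#' (AP) axis.
#'
#' Meshes recovered from label images carry no polygon outlines; for those,
#' pass `cells = NULL` and supply `centroids`, `vertex_cells` and `adjacency`
#' explicitly. Polygon-dependent operations refuse such meshes with an
#' informative error.
#'
#' @param vertices numeric matrix (n x 2) of vertex positions.
#' @param cells named list (names = cell ids) of integer vectors indexing
#'   `vertices`, each an ordered counter-clockwise cycle; or `NULL` for
#'   outline-free meshes.
#' @param frame_time frame time in hours APF (or unitless); `NA` if untimed.
#' @param centroids,areas,adjacency,vertex_cells optional pre-computed
#'   topology; derived from `cells` when those are given.
#' @return an object of class `cell_mesh`.
#' @export
new_cell_mesh <- function(vertices, cells, frame_time = NA_real_,
                          centroids = NULL, areas = NULL,
                          adjacency = NULL, vertex_cells = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 2L) stop("`vertices` must be an n x 2 matrix")

  if (!is.null(cells)) {
    if (is.null(names(cells))) stop("`cells` must be a named list (names = cell ids)")
    ids <- as.integer(names(cells))
    cells <- lapply(cells, as.integer)

    # Orient every polygon counter-clockwise and cache centroid/area.
    n <- length(cells)
    centroids <- matrix(NA_real_, n, 2)
    areas <- numeric(n)
    for (k in seq_len(n)) {
      vv <- cells[[k]]
      xy <- vertices[vv, , drop = FALSE]
      a <- poly_signed_area(xy)
      if (a < 0) {
        vv <- rev(vv); cells[[k]] <- vv
        xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
        a <- -a
      }
      areas[k] <- a
      centroids[k, ] <- poly_centroid(xy)
    }

    # Edge table: unordered (vmin, vmax) per consecutive polygon pair.
    ecell <- integer(0); ekey <- character(0)
    for (k in seq_len(n)) {
      vv <- cells[[k]]
      v2 <- c(vv[-1], vv[1])
      ekey <- c(ekey, paste(pmin(vv, v2), pmax(vv, v2)))
      ecell <- c(ecell, rep.int(ids[k], length(vv)))
    }
    sp <- split(ecell, ekey)
    pairs <- sp[lengths(sp) == 2L]
    if (length(pairs)) {
      am <- t(vapply(pairs, function(p) c(min(p), max(p)), integer(2)))
      adjacency <- unique(am)
      dimnames(adjacency) <- NULL
    } else {
      adjacency <- matrix(integer(0), 0, 2)
    }

    # Per-vertex incident cells.
    vidx <- unlist(cells, use.names = FALSE)
    cid <- rep.int(ids, lengths(cells))
    vertex_cells <- vector("list", nrow(vertices))
    sp2 <- split(cid, vidx)
    vertex_cells[as.integer(names(sp2))] <- lapply(sp2, function(z) sort(unique(z)))
    empty <- vapply(vertex_cells, is.null, logical(1))
    vertex_cells[empty] <- list(integer(0))
  } else {
    if (is.null(centroids) || is.null(vertex_cells))
      stop("outline-free meshes need `centroids` and `vertex_cells`")
    ids <- as.integer(rownames(centroids))
    if (anyNA(ids)) stop("`centroids` must have cell ids as rownames")
    if (is.null(adjacency)) adjacency <- matrix(integer(0), 0, 2)
    if (is.null(areas)) areas <- rep(NA_real_, length(ids))
  }

  structure(list(
    vertices = vertices,
    cells = cells,
    cell_ids = ids,
    centroids = centroids,
    areas = areas,
    adjacency = adjacency,
    vertex_cells = vertex_cells,
    frame_time = frame_time
  ), class = "cell_mesh")
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh> %d cells, %d vertices, %d adjacencies%s%s\n",
              length(x$cell_ids), nrow(x$vertices), nrow(x$adjacency),
              if (is.null(x$cells)) " (no polygon outlines)" else "",
              if (is.finite(x$frame_time)) sprintf(", t = %g h", x$frame_time) else ""))
  invisible(x)
}

#' Number of cells in a mesh
#' @param mesh a `cell_mesh`.
#' @return integer count.
#' @export
n_cells <- function(mesh) length(mesh$cell_ids)

#' Polygon coordinates of one cell
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param cell_id cell id.
#' @return matrix of polygon vertex coordinates (counter-clockwise).
#' @export
cell_polygon <- function(mesh, cell_id) {
  if (is.null(mesh$cells)) stop("mesh carries no polygon outlines")
  k <- match(as.integer(cell_id), mesh$cell_ids)
  if (is.na(k)) stop("unknown cell id: ", cell_id)
  mesh$vertices[mesh$cells[[k]], , drop = FALSE]
}

#' Validate mesh invariants
#'
#' Checks that adjacency is symmetric-by-representation (stored as unordered
#' pairs) and irreflexive, that adjacent cells share at least one vertex, that
#' polygons are simple with positive area, and that total cell area does not
#' exceed the bounding-box area.
#'
#' @param mesh a `cell_mesh`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_cell_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "cell_mesh"))
  adj <- mesh$adjacency
  if (nrow(adj) && any(adj[, 1] == adj[, 2])) stop("adjacency is not irreflexive")
  if (!is.null(mesh$cells)) {
    if (any(mesh$areas <= 0)) stop("non-positive cell area")
    for (k in seq_along(mesh$cells)) {
      xy <- mesh$vertices[mesh$cells[[k]], , drop = FALSE]
      if (!poly_is_simple(xy))
        stop("self-intersecting polygon for cell ", mesh$cell_ids[k])
    }
    if (nrow(adj)) {
      for (r in seq_len(nrow(adj))) {
        a <- mesh$cells[[match(adj[r, 1], mesh$cell_ids)]]
        b <- mesh$cells[[match(adj[r, 2], mesh$cell_ids)]]
        if (!length(intersect(a, b)))
          stop("adjacent pair shares no vertex: ", adj[r, 1], "-", adj[r, 2])
      }
    }
    bb <- apply(mesh$vertices, 2, range)
    bbox_area <- prod(bb[2, ] - bb[1, ])
    if (sum(mesh$areas) > bbox_area * (1 + 1e-9))
      stop("total cell area exceeds bounding box")
  }
  invisible(TRUE)
}

#' Apply an area-preserving pure shear to a mesh
#'
#' Maps every coordinate (x, y) to (x e^s, y e^-s). This is the deformation
#' mode of convergent extension along the PD axis: a natural (Hencky) strain
#' of +s along x and -s along y, with the tissue area exactly preserved
#' (the map has unit determinant). Topology is unchanged.
#'
#' @param mesh a `cell_mesh`.
#' @param s natural-strain amount (dimensionless).
#' @return the sheared `cell_mesh`.
#' @export
apply_pure_shear <- function(mesh, s) {
  check_scalar(s, "s")
  transform_mesh(mesh, diag(c(exp(s), exp(-s))))
}

#' Apply a linear map to all mesh coordinates
#'
#' @param mesh a `cell_mesh`.
#' @param A 2 x 2 matrix with positive determinant.
#' @return the transformed `cell_mesh`.
#' @export
transform_mesh <- function(mesh, A) {
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(2L, 2L)))
  if (det(A) <= 0) stop("`A` must have positive determinant")
  m <- mesh
  m$vertices <- mesh$vertices %*% t(A)
  m$centroids <- mesh$centroids %*% t(A)
  m$areas <- mesh$areas * det(A)
  m
}

#' Rotate a mesh about the origin
#' @param mesh a `cell_mesh`.
#' @param theta rotation angle in radians (counter-clockwise).
#' @return the rotated `cell_mesh`.
#' @export
rotate_mesh <- function(mesh, theta) {
  check_scalar(theta, "theta")
  transform_mesh(mesh, matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2))
}

#' Cell-cell junction table
#'
#' One row per shared edge between two adjacent cells: the two cell ids, the
#' two endpoint vertex ids, the junction length, and its acute angle to the
#' PD (x) axis in degrees.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @return data.frame with columns `cell_a`, `cell_b`, `v1`, `v2`,
#'   `length`, `angle_deg`.
#' @export
mesh_junctions <- function(mesh) {
  if (is.null(mesh$cells)) stop("mesh carries no polygon outlines")
  ids <- mesh$cell_ids
  ekey <- character(0); ecell <- integer(0); ev1 <- integer(0); ev2 <- integer(0)
  for (k in seq_along(mesh$cells)) {
    vv <- mesh$cells[[k]]
    v2 <- c(vv[-1], vv[1])
    ekey <- c(ekey, paste(pmin(vv, v2), pmax(vv, v2)))
    ecell <- c(ecell, rep.int(ids[k], length(vv)))
    ev1 <- c(ev1, pmin(vv, v2)); ev2 <- c(ev2, pmax(vv, v2))
  }
  ord <- order(ekey)
  ekey <- ekey[ord]; ecell <- ecell[ord]; ev1 <- ev1[ord]; ev2 <- ev2[ord]
  dup <- duplicated(ekey)
  shared <- ekey %in% ekey[dup]
  ekey_s <- ekey[shared]; ecell_s <- ecell[shared]; ev1_s <- ev1[shared]; ev2_s <- ev2[shared]
  idx1 <- which(!duplicated(ekey_s))
  idx2 <- idx1 + 1L
  v1 <- ev1_s[idx1]; v2 <- ev2_s[idx1]
  d <- mesh$vertices[v2, , drop = FALSE] - mesh$vertices[v1, , drop = FALSE]
  data.frame(
    cell_a = pmin(ecell_s[idx1], ecell_s[idx2]),
    cell_b = pmax(ecell_s[idx1], ecell_s[idx2]),
    v1 = v1, v2 = v2,
    length = sqrt(rowSums(d^2)),
    angle_deg = axis_angle(d[, 1], d[, 2]) * 180 / pi
  )
}

# Vertex ids lying on the mesh bounding box (hull of a clipped tessellation).
boundary_vertices <- function(mesh, eps = 1e-9) {
  v <- mesh$vertices
  bb <- apply(v, 2, range)
  which(v[, 1] < bb[1, 1] + eps | v[, 1] > bb[2, 1] - eps |
        v[, 2] < bb[1, 2] + eps | v[, 2] > bb[2, 2] - eps)
}

# Cells having at least one vertex on the bounding box.
boundary_cells <- function(mesh) {
  bv <- boundary_vertices(mesh)
  sort(unique(unlist(mesh$vertex_cells[bv], use.names = FALSE)))
}

# Adjacency as a fast lookup key vector "a:b" with a < b.
adjacency_keys <- function(mesh) {
  adj <- mesh$adjacency
  if (!nrow(adj)) return(character(0))
  paste(adj[, 1], adj[, 2], sep = ":")
}
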