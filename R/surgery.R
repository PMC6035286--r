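# Topological surgery on cell meshes: planted T1 neighbor exchanges, T2
# extrusions and rosette formation. These are the ground-truth events that
# the kinematics module must recover, so each operation performs minimal,
# bounded-geometry edits and leaves the rest of the mesh untouched.

# Drop vertices referenced by no cell and re-index.
compact_mesh <- function(mesh) {
  used <- sort(unique(unlist(mesh$cells, use.names = FALSE)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  cells <- lapply(mesh$cells, function(vv) remap[vv])
  names(cells) <- names(mesh$cells)
  new_cell_mesh(mesh$vertices[used, , drop = FALSE], cells,
                frame_time = mesh$frame_time)
}

# Interior T1 candidate edges: both endpoints tricellular, distinct third
# cells, quartet away from the hull, and the two edge cells keep >= 4
# vertices after losing one.
t1_candidate_edges <- function(mesh, exclude_cells = integer(0)) {
  jn <- mesh_junctions(mesh)
  deg <- lengths(mesh$vertex_cells)
  bc <- boundary_cells(mesh)
  keep <- logical(nrow(jn))
  third <- matrix(NA_integer_, nrow(jn), 2)
  for (r in seq_len(nrow(jn))) {
    v1 <- jn$v1[r]; v2 <- jn$v2[r]
    if (deg[v1] != 3L || deg[v2] != 3L) next
    ab <- c(jn$cell_a[r], jn$cell_b[r])
    c3 <- setdiff(mesh$vertex_cells[[v1]], ab)
    d3 <- setdiff(mesh$vertex_cells[[v2]], ab)
    if (length(c3) != 1L || length(d3) != 1L || c3 == d3) next
    quartet <- c(ab, c3, d3)
    if (any(quartet %in% bc) || any(quartet %in% exclude_cells)) next
    na <- length(mesh$cells[[match(ab[1], mesh$cell_ids)]])
    nb <- length(mesh$cells[[match(ab[2], mesh$cell_ids)]])
    if (na < 4L || nb < 4L) next
    keep[r] <- TRUE
    third[r, ] <- c(c3, d3)
  }
  cbind(jn[keep, c("cell_a", "cell_b", "v1", "v2", "length", "angle_deg")],
        cell_c = third[keep, 1], cell_d = third[keep, 2])
}

#' Perform a T1 neighbor exchange
#'
#' Collapses the junction between two cells (a, b) to its midpoint and
#' reopens it, at the pre-collapse edge length, between the other two cells
#' of the quartet (c, d): the pair (a, b) loses adjacency and (c, d) gains
#' it. Both endpoints must be tricellular vertices. Geometry is edited only
#' at the two vertices involved.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param v1,v2 vertex ids of the junction to exchange.
#' @return the modified `cell_mesh`, with attribute `quartet`
#'   (ids a, b, c, d).
#' @export
plant_t1 <- function(mesh, v1, v2) {
  ab <- intersect(mesh$vertex_cells[[v1]], mesh$vertex_cells[[v2]])
  if (length(ab) != 2L) stop("vertices do not bound a shared junction")
  cc <- setdiff(mesh$vertex_cells[[v1]], ab)
  dd <- setdiff(mesh$vertex_cells[[v2]], ab)
  if (length(cc) != 1L || length(dd) != 1L || cc == dd)
    stop("junction is not an interior quartet edge")
  p1 <- mesh$vertices[v1, ]; p2 <- mesh$vertices[v2, ]
  mid <- (p1 + p2) / 2
  len <- sqrt(sum((p2 - p1)^2))
  u <- (p2 - p1) / len
  nrm <- c(-u[2], u[1])

  ia <- match(ab[1], mesh$cell_ids); ib <- match(ab[2], mesh$cell_ids)
  # put the new vertex for cell a on a's side of the old edge
  sa <- sign(sum((mesh$centroids[ia, ] - mid) * nrm))
  if (sa == 0) sa <- 1
  wa_pos <- mid + (len / 2) * nrm * sa
  wb_pos <- mid - (len / 2) * nrm * sa

  verts <- rbind(mesh$vertices, wa_pos, wb_pos)
  wa <- nrow(verts) - 1L; wb <- nrow(verts)
  cells <- mesh$cells

  replace_pair <- function(vv, with) {
    out <- integer(0)
    placed <- FALSE
    for (v in vv) {
      if (v %in% c(v1, v2)) {
        if (!placed) { out <- c(out, with); placed <- TRUE }
      } else out <- c(out, v)
    }
    out
  }
  cells[[ia]] <- replace_pair(cells[[ia]], wa)
  cells[[ib]] <- replace_pair(cells[[ib]], wb)

  insert_pair <- function(vv, at, first, second, verts) {
    i <- match(at, vv)
    prev <- vv[if (i == 1) length(vv) else i - 1L]
    nxt <- vv[if (i == length(vv)) 1L else i + 1L]
    d1 <- sum((verts[prev, ] - verts[first, ])^2) + sum((verts[second, ] - verts[nxt, ])^2)
    d2 <- sum((verts[prev, ] - verts[second, ])^2) + sum((verts[first, ] - verts[nxt, ])^2)
    ins <- if (d1 <= d2) c(first, second) else c(second, first)
    append(vv[-i], ins, after = i - 1L)
  }
  ic <- match(cc, mesh$cell_ids); id <- match(dd, mesh$cell_ids)
  cells[[ic]] <- insert_pair(cells[[ic]], v1, wa, wb, verts)
  cells[[id]] <- insert_pair(cells[[id]], v2, wa, wb, verts)

  # orphaned old vertices are kept so vertex ids stay stable across frames
  out <- new_cell_mesh(verts, cells, frame_time = mesh$frame_time)
  attr(out, "quartet") <- c(ab, cc, dd)
  out
}

#' Shrink a cell toward its centroid
#'
#' Moves the cell's vertices toward its centroid by `factor`; shared vertices
#' drag the neighboring polygons along, so neighbors expand into the vacated
#' space. Used to give planted T2 events a shrinking-area history.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param cell_id cell to shrink.
#' @param factor scale factor in (0, 1).
#' @return the modified `cell_mesh`.
#' @export
shrink_cell <- function(mesh, cell_id, factor = 0.55) {
  if (factor <= 0 || factor >= 1) stop("`factor` must be in (0, 1)")
  k <- match(as.integer(cell_id), mesh$cell_ids)
  if (is.na(k)) stop("unknown cell id: ", cell_id)
  ctr <- mesh$centroids[k, ]
  vv <- mesh$cells[[k]]
  verts <- mesh$vertices
  verts[vv, ] <- sweep(sweep(verts[vv, , drop = FALSE], 2, ctr) * factor, 2, ctr, `+`)
  new_cell_mesh(verts, mesh$cells, frame_time = mesh$frame_time)
}

#' Remove a cell (T2 extrusion)
#'
#' Deletes the cell from the mesh. Neighboring polygons are untouched, so a
#' micro-hole remains at the extrusion site; its former vertices become
#' bicellular and are therefore skipped by the triangulation.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param cell_id cell to extrude.
#' @return the modified `cell_mesh`.
#' @export
plant_t2 <- function(mesh, cell_id) {
  k <- match(as.integer(cell_id), mesh$cell_ids)
  if (is.na(k)) stop("unknown cell id: ", cell_id)
  new_cell_mesh(mesh$vertices, mesh$cells[-k], frame_time = mesh$frame_time)
}

#' Form a rosette at a vertex
#'
#' Collapses two junctions incident to a tricellular vertex, merging the
#' vertex with two of its neighboring vertices into a single point where
#' five or more cells meet.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param v a tricellular vertex id.
#' @return the modified `cell_mesh`, with attribute `rosette_cells`.
#' @export
plant_rosette <- function(mesh, v) {
  nb <- vertex_neighbors(mesh, v)
  deg <- lengths(mesh$vertex_cells)
  nb <- nb[deg[nb] >= 3L]
  if (length(nb) < 2L) stop("vertex has too few tricellular neighbors")
  nb <- nb[1:2]
  grp <- c(v, nb)
  pos <- colMeans(mesh$vertices[grp, , drop = FALSE])
  verts <- rbind(mesh$vertices, pos)
  nid <- nrow(verts)
  cells <- lapply(mesh$cells, function(vv) {
    vv[vv %in% grp] <- nid
    # collapse runs of the merged id (cyclically)
    vv <- vv[!(vv == nid & c(FALSE, vv[-length(vv)] == nid))]
    if (length(vv) > 1 && vv[1] == nid && vv[length(vv)] == nid)
      vv <- vv[-length(vv)]
    vv
  })
  names(cells) <- names(mesh$cells)
  if (any(lengths(cells) < 3L)) stop("rosette collapse would degenerate a cell")
  out <- new_cell_mesh(verts, cells, frame_time = mesh$frame_time)
  attr(out, "rosette_cells") <- sort(unique(unlist(
    mesh$vertex_cells[grp], use.names = FALSE)))
  out
}

# Vertex ids connected to v by a cell edge.
vertex_neighbors <- function(mesh, v) {
  out <- integer(0)
  for (cid in mesh$vertex_cells[[v]]) {
    vv <- mesh$cells[[match(cid, mesh$cell_ids)]]
    i <- match(v, vv)
    out <- c(out, vv[if (i == 1) length(vv) else i - 1L],
             vv[if (i == length(vv)) 1L else i + 1L])
  }
  sort(unique(out))
}
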