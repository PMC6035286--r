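# Bridge from label rasters (segmentation output) back to the mesh world:
# centroids, adjacency across thin membrane lines, and tricellular vertices.

#' Build a cell mesh from a label map
#'
#' Recovers the cell-center network from an integer label raster: per-label
#' pixel centroids, adjacency between labels separated by at most ~2 px of
#' membrane, and tricellular vertices where three or more labels meet. The
#' result carries no polygon outlines but supports triangulation and all
#' elongation measurements.
#'
#' Adjacency and vertices use a voting scheme over membrane (0) pixels: each
#' membrane pixel looks at the distinct labels within Chebyshev radius
#' `radius`; pixels seeing exactly two labels vote for that pair (adjacency
#' requires >= `min_votes` votes, which suppresses spurious contacts at
#' vertices), pixels seeing three or more mark a vertex; vertex pixels are
#' clustered into connected components.
#'
#' @param labels integer label matrix (0 = membrane/background).
#' @param pixel_size physical size of one pixel (tissue units / px).
#' @param radius membrane search radius in pixels.
#' @param min_votes minimal pixel votes for an adjacency.
#' @return a `cell_mesh` without polygon outlines (x = column, y = row,
#'   scaled by `pixel_size`).
#' @export
mesh_from_labels <- function(labels, pixel_size = 1, radius = 2L, min_votes = 2L) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) < 3) stop("need >= 3 positive labels")
  H <- nrow(labels); W <- ncol(labels)

  pos <- which(labels > 0)
  rr <- (pos - 1) %% H + 1; cc <- (pos - 1) %/% H + 1
  lv <- labels[pos]
  cx <- tapply(cc, lv, mean) - 0.5
  cy <- tapply(rr, lv, mean) - 0.5
  centroids <- cbind(as.numeric(cx), as.numeric(cy)) * pixel_size
  rownames(centroids) <- names(cx)

  # window stack over membrane pixels
  mem <- which(labels == 0L)
  mr <- (mem - 1) %% H + 1; mc <- (mem - 1) %/% H + 1
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  stack <- matrix(0L, length(mem), nrow(offs))
  for (k in seq_len(nrow(offs))) {
    r2 <- mr + offs$dr[k]; c2 <- mc + offs$dc[k]
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    v <- integer(length(mem))
    v[ok] <- labels[cbind(r2[ok], c2[ok])]
    stack[, k] <- v
  }
  n_distinct <- integer(length(mem))
  pair_key <- character(length(mem))
  seen <- vector("list", length(mem))
  for (i in seq_len(length(mem))) {
    u <- unique(stack[i, ]); u <- u[u > 0]
    n_distinct[i] <- length(u)
    if (length(u) == 2L) {
      u <- sort(u); pair_key[i] <- paste(u[1], u[2], sep = ":")
    } else if (length(u) >= 3L) {
      seen[[i]] <- sort(u)
    }
  }

  votes <- table(pair_key[pair_key != ""])
  keep <- names(votes)[votes >= min_votes]
  adj <- if (length(keep)) {
    t(vapply(strsplit(keep, ":", fixed = TRUE),
             function(p) as.integer(p), integer(2)))
  } else matrix(integer(0), 0, 2)

  # vertex pixels -> connected components
  vmask <- matrix(FALSE, H, W)
  vidx <- mem[n_distinct >= 3L]
  vmask[vidx] <- TRUE
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(vmask * 1)))
  comp_ids <- sort(unique(comp[comp > 0]))
  verts <- matrix(NA_real_, length(comp_ids), 2)
  vcl <- vector("list", length(comp_ids))
  lab_by_pix <- seen[n_distinct >= 3L]
  comp_of_pix <- comp[vidx]
  for (j in seq_along(comp_ids)) {
    sel <- comp_of_pix == comp_ids[j]
    pix <- vidx[sel]
    pr <- (pix - 1) %% H + 1; pc <- (pix - 1) %/% H + 1
    verts[j, ] <- c(mean(pc) - 0.5, mean(pr) - 0.5) * pixel_size
    vcl[[j]] <- sort(unique(unlist(lab_by_pix[sel], use.names = FALSE)))
  }

  # adjacency must connect cells sharing a vertex too (votes cover edges);
  # keep as voted -- vertices are informational for triangulation
  new_cell_mesh(verts, cells = NULL, centroids = centroids,
                adjacency = adj, vertex_cells = vcl)
}
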