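# Time-resolved analysis: natural strain series, shear rates, the
# rearrangement shear Rxx as the residual between tissue shear and
# cell-shape change, and discrete T1/T2/rosette event detection on
# tracked mesh series.

#' Elongation time series
#'
#' Container for the two curves the continuum model is fitted to: mean cell
#' elongation `Qxx(t)` and tissue elongation `(L-H)(t)`.
#'
#' @param time times in hours APF, strictly increasing.
#' @param Qxx mean cell elongation per time point.
#' @param LmH tissue natural-strain difference L - H per time point.
#' @param sd_Qxx,sd_LmH optional per-point standard deviations.
#' @param provenance `"measured"` or `"synthetic"`.
#' @return data.frame of class `elongation_series`.
#' @export
elongation_series <- function(time, Qxx, LmH, sd_Qxx = NULL, sd_LmH = NULL,
                              provenance = c("measured", "synthetic")) {
  provenance <- match.arg(provenance)
  if (length(time) != length(Qxx) || length(time) != length(LmH))
    stop("`time`, `Qxx` and `LmH` must have equal length")
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  df <- data.frame(time = time, Qxx = Qxx, LmH = LmH)
  if (!is.null(sd_Qxx)) df$sd_Qxx <- sd_Qxx
  if (!is.null(sd_LmH)) df$sd_LmH <- sd_LmH
  structure(df, class = c("elongation_series", "data.frame"),
            provenance = provenance)
}

# First derivative on a (possibly non-uniform) grid: central differences at
# interior points, second-order one-sided stencils at the ends.
fd_derivative <- function(y, t) {
  n <- length(y)
  if (n < 3) stop("need >= 3 points for differentiation")
  d <- numeric(n)
  for (i in 2:(n - 1)) {
    h1 <- t[i] - t[i - 1]; h2 <- t[i + 1] - t[i]
    d[i] <- (h1^2 * y[i + 1] - h2^2 * y[i - 1] - (h1^2 - h2^2) * y[i]) /
      (h1 * h2 * (h1 + h2))
  }
  h1 <- t[2] - t[1]; h2 <- t[3] - t[2]
  d[1] <- (-(2 * h1 + h2) / (h1 * (h1 + h2))) * y[1] +
    ((h1 + h2) / (h1 * h2)) * y[2] - (h1 / (h2 * (h1 + h2))) * y[3]
  h1 <- t[n - 1] - t[n - 2]; h2 <- t[n] - t[n - 1]
  d[n] <- (h2 / (h1 * (h1 + h2))) * y[n - 2] -
    ((h1 + h2) / (h1 * h2)) * y[n - 1] +
    ((h1 + 2 * h2) / (h2 * (h1 + h2))) * y[n]
  d
}

#' Natural strain series from tissue shapes
#'
#' Per-frame natural strains relative to the first frame:
#' `L = log(l/l0)`, `H = log(h/h0)` with `l0`, `h0` from frame 0.
#'
#' @param shapes list of [tissue_shape()] objects (or a data.frame with
#'   columns `l`, `h`), time-ordered.
#' @param time optional times (hours APF).
#' @return data.frame with columns `time`, `L`, `H`, `LmH`.
#' @export
natural_strain_series <- function(shapes, time = NULL) {
  if (is.data.frame(shapes)) {
    l <- shapes$l; h <- shapes$h
  } else {
    l <- vapply(shapes, `[[`, numeric(1), "l")
    h <- vapply(shapes, `[[`, numeric(1), "h")
  }
  if (length(l) < 2) stop("need >= 2 frames")
  if (any(l <= 0) || any(h <= 0)) stop("tissue dimensions must be positive")
  if (is.null(time)) time <- seq_along(l) - 1
  L <- log(l / l[1]); H <- log(h / h[1])
  data.frame(time = time, L = L, H = H, LmH = L - H)
}

#' Tissue shear rate from tissue elongation
#'
#' The anisotropic part of the tissue velocity gradient,
#' `vxx = 1/2 d(L-H)/dt`, by finite differences (central at interior points,
#' second-order one-sided at the ends).
#'
#' @param LmH tissue elongation series L - H.
#' @param time times (hours APF), >= 3 points.
#' @return numeric vector vxx(t) in 1/h.
#' @export
shear_rate <- function(LmH, time) {
  0.5 * fd_derivative(LmH, time)
}

#' Rearrangement shear Rxx(t)
#'
#' The contribution of cellular rearrangements to tissue shear, measured as
#' the residual between tissue shear rate and the rate of mean cell-shape
#' change: `Rxx = 1/2 d(L-H)/dt - dQxx/dt`. Both derivatives use the same
#' finite-difference operator, so the discrete decomposition identity
#' `vxx = dQxx/dt + Rxx` holds exactly at every time point by construction.
#'
#' @param series an [elongation_series()] with >= 3 timepoints.
#' @return data.frame with columns `time`, `vxx`, `dQxx_dt`, `Rxx` (1/h).
#' @export
rearrangement_shear <- function(series) {
  tt <- series$time
  if (length(tt) < 3) stop("need >= 3 timepoints")
  vxx <- shear_rate(series$LmH, tt)
  dq <- fd_derivative(series$Qxx, tt)
  data.frame(time = tt, vxx = vxx, dQxx_dt = dq, Rxx = vxx - dq)
}

#' Detect T1, T2 and rosette events on a tracked mesh series
#'
#' Operates purely on tracked topology between consecutive frames:
#' \itemize{
#'   \item T2 (extrusion): a cell id present in frame k and absent in k+1,
#'     with its area having decreased over the preceding frames (guards
#'     against tracking loss misread as extrusion; with fewer than two
#'     preceding observations the disappearance alone counts).
#'   \item T1 (neighbor exchange): an adjacency pair (a, b) lost between
#'     frames k and k+1 while the complementary pair of the quartet -- two
#'     common neighbors (c, d) of a and b in frame k -- becomes adjacent in
#'     k+1. Pairs involving cells that disappeared are excluded.
#'   \item Rosette: a vertex with >= 5 incident cells (4-fold vertices are
#'     transient T1 intermediates), counted when no vertex with >= 3 shared
#'     incident cells was already a rosette in the previous frame.
#' }
#'
#' @param series a `mesh_series` (see [simulate_tissue_series()] /
#'   [simulate_event_series()]) with persistent cell ids.
#' @param rosette_order minimal number of cells at a vertex to call a
#'   rosette (default 5).
#' @param t2_shrink maximal area ratio (last/first over the preceding
#'   window) for a disappearance to count as T2 (default 0.9).
#' @return object of class `event_counts`: list with `n_T1`, `n_T2`,
#'   `n_rosette`, `cells_involved`, `total_cells`, and `events`
#'   (data.frame: `time`, `kind`, `cells` as comma-joined ids).
#' @export
detect_events <- function(series, rosette_order = 5L, t2_shrink = 0.9) {
  if (!inherits(series, "mesh_series"))
    stop("`series` must be a tracked mesh_series")
  frames <- series$frames
  if (length(frames) < 2) stop("need >= 2 frames")
  ids_per <- lapply(frames, `[[`, "cell_ids")
  common <- Reduce(union, ids_per)
  ev_time <- numeric(0); ev_kind <- character(0); ev_cells <- character(0)

  rosette_sets_prev <- list()
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    deg <- lengths(fr$vertex_cells)
    rs <- fr$vertex_cells[deg >= rosette_order]
    if (k > 1) {
      for (s in rs) {
        seen <- any(vapply(rosette_sets_prev,
                           function(p) length(intersect(p, s)) >= 3L, logical(1)))
        if (!seen) {
          ev_time <- c(ev_time, frame_time_or(fr, k))
          ev_kind <- c(ev_kind, "rosette")
          ev_cells <- c(ev_cells, paste(sort(s), collapse = ","))
        }
      }
    }
    rosette_sets_prev <- rs
  }

  for (k in seq_len(length(frames) - 1L)) {
    a <- frames[[k]]; b <- frames[[k + 1L]]
    tb <- frame_time_or(b, k + 1L)
    gone <- setdiff(a$cell_ids, b$cell_ids)

    # T2: disappearance with shrinking-area history
    for (g in gone) {
      hist_area <- vapply(frames[seq_len(k)], function(f) {
        i <- match(g, f$cell_ids)
        if (is.na(i)) NA_real_ else f$areas[i]
      }, numeric(1))
      hist_area <- hist_area[is.finite(hist_area)]
      shrank <- length(hist_area) < 2 ||
        hist_area[length(hist_area)] <= t2_shrink * hist_area[1]
      if (shrank) {
        ev_time <- c(ev_time, tb); ev_kind <- c(ev_kind, "T2")
        ev_cells <- c(ev_cells, as.character(g))
      }
    }

    keys_a <- adjacency_keys(a); keys_b <- adjacency_keys(b)
    lost <- setdiff(keys_a, keys_b)
    gained <- setdiff(keys_b, keys_a)
    if (length(gone)) {
      drop_key <- function(keys) {
        sp <- strsplit(keys, ":", fixed = TRUE)
        bad <- vapply(sp, function(p) any(as.integer(p) %in% gone), logical(1))
        keys[!bad]
      }
      lost <- drop_key(lost); gained <- drop_key(gained)
    }
    if (length(lost) && length(gained)) {
      adj_a <- a$adjacency
      neigh <- function(id) c(adj_a[adj_a[, 1] == id, 2], adj_a[adj_a[, 2] == id, 1])
      for (lk in lost) {
        p <- as.integer(strsplit(lk, ":", fixed = TRUE)[[1]])
        cm <- intersect(neigh(p[1]), neigh(p[2]))
        if (length(cm) < 2) next
        comb <- utils::combn(sort(cm), 2)
        for (j in seq_len(ncol(comb))) {
          gk <- paste(comb[1, j], comb[2, j], sep = ":")
          if (gk %in% gained) {
            ev_time <- c(ev_time, tb); ev_kind <- c(ev_kind, "T1")
            ev_cells <- c(ev_cells,
                          paste(sort(c(p, comb[, j])), collapse = ","))
            break
          }
        }
      }
    }
  }

  events <- data.frame(time = ev_time, kind = ev_kind, cells = ev_cells,
                       stringsAsFactors = FALSE)
  involved <- unique(unlist(strsplit(events$cells, ",", fixed = TRUE)))
  structure(list(
    n_T1 = sum(events$kind == "T1"),
    n_T2 = sum(events$kind == "T2"),
    n_rosette = sum(events$kind == "rosette"),
    cells_involved = length(involved),
    total_cells = length(common),
    events = events
  ), class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf("<event_counts> T1: %d, T2: %d, rosettes: %d (%d of %d cells involved)\n",
              x$n_T1, x$n_T2, x$n_rosette, x$cells_involved, x$total_cells))
  invisible(x)
}

frame_time_or <- function(frame, k) {
  if (is.finite(frame$frame_time)) frame$frame_time else as.numeric(k)
}

#' Measure an elongation series from a tracked mesh series
#'
#' Per frame: triangulates the mesh and averages the per-triangle elongation
#' tensors to get `Qxx`; measures tissue extents and forms the natural
#' strains relative to the first frame to get `L - H`.
#'
#' @param series a `mesh_series`.
#' @param weighting triangle averaging mode passed to [mean_elongation()].
#' @return an [elongation_series()] with provenance `"measured"`.
#' @export
measure_series <- function(series, weighting = "uniform") {
  frames <- series$frames
  qs <- vapply(frames, function(f) mean_elongation(triangulate(f), weighting)[1],
               numeric(1))
  shp <- lapply(frames, tissue_shape)
  ns <- natural_strain_series(shp, time = series$times)
  elongation_series(series$times, qs, ns$LmH, provenance = "measured")
}
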