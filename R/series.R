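# Tracked mesh time series with ground truth: kinematically imposed tissue
# shear plus planted rearrangement events. The generator decides how much
# shear comes from cell-shape change vs rearrangements and records it, so
# the kinematics module can be validated closed-loop.

new_mesh_series <- function(frames, times, ground_truth) {
  structure(list(frames = frames, times = times, ground_truth = ground_truth),
            class = "mesh_series")
}

#' @export
print.mesh_series <- function(x, ...) {
  cat(sprintf("<mesh_series> %d frames, t = %g..%g, %d ground-truth events\n",
              length(x$frames), min(x$times), max(x$times),
              nrow(x$ground_truth$events)))
  invisible(x)
}

# Mean Qxx of a mesh via the triangulation.
measure_mean_qxx <- function(mesh) mean_elongation(triangulate(mesh))[[1]]

#' Simulate a tissue undergoing convergent extension
#'
#' Produces a tracked mesh series whose measured kinematics follow the
#' continuum model: per frame interval the generator (i) applies an affine
#' pure shear so the tissue elongation (L-H) tracks the model prediction and
#' (ii) plants T1 neighbor exchanges until the measured mean cell elongation
#' returns to the model's Qxx(t), so that the cumulative shear carried by
#' rearrangements approximates `Rxx = lambda qxx`. Shear targets are
#' absolute, so T1 quantization errors do not accumulate. All planted shear
#' and events are recorded in `ground_truth`.
#'
#' @param sched a [myosin_schedule()].
#' @param params a [model_params()].
#' @param Qxx0 initial mean cell elongation (the mesh is pre-sheared to it).
#' @param dt frame interval in hours (> 0).
#' @param t_end final time (must exceed `sched$t0`).
#' @param n_cells,disorder passed to [make_cell_mesh()].
#' @param seed integer seed.
#' @return a `mesh_series`: `frames` (list of `cell_mesh`), `times`, and
#'   `ground_truth` with per-interval applied shear `sxx`, planted
#'   rearrangement shear `rxx_planted`, the event table, and the model paths.
#' @export
simulate_tissue_series <- function(sched, params, Qxx0 = 0, dt = 0.25,
                                   t_end = 7, n_cells = 400, disorder = 0.3,
                                   seed = 1L) {
  stopifnot(inherits(sched, "myosin_schedule"), inherits(params, "ce_params"))
  if (dt <= 0) stop("`dt` must be > 0")
  if (t_end <= sched$t0) stop("`t_end` must exceed the schedule t0")
  times <- seq(sched$t0, t_end, by = dt)
  qm <- solve_Qxx_closed(params, Qxx0, sched, times)
  if (any(abs(qm) > 1))
    stop("parameters drive |Qxx| > 1; the triangulation would degenerate")
  lm <- predict_LmH(params, sched, times, Qxx0 = Qxx0)

  mesh <- make_cell_mesh(n_cells, disorder, seed, frame_time = times[1])
  # pre-shear the (statistically isotropic) mesh onto Qxx0
  for (it in 1:3) {
    q <- measure_mean_qxx(mesh)
    if (abs(q - Qxx0) < 1e-6) break
    mesh <- apply_pure_shear(mesh, Qxx0 - q)
  }

  set.seed(seed + 1L)
  frames <- vector("list", length(times))
  frames[[1]] <- mesh
  sxx <- numeric(length(times) - 1L)
  ev_time <- numeric(0); ev_kind <- character(0); ev_cells <- character(0)
  cq <- cumulative_qxx(times, sched)

  for (k in 2:length(times)) {
    ds <- (lm[k] - lm[k - 1]) / 2
    mesh <- apply_pure_shear(mesh, ds)
    sxx[k - 1] <- ds
    if (params$lam != 0) {
      used <- integer(0)
      cur <- measure_mean_qxx(mesh)
      cand_all <- t1_candidate_edges(mesh)
      for (step in 1:30) {
        err <- cur - qm[k]
        if (abs(err) < 1.5e-3) break
        cand <- cand_all[!(cand_all$cell_a %in% used | cand_all$cell_b %in% used |
                           cand_all$cell_c %in% used | cand_all$cell_d %in% used), ]
        if (!nrow(cand)) break
        pick <- sample.int(nrow(cand), min(18L, nrow(cand)))
        best <- NULL; best_err <- abs(err); best_q <- cur
        for (r in pick) {
          trial <- try(plant_t1(mesh, cand$v1[r], cand$v2[r]), silent = TRUE)
          if (inherits(trial, "try-error")) next
          ok <- !inherits(try(validate_quartet(trial, attr(trial, "quartet")),
                              silent = TRUE), "try-error")
          if (!ok) next
          qn <- measure_mean_qxx(trial)
          if (abs(qn - qm[k]) < best_err) {
            best <- trial; best_err <- abs(qn - qm[k]); best_q <- qn
          }
        }
        if (is.null(best)) break
        mesh <- best; cur <- best_q
        quartet <- attr(best, "quartet")
        used <- c(used, quartet)
        ev_time <- c(ev_time, times[k]); ev_kind <- c(ev_kind, "T1")
        ev_cells <- c(ev_cells, paste(sort(quartet), collapse = ","))
      }
    }
    mesh$frame_time <- times[k]
    frames[[k]] <- mesh
  }

  gt <- list(
    sxx = sxx,
    rxx_planted = params$lam * diff(cq) / diff(times),
    events = data.frame(time = ev_time, kind = ev_kind, cells = ev_cells,
                        stringsAsFactors = FALSE),
    params = params, sched = sched,
    model_Qxx = qm, model_LmH = lm
  )
  new_mesh_series(frames, times, gt)
}

# Cheap local validity check after a T1: the quartet polygons are simple
# with positive area.
validate_quartet <- function(mesh, quartet) {
  for (id in quartet) {
    k <- match(id, mesh$cell_ids)
    xy <- mesh$vertices[mesh$cells[[k]], , drop = FALSE]
    if (poly_signed_area(xy) <= 0 || !poly_is_simple(xy))
      stop("invalid quartet polygon")
  }
  invisible(TRUE)
}

#' Simulate a static tissue with planted rearrangement events
#'
#' A mesh series with no imposed deformation, into which a requested number
#' of T1, T2 and rosette events are planted at scheduled frames. T2 victims
#' shrink over the two frames preceding their extrusion. Ground truth lists
#' every planted event with its frame time and participating cells.
#'
#' @param n_cells,disorder,seed passed to [make_cell_mesh()].
#' @param n_frames number of frames (>= 4 when T2 events are requested).
#' @param n_t1,n_t2,n_rosette event counts to plant.
#' @return a `mesh_series`.
#' @export
simulate_event_series <- function(n_cells = 150, disorder = 0.3, n_frames = 8,
                                  n_t1 = 3, n_t2 = 1, n_rosette = 1,
                                  seed = 1L) {
  if (n_t2 > 0 && n_frames < 4) stop("T2 planting needs >= 4 frames")
  n_events <- n_t1 + n_t2 + n_rosette
  if (n_frames < 2) stop("need >= 2 frames")
  mesh <- make_cell_mesh(n_cells, disorder, seed, frame_time = 0)
  set.seed(seed + 7L)

  # schedule events on frames 2..n_frames (T2 needs two shrink frames first)
  kinds <- sample(c(rep("T1", n_t1), rep("T2", n_t2), rep("rosette", n_rosette)))
  min_frame <- ifelse(kinds == "T2", 4L, 2L)
  at_frame <- vapply(min_frame, function(m) sample(seq.int(m, n_frames), 1L),
                     integer(1))

  used <- integer(0)
  plan <- vector("list", n_events)
  bc <- boundary_cells(mesh)
  deg <- lengths(mesh$vertex_cells)
  for (i in seq_len(n_events)) {
    if (kinds[i] == "T1") {
      cand <- t1_candidate_edges(mesh, exclude_cells = used)
      if (!nrow(cand)) stop("no usable T1 candidate edge left")
      r <- sample.int(nrow(cand), 1L)
      plan[[i]] <- list(kind = "T1", frame = at_frame[i],
                        v1 = cand$v1[r], v2 = cand$v2[r],
                        cells = c(cand$cell_a[r], cand$cell_b[r],
                                  cand$cell_c[r], cand$cell_d[r]))
      used <- c(used, plan[[i]]$cells)
    } else if (kinds[i] == "T2") {
      pool <- setdiff(mesh$cell_ids, c(bc, used))
      # prefer small cells away from other events
      pool <- pool[order(mesh$areas[match(pool, mesh$cell_ids)])]
      if (!length(pool)) stop("no usable T2 victim left")
      vic <- pool[1]
      nb <- unique(c(mesh$adjacency[mesh$adjacency[, 1] == vic, 2],
                     mesh$adjacency[mesh$adjacency[, 2] == vic, 1]))
      plan[[i]] <- list(kind = "T2", frame = at_frame[i], victim = vic,
                        cells = vic)
      used <- c(used, vic, nb)
    } else {
      vs <- which(deg == 3L)
      ok <- vapply(vs, function(v) {
        cc <- mesh$vertex_cells[[v]]
        !any(cc %in% c(bc, used)) &&
          all(lengths(mesh$cells[match(cc, mesh$cell_ids)]) >= 5L)
      }, logical(1))
      vs <- vs[ok]
      if (!length(vs)) stop("no usable rosette vertex left")
      v <- vs[sample.int(length(vs), 1L)]
      cells <- sort(unique(unlist(mesh$vertex_cells[
        c(v, vertex_neighbors(mesh, v))], use.names = FALSE)))
      plan[[i]] <- list(kind = "rosette", frame = at_frame[i], vertex = v,
                        cells = cells)
      used <- c(used, cells)
    }
  }

  frames <- vector("list", n_frames)
  frames[[1]] <- mesh
  ev_time <- numeric(0); ev_kind <- character(0); ev_cells <- character(0)
  for (k in 2:n_frames) {
    for (i in seq_len(n_events)) {
      p <- plan[[i]]
      if (p$kind == "T2") {
        if (k == p$frame - 2L) mesh <- shrink_cell(mesh, p$victim, 0.6)
        if (k == p$frame - 1L) mesh <- shrink_cell(mesh, p$victim, 0.5)
        if (k == p$frame) {
          mesh <- plant_t2(mesh, p$victim)
          ev_time <- c(ev_time, k - 1); ev_kind <- c(ev_kind, "T2")
          ev_cells <- c(ev_cells, as.character(p$victim))
        }
      } else if (p$kind == "T1" && k == p$frame) {
        mesh <- plant_t1(mesh, p$v1, p$v2)
        ev_time <- c(ev_time, k - 1); ev_kind <- c(ev_kind, "T1")
        ev_cells <- c(ev_cells, paste(sort(p$cells), collapse = ","))
      } else if (p$kind == "rosette" && k == p$frame) {
        mesh <- plant_rosette(mesh, p$vertex)
        ev_time <- c(ev_time, k - 1); ev_kind <- c(ev_kind, "rosette")
        ev_cells <- c(ev_cells, paste(attr(mesh, "rosette_cells"), collapse = ","))
      }
    }
    mesh$frame_time <- k - 1
    frames[[k]] <- mesh
  }
  gt <- list(sxx = rep(0, n_frames - 1L), rxx_planted = rep(0, n_frames - 1L),
             events = data.frame(time = ev_time, kind = ev_kind,
                                 cells = ev_cells, stringsAsFactors = FALSE),
             params = NULL, sched = NULL)
  new_mesh_series(frames, seq_len(n_frames) - 1, gt)
}

#' Jitter every frame of a mesh series
#'
#' Adds independent Gaussian positional noise to all vertices of every frame
#' (topology and tracking untouched); emulates imprecise segmentation of a
#' tracked movie.
#'
#' @param series a `mesh_series`.
#' @param sd_frac noise sd as a fraction of the mean cell diameter.
#' @param seed integer seed.
#' @return the jittered `mesh_series`.
#' @export
jitter_mesh_series <- function(series, sd_frac = 0.02, seed = 1L) {
  out <- series
  out$frames <- lapply(seq_along(series$frames), function(k) {
    jitter_mesh(series$frames[[k]], sd_frac, seed + k)
  })
  out
}
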