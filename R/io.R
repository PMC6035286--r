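# File formats: 16-bit TIFF label maps, JSON meshes with a documented
# schema, CSV time courses with a units comment line, and the YAML run
# configuration with strict key validation.

MESH_SCHEMA_VERSION <- "1.0"

#' Write / read a label map as single-channel 16-bit TIFF
#'
#' @param labelmap integer matrix (values 0..65535).
#' @param path file path.
#' @return `read_labelmap`: integer matrix. `write_labelmap`: the path,
#'   invisibly.
#' @export
write_labelmap <- function(labelmap, path) {
  if (!is.matrix(labelmap)) stop("`labelmap` must be a matrix")
  if (any(labelmap < 0) || any(labelmap > 65535))
    stop("labels must be in 0..65535 for 16-bit storage")
  tiff::writeTIFF(labelmap / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(x)) == 3L) stop("multi-channel rasters are not label maps")
  bps <- attr(x, "bits.per.sample")
  fmt <- attr(x, "sample.format")
  if ((!is.null(bps) && bps > 16L) || identical(fmt, "float") || is.double(x))
    stop("floating-point rasters are not label maps")
  out <- matrix(as.integer(x), nrow(x), ncol(x))
  out
}

#' Write / read a cell mesh as JSON
#'
#' Schema (version 1.0): `schema_version`; `frame_time`; `vertices` (n x 2
#' array); `cells` (list of `{id, vertex_ids}` with 1-based indices into
#' `vertices`); `adjacency` (m x 2 array of cell id pairs). Round trips are
#' lossless to double precision. Reading validates required fields, the
#' schema version, and that adjacency pairs are unordered and irreflexive.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param path file path.
#' @return `read_mesh`: a `cell_mesh`. `write_mesh`: the path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  if (is.null(mesh$cells)) stop("mesh carries no polygon outlines")
  obj <- list(
    schema_version = MESH_SCHEMA_VERSION,
    frame_time = mesh$frame_time,
    vertices = mesh$vertices,
    cells = lapply(seq_along(mesh$cells), function(k) {
      list(id = mesh$cell_ids[k], vertex_ids = mesh$cells[[k]])
    }),
    adjacency = mesh$adjacency
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("schema_version", "vertices", "cells")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("mesh JSON is missing required fields: ", paste(miss, collapse = ", "))
  if (!identical(obj$schema_version, MESH_SCHEMA_VERSION))
    stop("unsupported mesh schema version: ", obj$schema_version)
  cells <- lapply(obj$cells$vertex_ids, as.integer)
  names(cells) <- as.character(obj$cells$id)
  ft <- if (is.null(obj$frame_time)) NA_real_ else as.numeric(obj$frame_time)
  mesh <- new_cell_mesh(matrix(as.numeric(obj$vertices), ncol = 2), cells,
                        frame_time = ft)
  if (!is.null(obj$adjacency) && length(obj$adjacency)) {
    adj <- matrix(as.integer(obj$adjacency), ncol = 2)
    if (any(adj[, 1] == adj[, 2])) stop("mesh JSON adjacency is reflexive")
    k1 <- paste(pmin(adj[, 1], adj[, 2]), pmax(adj[, 1], adj[, 2]))
    if (anyDuplicated(k1)) stop("mesh JSON adjacency has asymmetric duplicates")
    k2 <- paste(mesh$adjacency[, 1], mesh$adjacency[, 2])
    if (!setequal(k1, k2))
      stop("mesh JSON adjacency is inconsistent with the cell polygons")
  }
  mesh
}

#' Write a CSV with a units comment line
#'
#' @param df data.frame.
#' @param path file path.
#' @param units character: a short units/column description written as a
#'   leading `#` comment line.
#' @return the path, invisibly.
#' @export
write_csv_units <- function(df, path, units = "") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(units)) writeLines(paste0("# ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_units()]
#' @param path file path.
#' @return data.frame.
#' @export
read_csv_units <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

# --- run configuration -------------------------------------------------------

default_config <- function() {
  list(
    schema_version = "1.0",
    seed = 1L,
    simulate = list(n_cells = 400L, disorder = 0.3, dt = 0.25, t_end = 7,
                    Qxx0 = 0),
    model = list(t0 = 4, t1 = 5, t2 = 6, magnitude = 1,
                 tau_s = 0.5, zeta_over_2K = -0.1, lam = 0.1),
    fit = list(tau_min = 0.1, tau_max = 1, tau_n = 10L, fit_mode = "joint"),
    render = list(px_per_unit = 45, membrane_width_px = 2, snr = Inf),
    segmentation = list(alpha = 0.8, ridge_scale = 1.2, min_area = 150L,
                        h = 0.03),
    morphometry = list(angle_threshold_deg = 30, weighting = "uniform")
  )
}

#' Read / write / validate the pipeline run configuration
#'
#' YAML file mirroring [default_config()]; unknown keys (at any level) are
#' rejected, missing keys fall back to the documented defaults, and a
#' write-read round trip is lossless.
#'
#' @param path YAML file path.
#' @param config configuration list (as returned by `read_config` or
#'   [default_config()]).
#' @return `read_config`: validated configuration list of class
#'   `run_config`.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  validate_config(usr)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_config
#' @param config a raw configuration list to validate and complete.
#' @export
validate_config <- function(config) {
  def <- default_config()
  merge_block <- function(usr, def, prefix) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(prefix, unknown), collapse = ", "))
    out <- def
    for (nm in names(usr)) {
      if (is.list(def[[nm]])) {
        out[[nm]] <- merge_block(usr[[nm]], def[[nm]], paste0(prefix, nm, "."))
      } else {
        out[[nm]] <- usr[[nm]]
      }
    }
    out
  }
  cfg <- merge_block(config, def, "")
  with(cfg$model, {
    if (!(t0 < t1 && t1 < t2)) stop("config model: need t0 < t1 < t2")
    if (tau_s <= 0) stop("config model: tau_s must be > 0")
  })
  if (cfg$fit$tau_min <= 0 || cfg$fit$tau_max < cfg$fit$tau_min ||
      cfg$fit$tau_n < 1)
    stop("config fit: invalid tau_s grid")
  structure(cfg, class = "run_config")
}
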