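# Synthetic intensity signals: model-generated elongation curves for
# parameter-recovery studies, orientation-dependent junction intensities
# with tunable PD/AP polarity, and 1-D surface-coverage profiles.

#' Synthesize noisy elongation curves from the continuum model
#'
#' Forward-solves the model for Qxx(t) and (L-H)(t) and adds i.i.d. Gaussian
#' noise. The reference point (L-H)(t0) stays exactly 0 (it defines the
#' strain origin, not a measurement). The generating parameters are attached
#' as ground truth.
#'
#' @param params a [model_params()] (ground truth).
#' @param sched a [myosin_schedule()].
#' @param Qxx0 initial mean cell elongation at t0.
#' @param noise_sd noise standard deviation (>= 0), same for both curves.
#' @param timepoints sampling times (>= 4 points, all >= t0).
#' @param seed integer seed.
#' @return an [elongation_series()] with provenance `"synthetic"` and
#'   attribute `truth` (the generating parameters).
#' @export
synth_elongation_data <- function(params, sched = myosin_schedule(), Qxx0 = 0,
                                  noise_sd = 0.01,
                                  timepoints = seq(4, 7, by = 0.25),
                                  seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (length(timepoints) < 4) stop("need >= 4 timepoints")
  q <- solve_Qxx_closed(params, Qxx0, sched, timepoints)
  lh <- predict_LmH(params, sched, timepoints, Qxx0 = Qxx0)
  if (noise_sd > 0) {
    set.seed(seed)
    q <- q + stats::rnorm(length(q), sd = noise_sd)
    lh <- lh + stats::rnorm(length(lh), sd = noise_sd)
  }
  lh[timepoints == sched$t0] <- 0
  out <- elongation_series(timepoints, q, lh,
                           sd_Qxx = rep(noise_sd, length(q)),
                           sd_LmH = rep(noise_sd, length(q)),
                           provenance = "synthetic")
  attr(out, "truth") <- params
  out
}

#' Synthesize junction intensities with planar polarity
#'
#' Assigns an intensity to every junction of a mesh so that the expected
#' polarity ratio (mean intensity on AP-oriented junctions over mean on
#' PD-oriented junctions, classified with the same angular threshold as the
#' measurement) equals `pd_ap_ratio`: AP-oriented junctions get mean
#' `pd_ap_ratio`, PD-oriented junctions mean 1, junctions in the transition
#' zone interpolate linearly in angle. Multiplicative Gaussian noise of sd
#' `noise_sd` is applied per junction.
#'
#' @param mesh a `cell_mesh` with polygon outlines.
#' @param pd_ap_ratio expected polarity ratio (> 0); 2 emulates the 2-fold
#'   junctional myosin polarity of the convergent-extension stage.
#' @param noise_sd relative intensity noise (>= 0).
#' @param seed integer seed.
#' @param angle_threshold_deg orientation-class half-width (degrees), matching
#'   [junction_polarity_ratio()].
#' @return numeric vector of intensities aligned with [mesh_junctions()] rows.
#' @export
synth_junction_intensities <- function(mesh, pd_ap_ratio = 2, noise_sd = 0,
                                       seed = 1L, angle_threshold_deg = 30) {
  if (pd_ap_ratio <= 0) stop("`pd_ap_ratio` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  jn <- mesh_junctions(mesh)
  a <- jn$angle_deg
  thr <- angle_threshold_deg
  w <- ifelse(a <= thr, 0, ifelse(a >= 90 - thr, 1,
                                  (a - thr) / (90 - 2 * thr)))
  base <- 1 + (pd_ap_ratio - 1) * w
  if (noise_sd > 0) {
    set.seed(seed)
    base <- base * (1 + stats::rnorm(length(base), sd = noise_sd))
  }
  base
}

#' Synthesize a 1-D surface-intensity profile with known coverage
#'
#' Builds a profile along an epithelial surface in which contiguous
#' "covered" segments (e.g. ECM on the surface) total a planted fraction of
#' the samples, at `contrast`-fold the uncovered intensity, plus Gaussian
#' noise. The ground-truth covered mask is attached.
#'
#' @param coverage_frac planted covered fraction in `[0, 1]`.
#' @param n_samples profile length.
#' @param contrast covered/uncovered mean intensity ratio.
#' @param seed integer seed.
#' @param n_segments number of covered segments the coverage is split into.
#' @param noise_sd additive noise sd (in units of the uncovered intensity).
#' @return numeric profile with attribute `covered` (logical mask).
#' @export
synth_surface_profile <- function(coverage_frac, n_samples = 1000, contrast = 10,
                                  seed = 1L, n_segments = 3, noise_sd = 0.2) {
  if (coverage_frac < 0 || coverage_frac > 1) stop("`coverage_frac` must be in [0, 1]")
  set.seed(seed)
  covered <- logical(n_samples)
  n_cov <- round(coverage_frac * n_samples)
  if (n_cov > 0) {
    if (n_cov >= n_samples) {
      covered[] <- TRUE
    } else {
      sizes <- diff(round(seq(0, n_cov, length.out = min(n_segments, n_cov) + 1)))
      sizes <- sizes[sizes > 0]
      gaps <- n_samples - n_cov
      starts <- sort(sample.int(gaps, length(sizes), replace = FALSE))
      pos <- 1L
      prev_end <- 0L
      for (i in seq_along(sizes)) {
        s <- starts[i] + prev_end
        covered[seq.int(s + 1, s + sizes[i])] <- TRUE
        prev_end <- prev_end + sizes[i]
      }
    }
  }
  prof <- ifelse(covered, contrast, 1) + stats::rnorm(n_samples, sd = noise_sd)
  attr(prof, "covered") <- covered
  prof
}
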