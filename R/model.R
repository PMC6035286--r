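# Active continuum model of autonomous convergent extension.
#
# The tissue is a rectangle under spatially uniform shear along the PD (x)
# axis. Tissue shear rate decomposes into cell-shape change plus cellular
# rearrangements, rearrangements respond to myosin anisotropy q_xx with rate
# lambda, and the traceless stress balance under free boundaries gives a
# linear relaxation ODE for the mean cell elongation:
#
#   dQxx/dt = -Qxx / tau_s - (zeta/2K) / tau_s * qxx(t)
#
# with tau_s = mu/K the shape relaxation time and zeta/2K the active-stress
# ratio (negative: AP-contractile). Tissue elongation follows as
#
#   (L-H)(t) = -2 Int_{t0}^{t} [ Qxx/tau_s + ((zeta/2K)/tau_s - lambda) qxx ] dt'
#
# All three effective parameters (tau_s, zeta/2K, lambda) are identifiable
# only as ratios; K, mu, zeta are not fit separately.

#' Piecewise-linear myosin anisotropy schedule
#'
#' Myosin anisotropy is held at `magnitude` on (t0, t1), ramps linearly to 0
#' on (t1, t2), and is 0 after t2. Defaults place the active pulse at
#' 4--5 h APF with a 1 h ramp-down, matching measured myosin anisotropy
#' dynamics in the pupal wing.
#'
#' @param t0,t1,t2 schedule breakpoints in hours APF; must be increasing.
#' @param magnitude plateau anisotropy (dimensionless, default 1; the scale
#'   is a normalization absorbed into zeta and lambda).
#' @return object of class `myosin_schedule`.
#' @export
myosin_schedule <- function(t0 = 4, t1 = 5, t2 = 6, magnitude = 1) {
  if (!(t0 < t1 && t1 < t2)) stop("need t0 < t1 < t2")
  check_scalar(magnitude, "magnitude")
  structure(list(t0 = t0, t1 = t1, t2 = t2, magnitude = magnitude),
            class = "myosin_schedule")
}

#' Evaluate the myosin anisotropy schedule
#'
#' Boundary points resolve by right-continuity at t1 (the ramp starts with
#' value `magnitude` there) and the ramp reaches exactly 0 at t2; these are
#' measure-zero choices that do not affect any integral.
#'
#' @param t time(s) in hours APF; must satisfy `t >= t0`.
#' @param sched a [myosin_schedule()].
#' @return qxx value(s), dimensionless.
#' @export
qxx_schedule <- function(t, sched) {
  stopifnot(inherits(sched, "myosin_schedule"))
  if (any(t < sched$t0 - 1e-12)) stop("`t` must be >= schedule t0")
  out <- numeric(length(t))
  out[t < sched$t1] <- sched$magnitude
  ramp <- t >= sched$t1 & t < sched$t2
  out[ramp] <- sched$magnitude * (sched$t2 - t[ramp]) / (sched$t2 - sched$t1)
  out
}

#' Continuum model parameters
#'
#' @param tau_s cell-shape relaxation timescale mu/K in hours (> 0).
#' @param zeta_over_2K dimensionless active-stress ratio (negative values
#'   drive AP contraction / PD extension).
#' @param lam rearrangement response rate lambda in 1/h.
#' @return object of class `ce_params`.
#' @export
model_params <- function(tau_s, zeta_over_2K, lam) {
  check_scalar(tau_s, "tau_s"); check_scalar(zeta_over_2K, "zeta_over_2K")
  check_scalar(lam, "lam")
  if (tau_s <= 0) stop("`tau_s` must be > 0")
  structure(list(tau_s = tau_s, zeta_over_2K = zeta_over_2K, lam = lam),
            class = "ce_params")
}

#' @export
print.ce_params <- function(x, ...) {
  cat(sprintf("<ce_params> tau_s = %g h, zeta/2K = %g, lambda = %g /h\n",
              x$tau_s, x$zeta_over_2K, x$lam))
  invisible(x)
}

# (1/tau) Int_{t0}^{t} exp(-(t - t')/tau) qxx(t') dt', evaluated with
# per-segment closed forms (constant and linear segments integrate exactly
# against the exponential kernel). Written with the damped kernel
# exp(-(t - t')/tau) <= 1 so it is stable down to very small tau.
qxx_response <- function(t, sched, tau) {
  m <- sched$magnitude
  resp <- numeric(length(t))
  # segment generator: [a, b], q = alpha + beta t'
  seg <- function(t, a, b, alpha, beta) {
    b <- pmin(b, t)
    use <- b > a
    out <- numeric(length(t))
    tt <- t[use]; bb <- b[use]
    f <- function(tp) exp(-(tt - tp) / tau) * (alpha + beta * tp - beta * tau)
    out[use] <- f(bb) - f(a)
    out
  }
  resp <- seg(t, sched$t0, sched$t1, m, 0) +
    seg(t, sched$t1, sched$t2,
        m * sched$t2 / (sched$t2 - sched$t1), -m / (sched$t2 - sched$t1))
  resp
}

#' Closed-form solution for mean cell elongation
#'
#' Evaluates the exact solution of the relaxation ODE for `Qxx(t)` with the
#' piecewise-linear myosin schedule, using per-segment antiderivatives
#' against the exponential kernel (numerically stable for small `tau_s`).
#'
#' @param params a [model_params()].
#' @param Qxx0 initial mean cell elongation at the schedule's t0.
#' @param sched a [myosin_schedule()].
#' @param times evaluation times (hours APF, all >= t0).
#' @return numeric vector Qxx(times).
#' @export
solve_Qxx_closed <- function(params, Qxx0, sched, times) {
  stopifnot(inherits(params, "ce_params"), inherits(sched, "myosin_schedule"))
  if (any(times < sched$t0 - 1e-12)) stop("`times` must be >= schedule t0")
  Qxx0 * exp(-(times - sched$t0) / params$tau_s) -
    params$zeta_over_2K * qxx_response(times, sched, params$tau_s)
}

#' Numerically integrated mean cell elongation
#'
#' Adaptive integration of `dQxx/dt = -Qxx/tau_s - (zeta/2K)/tau_s qxx(t)`
#' with \code{deSolve}, restarted at the schedule breakpoints t1, t2 so the
#' integrator never steps across a derivative discontinuity. Serves as the
#' independent cross-check of [solve_Qxx_closed()].
#'
#' @inheritParams solve_Qxx_closed
#' @param tol relative and absolute tolerance passed to the integrator.
#' @return numeric vector Qxx(times).
#' @export
solve_Qxx_ode <- function(params, Qxx0, sched, times, tol = 1e-10) {
  stopifnot(inherits(params, "ce_params"), inherits(sched, "myosin_schedule"))
  if (tol <= 0) stop("`tol` must be > 0")
  if (any(times < sched$t0 - 1e-12)) stop("`times` must be >= schedule t0")
  rhs <- function(t, y, p) {
    list(-(y[1] + params$zeta_over_2K * qxx_schedule(t, sched)) / params$tau_s)
  }
  brk <- c(sched$t0, sched$t1, sched$t2, max(times) + 1e-9)
  tq <- sort(unique(times))
  y0 <- Qxx0
  sol_t <- numeric(0); sol_y <- numeric(0)
  for (k in seq_len(length(brk) - 1L)) {
    a <- brk[k]; b <- min(brk[k + 1], max(tq))
    if (a > max(tq)) break
    tt <- unique(c(a, tq[tq > a & tq <= b], b))
    out <- deSolve::ode(y = y0, times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = tol, atol = tol)
    if (attr(out, "istate")[1] < 0) stop("ODE integration failed")
    sol_t <- c(sol_t, out[, 1]); sol_y <- c(sol_y, out[, 2])
    y0 <- out[nrow(out), 2]
  }
  sol_y[match(round(times, 12), round(sol_t, 12))]
}

#' Predicted tissue elongation L - H
#'
#' Integrates the tissue natural-strain rate
#' `-2 [ Qxx/tau_s + ((zeta/2K)/tau_s - lambda) qxx ]` from t0, with
#' `(L-H)(t0) = 0`, using Gauss--Legendre quadrature on the closed-form
#' integrand, split at the schedule breakpoints so every panel is smooth.
#'
#' @inheritParams solve_Qxx_closed
#' @param Qxx_path optional Qxx values aligned with `times`; checked for
#'   consistency with the closed-form solution (guards against mismatched
#'   parameter/path inputs).
#' @param Qxx0 initial elongation; defaults to `Qxx_path[1]` when a path is
#'   given.
#' @return numeric vector (L-H)(times).
#' @export
predict_LmH <- function(params, sched, times, Qxx_path = NULL, Qxx0 = NULL) {
  stopifnot(inherits(params, "ce_params"), inherits(sched, "myosin_schedule"))
  if (any(times < sched$t0 - 1e-12)) stop("`times` must be >= schedule t0")
  if (is.null(Qxx0)) {
    Qxx0 <- if (!is.null(Qxx_path)) Qxx_path[1] else 0
  }
  if (!is.null(Qxx_path)) {
    if (length(Qxx_path) != length(times))
      stop("`Qxx_path` is misaligned with `times`")
    chk <- solve_Qxx_closed(params, Qxx0, sched, times)
    if (max(abs(chk - Qxx_path)) > 1e-6 + 1e-3 * max(abs(chk)))
      stop("`Qxx_path` is inconsistent with `params`/`sched`")
  }
  integrand <- function(tp) {
    Q <- solve_Qxx_closed(params, Qxx0, sched, tp)
    Q / params$tau_s +
      (params$zeta_over_2K / params$tau_s - params$lam) * qxx_schedule(tp, sched)
  }
  ts <- sort(unique(c(sched$t0, times)))
  # panel edges: consecutive times plus schedule breakpoints falling inside
  cum <- numeric(length(ts)); acc <- 0
  for (k in seq_len(length(ts) - 1L)) {
    a <- ts[k]; b <- ts[k + 1L]
    edges <- sort(unique(c(a, sched$t1[sched$t1 > a & sched$t1 < b],
                           sched$t2[sched$t2 > a & sched$t2 < b], b)))
    for (j in seq_len(length(edges) - 1L)) {
      gl <- pracma::gaussLegendre(16, edges[j], edges[j + 1L])
      acc <- acc + sum(gl$w * integrand(gl$x))
    }
    cum[k + 1L] <- acc
  }
  -2 * cum[match(times, ts)]
}

#' Fit the continuum model to elongation data
#'
#' For each candidate relaxation timescale `tau_s` on a grid, fits the two
#' remaining parameters (`zeta/2K`, `lambda`) to the measured mean cell
#' elongation Qxx(t) and tissue elongation (L-H)(t) jointly. Given `tau_s`
#' the model is linear in both parameters, so the inner fit is an exact
#' linear least-squares solve (no iterative optimizer, no convergence
#' failures on finite data). The initial elongation Qxx(t0) is pinned to the
#' measured value at t0. Returns the full grid so the SSE-vs-tau_s profile
#' and the parameter trends can be inspected.
#'
#' @param data an [elongation_series()] (columns `time`, `Qxx`, `LmH`,
#'   optional `sd_Qxx`, `sd_LmH`).
#' @param sched a [myosin_schedule()].
#' @param tau_grid candidate tau_s values in hours (default 10 values,
#'   0.1--1 h, the physiologically plausible range).
#' @param fit_mode `"joint"` (default): one least-squares solve pooling the
#'   residuals of both curves with equal weight; `"sequential"`: fit zeta/2K
#'   on Qxx(t) alone, then lambda on (L-H)(t).
#' @param use_sd if `TRUE` and the data carry per-point sd columns, weight
#'   residuals by 1/sd.
#' @return object of class `ce_fit`: list with `grid` (data.frame: `tau_s`,
#'   `zeta_over_2K`, `lam`, `sse`, `ok`), `best` (row at minimal SSE as a
#'   [model_params()]), `Qxx0`, `sched`, `fit_mode`.
#' @export
fit_ce_model <- function(data, sched = myosin_schedule(),
                         tau_grid = seq(0.1, 1, length.out = 10),
                         fit_mode = c("joint", "sequential"),
                         use_sd = FALSE) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(inherits(sched, "myosin_schedule"))
  if (!length(tau_grid)) stop("`tau_grid` must be non-empty")
  tt <- data$time; Q <- data$Qxx; LH <- data$LmH
  if (length(tt) < 4) stop("need >= 4 timepoints")
  if (!all(is.finite(tt)) || !all(is.finite(Q)) || !all(is.finite(LH)))
    stop("non-finite values in elongation data")
  Qxx0 <- Q[which.min(abs(tt - sched$t0))]
  wQ <- rep(1, length(tt)); wL <- wQ
  if (use_sd && !is.null(data$sd_Qxx)) wQ <- 1 / data$sd_Qxx
  if (use_sd && !is.null(data$sd_LmH)) wL <- 1 / data$sd_LmH
  wL[tt == sched$t0] <- 0   # (L-H)(t0) = 0 is the reference, not a residual

  Cq <- cumulative_qxx(tt, sched)   # Int qxx dt'
  rows <- lapply(tau_grid, function(tau) {
    A <- Qxx0 * exp(-(tt - sched$t0) / tau)
    J <- qxx_response(tt, sched, tau)       # Qxx = A - (zeta/2K) J
    yQ <- Q - A
    yL <- LH - 2 * (A - Qxx0)
    ok <- TRUE; z <- NA_real_; l <- NA_real_
    res <- try({
      if (fit_mode == "joint") {
        X <- rbind(cbind(-J * wQ, 0), cbind(-2 * J * wL, 2 * Cq * wL))
        y <- c(yQ * wQ, yL * wL)
        th <- qr.solve(X, y)
      } else {
        z1 <- sum(-J * wQ^2 * yQ) / sum(J^2 * wQ^2)
        r2 <- yL + 2 * z1 * J
        l1 <- sum(2 * Cq * wL^2 * r2) / sum(4 * Cq^2 * wL^2)
        th <- c(z1, l1)
      }
      th
    }, silent = TRUE)
    if (inherits(res, "try-error") || !all(is.finite(res))) {
      ok <- FALSE
    } else {
      z <- res[1]; l <- res[2]
    }
    sse <- if (ok) {
      Qhat <- A - z * J
      LHhat <- 2 * (Qhat - Qxx0) + 2 * l * Cq
      sum(((Q - Qhat) * wQ)^2) + sum(((LH - LHhat) * wL)^2)
    } else NA_real_
    data.frame(tau_s = tau, zeta_over_2K = z, lam = l, sse = sse, ok = ok)
  })
  grid <- do.call(rbind, rows)
  bi <- which.min(ifelse(grid$ok, grid$sse, Inf))
  best <- model_params(grid$tau_s[bi], grid$zeta_over_2K[bi], grid$lam[bi])
  structure(list(grid = grid, best = best, Qxx0 = Qxx0, sched = sched,
                 fit_mode = fit_mode), class = "ce_fit")
}

#' @export
print.ce_fit <- function(x, ...) {
  cat(sprintf("<ce_fit> %d tau_s grid points; best: tau_s = %g h, zeta/2K = %.4g, lambda = %.4g /h (SSE %.3g)\n",
              nrow(x$grid), x$best$tau_s, x$best$zeta_over_2K, x$best$lam,
              min(x$grid$sse, na.rm = TRUE)))
  invisible(x)
}

# Exact cumulative integral of the piecewise-linear schedule from t0.
cumulative_qxx <- function(t, sched) {
  m <- sched$magnitude
  plateau <- pmax(0, pmin(t, sched$t1) - sched$t0) * m
  # ramp integral: from t1 to min(t, t2) of m (t2 - t')/(t2 - t1)
  u <- pmax(0, pmin(t, sched$t2) - sched$t1)
  w <- sched$t2 - sched$t1
  ramp <- m * (u - u^2 / (2 * w))
  plateau + ramp
}
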