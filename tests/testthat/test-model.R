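sch <- myosin_schedule()

test_that("myosin schedule evaluates the piecewise form", {
  expect_equal(qxx_schedule(4.5, sch), 1)
  expect_equal(qxx_schedule(5.5, sch), 0.5)
  expect_equal(qxx_schedule(c(6, 7), sch), c(0, 0))
  expect_equal(qxx_schedule(5, sch), 1)          # right-continuous at t1
  expect_error(qxx_schedule(3.9, sch), ">= schedule t0")
  expect_error(myosin_schedule(5, 4, 6), "t0 < t1 < t2")
})

test_that("closed form and adaptive ODE agree across the physiological grid", {
  tt <- seq(4, 8, by = 0.1)
  for (tau in c(0.1, 0.5, 1)) {
    for (z in c(-0.14, -0.1, -0.06)) {
      for (q0 in c(-0.1, 0, 0.1)) {
        p <- model_params(tau, z, 0.1)
        a <- solve_Qxx_closed(p, q0, sch, tt)
        b <- solve_Qxx_ode(p, q0, sch, tt)
        expect_lt(max(abs(a - b)), 1e-6)
      }
    }
  }
})

test_that("analytic limits of the elongation ODE", {
  tt <- seq(4, 8, by = 0.05)
  # no active stress: pure exponential relaxation at rate 1/tau_s
  p <- model_params(0.5, 0, 0.1)
  expect_equal(solve_Qxx_closed(p, 0.2, sch, tt), 0.2 * exp(-(tt - 4) / 0.5),
               tolerance = 1e-12)
  # held drive qxx = 1: stationary value -zeta/2K
  hold <- myosin_schedule(4, 1e5, 2e5)
  p2 <- model_params(0.5, -0.1, 0)
  expect_equal(solve_Qxx_closed(p2, 0, hold, 50), 0.1, tolerance = 1e-12)
  # tau_s -> 0: quasi-static adhesion to the drive
  p3 <- model_params(0.01, -0.1, 0.1)
  mid <- c(4.5, 5.5, 6.5)
  # absolute deviation bounded by tau |q'| |zeta/2K| on the ramp
  expect_lt(max(abs(solve_Qxx_closed(p3, 0, sch, mid) -
                    0.1 * qxx_schedule(mid, sch))), 2e-3)
  expect_error(model_params(-1, 0, 0), "tau_s")
})

test_that("particular solution is linear in zeta/2K", {
  tt <- seq(4, 7, by = 0.25)
  base <- solve_Qxx_closed(model_params(0.4, -0.05, 0), 0, sch, tt)
  doubled <- solve_Qxx_closed(model_params(0.4, -0.10, 0), 0, sch, tt)
  expect_equal(doubled, 2 * base, tolerance = 1e-12)
})

test_that("tissue elongation obeys the decomposition identity", {
  tt <- seq(4, 8, by = 0.1)
  p <- model_params(0.5, -0.1, 0.1)
  lh <- predict_LmH(p, sch, tt, Qxx0 = -0.05)
  # exact identity: L-H = 2 (Qxx - Qxx0) + 2 lambda Int qxx
  q <- solve_Qxx_closed(p, -0.05, sch, tt)
  ident <- 2 * (q - (-0.05)) + 2 * p$lam * wingmorph:::cumulative_qxx(tt, sch)
  expect_lt(max(abs(lh - ident)), 1e-9)
  # no drive, no initial elongation: identically zero
  p0 <- model_params(0.5, 0, 0)
  expect_equal(predict_LmH(p0, sch, tt, Qxx0 = 0), rep(0, length(tt)))
  # PD extension: with lambda > 0 and zeta/2K < 0, L-H is non-decreasing
  # over the full-drive plateau (tissue extends along PD)
  on <- tt <= 5
  expect_true(all(diff(lh[on]) > -1e-12))
  # misaligned path is refused
  expect_error(predict_LmH(p, sch, tt, Qxx_path = q[-1]), "misaligned")
})

test_that("synthetic elongation data pass through the model exactly at zero noise", {
  p <- model_params(0.5, -0.1, 0.1)
  tp <- seq(4, 7, by = 0.25)
  d <- synth_elongation_data(p, sch, Qxx0 = -0.05, noise_sd = 0, timepoints = tp)
  expect_equal(d$Qxx, solve_Qxx_closed(p, -0.05, sch, tp))
  expect_equal(d$LmH, predict_LmH(p, sch, tp, Qxx0 = -0.05))
  # (L-H)(t0) = 0 even with noise
  dn <- synth_elongation_data(p, sch, -0.05, noise_sd = 0.05, timepoints = tp, seed = 3)
  expect_identical(dn$LmH[1], 0)
  expect_error(synth_elongation_data(p, sch, 0, noise_sd = -1, timepoints = tp),
               "noise_sd")
  expect_error(synth_elongation_data(p, sch, 0, 0, timepoints = c(4, 5)), ">= 4")
})

test_that("fit recovers the generating parameters exactly on noiseless data", {
  truth <- model_params(0.5, -0.10, 0.10)
  d <- synth_elongation_data(truth, sch, Qxx0 = -0.05, noise_sd = 0,
                             timepoints = seq(4, 7, by = 0.25))
  f <- fit_ce_model(d, sch, tau_grid = seq(0.1, 1, length.out = 10))
  at <- which.min(abs(f$grid$tau_s - 0.5))
  expect_equal(f$grid$zeta_over_2K[at], -0.10, tolerance = 1e-4)
  expect_equal(f$grid$lam[at], 0.10, tolerance = 1e-4)
  expect_identical(which.min(f$grid$sse), at)
  # sequential mode lands on the same optimum on noiseless data
  fs <- fit_ce_model(d, sch, tau_grid = 0.5, fit_mode = "sequential")
  expect_equal(fs$grid$zeta_over_2K, -0.10, tolerance = 1e-4)
  expect_equal(fs$grid$lam, 0.10, tolerance = 1e-4)
})

test_that("the fit objective is strictly convex in (zeta/2K, lambda)", {
  # the design matrix of the inner linear solve has a positive definite
  # normal matrix at every grid point (identifiability with both curves)
  truth <- model_params(0.5, -0.10, 0.10)
  tt <- seq(4, 7, by = 0.25)
  d <- synth_elongation_data(truth, sch, Qxx0 = -0.05, noise_sd = 0, timepoints = tt)
  for (tau in seq(0.1, 1, length.out = 10)) {
    J <- wingmorph:::qxx_response(tt, sch, tau)
    Cq <- wingmorph:::cumulative_qxx(tt, sch)
    X <- rbind(cbind(-J, 0), cbind(-2 * J, 2 * Cq))
    ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(fit_ce_model(within(d, Qxx[2] <- NA), sch), "non-finite")
})
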