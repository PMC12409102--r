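# Dense noise-free polynomial samples: the spline fit reproduces the curve
# essentially exactly, so analytic extrema are the oracle for the
# derivative-based breakpoint search.
poly_fit <- function(f, lower = 0, upper = 1, n = 2000) {
  x <- seq(lower, upper, length.out = n)
  # suppressWarnings: ML smoothing of noise-free polynomials can end with a
  # step-failure note while still returning an essentially exact fit
  suppressWarnings(fit_phase_gam(x, f(x)))
}

test_that("knot policies are compared by AIC", {
  set.seed(1)
  x <- runif(500)
  y <- sin(6 * x) + rnorm(500, 0, 0.05)
  fit <- fit_phase_gam(x, y, knot_policy = "aic")
  expect_named(fit$aic, c("restricted", "unrestricted"))
  expect_equal(fit$knot_policy, names(which.min(fit$aic)))
  fit_r <- fit_phase_gam(x, y, knot_policy = "restricted")
  expect_equal(fit_r$knot_policy, "restricted")
  expect_error(fit_phase_gam(rep(0.5, 100), rnorm(100)), "degenerate")
  expect_error(fit_phase_gam(1:10, 1:10), ">= 50")
})

test_that("breakpoints recover analytic extrema of polynomials", {
  # parabola: vertex at 0.5, rise then fall
  fit <- poly_fit(function(x) -(x - 0.5)^2)
  bp <- find_breakpoints(fit)
  expect_equal(nrow(bp), 1L)
  step <- diff(fit$range) / 1000
  expect_lt(abs(bp$phi_psii - 0.5), 2 * step)
  expect_equal(bp$direction, "+to-")

  # cubic: stationary points at +-sqrt(0.3)
  fit3 <- poly_fit(function(x) x^3 - 0.9 * x, lower = -1, upper = 1)
  bp3 <- find_breakpoints(fit3)
  expect_equal(nrow(bp3), 2L)
  step3 <- diff(fit3$range) / 1000
  expect_lt(abs(bp3$phi_psii[1] + sqrt(0.3)), 2 * step3)
  expect_lt(abs(bp3$phi_psii[2] - sqrt(0.3)), 2 * step3)
  expect_equal(bp3$direction, c("+to-", "-to+"))
})

test_that("monotone curves yield no breakpoints", {
  fit <- poly_fit(function(x) 2 * x + 1)
  expect_equal(nrow(find_breakpoints(fit)), 0L)
  fit_exp <- poly_fit(function(x) exp(-3 * x))
  expect_equal(nrow(find_breakpoints(fit_exp)), 0L)
})

test_that("breakpoint locations are stable under grid refinement", {
  fit <- poly_fit(function(x) -(x^3 - 0.9 * x), lower = -1, upper = 1)
  bp1 <- find_breakpoints(fit, grid_size = 1000)
  bp2 <- find_breakpoints(fit, grid_size = 2000)
  expect_equal(nrow(bp1), nrow(bp2))
  step <- diff(fit$range) / 1000
  expect_true(all(abs(bp1$phi_psii - bp2$phi_psii) < step))
})

test_that("phase labels follow slope signs and ordering", {
  # one breakpoint, slopes (+, -) in increasing PhiPSII: NPQ- then PQ-limited
  fit <- poly_fit(function(x) -(x - 0.5)^2)
  ph <- classify_phases(find_breakpoints(fit), fit)
  expect_equal(ph$phase, c("NPQ-limited", "PQ-limited"))
  expect_equal(ph$slope_sign, c(1, -1))
  # slopes (-, +, -): stress at low PhiPSII, then NPQ-, then PQ-limited
  fit3 <- poly_fit(function(x) -(x^3 - 0.9 * x), lower = -1, upper = 1)
  ph3 <- classify_phases(find_breakpoints(fit3), fit3)
  expect_equal(ph3$phase, c("stress", "NPQ-limited", "PQ-limited"))
  # no breakpoints: single segment labelled by slope
  fit_dec <- poly_fit(function(x) exp(-3 * x))
  ph_dec <- classify_phases(find_breakpoints(fit_dec), fit_dec)
  expect_equal(ph_dec$phase, "PQ-limited")
  fit_inc <- poly_fit(function(x) 2 * x)
  expect_equal(classify_phases(find_breakpoints(fit_inc), fit_inc)$phase,
               "NPQ-limited")
  # exhaustive cover: segments tile the working range
  expect_equal(ph3$lower[1], fit3$range[1])
  expect_equal(ph3$upper[nrow(ph3)], fit3$range[2])
  expect_equal(ph3$lower[-1], ph3$upper[-nrow(ph3)])
})

test_that("breakpoints map to PAR through the inverted light response", {
  # constructed monotone decay: PhiPSII(PAR) = 0.8 exp(-PAR/600)
  par <- seq(1, 2000, length.out = 3000)
  rec <- data.frame(par = par, phi_psii = 0.8 * exp(-par / 600),
                    phi_no = 0.2, phi_npq = 0.2)
  ypg <- fit_yield_par_gams(rec, responses = "phi_psii")
  m <- map_breakpoint_to_par(0.553, ypg)
  expect_false(m$extrapolated)
  expect_equal(m$par, 600 * log(0.8 / 0.553), tolerance = 3)
  # boundary: breakpoint equal to the fitted PhiPSII at the lowest PAR
  bp0 <- as.vector(predict(ypg$phi_psii$model, data.frame(x = 1)))
  m0 <- map_breakpoint_to_par(bp0, ypg)
  expect_lt(m0$par, 5)
  # outside the fitted range -> extrapolated, no PAR
  mx <- map_breakpoint_to_par(0.95, ypg)
  expect_true(mx$extrapolated)
  expect_true(is.na(mx$par))
})

test_that("yield-PAR smooths reproduce generator shapes", {
  cfg <- synthetic_config()
  cr <- canopy_response_curve(cfg, "dry", heights = seq(0.5, 49.5, by = 0.05))
  ypg <- fit_yield_par_gams(cr, responses = c("phi_psii", "phi_npq"))
  grid <- data.frame(x = seq(quantile(cr$par, 0.05),
                             quantile(cr$par, 0.95), length.out = 200))
  psii_hat <- predict(ypg$phi_psii$model, grid)
  expect_true(all(diff(psii_hat) < 0))          # strictly decreasing
  npq_hat <- predict(ypg$phi_npq$model, grid)
  expect_true(all(diff(npq_hat) > 0))           # saturating increase
  expect_gt(ypg$phi_psii$deviance_explained, 0.99)
  # constant response: trivial smooth
  cr$flat <- 0.3
  flat <- fit_yield_par_gams(cr, responses = "flat")
  expect_lt(flat$flat$deviance_explained, 1e-6)
  expect_equal(flat$flat$edf, 0)
})

test_that("noise-free bootstrap uncertainties collapse to zero", {
  par <- seq(1, 1500, length.out = 400)
  phi_psii <- 0.8 * exp(-par / 500)
  phi_no <- 0.18 + 0.05 * sin(pi * phi_psii / 0.8)  # one interior maximum
  rec <- data.frame(par = par, phi_psii = phi_psii, phi_no = phi_no)
  pa <- phase_analysis(rec, n_boot = 25, seed = 4)
  expect_equal(nrow(pa$breakpoints), 1L)
  expect_lt(pa$breakpoints$phi_psii_se, 0.01)
  expect_lt(pa$breakpoints$par_se, 10)
  expect_false(pa$breakpoints$extrapolated)
})

test_that("phase analysis of a dry campaign is reproducible end to end", {
  cfg <- synthetic_config(seed = 31, seasons = "dry")
  kept <- qc_filter(compute_yields(simulate_campaign(cfg)))$kept
  pa1 <- suppressWarnings(phase_analysis(kept, season = "dry", n_boot = 10,
                                         seed = 9))
  pa2 <- suppressWarnings(phase_analysis(kept, season = "dry", n_boot = 10,
                                         seed = 9))
  expect_equal(pa1$breakpoints, pa2$breakpoints)
  expect_equal(pa1$season, "dry")
  expect_true(all(c("phi_psii", "phi_psii_se", "direction", "par", "par_se",
                    "extrapolated") %in% names(pa1$breakpoints)))
  # mapped PAR decreases as breakpoint PhiPSII increases (monotone inversion)
  bp <- pa1$breakpoints[!pa1$breakpoints$extrapolated, ]
  if (nrow(bp) >= 2) {
    ord <- order(bp$phi_psii)
    expect_true(all(diff(bp$par[ord]) < 0))
  }
})
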