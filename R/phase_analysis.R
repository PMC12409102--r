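#' Penalized-spline fit of PhiNO on PhiPSII
#'
#' Smooths the relationship between nonregulated losses and photochemical
#' yield with a penalized regression spline, the substrate for
#' derivative-based breakpoint detection. Two knot policies are compared by
#' AIC: `"restricted"` (basis dimension 5) and `"unrestricted"` (basis
#' dimension 20); `knot_policy = "aic"` (default) fits both and keeps the
#' better one. Smoothness is selected by maximum likelihood.
#'
#' @param phi_psii,phi_no Paired numeric vectors (>= 50 observations).
#' @param knot_policy `"aic"`, `"unrestricted"` or `"restricted"`.
#' @param trim Quantile pair restricting the working PhiPSII range for
#'   derivative analysis (default `c(0.01, 0.99)`), avoiding the edge
#'   artifacts of penalized splines.
#' @return Object of class `phase_gam`: list with the mgcv `model`, `edf`,
#'   `deviance_explained`, `aic` (named for both policies), the policy used,
#'   and the trimmed working `range`.
#' @export
fit_phase_gam <- function(phi_psii, phi_no,
                          knot_policy = c("aic", "unrestricted", "restricted"),
                          trim = c(0.01, 0.99)) {
  knot_policy <- match.arg(knot_policy)
  keep <- is.finite(phi_psii) & is.finite(phi_no)
  x <- phi_psii[keep]; y <- phi_no[keep]
  if (length(x) < 50) stop("need >= 50 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate (constant) input", call. = FALSE)
  }
  dat <- data.frame(x = x, y = y)
  fits <- list(
    restricted = mgcv::gam(y ~ s(x, k = 5), data = dat, method = "ML"),
    unrestricted = mgcv::gam(y ~ s(x, k = 20), data = dat, method = "ML"))
  aics <- vapply(fits, stats::AIC, numeric(1))
  used <- switch(knot_policy,
                 aic = names(aics)[which.min(aics)],
                 knot_policy)
  model <- fits[[used]]
  structure(list(model = model, edf = sum(model$edf) - 1,
                 deviance_explained = summary(model)$dev.expl,
                 aic = aics, knot_policy = used,
                 range = unname(stats::quantile(x, trim)),
                 n = length(x), data = dat),
            class = "phase_gam")
}

#' @export
print.phase_gam <- function(x, ...) {
  cat(sprintf("PhiNO ~ s(PhiPSII) [%s knots; n = %d]\n", x$knot_policy, x$n))
  cat(sprintf("  edf = %.2f, deviance explained = %.3f\n",
              x$edf, x$deviance_explained))
  cat(sprintf("  AIC: restricted = %.1f, unrestricted = %.1f\n",
              x$aic["restricted"], x$aic["unrestricted"]))
  invisible(x)
}

# Evaluate a phase_gam (or any gam with covariate `x`) on new x values.
.predict_curve <- function(fit, x) {
  model <- if (inherits(fit, "phase_gam")) fit$model else fit
  as.vector(stats::predict(model, data.frame(x = x)))
}

#' Locate breakpoints as derivative sign changes
#'
#' Evaluates the fitted smooth on an even grid spanning the working range
#' (by default the 1st-99th percentile span of the observed PhiPSII),
#' computes the first derivative by central finite differences, and reports
#' every location where the derivative changes sign. Derivative magnitudes
#' below `slope_tol` are treated as zero so plateaus do not generate spurious
#' crossings; each breakpoint is placed by linear interpolation of the
#' derivative's zero crossing.
#'
#' @param fit A [fit_phase_gam()] object (or a bare mgcv fit on covariate
#'   `x`, in which case `lower`/`upper` are required).
#' @param grid_size Number of grid points (default 1000).
#' @param lower,upper Working range; defaults to the fit's trimmed range.
#' @param slope_tol Derivative magnitude treated as zero (default 1e-6).
#' @return data.frame with `phi_psii`, `direction` (`"+to-"` / `"-to+"`,
#'   read in increasing PhiPSII) and `derivative_gap`; zero rows when the
#'   curve is monotone.
#' @export
find_breakpoints <- function(fit, grid_size = 1000, lower = NULL, upper = NULL,
                             slope_tol = 1e-6) {
  if (inherits(fit, "phase_gam")) {
    if (is.null(lower)) lower <- fit$range[1]
    if (is.null(upper)) upper <- fit$range[2]
  }
  if (is.null(lower) || is.null(upper)) {
    stop("`lower` and `upper` are required for bare model objects",
         call. = FALSE)
  }
  grid <- seq(lower, upper, length.out = grid_size)
  f <- .predict_curve(fit, grid)
  h <- grid[2] - grid[1]
  d <- (f[-(1:2)] - f[seq_len(grid_size - 2)]) / (2 * h)
  xd <- grid[-c(1, grid_size)]
  s <- sign(d)
  s[abs(d) < slope_tol] <- 0
  nz <- which(s != 0)
  if (length(nz) < 2) {
    return(data.frame(phi_psii = numeric(), direction = character(),
                      derivative_gap = numeric()))
  }
  chg <- which(s[nz][-1] != s[nz][-length(nz)])
  if (!length(chg)) {
    return(data.frame(phi_psii = numeric(), direction = character(),
                      derivative_gap = numeric()))
  }
  i1 <- nz[chg]; i2 <- nz[chg + 1]
  x0 <- xd[i1] + d[i1] * (xd[i2] - xd[i1]) / (d[i1] - d[i2])
  data.frame(phi_psii = x0,
             direction = ifelse(s[i1] > 0, "+to-", "-to+"),
             derivative_gap = xd[i2] - xd[i1], row.names = NULL)
}

#' Label PQ-limited, NPQ-limited and stress phases
#'
#' Cuts the working PhiPSII range at the breakpoints and labels each segment
#' from the sign of the fitted slope: a negative-slope segment on the
#' high-PhiPSII (low irradiance) side is photochemical-quenching limited
#' ("PQ-limited"); positive-slope segments are NPQ-limited; a negative-slope
#' segment below the NPQ-limited region (high irradiance) is the high-stress
#' phase. With more than two breakpoints all segments are still labeled by
#' this rule, with a warning. Every point of the range receives exactly one
#' label.
#'
#' @param breakpoints Output of [find_breakpoints()].
#' @param fit The fitted [fit_phase_gam()] object.
#' @param lower,upper Working range; defaults to the fit's trimmed range.
#' @return data.frame with `lower`, `upper`, `slope_sign`, `phase`, ordered
#'   by increasing PhiPSII.
#' @export
classify_phases <- function(breakpoints, fit, lower = NULL, upper = NULL) {
  if (inherits(fit, "phase_gam")) {
    if (is.null(lower)) lower <- fit$range[1]
    if (is.null(upper)) upper <- fit$range[2]
  }
  if (nrow(breakpoints) > 2) {
    warning("more than two breakpoints; labeling all segments by slope and ",
            "ordering", call. = FALSE)
  }
  edges <- c(lower, sort(breakpoints$phi_psii), upper)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  eps <- (upper - lower) * 1e-4
  slope <- (.predict_curve(fit, mids + eps) -
              .predict_curve(fit, mids - eps)) / (2 * eps)
  sgn <- ifelse(slope >= 0, 1, -1)
  n_seg <- length(mids)
  phase <- character(n_seg)
  pos <- which(sgn > 0)
  top_pos <- if (length(pos)) max(pos) else 0L
  for (i in seq_len(n_seg)) {
    phase[i] <- if (sgn[i] > 0) "NPQ-limited"
                else if (i > top_pos) "PQ-limited"
                else "stress"
  }
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             slope_sign = sgn, phase = phase, row.names = NULL)
}

#' Per-yield smooths against PAR
#'
#' Fits one penalized-spline GAM per quantum yield (and optionally qL/NPQt)
#' against PAR, reporting effective degrees of freedom and deviance
#' explained. The PhiPSII fit doubles as the monotone light-response curve
#' used to map breakpoints to PAR.
#'
#' @param records data.frame with `par` and the response columns.
#' @param season Optional season filter (requires a `season` column).
#' @param responses Response columns (default the three yields).
#' @param k Basis dimension (default 20).
#' @return Named list of class `yield_par_gams`; each element holds `model`,
#'   `edf`, `deviance_explained`, `n`.
#' @export
fit_yield_par_gams <- function(records, season = NULL,
                               responses = c("phi_psii", "phi_no", "phi_npq"),
                               k = 20) {
  stopifnot(is.data.frame(records), "par" %in% names(records),
            all(responses %in% names(records)))
  if (!is.null(season)) {
    stopifnot("season" %in% names(records))
    records <- records[records$season == season, , drop = FALSE]
  }
  if (nrow(records) < 50) stop("need >= 50 records", call. = FALSE)
  out <- lapply(responses, function(resp) {
    dat <- data.frame(x = records$par, y = records[[resp]])
    dat <- dat[stats::complete.cases(dat), ]
    if (stats::sd(dat$y) < 1e-12) {
      # degenerate response: intercept-only fit, nothing to explain
      model <- mgcv::gam(y ~ 1, data = dat)
      return(list(model = model, edf = 0, deviance_explained = 0,
                  n = nrow(dat), par_range = range(dat$x)))
    }
    model <- mgcv::gam(y ~ s(x, k = k), data = dat, method = "ML")
    list(model = model, edf = sum(model$edf) - 1,
         deviance_explained = summary(model)$dev.expl, n = nrow(dat),
         par_range = range(dat$x))
  })
  names(out) <- responses
  class(out) <- "yield_par_gams"
  out
}

#' Map a PhiPSII breakpoint to PAR
#'
#' Inverts the season's fitted monotone-decreasing PhiPSII light response:
#' the PAR at a breakpoint is where the fitted PhiPSII(PAR) curve crosses the
#' breakpoint value, found by linear interpolation on a dense grid.
#' Breakpoints outside the fitted PhiPSII range are flagged as extrapolated
#' and get no PAR value.
#'
#' @param bp_phi_psii Breakpoint PhiPSII value(s).
#' @param psii_par_fit Either the `phi_psii` element of
#'   [fit_yield_par_gams()] or the whole list.
#' @param grid_size Inversion grid size (default 2000).
#' @return data.frame with `phi_psii`, `par`, `extrapolated`.
#' @export
map_breakpoint_to_par <- function(bp_phi_psii, psii_par_fit,
                                  grid_size = 2000) {
  if (inherits(psii_par_fit, "yield_par_gams")) {
    psii_par_fit <- psii_par_fit$phi_psii
  }
  rng <- psii_par_fit$par_range
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  f <- as.vector(stats::predict(psii_par_fit$model, data.frame(x = grid)))
  par_at <- vapply(bp_phi_psii, function(bp) {
    dif <- f - bp
    cross <- which(dif[-1] * dif[-length(dif)] <= 0)
    if (!length(cross)) return(NA_real_)
    i <- cross[1]
    grid[i] + (grid[i + 1] - grid[i]) * dif[i] / (dif[i] - dif[i + 1])
  }, numeric(1))
  data.frame(phi_psii = bp_phi_psii, par = par_at,
             extrapolated = is.na(par_at), row.names = NULL)
}

#' Full breakpoint and phase analysis for one season
#'
#' Chains the season's PhiNO-PhiPSII smooth, derivative breakpoint search,
#' phase classification, and PAR mapping through the inverted PhiPSII light
#' response. Uncertainty on breakpoint locations and mapped PAR comes from a
#' seeded nonparametric bootstrap over records: each replicate refits both
#' smooths, relocates breakpoints (matched to the originals by proximity) and
#' re-inverts the light response.
#'
#' @param records Quality-controlled records with `phi_psii`, `phi_no`,
#'   `par` (and `season` if `season` is given).
#' @param season Optional season filter.
#' @param knot_policy Passed to [fit_phase_gam()].
#' @param grid_size Derivative grid size (default 1000).
#' @param n_boot Bootstrap replicates (default 200; 0 skips uncertainty).
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `breakpoint_result`: list with `season`,
#'   `breakpoints` (data.frame: `phi_psii`, `phi_psii_se`, `direction`,
#'   `par`, `par_se`, `extrapolated`), `phases`, `fit` diagnostics (edf,
#'   deviance explained, AIC table), `psii_par` diagnostics, `n`, `n_boot`.
#' @export
phase_analysis <- function(records, season = NULL,
                           knot_policy = c("aic", "unrestricted", "restricted"),
                           grid_size = 1000, n_boot = 200, seed = 1L) {
  knot_policy <- match.arg(knot_policy)
  if (!is.null(season)) {
    stopifnot("season" %in% names(records))
    records <- records[records$season == season, , drop = FALSE]
  }
  need <- c("phi_psii", "phi_no", "par")
  stopifnot(all(need %in% names(records)))
  records <- records[stats::complete.cases(records[need]), , drop = FALSE]

  fit <- fit_phase_gam(records$phi_psii, records$phi_no,
                       knot_policy = knot_policy)
  bps <- find_breakpoints(fit, grid_size = grid_size)
  phases <- classify_phases(bps, fit)
  ypg <- fit_yield_par_gams(records, responses = "phi_psii")
  mapped <- map_breakpoint_to_par(bps$phi_psii, ypg)

  bp_se <- par_se <- rep(NA_real_, nrow(bps))
  if (n_boot > 0 && nrow(bps) > 0) {
    set.seed(seed)
    boot_bp <- matrix(NA_real_, n_boot, nrow(bps))
    boot_par <- matrix(NA_real_, n_boot, nrow(bps))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(records), replace = TRUE)
      rb <- records[idx, , drop = FALSE]
      fb <- tryCatch(fit_phase_gam(rb$phi_psii, rb$phi_no,
                                   knot_policy = fit$knot_policy),
                     error = function(e) NULL)
      if (is.null(fb)) next
      bb <- find_breakpoints(fb, grid_size = grid_size)
      if (!nrow(bb)) next
      yb <- tryCatch(fit_yield_par_gams(rb, responses = "phi_psii"),
                     error = function(e) NULL)
      for (j in seq_len(nrow(bps))) {
        cand <- bb[bb$direction == bps$direction[j], , drop = FALSE]
        if (!nrow(cand)) next
        jj <- which.min(abs(cand$phi_psii - bps$phi_psii[j]))
        boot_bp[b, j] <- cand$phi_psii[jj]
        if (!is.null(yb)) {
          boot_par[b, j] <- map_breakpoint_to_par(cand$phi_psii[jj], yb)$par
        }
      }
    }
    bp_se <- apply(boot_bp, 2, stats::sd, na.rm = TRUE)
    par_se <- apply(boot_par, 2, stats::sd, na.rm = TRUE)
  }

  breakpoints <- data.frame(phi_psii = bps$phi_psii, phi_psii_se = bp_se,
                            direction = bps$direction, par = mapped$par,
                            par_se = par_se,
                            extrapolated = mapped$extrapolated,
                            row.names = NULL)
  structure(list(season = if (is.null(season)) NA_character_ else season,
                 breakpoints = breakpoints, phases = phases,
                 edf = fit$edf, deviance_explained = fit$deviance_explained,
                 aic = fit$aic, knot_policy = fit$knot_policy,
                 psii_par_edf = ypg$phi_psii$edf,
                 psii_par_deviance = ypg$phi_psii$deviance_explained,
                 n = fit$n, n_boot = n_boot, fit = fit),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  cat("Phase analysis",
      if (!is.na(x$season)) paste0("(", x$season, " season)"),
      sprintf("[n = %d, %s knots, edf = %.2f, dev.expl = %.3f]\n",
              x$n, x$knot_policy, x$edf, x$deviance_explained))
  bp <- x$breakpoints
  if (!nrow(bp)) {
    cat("  no breakpoints: monotone relationship\n")
  } else {
    for (i in seq_len(nrow(bp))) {
      cat(sprintf("  breakpoint at PhiPSII = %.3f (+-%.3f) [%s], PAR = %s\n",
                  bp$phi_psii[i], bp$phi_psii_se[i], bp$direction[i],
                  if (bp$extrapolated[i]) "extrapolated" else
                    sprintf("%.1f (+-%.1f)", bp$par[i], bp$par_se[i])))
    }
  }
  ph <- x$phases
  cat("  phases (increasing PhiPSII): ",
      paste(sprintf("%s [%.3f, %.3f]", ph$phase, ph$lower, ph$upper),
            collapse = " | "), "\n", sep = "")
  invisible(x)
}
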