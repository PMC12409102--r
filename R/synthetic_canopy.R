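#' Configuration for the synthetic canopy campaign generator
#'
#' Bundles every parameter of the seeded field-campaign simulator: sampling
#' design (trees per stratum, three crown positions per tree, leaves per
#' branch, species pool sizes), canopy optics (leaf-area-density layers,
#' Beer-Lambert extinction, lognormal sunfleck noise), microclimate trends
#' (top-of-canopy PAR, VPD and temperature gradients), leaf physiology
#' response curves (saturating NPQt and declining qL light responses with a
#' VPD multiplier and lognormal species effects on NPQt) and measurement
#' noise. The wet and dry seasons share all physiology except `par_top`,
#' `npq_max`, `beta_vpd` and the species-effect sd.
#'
#' Defaults emulate a two-season campaign in a tall tropical forest: PAR and
#' VPD increase with height; the dry season reaches high irradiance
#' (`par_top = 2200` umol m-2 s-1) under which saturated NPQt no longer
#' compensates the continuing qL decline, so the nonregulated-loss yield rises
#' again at extreme PAR and the relationship between PhiNO and PhiPSII becomes
#' triphasic; the cloudier wet season (`par_top = 550`, diffuse light) stays
#' below that regime and shows a single interior breakpoint.
#'
#' @param seed Integer seed; fully determines the generated campaign.
#' @param n_trees_per_stratum Trees sampled in each of the three strata.
#' @param branches_per_tree Crown positions sampled per tree (bottom, middle,
#'   top); fixed design of 3.
#' @param leaves_per_branch Leaves measured on each branch (>= 3).
#' @param seasons Character subset of `c("wet", "dry")`.
#' @param strata_tree_heights List of length-2 numeric ranges (m) from which
#'   tree-top heights are drawn uniformly in each stratum.
#' @param crown_fractions Branch heights as fractions of tree height.
#' @param lad_layers data.frame with `h_lo`, `h_hi`, `lai`: leaf-area-index
#'   layers of the canopy (two-layer default: dense understory below 20 m,
#'   upper crown 25-45 m).
#' @param extinction_k Light-extinction coefficient per unit leaf-area index.
#' @param sunfleck_sigma Lognormal sd of multiplicative PAR noise (sunflecks
#'   and shading).
#' @param par_top Named vector, top-of-canopy PAR per season (umol m-2 s-1).
#' @param vpd_floor,vpd_top Forest-floor VPD and named per-season
#'   top-of-canopy VPD (kPa); linear height trend between them.
#' @param vpd_noise_sd Gaussian noise sd on VPD (kPa).
#' @param temp_floor,temp_top,temp_noise_sd Air-temperature trend (deg C) and
#'   noise.
#' @param n_species Named vector, species-pool size per season.
#' @param species_sd Named vector, sd of the lognormal species random effect
#'   on NPQt per season.
#' @param npq_max Named vector, per-season asymptote of the NPQt light
#'   response.
#' @param npq_par50,npq_hill Half-saturation PAR and Hill exponent of the
#'   NPQt light response.
#' @param beta_vpd Named vector, linear VPD multiplier on NPQt per season.
#' @param ql_floor,ql_par50,ql_m Floor, half-decline PAR and shape of the
#'   declining qL light response.
#' @param npq_noise_sd Lognormal biological noise sd on NPQt.
#' @param ql_noise_sd Lognormal noise sd on the closed fraction `1 - qL`.
#' @param fluor_gain_sd,fs_noise_sd,ratio_noise_sd Multiplicative
#'   measurement noise on the fluorescence channels: a gain factor common to
#'   Fs/Fm'/Fo' (which cancels from every derived ratio), an Fs-specific
#'   jitter, and an optional independent Fm'/Fo' jitter. The last defaults
#'   to 0 because it distorts the Fm'/Fo' ratio and makes measured NPQt
#'   negative wherever the true value is near zero (deep shade), so the set
#'   of quality-control rejections would no longer coincide with the
#'   deliberately corrupted rows.
#' @param corrupt_frac Fraction of rows corrupted (Fs pushed above Fm') to
#'   exercise quality control.
#' @param k_dark Assumed dark-adapted `Fm/Fo - 1` (default 4.88).
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [simulate_campaign()], [canopy_response_curve()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_trees_per_stratum = 25L,
                             branches_per_tree = 3L,
                             leaves_per_branch = 5L,
                             seasons = c("wet", "dry"),
                             strata_tree_heights = list(S1 = c(8, 19),
                                                        S2 = c(22, 38),
                                                        S3 = c(41, 50)),
                             crown_fractions = c(bottom = 0.55, middle = 0.75,
                                                 top = 0.95),
                             lad_layers = data.frame(h_lo = c(0, 25),
                                                     h_hi = c(20, 45),
                                                     lai = c(4, 3)),
                             extinction_k = 0.55,
                             sunfleck_sigma = 0.35,
                             par_top = c(wet = 550, dry = 2200),
                             vpd_floor = 0.8,
                             vpd_top = c(wet = 2.4, dry = 3.2),
                             vpd_noise_sd = 0.6,
                             temp_floor = 26,
                             temp_top = 31,
                             temp_noise_sd = 0.4,
                             n_species = c(wet = 14L, dry = 18L),
                             species_sd = c(wet = 0.15, dry = 0.25),
                             npq_max = c(wet = 6.5, dry = 2.4),
                             npq_par50 = 300,
                             npq_hill = 3,
                             beta_vpd = c(wet = 0.05, dry = 0.08),
                             ql_floor = 0.02,
                             ql_par50 = 120,
                             ql_m = 0.5,
                             npq_noise_sd = 0.12,
                             ql_noise_sd = 0.08,
                             fluor_gain_sd = 0.01,
                             fs_noise_sd = 0.004,
                             ratio_noise_sd = 0,
                             corrupt_frac = 0.05,
                             k_dark = 4.88) {
  seasons <- match.arg(seasons, c("wet", "dry"), several.ok = TRUE)
  cfg <- list(seed = as.integer(seed),
              n_trees_per_stratum = as.integer(n_trees_per_stratum),
              branches_per_tree = as.integer(branches_per_tree),
              leaves_per_branch = as.integer(leaves_per_branch),
              seasons = seasons,
              strata_tree_heights = strata_tree_heights,
              crown_fractions = crown_fractions,
              lad_layers = lad_layers,
              extinction_k = extinction_k,
              sunfleck_sigma = sunfleck_sigma,
              par_top = par_top,
              vpd_floor = vpd_floor, vpd_top = vpd_top,
              vpd_noise_sd = vpd_noise_sd,
              temp_floor = temp_floor, temp_top = temp_top,
              temp_noise_sd = temp_noise_sd,
              n_species = n_species, species_sd = species_sd,
              npq_max = npq_max, npq_par50 = npq_par50, npq_hill = npq_hill,
              beta_vpd = beta_vpd,
              ql_floor = ql_floor, ql_par50 = ql_par50, ql_m = ql_m,
              npq_noise_sd = npq_noise_sd, ql_noise_sd = ql_noise_sd,
              fluor_gain_sd = fluor_gain_sd,
              fs_noise_sd = fs_noise_sd,
              ratio_noise_sd = ratio_noise_sd,
              corrupt_frac = corrupt_frac,
              k_dark = k_dark)
  scalars <- c("extinction_k", "sunfleck_sigma", "vpd_floor", "vpd_noise_sd",
               "temp_noise_sd", "npq_par50", "npq_hill", "ql_par50", "ql_m",
               "npq_noise_sd", "ql_noise_sd", "fluor_gain_sd",
               "fs_noise_sd", "ratio_noise_sd", "k_dark")
  for (nm in scalars) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 0) {
      stop("`", nm, "` must be a single nonnegative number", call. = FALSE)
    }
  }
  for (nm in c("par_top", "vpd_top", "npq_max", "beta_vpd", "species_sd")) {
    if (!all(seasons %in% names(cfg[[nm]]))) {
      stop("`", nm, "` must be named for every season in `seasons`",
           call. = FALSE)
    }
  }
  if (cfg$leaves_per_branch < 3L) {
    stop("`leaves_per_branch` must be >= 3", call. = FALSE)
  }
  if (cfg$ql_floor <= 0 || cfg$ql_floor >= 1) {
    stop("`ql_floor` must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$corrupt_frac < 0 || cfg$corrupt_frac >= 1) {
    stop("`corrupt_frac` must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  n_leaf <- 3L * x$n_trees_per_stratum * x$branches_per_tree *
    x$leaves_per_branch
  cat("Synthetic canopy campaign configuration\n")
  cat("  seasons:", paste(x$seasons, collapse = ", "),
      " | records per season:", n_leaf, "\n")
  cat("  design: 3 strata x", x$n_trees_per_stratum, "trees x",
      x$branches_per_tree, "branches x", x$leaves_per_branch, "leaves\n")
  cat("  par_top:", paste(names(x$par_top), x$par_top, collapse = ", "),
      "| seed:", x$seed, "\n")
  invisible(x)
}

# Cumulative leaf-area index above height h for the layered canopy.
.lai_above <- function(height, layers) {
  vapply(height, function(h) {
    above <- pmax(pmin(layers$h_hi, Inf) - pmax(layers$h_lo, h), 0)
    sum(layers$lai * above / (layers$h_hi - layers$h_lo))
  }, numeric(1))
}

# Deterministic microclimate trends with height.
.par_mean <- function(height, season, config) {
  unname(config$par_top[season]) *
    exp(-config$extinction_k * .lai_above(height, config$lad_layers))
}

.vpd_mean <- function(height, season, config) {
  top <- max(config$lad_layers$h_hi)
  frac <- pmin(height / top, 1)
  config$vpd_floor + (unname(config$vpd_top[season]) - config$vpd_floor) * frac
}

.temp_mean <- function(height, config) {
  top <- max(config$lad_layers$h_hi)
  frac <- pmin(height / top, 1)
  config$temp_floor + (config$temp_top - config$temp_floor) * frac
}

#' Simulate leaf-level microenvironment at given heights
#'
#' Expected PAR follows Beer-Lambert extinction of the top-of-canopy
#' irradiance through the cumulative leaf area above each height, with
#' multiplicative lognormal sunfleck noise (unit mean). VPD and air
#' temperature interpolate their floor-to-top trends with additive Gaussian
#' noise; relative humidity is back-computed from VPD and temperature so that
#' [derive_vpd()] round-trips. Uses the current RNG state.
#'
#' @param height Numeric vector of heights above ground (m, >= 0).
#' @param season `"wet"` or `"dry"`.
#' @param config A [synthetic_config()].
#' @return data.frame with columns `par`, `air_temp`, `rh`, `vpd`.
#' @export
simulate_microenvironment <- function(height, season, config) {
  stopifnot(inherits(config, "synthetic_config"))
  season <- match.arg(season, c("wet", "dry"))
  if (any(height < 0)) stop("`height` must be >= 0", call. = FALSE)
  n <- length(height)
  sig <- config$sunfleck_sigma
  par <- .par_mean(height, season, config) *
    stats::rlnorm(n, meanlog = -sig^2 / 2, sdlog = sig)
  vpd <- pmax(.vpd_mean(height, season, config) +
                stats::rnorm(n, 0, config$vpd_noise_sd), 0.05)
  air_temp <- .temp_mean(height, config) +
    stats::rnorm(n, 0, config$temp_noise_sd)
  es <- 0.61078 * exp(17.27 * air_temp / (air_temp + 237.3))
  rh <- pmin(pmax(100 * (1 - vpd / es), 1), 100)
  # keep vpd consistent with the clamped rh
  vpd <- es * (1 - rh / 100)
  data.frame(par = par, air_temp = air_temp, rh = rh, vpd = vpd)
}

#' Noise-free regulatory state implied by the generator physiology
#'
#' The expected NPQt follows a Hill-saturating light response scaled by a
#' linear VPD multiplier; the expected qL declines from 1 at darkness toward
#' `ql_floor` as a shifted power law:
#' `E(NPQt) = npq_max PAR^n / (par50^n + PAR^n) (1 + beta_vpd VPD)` and
#' `E(qL) = ql_floor + (1 - ql_floor) / (1 + PAR/ql_par50)^m`.
#'
#' @param par PAR, umol m-2 s-1 (>= 0).
#' @param vpd VPD, kPa.
#' @inheritParams simulate_microenvironment
#' @return data.frame with columns `ql`, `npqt`.
#' @export
photostate_mean <- function(par, vpd, season, config) {
  stopifnot(inherits(config, "synthetic_config"))
  season <- match.arg(season, c("wet", "dry"))
  if (any(par < 0)) stop("`par` must be >= 0", call. = FALSE)
  n <- config$npq_hill
  npqt <- unname(config$npq_max[season]) * par^n /
    (config$npq_par50^n + par^n) * (1 + unname(config$beta_vpd[season]) * vpd)
  ql <- config$ql_floor +
    (1 - config$ql_floor) / (1 + par / config$ql_par50)^config$ql_m
  data.frame(ql = ql, npqt = npqt)
}

#' Simulate the leaf regulatory state (qL, NPQt)
#'
#' Draws a noisy regulatory state around [photostate_mean()]: NPQt is
#' multiplied by the lognormal species effect `exp(species_effect)` and
#' unit-mean lognormal biological noise; the closed fraction `1 - qL` gets
#' unit-mean lognormal noise, keeping `qL` in `(0, 1]` and leaving the
#' darkness limit (`PAR = 0`: `qL = 1`, `NPQt = 0`) exact even under noise.
#' Uses the current RNG state.
#'
#' @inheritParams photostate_mean
#' @param species_effect Per-record species random effect on `log(NPQt)`.
#' @return data.frame with columns `ql`, `npqt`.
#' @export
simulate_photostate <- function(par, vpd, species_effect, season, config) {
  mu <- photostate_mean(par, vpd, season, config)
  n <- nrow(mu)
  s_npq <- config$npq_noise_sd
  npqt <- mu$npqt * exp(species_effect +
                          stats::rnorm(n, -s_npq^2 / 2, s_npq))
  s_ql <- config$ql_noise_sd
  closed <- (1 - mu$ql) * exp(stats::rnorm(n, -s_ql^2 / 2, s_ql))
  ql <- pmin(pmax(1 - closed, 1e-6), 1)
  data.frame(ql = ql, npqt = npqt)
}

#' Noise-free canopy response curve
#'
#' Composes the deterministic microclimate trends and the noise-free
#' physiology into the expected regulatory state and quantum yields along a
#' height grid. The closed forms
#' `PhiPSII = k qL / (k qL + 1 + NPQt)` and `PhiNO = 1 / (1 + k qL + NPQt)`
#' follow from the forward fluorescence model. This is the analytic truth
#' against which breakpoint recovery is judged.
#'
#' @inheritParams simulate_microenvironment
#' @param heights Height grid (m); default spans the canopy densely.
#' @return data.frame with `height`, `par`, `vpd`, `ql`, `npqt`, `phi_psii`,
#'   `phi_no`, `phi_npq`, ordered by increasing PAR.
#' @export
canopy_response_curve <- function(config, season,
                                  heights = seq(0.5, 49.5, by = 0.02)) {
  stopifnot(inherits(config, "synthetic_config"))
  season <- match.arg(season, c("wet", "dry"))
  par <- .par_mean(heights, season, config)
  vpd <- .vpd_mean(heights, season, config)
  st <- photostate_mean(par, vpd, season, config)
  k <- config$k_dark
  phi_no <- 1 / (1 + k * st$ql + st$npqt)
  phi_psii <- k * st$ql / (k * st$ql + 1 + st$npqt)
  out <- data.frame(height = heights, par = par, vpd = vpd,
                    ql = st$ql, npqt = st$npqt,
                    phi_psii = phi_psii, phi_no = phi_no,
                    phi_npq = 1 - phi_psii - phi_no)
  out[order(out$par), , drop = FALSE]
}

#' Analytic extrema of the noise-free PhiNO-PhiPSII relationship
#'
#' Scans the noise-free [canopy_response_curve()] for interior sign changes of
#' `dPhiNO/dPAR`. The maximum (rise-to-fall going up in PAR) is the
#' generator's true phase-shift breakpoint between the PQ-limited and
#' NPQ-limited regimes; a minimum at high PAR marks the onset of the stress
#' phase.
#'
#' @inheritParams canopy_response_curve
#' @return data.frame with columns `type` (`"max"`/`"min"`), `par`,
#'   `phi_psii`, `phi_no`; zero rows when the curve is monotone.
#' @export
analytic_extrema <- function(config, season) {
  cr <- canopy_response_curve(config, season)
  d <- diff(cr$phi_no)
  s <- sign(d)
  idx <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1L
  if (!length(idx)) {
    return(data.frame(type = character(), par = numeric(),
                      phi_psii = numeric(), phi_no = numeric()))
  }
  data.frame(type = ifelse(s[idx] < 0, "max", "min"),
             par = cr$par[idx], phi_psii = cr$phi_psii[idx],
             phi_no = cr$phi_no[idx], row.names = NULL)
}

#' Simulate a full seeded canopy campaign
#'
#' Generates the raw measurement table of a field campaign under the
#' configured design: for each season, trees are placed in the three strata,
#' three crown-position branches per tree carry `leaves_per_branch` leaves,
#' each leaf gets a microenvironment draw, a species-and-noise-perturbed
#' regulatory state, and raw fluorescence `(Fs, Fm', Fo')` emitted through
#' [forward_fluorescence()] with multiplicative measurement noise. A seeded
#' fraction of rows is corrupted (`Fs` pushed above `Fm'`, flagged in the
#' `corrupted` column) to exercise [qc_filter()]. The output is fully
#' determined by `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return data.frame with one row per leaf measurement: design identifiers
#'   (`season`, `tree_id`, `species`, `branch_position`, `leaf_id`),
#'   `height_m`, microenvironment (`par`, `air_temp`, `rh`, `vpd`), raw
#'   fluorescence (`fs`, `fm_prime`, `fo_prime`) and `corrupted`. The
#'   configuration is attached as attribute `"config"`.
#' @export
simulate_campaign <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  pieces <- list()
  for (season in config$seasons) {
    n_sp <- unname(config$n_species[season])
    pool <- sprintf("%s_sp%02d", season, seq_len(n_sp))
    sp_eff <- stats::rnorm(n_sp, 0, unname(config$species_sd[season]))
    names(sp_eff) <- pool
    for (stratum in names(config$strata_tree_heights)) {
      rng <- config$strata_tree_heights[[stratum]]
      n_tr <- config$n_trees_per_stratum
      tree_h <- stats::runif(n_tr, rng[1], rng[2])
      tree_sp <- sample(pool, n_tr, replace = TRUE)
      for (i in seq_len(n_tr)) {
        tree_id <- sprintf("%s_%s_t%02d", season, stratum, i)
        for (bp in names(config$crown_fractions)[seq_len(config$branches_per_tree)]) {
          bh <- tree_h[i] * config$crown_fractions[[bp]]
          nl <- config$leaves_per_branch
          leaf_h <- pmax(bh + stats::runif(nl, -0.5, 0.5), 0.3)
          env <- simulate_microenvironment(leaf_h, season, config)
          st <- simulate_photostate(env$par, env$vpd,
                                    rep(sp_eff[tree_sp[i]], nl),
                                    season, config)
          pieces[[length(pieces) + 1L]] <- data.frame(
            season = season, tree_id = tree_id, species = tree_sp[i],
            branch_position = bp, leaf_id = seq_len(nl),
            height_m = leaf_h, env, ql_true = st$ql, npqt_true = st$npqt)
        }
      }
    }
  }
  tab <- do.call(rbind, pieces)
  rownames(tab) <- NULL

  fl <- forward_fluorescence(tab$ql_true, tab$npqt_true, config$k_dark)
  n <- nrow(tab)
  gain <- exp(stats::rnorm(n, 0, config$fluor_gain_sd))
  ch <- function(sd) exp(stats::rnorm(n, 0, sd))
  tab$fs <- fl$fs * gain * ch(config$fs_noise_sd)
  tab$fm_prime <- fl$fm_prime * gain * ch(config$ratio_noise_sd)
  tab$fo_prime <- fl$fo_prime * gain * ch(config$ratio_noise_sd)
  tab$ql_true <- NULL
  tab$npqt_true <- NULL

  tab$corrupted <- FALSE
  n_bad <- round(config$corrupt_frac * n)
  if (n_bad > 0) {
    idx <- sample.int(n, n_bad)
    tab$fs[idx] <- tab$fm_prime[idx] * stats::runif(n_bad, 1.02, 1.15)
    tab$corrupted[idx] <- TRUE
  }
  attr(tab, "config") <- config
  tab
}
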