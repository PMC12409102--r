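# Shared simulated regression fixture: response linear in standardized PAR
# with species intercepts and small residual noise.
sim_lmm_data <- function(n = 400, n_sp = 12, beta_par = 0.1, sp_sd = 0.05,
                         resid_sd = 0.01, seed = 1) {
  set.seed(seed)
  sp <- factor(sample(paste0("sp", seq_len(n_sp)), n, replace = TRUE))
  sp_eff <- rnorm(n_sp, 0, sp_sd)
  par <- rlnorm(n, 5, 0.8)
  vpd <- rnorm(n, 2, 0.5)
  height_m <- runif(n, 1, 48)
  y <- 0.5 + beta_par * as.numeric(scale(par)) +
    sp_eff[as.integer(sp)] + rnorm(n, 0, resid_sd)
  data.frame(y = y, par = par, vpd = vpd, height_m = height_m, species = sp)
}

test_that("mixed model recovers standardized coefficients", {
  dat <- sim_lmm_data()
  fit <- fit_lmm(dat, "y")
  cf <- fit$coefficients
  b_par <- cf[cf$term == "par", ]
  expect_equal(b_par$estimate, 0.1, tolerance = 0.02)
  expect_true(b_par$significant)
  for (tm in c("vpd", "height_m")) {
    row <- cf[cf$term == tm, ]
    expect_true(row$ci_lo < 0 && row$ci_hi > 0)  # CIs cover zero
  }
  expect_gt(fit$var_random, 0)
  expect_equal(fit$n, 400L)
})

test_that("deterministic limit gives exact coefficients and R2 near 1", {
  set.seed(3)
  n <- 200
  dat <- data.frame(par = rnorm(n), vpd = rnorm(n), height_m = rnorm(n),
                    species = factor(rep(paste0("s", 1:5), each = 40)))
  dat$y <- 0.4 + 0.2 * as.numeric(scale(dat$par)) + rnorm(n, 0, 1e-8)
  expect_warning(fit <- fit_lmm(dat, "y"), "singular")
  expect_true(fit$singular)
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "par"], 0.2, tolerance = 1e-6)
  expect_equal(fit$r2_marginal, fit$r2_conditional)
  expect_gt(fit$r2_marginal, 0.999)
})

test_that("a response independent of everything has near-zero marginal R2", {
  set.seed(9)
  dat <- sim_lmm_data(beta_par = 0, sp_sd = 0, resid_sd = 1, seed = 9)
  fit <- suppressWarnings(fit_lmm(dat, "y"))
  expect_lt(fit$r2_marginal, 0.03)
})

test_that("variance-component R2 matches configured components", {
  # components: var_fixed = 1, var_random = 0.5, var_resid = 0.5
  # (many species so the realized random-effect variance is close to 0.5)
  set.seed(11)
  n <- 5000
  sp <- factor(rep(paste0("s", 1:200), length.out = n))
  sp_eff <- rnorm(200, 0, sqrt(0.5))
  dat <- data.frame(par = rnorm(n), vpd = rnorm(n), height_m = rnorm(n),
                    species = sp)
  dat$y <- dat$par + sp_eff[as.integer(sp)] + rnorm(n, 0, sqrt(0.5))
  fit <- fit_lmm(dat, "y")
  r2 <- r2_nakagawa(fit)
  expect_equal(r2$marginal, 0.5, tolerance = 0.04)
  expect_equal(r2$conditional, 0.75, tolerance = 0.04)
  expect_equal(r2$species_share, fit$r2_conditional - fit$r2_marginal)
})

test_that("VIF follows its closed form", {
  set.seed(5)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  dat <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- vif(dat, c("x1", "x2", "x3"))
  expect_true(all(abs(v - 1) < 0.05))
  # explained variance share 0.75 -> VIF 4
  dat$x4 <- sqrt(3) * dat$x1 + rnorm(n)
  v4 <- vif(dat, c("x1", "x4", "x2"))
  expect_equal(unname(v4["x4"]), 4, tolerance = 0.3)
  # exact collinearity
  dat$x5 <- dat$x1 + dat$x2
  expect_warning(v5 <- vif(dat, c("x1", "x2", "x5")), "collinearity")
  expect_true(is.infinite(v5["x5"]))
})

# Beta-likelihood GAMM fixture: saturating PAR response on the logit scale,
# both seasons, species random intercepts.
sim_gamm_data <- function(n = 600, seed = 2, dry_shift = 0, phi = 60) {
  set.seed(seed)
  season <- factor(rep(c("wet", "dry"), each = n / 2))
  par <- runif(n, 5, 1500)
  vpd <- runif(n, 0.5, 3.5)
  height_m <- runif(n, 1, 48)
  species <- factor(sample(paste0("sp", 1:10), n, replace = TRUE))
  eta <- qlogis(0.25) + 1.2 * par / (par + 300) +
    ifelse(season == "dry", dry_shift, 0)
  mu <- plogis(eta)
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  data.frame(y = y, par = par, vpd = vpd, height_m = height_m,
             season = season, species = species, mu_true = mu)
}

test_that("beta GAMM recovers a saturating smooth and near-linear edf", {
  dat <- sim_gamm_data()
  fit <- fit_gamm(dat, "y")
  expect_s3_class(fit$model, "gam")
  expect_true(all(fit$smooths$edf >= 0))
  expect_gt(fit$deviance_explained, 0.4)
  # fitted mean close to truth over the bulk of the PAR range
  inner <- dat$par > quantile(dat$par, 0.05) &
    dat$par < quantile(dat$par, 0.95)
  pred <- predict(fit$model, dat, type = "response",
                  exclude = "s(species)")
  expect_lt(max(abs(pred[inner] - dat$mu_true[inner])), 0.06)
})

test_that("constant and linear responses shrink to trivial smooths", {
  set.seed(4)
  n <- 500
  dat <- data.frame(par = runif(n, 0, 1000), vpd = runif(n, 0, 3),
                    height_m = runif(n, 0, 45),
                    season = factor(rep(c("wet", "dry"), length.out = n)),
                    species = factor(rep(paste0("s", 1:6), length.out = n)))
  dat$y <- 0.4 + rnorm(n, 0, 0.01)  # essentially constant
  fit <- fit_gamm(dat, "y")
  expect_lt(fit$deviance_explained, 0.1)
  expect_true(all(fit$smooths$edf[fit$smooths$term != "species"] < 3))
  # linear-in-PAR truth on the logit scale: penalization keeps the fitted
  # linear predictor essentially affine in PAR
  dat$y <- plogis(-1 + 0.002 * dat$par) + rnorm(n, 0, 0.05)
  dat$y <- pmin(pmax(dat$y, 1e-4), 1 - 1e-4)
  fit2 <- fit_gamm(dat, "y")
  par_edf <- fit2$smooths$edf[fit2$smooths$term == "par"]
  expect_true(all(par_edf < 2.5))
  eta <- predict(fit2$model, dat, exclude = "s(species)")
  for (ssn in c("wet", "dry")) {
    sel <- dat$season == ssn
    lin <- lm(eta[sel] ~ dat$par[sel])
    expect_gt(summary(lin)$r.squared, 0.995)
  }
})

test_that("boundary responses are squeezed with a warning", {
  set.seed(6)
  dat <- sim_gamm_data(n = 200, seed = 6)
  dat$y[1] <- 0
  dat$y[2] <- 1
  expect_warning(fit <- fit_gamm(dat, "y"), "squeezed")
  expect_s3_class(fit$model, "gam")
})

test_that("seasonal smooth difference flags a constructed shift", {
  dat <- sim_gamm_data(n = 900, seed = 8, dry_shift = 0.4)
  fit <- fit_gamm(dat, "y")
  d <- smooth_difference(fit, "par")
  expect_gt(mean(d$significant), 0.5)
  expect_gt(mean(d$diff), 0)          # dry above wet on the link scale
  # identical seasonal truths: significance only at the nominal-rate level
  dat0 <- sim_gamm_data(n = 900, seed = 8, dry_shift = 0)
  d0 <- smooth_difference(fit_gamm(dat0, "y"), "par")
  expect_lt(mean(d0$significant), 0.25)
  # a season differenced against itself vanishes identically
  dself <- smooth_difference(fit, "par", season_levels = c("dry", "dry"))
  expect_true(all(abs(dself$diff) < 1e-12))
  expect_true(all(!dself$significant))
})

test_that("hierarchical partitioning splits orthogonal signal correctly", {
  set.seed(10)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- sqrt(0.3) * x1 + sqrt(0.2) * x2 + rnorm(n, 0, sqrt(0.5))
  dat <- data.frame(y = y, x1 = x1, x2 = x2)
  hp <- hierarchical_partition(dat, "y", c("x1", "x2"), family = "gaussian")
  total <- attr(hp, "deviance_explained")
  expect_equal(sum(hp$share), total, tolerance = 1e-8)
  expect_equal(hp$share[hp$predictor == "x1"], 0.3, tolerance = 0.05)
  expect_equal(hp$share[hp$predictor == "x2"], 0.2, tolerance = 0.05)
  # independence: each share matches its single-predictor explained deviance
  d1 <- attr(hierarchical_partition(dat, "y", "x1", family = "gaussian"),
             "deviance_explained")
  d2 <- attr(hierarchical_partition(dat, "y", "x2", family = "gaussian"),
             "deviance_explained")
  expect_equal(hp$share, c(d1, d2), tolerance = 0.02)
  # permutation invariance of input order
  hp2 <- hierarchical_partition(dat, "y", c("x2", "x1"), family = "gaussian")
  expect_equal(hp$share[match(hp2$predictor, hp$predictor)], hp2$share,
               tolerance = 1e-10)
})

test_that("single and irrelevant predictors take trivial shares", {
  set.seed(12)
  n <- 500
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  dat$y <- dat$x1 + rnorm(n, 0, 0.5)
  hp1 <- hierarchical_partition(dat, "y", "x1", family = "gaussian")
  expect_equal(hp1$share, attr(hp1, "deviance_explained"))
  hp2 <- hierarchical_partition(dat, "y", c("x1", "x2"),
                                family = "gaussian")
  expect_lt(hp2$share[hp2$predictor == "x2"], 0.02)
  expect_error(hierarchical_partition(dat, "y", rep("x1", 5)), "1..4")
})
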