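#' Mixed multiple regression of a yield on environmental drivers
#'
#' Fits a linear mixed model of the response on z-scored predictors with a
#' species random intercept, `y ~ z(PAR) + z(VPD) + z(H) + (1 | species)`.
#' Standardizing the predictors (not the response) makes the fixed-effect
#' coefficients comparable across predictors: each is the change in the yield
#' per predictor standard deviation. A predictor is deemed significant when
#' its Wald 95% confidence interval excludes zero. Singular random-effect
#' fits fall back to a fixed-effects model with a warning.
#'
#' @param records data.frame of (typically quality-controlled) records.
#' @param response Name of the response column (a yield, `ql`, `npqt`, ...).
#' @param predictors Character vector of predictor columns (default
#'   `c("par", "vpd", "height_m")`).
#' @param group Name of the random-intercept grouping column (default
#'   `"species"`).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return Object of class `lmm_fit`: list with `coefficients` (term,
#'   estimate, se, ci_lo, ci_hi, significant), variance components
#'   (`var_fixed`, `var_random`, `var_resid`), `r2_marginal`,
#'   `r2_conditional`, `n`, `singular`, and the underlying `model`.
#' @seealso [r2_nakagawa()], [vif()]
#' @export
fit_lmm <- function(records, response, predictors = c("par", "vpd", "height_m"),
                    group = "species", conf_level = 0.95) {
  stopifnot(is.data.frame(records),
            response %in% names(records),
            all(predictors %in% names(records)),
            group %in% names(records))
  dat <- records[stats::complete.cases(records[c(response, predictors, group)]),
                 c(response, predictors, group)]
  if (nrow(dat) < 10) stop("need >= 10 complete records", call. = FALSE)
  dat[[group]] <- factor(dat[[group]])
  if (nlevels(dat[[group]]) < 2) {
    stop("need >= 2 levels of `", group, "`", call. = FALSE)
  }
  for (p in predictors) dat[[p]] <- as.numeric(scale(dat[[p]]))

  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + "),
                                 "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = dat)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular random-effect fit; falling back to fixed effects",
            call. = FALSE)
    fit_fx <- stats::lm(stats::as.formula(
      paste(response, "~", paste(predictors, collapse = " + "))), data = dat)
    beta <- stats::coef(fit_fx)
    se <- sqrt(diag(stats::vcov(fit_fx)))
    var_random <- 0
    var_resid <- summary(fit_fx)$sigma^2
    X <- stats::model.matrix(fit_fx)
    model <- fit_fx
  } else {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_random <- sum(vc$vcov[vc$grp != "Residual"])
    var_resid <- vc$vcov[vc$grp == "Residual"]
    X <- lme4::getME(fit, "X")
    model <- fit
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lo = unname(beta - z * se),
                      ci_hi = unname(beta + z * se), row.names = NULL)
  coefs$significant <- coefs$ci_lo > 0 | coefs$ci_hi < 0
  coefs$significant[coefs$term == "(Intercept)"] <- NA
  var_fixed <- stats::var(as.vector(X %*% beta))
  tot <- var_fixed + var_random + var_resid
  out <- structure(list(response = response, predictors = predictors,
                        group = group, coefficients = coefs,
                        var_fixed = var_fixed, var_random = var_random,
                        var_resid = var_resid,
                        r2_marginal = var_fixed / tot,
                        r2_conditional = (var_fixed + var_random) / tot,
                        n = nrow(dat), singular = singular, model = model),
                   class = "lmm_fit")
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Mixed model:", x$response, "~", paste(x$predictors, collapse = " + "),
      "+ (1 |", x$group, ")  [n =", paste0(x$n, "]"), "\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-12s %+ .4f  [%+.4f, %+.4f]%s\n", cf$term[i],
                cf$estimate[i], cf$ci_lo[i], cf$ci_hi[i],
                ifelse(isTRUE(cf$significant[i]), " *", "")))
  }
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f%s\n",
              x$r2_marginal, x$r2_conditional,
              if (x$singular) "  (singular fit, fixed effects only)" else ""))
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-component R-squared for Gaussian mixed models: the marginal value
#' is the share of total variance explained by the fixed effects,
#' `var_f / (var_f + var_r + var_e)`; the conditional value adds the random
#' (species) variance to the numerator. Their difference is the species
#' share.
#'
#' @param fit An [fit_lmm()] object.
#' @return list with `marginal`, `conditional`, `species_share`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  list(marginal = fit$r2_marginal,
       conditional = fit$r2_conditional,
       species_share = fit$r2_conditional - fit$r2_marginal)
}

#' Variance inflation factors
#'
#' Multicollinearity diagnostic: for each predictor `j`,
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor `j`
#' on the remaining predictors. Perfect collinearity is reported as `Inf`
#' with a warning.
#'
#' @param records data.frame containing the predictor columns.
#' @param predictors Character vector of at least two predictor columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(records, predictors) {
  stopifnot(is.data.frame(records), all(predictors %in% names(records)),
            length(predictors) >= 2)
  dat <- records[stats::complete.cases(records[predictors]), predictors]
  if (nrow(dat) <= length(predictors)) {
    stop("need more rows than predictors", call. = FALSE)
  }
  out <- vapply(predictors, function(p) {
    # suppressWarnings: an exact linear dependence triggers lm's
    # "essentially perfect fit" warning; we report Inf below instead
    r2 <- suppressWarnings(summary(stats::lm(
      stats::as.formula(paste(p, "~", paste(setdiff(predictors, p),
                                            collapse = " + "))),
      data = dat))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(!is.finite(out))) {
    warning("perfect collinearity: infinite VIF for ",
            paste(names(out)[!is.finite(out)], collapse = ", "),
            call. = FALSE)
  }
  out
}

# Squeeze a (0,1) response away from the boundary for the beta likelihood.
.squeeze01 <- function(y) {
  if (any(y <= 0 | y >= 1)) {
    warning("response values at the [0, 1] boundary squeezed before the ",
            "beta fit", call. = FALSE)
    n <- length(y)
    y <- (y * (n - 1) + 0.5) / n
  }
  y
}

#' Season-stratified additive mixed model of a yield
#'
#' Fits a generalized additive mixed model of the response on penalized
#' regression splines of PAR, VPD and height, each with basis dimension
#' `k = 5` and a separate smooth per season, plus a parametric season effect
#' and a ridge-penalized species random intercept. The likelihood is a beta
#' distribution with logit link (the response is a yield in (0, 1)), with
#' smoothness selected by maximum likelihood. Boundary response values are
#' squeezed with a warning. With a single season present, the by-season
#' structure drops to plain smooths with a message.
#'
#' @param records data.frame with the response, `par`, `vpd`, `height_m`,
#'   `season` and `species` columns.
#' @param response Name of the response column (values in `(0, 1)`).
#' @param predictors Numeric predictor columns to smooth over (default
#'   `c("par", "vpd", "height_m")`).
#' @param k Basis dimension per smooth (default 5).
#' @param family `"beta"` (default) or `"gaussian"`.
#' @return Object of class `gamm_fit`: list with the mgcv `model`, `smooths`
#'   (term, season, edf), `deviance_explained`, `n`, `seasons`.
#' @seealso [smooth_difference()], [hierarchical_partition()]
#' @export
fit_gamm <- function(records, response,
                     predictors = c("par", "vpd", "height_m"), k = 5,
                     family = c("beta", "gaussian")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(records), response %in% names(records),
            all(predictors %in% names(records)),
            all(c("season", "species") %in% names(records)))
  dat <- records[stats::complete.cases(
    records[c(response, predictors, "season", "species")]),
    c(response, predictors, "season", "species")]
  dat$season <- factor(dat$season)
  dat$species <- factor(dat$species)
  two_seasons <- nlevels(dat$season) >= 2
  if (!two_seasons) {
    message("single season present; fitting season-free smooths")
  }
  y <- dat[[response]]
  if (family == "beta") dat[[response]] <- .squeeze01(y)
  sm <- if (two_seasons) {
    paste0("s(", predictors, ", by = season, k = ", k, ", bs = \"cr\")",
           collapse = " + ")
  } else {
    paste0("s(", predictors, ", k = ", k, ", bs = \"cr\")", collapse = " + ")
  }
  rhs <- paste(c(if (two_seasons) "season", sm, "s(species, bs = \"re\")"),
               collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fam <- if (family == "beta") mgcv::betar(link = "logit") else stats::gaussian()
  model <- mgcv::gam(fml, data = dat, family = fam, method = "ML")
  st <- summary(model)$s.table
  lab <- rownames(st)
  smooths <- data.frame(
    label = lab,
    term = sub("^s\\(([^,)]+).*$", "\\1", lab),
    season = ifelse(grepl(":season", lab),
                    sub("^.*:season", "", lab), NA_character_),
    edf = unname(st[, "edf"]), row.names = NULL)
  structure(list(model = model, response = response, predictors = predictors,
                 smooths = smooths,
                 deviance_explained = summary(model)$dev.expl,
                 family = family, k = k, n = nrow(dat),
                 seasons = levels(dat$season), data = dat),
            class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat("Additive mixed model:", x$response, "(", x$family,
      "likelihood, k =", x$k, ")  [n =", paste0(x$n, "]"), "\n")
  s <- x$smooths
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-28s edf = %.2f\n", s$label[i], s$edf[i]))
  }
  cat(sprintf("  deviance explained = %.3f\n", x$deviance_explained))
  invisible(x)
}

#' Seasonal difference of a smooth effect (dry - wet)
#'
#' Pointwise difference between the two seasonal versions of one smooth term,
#' evaluated on a grid of the shared covariate range with the other
#' covariates held at their medians. The difference includes the parametric
#' season effect (a seasonal level shift belongs to the seasonal contrast)
#' and excludes the species random effect; its standard error comes from the
#' model covariance through the prediction-matrix contrast, with
#' `CI = +-1.96 SE`. Bands where the CI excludes zero are flagged
#' significant.
#'
#' @param fit A two-season [fit_gamm()] object.
#' @param term One of the fitted smooth covariates (e.g. `"par"`).
#' @param n_grid Grid size (default 200).
#' @param season_levels Length-2 character vector naming the minuend and
#'   subtrahend season (default `c("dry", "wet")`).
#' @return data.frame with `x`, `diff`, `se`, `lo`, `hi`, `significant`;
#'   attribute `term`. The difference is on the link (logit) scale.
#' @export
smooth_difference <- function(fit, term, n_grid = 200,
                              season_levels = c("dry", "wet")) {
  stopifnot(inherits(fit, "gamm_fit"), term %in% fit$predictors)
  if (length(fit$seasons) < 2) {
    stop("seasonal difference needs both seasons fitted", call. = FALSE)
  }
  dat <- fit$data
  r1 <- range(dat[[term]][dat$season == season_levels[1]])
  r2 <- range(dat[[term]][dat$season == season_levels[2]])
  lo <- max(r1[1], r2[1]); hi <- min(r1[2], r2[2])
  if (lo >= hi) stop("seasons have disjoint covariate ranges", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)

  nd <- dat[rep(1L, n_grid), , drop = FALSE]
  for (p in fit$predictors) nd[[p]] <- stats::median(dat[[p]])
  nd[[term]] <- grid
  nd$species <- factor(levels(dat$species)[1], levels = levels(dat$species))
  nd1 <- nd; nd1$season <- factor(season_levels[1], levels = levels(dat$season))
  nd2 <- nd; nd2$season <- factor(season_levels[2], levels = levels(dat$season))
  X1 <- stats::predict(fit$model, nd1, type = "lpmatrix")
  X2 <- stats::predict(fit$model, nd2, type = "lpmatrix")
  Xd <- X1 - X2
  # drop the species random-effect columns from the contrast
  re_cols <- grep("^s\\(species\\)", colnames(Xd))
  if (length(re_cols)) Xd[, re_cols] <- 0
  beta <- stats::coef(fit$model)
  dif <- as.vector(Xd %*% beta)
  se <- sqrt(rowSums((Xd %*% stats::vcov(fit$model)) * Xd))
  out <- data.frame(x = grid, diff = dif, se = se,
                    lo = dif - 1.96 * se, hi = dif + 1.96 * se)
  out$significant <- out$lo > 0 | out$hi < 0
  attr(out, "term") <- term
  attr(out, "seasons") <- season_levels
  out
}

#' Hierarchical partitioning of explained deviance
#'
#' Attributes the full model's explained deviance to individual predictors by
#' all-subsets averaging: every one of the `2^p` predictor subsets is fitted
#' as a GAM (numeric predictors as `k`-basis smooths, factors as
#' ridge-penalized random effects), and each predictor's share is its
#' marginal deviance contribution averaged over all orderings. Negative
#' averaged shares are floored at zero and the remainder renormalized (with a
#' message) so shares always sum to the full model's explained deviance.
#'
#' @param records data.frame of records.
#' @param response Response column name.
#' @param predictors Up to 4 predictor columns (numeric or factor).
#' @param family `"beta"` or `"gaussian"`.
#' @param k Basis dimension for numeric smooths (default 5).
#' @return data.frame with `predictor`, `share` (deviance fraction) and
#'   `share_of_explained`; attribute `deviance_explained` (full model).
#' @export
hierarchical_partition <- function(records, response, predictors,
                                   family = c("beta", "gaussian"), k = 5) {
  family <- match.arg(family)
  p <- length(predictors)
  stopifnot(is.data.frame(records), response %in% names(records),
            all(predictors %in% names(records)))
  if (p < 1 || p > 4) stop("need 1..4 predictors", call. = FALSE)
  dat <- records[stats::complete.cases(records[c(response, predictors)]),
                 c(response, predictors)]
  for (pr in predictors) {
    if (!is.numeric(dat[[pr]])) dat[[pr]] <- factor(dat[[pr]])
  }
  if (family == "beta") dat[[response]] <- .squeeze01(dat[[response]])
  fam <- if (family == "beta") mgcv::betar(link = "logit") else stats::gaussian()

  term_of <- function(pr) {
    if (is.factor(dat[[pr]])) paste0("s(", pr, ", bs = \"re\")")
    else paste0("s(", pr, ", k = ", k, ", bs = \"cr\")")
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  dev_of <- numeric(nrow(subsets))
  for (i in seq_len(nrow(subsets))) {
    sel <- predictors[unlist(subsets[i, ])]
    rhs <- if (length(sel)) paste(vapply(sel, term_of, character(1)),
                                  collapse = " + ") else "1"
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- tryCatch(mgcv::gam(fml, data = dat, family = fam, method = "ML"),
                    error = function(e) {
                      stop("subset fit failed for {", paste(sel, collapse = ", "),
                           "}: ", conditionMessage(e), call. = FALSE)
                    })
    dev_of[i] <- summary(fit)$dev.expl
  }
  key <- apply(subsets, 1, function(r) paste(as.integer(r), collapse = ""))
  lookup <- stats::setNames(dev_of, key)
  dev_sub <- function(mask) lookup[[paste(as.integer(mask), collapse = "")]]

  shares <- numeric(p)
  for (j in seq_len(p)) {
    contrib <- 0
    for (i in seq_len(nrow(subsets))) {
      mask <- unlist(subsets[i, ])
      if (mask[j]) next
      s <- sum(mask)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      with_j <- mask; with_j[j] <- TRUE
      contrib <- contrib + w * (dev_sub(with_j) - dev_sub(mask))
    }
    shares[j] <- contrib
  }
  total <- dev_of[nrow(subsets)]  # all-predictors model
  if (any(shares < 0)) {
    message("negative averaged shares floored at zero and renormalized: ",
            paste(predictors[shares < 0], collapse = ", "))
    shares[shares < 0] <- 0
    if (sum(shares) > 0) shares <- shares * total / sum(shares)
  }
  out <- data.frame(predictor = predictors, share = shares,
                    share_of_explained = if (total > 0) shares / total
                                         else NA_real_,
                    row.names = NULL)
  attr(out, "deviance_explained") <- total
  out
}
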