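#' Assign canopy stratum labels from height
#'
#' Partitions heights into the three canopy strata used throughout the
#' analyses: lower canopy `S1 = [0, 20)` m, mid-canopy `S2 = [20, 40)` m and
#' upper canopy `S3 = [40, Inf)` m. Intervals are half-open with boundaries
#' assigned upward, so every nonnegative height maps to exactly one stratum.
#'
#' @param height Numeric vector of heights above ground (m, >= 0).
#' @return Factor with levels `S1`, `S2`, `S3`.
#' @export
#' @examples
#' assign_stratum(c(10, 20, 45))
assign_stratum <- function(height) {
  if (any(!is.finite(height)) || any(height < 0)) {
    stop("`height` must be finite and >= 0", call. = FALSE)
  }
  idx <- findInterval(height, c(0, 20, 40))
  factor(c("S1", "S2", "S3")[idx], levels = c("S1", "S2", "S3"))
}

#' Vertical canopy profile of a variable
#'
#' Bins records into fixed-width height increments (1 m by default) and
#' reports the per-bin sample size, mean and confidence-interval half-width
#' (Student-t, 90% by default). The CI is undefined (`NA`) for single-record
#' bins; empty bins are omitted.
#'
#' @param records data.frame with a `height_m` column.
#' @param variable Name of the column to profile.
#' @param bin_width Height bin width in m (default 1).
#' @param ci Confidence level (default 0.90).
#' @return data.frame with `bin_lo`, `bin_mid`, `n`, `mean`, `ci_half`;
#'   attributes `variable` and `ci`.
#' @export
vertical_profile <- function(records, variable, bin_width = 1, ci = 0.90) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            "height_m" %in% names(records), variable %in% names(records))
  x <- records[[variable]]
  keep <- is.finite(x) & is.finite(records$height_m)
  x <- x[keep]
  h <- records$height_m[keep]
  bin <- floor(h / bin_width) * bin_width
  sp <- split(x, bin)
  n <- lengths(sp)
  m <- vapply(sp, mean, numeric(1))
  sdv <- vapply(sp, stats::sd, numeric(1))
  half <- rep(NA_real_, length(n))
  ok <- n >= 2
  half[ok] <- stats::qt(1 - (1 - ci) / 2, n[ok] - 1) * sdv[ok] / sqrt(n[ok])
  out <- data.frame(bin_lo = as.numeric(names(sp)),
                    bin_mid = as.numeric(names(sp)) + bin_width / 2,
                    n = as.integer(n), mean = m, ci_half = half,
                    row.names = NULL)
  out <- out[order(out$bin_lo), , drop = FALSE]
  attr(out, "variable") <- variable
  attr(out, "ci") <- ci
  out
}

# Compact letter display by insert-and-absorb: groups sharing a letter are
# not significantly different. `groups` must be ordered the way letters
# should read (here: descending median); `sig` is a logical matrix of
# significant pairwise differences.
.cld_letters <- function(groups, sig) {
  cols <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !sig[i, j]) next
      gi <- groups[i]; gj <- groups[j]
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (all(c(gi, gj) %in% col)) {
          cols[[ci]] <- setdiff(col, gi)
          cols[[length(cols) + 1L]] <- setdiff(col, gj)
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] %in% cols[[b]]) &&
              length(cols[[a]]) < length(cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      # drop duplicates among equal-length survivors
      cols <- unique(cols[keep])
    }
  }
  # order columns by first (highest-ranked) member for stable lettering
  first <- vapply(cols, function(cl) min(match(cl, groups)), numeric(1))
  cols <- cols[order(first)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], letters[ci])
    }
  }
  letters_out
}

#' Nonparametric comparison of canopy strata
#'
#' Kruskal-Wallis test across strata followed by pairwise Mann-Whitney
#' (Wilcoxon rank-sum) tests, summarized as a compact letter display in which
#' strata sharing a letter are not significantly different at `alpha`.
#' Pairwise p-values are reported both raw and Holm-adjusted; letters are
#' built on the adjusted values.
#'
#' @param records data.frame with the variable column and either a `stratum`
#'   column or `height_m` (strata then assigned with [assign_stratum()]).
#' @param variable Name of the column to compare.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return An object of class `strata_comparison`: list with `kw_stat`,
#'   `kw_df`, `kw_p`, `pairwise` (data.frame of raw and Holm-adjusted
#'   p-values), `letters` (named by stratum, ordered by descending median)
#'   and `medians`.
#' @export
strata_compare <- function(records, variable, alpha = 0.05) {
  stopifnot(is.data.frame(records), variable %in% names(records))
  if (!"stratum" %in% names(records)) {
    records$stratum <- assign_stratum(records$height_m)
  }
  x <- records[[variable]]
  g <- factor(records$stratum)
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding strata with < 2 records: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep2 <- !(g %in% small)
    x <- x[keep2]; g <- droplevels(g[keep2])
  }
  if (nlevels(g) < 2) {
    stop("need at least 2 strata with >= 2 records each", call. = FALSE)
  }
  kw <- stats::kruskal.test(x, g)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    stats::wilcox.test(x[g == pr[1]], x[g == pr[2]], exact = FALSE)$p.value
  })
  p_holm <- stats::p.adjust(p_raw, method = "holm")
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p_raw = p_raw, p_holm = p_holm, row.names = NULL)
  med <- vapply(split(x, g), stats::median, numeric(1))
  ord <- names(sort(med, decreasing = TRUE))
  sig <- matrix(FALSE, nlevels(g), nlevels(g), dimnames = list(ord, ord))
  for (r in seq_len(nrow(pw))) {
    if (pw$p_holm[r] < alpha) {
      sig[pw$group1[r], pw$group2[r]] <- TRUE
      sig[pw$group2[r], pw$group1[r]] <- TRUE
    }
  }
  lets <- .cld_letters(ord, sig)
  structure(list(variable = variable, kw_stat = unname(kw$statistic),
                 kw_df = unname(kw$parameter), kw_p = kw$p.value,
                 pairwise = pw, letters = lets, medians = med[ord],
                 alpha = alpha, n = length(x)),
            class = "strata_comparison")
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat("Strata comparison of", x$variable, "(n =", paste0(x$n, ")"), "\n")
  cat(sprintf("  Kruskal-Wallis chi-sq = %.3f, df = %d, p = %.3g\n",
              x$kw_stat, x$kw_df, x$kw_p))
  for (g in names(x$letters)) {
    cat(sprintf("  %s: median %.4g  %s\n", g, x$medians[g], x$letters[g]))
  }
  invisible(x)
}

#' Per-stratum means and lower-to-upper canopy change
#'
#' Reports the mean of a variable in each stratum and the change from the
#' lowest (S1) to the upper (S3) stratum expressed in percentage points,
#' `100 * (mean_S3 - mean_S1)` - the natural reading for quantum-yield
#' fractions.
#'
#' @inheritParams strata_compare
#' @return list with `means` (named by stratum) and `delta_pp`.
#' @export
strata_deltas <- function(records, variable) {
  stopifnot(is.data.frame(records), variable %in% names(records))
  if (!"stratum" %in% names(records)) {
    records$stratum <- assign_stratum(records$height_m)
  }
  x <- records[[variable]]
  g <- factor(records$stratum, levels = c("S1", "S2", "S3"))
  keep <- is.finite(x) & !is.na(g)
  means <- vapply(split(x[keep], g[keep]), mean, numeric(1))
  if (!all(c("S1", "S3") %in% names(means)) ||
      any(is.na(means[c("S1", "S3")]))) {
    stop("both S1 and S3 must be populated", call. = FALSE)
  }
  list(means = means, delta_pp = unname(100 * (means["S3"] - means["S1"])))
}
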