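#' leafquanta: leaf-level energy partitioning from steady-state fluorescence
#'
#' Quantum-yield partitioning of absorbed photons from pulse-amplitude-modulated
#' (PAM) chlorophyll fluorescence, canopy stratification and vertical profiles,
#' mixed-model and additive-model driver inference, and derivative-based
#' breakpoint/phase analysis of the relationship between nonregulated losses
#' and photochemical yield. A seeded synthetic campaign generator makes the
#' whole pipeline testable without field data.
#'
#' @keywords internal
#' @aliases leafquanta-package
"_PACKAGE"

# Dark-adapted Fm/Fo - 1 assumed by the rapid NPQ estimate. 4.88 encodes a
# dark-adapted Fv/Fm of 4.88/5.88 ~ 0.83, typical of unstressed leaves.
.k_dark_default <- 4.88

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be finite and positive", call. = FALSE)
  }
  invisible(x)
}

#' Rapid nonphotochemical quenching estimate (NPQt)
#'
#' Estimates nonphotochemical quenching from light-adapted fluorescence alone,
#' without a dark-adapted reference: `NPQt = k_dark / (Fm'/Fo' - 1) - 1`.
#' The constant `k_dark` encodes the assumed dark-adapted `Fm/Fo - 1`; with the
#' default 4.88, a leaf whose light-adapted ratio equals the dark-adapted value
#' 5.88 has `NPQt = 0`.
#'
#' @param fm_prime Maximum fluorescence under steady-state illumination
#'   (saturation pulse), relative units, positive.
#' @param fo_prime Minimal fluorescence under steady-state illumination after
#'   far-red re-oxidation of QA, relative units, positive.
#' @param k_dark Assumed dark-adapted `Fm/Fo - 1` (default 4.88).
#' @return Numeric vector of NPQt values (>= 0 for ratios below 5.88 is not
#'   guaranteed; NPQt is negative when the light-adapted ratio exceeds the
#'   assumed dark-adapted ratio, which quality control treats as noise).
#' @seealso [compute_ql()], [forward_fluorescence()]
#' @export
#' @examples
#' compute_npqt(5.88, 1)   # dark-adapted reference ratio -> 0
#' compute_npqt(2.22, 1)   # 4.88/1.22 - 1 = 3
compute_npqt <- function(fm_prime, fo_prime, k_dark = 4.88) {
  .check_positive(fm_prime, "fm_prime")
  .check_positive(fo_prime, "fo_prime")
  ratio <- fm_prime / fo_prime
  if (any(ratio <= 1)) {
    stop("invalid measurement: Fm'/Fo' must exceed 1", call. = FALSE)
  }
  k_dark / (ratio - 1) - 1
}

#' Fraction of open PSII centers (qL, lake model)
#'
#' Lake-model estimate of the fraction of photosystem II reaction centers in
#' the open state: `qL = ((Fm' - Fs)/(Fm' - Fo')) * (Fo'/Fs)`. Values lie in
#' `[0, 1]` whenever `Fo' <= Fs <= Fm'`; measurement noise can push `Fs`
#' slightly outside that interval, in which case the value is returned as-is
#' and left to [qc_filter()] rather than clamped.
#'
#' @param fs Steady-state fluorescence yield, relative units, positive.
#' @inheritParams compute_npqt
#' @return Numeric vector of qL values.
#' @export
#' @examples
#' compute_ql(fs = 1, fm_prime = 5.88, fo_prime = 1)      # all centers open
#' compute_ql(fs = 1.96, fm_prime = 1.96, fo_prime = 0.75) # all centers closed
compute_ql <- function(fs, fm_prime, fo_prime) {
  .check_positive(fs, "fs")
  .check_positive(fm_prime, "fm_prime")
  .check_positive(fo_prime, "fo_prime")
  if (any(fm_prime <= fo_prime)) {
    stop("invalid measurement: Fm' must exceed Fo'", call. = FALSE)
  }
  ((fm_prime - fs) / (fm_prime - fo_prime)) * (fo_prime / fs)
}

#' Quantum yield of nonregulated losses (PhiNO)
#'
#' `PhiNO = 1 / (1 + k_dark * qL + NPQt)`: the fraction of absorbed photons
#' lost to basal heat dissipation and fluorescence re-emission. This is the
#' leaf-level quantity that tracks solar-induced fluorescence yield most
#' closely. Strictly decreasing in both arguments.
#'
#' @param ql Fraction of open PSII centers, in `[0, 1]`.
#' @param npqt Rapid NPQ estimate, >= 0.
#' @inheritParams compute_npqt
#' @return Numeric vector in `(0, 1]`.
#' @export
#' @examples
#' compute_phi_no(ql = 0, npqt = 0)   # no quenching at all -> 1
#' compute_phi_no(ql = 1, npqt = 0)   # dark-adapted limit, 1/5.88
compute_phi_no <- function(ql, npqt, k_dark = 4.88) {
  if (any(!is.finite(ql)) || any(ql < 0 | ql > 1)) {
    stop("`ql` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(npqt)) || any(npqt < 0)) {
    stop("`npqt` must be finite and >= 0", call. = FALSE)
  }
  1 / (1 + k_dark * ql + npqt)
}

#' Quantum yield of PSII photochemistry (PhiPSII)
#'
#' `PhiPSII = (Fm' - Fs) / Fm'`, the fraction of absorbed photons driving
#' electron transport under the lake model.
#'
#' @inheritParams compute_ql
#' @return Numeric vector; in `[0, 1)` when `0 < Fs <= Fm'`. Negative values
#'   (noise pushing `Fs` above `Fm'`) are returned as-is for [qc_filter()].
#' @export
#' @examples
#' compute_phi_psii(fs = 1, fm_prime = 5.88) # dark-adapted Fv/Fm, 4.88/5.88
compute_phi_psii <- function(fs, fm_prime) {
  .check_positive(fs, "fs")
  .check_positive(fm_prime, "fm_prime")
  (fm_prime - fs) / fm_prime
}

#' Quantum yield of regulated heat dissipation (PhiNPQ)
#'
#' The three yields partition absorbed light exactly, so
#' `PhiNPQ = 1 - PhiPSII - PhiNO`. The identity is enforced by construction;
#' negative results are data (a failed measurement), handled by [qc_filter()].
#'
#' @param phi_psii Quantum yield of photochemistry.
#' @param phi_no Quantum yield of nonregulated losses.
#' @return Numeric vector.
#' @export
compute_phi_npq <- function(phi_psii, phi_no) {
  1 - phi_psii - phi_no
}

#' Vapor pressure deficit from air temperature and relative humidity
#'
#' Tetens saturation vapor pressure over air temperature,
#' `e_s = 0.61078 * exp(17.27 T / (T + 237.3))` kPa, scaled by the relative
#' humidity deficit: `VPD = e_s * (1 - RH/100)`.
#'
#' @param air_temp Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent, in `[0, 100]`.
#' @return VPD in kPa, >= 0; exactly 0 at saturation.
#' @export
#' @examples
#' derive_vpd(25, 100) # saturated air -> 0
#' derive_vpd(25, 50)  # ~1.584 kPa
derive_vpd <- function(air_temp, rh) {
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100)) {
    stop("`rh` must lie in [0, 100]", call. = FALSE)
  }
  es <- 0.61078 * exp(17.27 * air_temp / (air_temp + 237.3))
  es * (1 - rh / 100)
}

#' Exact forward fluorescence model (inverse of the yield algebra)
#'
#' Maps a regulatory state `(qL, NPQt)` to the raw fluorescence parameters
#' `(Fs, Fm', Fo')` that would produce it, under the normalization `Fo = 1`,
#' `Fm = k_dark + 1`. Quenching scales the saturation-pulse maximum as
#' `Fm' = Fm / (1 + NPQt)`; the light-adapted minimum follows the
#' Oxborough-Baker relation `1/Fo' = 1/Fo - 1/Fm + 1/Fm'`; and the steady
#' state solves the lake-model qL definition,
#' `Fs = A Fm' / (qL + A)` with `A = Fo' / (Fm' - Fo')`.
#'
#' Running [compute_npqt()] and [compute_ql()] on the output recovers the
#' inputs to machine precision, which makes this the round-trip oracle for the
#' yield algebra and the emission model of the synthetic campaign generator.
#'
#' @inheritParams compute_phi_no
#' @inheritParams compute_npqt
#' @return A data.frame with columns `fs`, `fm_prime`, `fo_prime`.
#' @export
#' @examples
#' forward_fluorescence(ql = 1, npqt = 0)     # dark-adapted: (1, 5.88, 1)
#' forward_fluorescence(ql = 0.5, npqt = 2)
forward_fluorescence <- function(ql, npqt, k_dark = 4.88) {
  if (any(!is.finite(ql)) || any(ql < 0 | ql > 1)) {
    stop("`ql` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(npqt)) || any(npqt < 0)) {
    stop("`npqt` must be finite and >= 0", call. = FALSE)
  }
  fm_dark <- k_dark + 1
  fm_prime <- fm_dark / (1 + npqt)
  fo_prime <- fm_dark / (fm_dark + npqt)
  a <- fo_prime / (fm_prime - fo_prime)
  fs <- a * fm_prime / (ql + a)
  data.frame(fs = fs, fm_prime = fm_prime, fo_prime = fo_prime)
}

#' Compute regulatory state and quantum yields for a table of measurements
#'
#' Adds `npqt`, `ql`, `phi_psii`, `phi_no` and `phi_npq` columns to a table of
#' leaf-level PAM records. Rows whose raw fluorescence is unusable
#' (non-positive values, `Fm' <= Fo'`, or `Fm'/Fo' <= 1`) get `NA` yields and
#' are rejected later by [qc_filter()]. When `vpd` is absent but `air_temp`
#' and `rh` are present, VPD is derived with [derive_vpd()].
#'
#' If the table already carries instrument-computed `ql`/`npqt`/yield columns
#' (as MultispeQ exports do), those are kept and the values recomputed from
#' raw fluorescence are only used for cross-validation: disagreements larger
#' than `crosscheck_tol` raise a warning. Set `recompute = TRUE` to overwrite
#' supplied columns.
#'
#' @param records A data.frame with columns `fs`, `fm_prime`, `fo_prime` (raw
#'   mode) and/or precomputed `ql`, `npqt`, `phi_psii`, `phi_no`, `phi_npq`.
#' @param k_dark Assumed dark-adapted `Fm/Fo - 1` (default 4.88).
#' @param recompute Overwrite supplied regulatory-state/yield columns from raw
#'   fluorescence (default `FALSE`).
#' @param crosscheck_tol Tolerance for reporting disagreement between supplied
#'   and recomputed values (default `1e-3`).
#' @return `records` with the derived columns appended.
#' @export
compute_yields <- function(records, k_dark = 4.88, recompute = FALSE,
                           crosscheck_tol = 1e-3) {
  stopifnot(is.data.frame(records))
  out <- records

  if (is.null(out$vpd) && !is.null(out$air_temp) && !is.null(out$rh)) {
    out$vpd <- derive_vpd(out$air_temp, out$rh)
  }

  has_raw <- all(c("fs", "fm_prime", "fo_prime") %in% names(out))
  derived_cols <- c("npqt", "ql", "phi_psii", "phi_no", "phi_npq")
  has_supplied <- all(derived_cols %in% names(out))

  if (!has_raw && !has_supplied) {
    stop("records must contain raw fluorescence (fs, fm_prime, fo_prime) ",
         "or precomputed yield columns", call. = FALSE)
  }

  if (has_raw) {
    ok <- is.finite(out$fs) & is.finite(out$fm_prime) & is.finite(out$fo_prime) &
      out$fs > 0 & out$fm_prime > 0 & out$fo_prime > 0 &
      out$fm_prime > out$fo_prime
    calc <- data.frame(npqt = rep(NA_real_, nrow(out)), ql = NA_real_,
                       phi_psii = NA_real_, phi_no = NA_real_,
                       phi_npq = NA_real_)
    if (any(ok)) {
      calc$npqt[ok] <- compute_npqt(out$fm_prime[ok], out$fo_prime[ok], k_dark)
      calc$ql[ok] <- compute_ql(out$fs[ok], out$fm_prime[ok], out$fo_prime[ok])
      calc$phi_psii[ok] <- compute_phi_psii(out$fs[ok], out$fm_prime[ok])
      # Eqn for PhiNO evaluated directly: qL/NPQt outside their domains are
      # noise cases that must flow to qc_filter, not error out here.
      calc$phi_no[ok] <- 1 / (1 + k_dark * calc$ql[ok] + calc$npqt[ok])
      calc$phi_npq[ok] <- compute_phi_npq(calc$phi_psii[ok], calc$phi_no[ok])
    }
    if (has_supplied && !recompute) {
      dev <- vapply(derived_cols, function(cl) {
        max(abs(out[[cl]] - calc[[cl]]), na.rm = TRUE)
      }, numeric(1))
      bad <- dev > crosscheck_tol
      if (any(bad, na.rm = TRUE)) {
        warning("supplied columns disagree with values recomputed from raw ",
                "fluorescence (max abs diff): ",
                paste0(derived_cols[bad], " = ",
                       signif(dev[bad], 3), collapse = ", "),
                call. = FALSE)
      }
    } else {
      for (cl in derived_cols) out[[cl]] <- calc[[cl]]
    }
  }
  out
}

#' Quality-control filter for yield partitions
#'
#' Keeps records whose three quantum yields are each strictly positive and sum
#' to one (within `tol`; the sum is exact when the yields were computed
#' internally, so the tolerance only matters for externally supplied values).
#' Records failing any rule are rejected with a per-rule ledger, mirroring the
#' exclusion of noisy raw measurements in field campaigns.
#'
#' @param records A data.frame carrying `phi_psii`, `phi_no`, `phi_npq`
#'   columns (see [compute_yields()]).
#' @param tol Tolerance on `|phi_psii + phi_no + phi_npq - 1|` (default 1e-6).
#' @return An object of class `qc_result`: a list with `kept` and `rejected`
#'   data.frames (both carrying `qc_pass` and `qc_reason` columns) and `log`,
#'   a data.frame of per-rule rejection counts.
#' @export
qc_filter <- function(records, tol = 1e-6) {
  stopifnot(is.data.frame(records))
  need <- c("phi_psii", "phi_no", "phi_npq")
  if (!all(need %in% names(records))) {
    stop("records lack yield columns; run compute_yields() first",
         call. = FALSE)
  }
  y <- records[need]
  reason <- rep(NA_character_, nrow(records))
  miss <- !stats::complete.cases(y)
  reason[miss & is.na(reason)] <- "unusable_raw_fluorescence"
  flag <- function(cond, lab) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- lab
  }
  flag(y$phi_psii <= 0, "nonpositive_phi_psii")
  flag(y$phi_no <= 0, "nonpositive_phi_no")
  flag(y$phi_npq <= 0, "nonpositive_phi_npq")
  flag(abs(y$phi_psii + y$phi_no + y$phi_npq - 1) > tol, "sum_not_unity")

  out <- records
  out$qc_pass <- is.na(reason)
  out$qc_reason <- reason
  kept <- out[out$qc_pass, , drop = FALSE]
  rejected <- out[!out$qc_pass, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("qc_filter removed every record", call. = FALSE)
  }
  rules <- c("unusable_raw_fluorescence", "nonpositive_phi_psii",
             "nonpositive_phi_no", "nonpositive_phi_npq", "sum_not_unity")
  log <- data.frame(rule = rules,
                    n = vapply(rules, function(r) sum(reason == r, na.rm = TRUE),
                               integer(1)),
                    row.names = NULL)
  structure(list(kept = kept, rejected = rejected, log = log,
                 n_input = nrow(records), tol = tol),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Quality control:", nrow(x$kept), "of", x$n_input, "records kept\n")
  lg <- x$log[x$log$n > 0, , drop = FALSE]
  if (nrow(lg)) {
    for (i in seq_len(nrow(lg))) {
      cat("  rejected ", lg$n[i], " (", lg$rule[i], ")\n", sep = "")
    }
  }
  invisible(x)
}
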