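#' Default column mapping for measurement tables
#'
#' Maps the package's canonical column names to the names found in an input
#' CSV. Override any entry to absorb instrument-specific headers.
#'
#' @return Named character vector `canonical = file_column`.
#' @export
default_column_map <- function() {
  cols <- c("fs", "fm_prime", "fo_prime", "par", "air_temp", "rh", "vpd",
            "height_m", "species", "season", "tree_id", "branch_position",
            "leaf_id", "ql", "npqt", "phi_psii", "phi_no", "phi_npq")
  stats::setNames(cols, cols)
}

#' Read a table of leaf-level measurements
#'
#' Reads a CSV of one row per leaf measurement, renames columns through the
#' mapping, coerces the numeric columns and drops rows whose numeric fields
#' fail to parse (reporting the count). The table must resolve either the
#' raw fluorescence triplet (`fs`, `fm_prime`, `fo_prime`) or precomputed
#' yields, plus `par`, `height_m`, `species` and `season`.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector `canonical = file_column`;
#'   defaults to [default_column_map()]. Only supplied entries override the
#'   defaults.
#' @return data.frame of typed records.
#' @export
read_records <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  present <- map[map %in% names(raw)]
  out <- raw[unname(present)]
  names(out) <- names(present)

  required_any <- list(raw = c("fs", "fm_prime", "fo_prime"),
                       yields = c("phi_psii", "phi_no", "phi_npq"))
  has_mode <- vapply(required_any, function(cl) all(cl %in% names(out)),
                     logical(1))
  if (!any(has_mode)) {
    stop("missing required columns: need ",
         paste(required_any$raw, collapse = ", "), " (raw mode) or ",
         paste(required_any$yields, collapse = ", "), " (yield mode); ",
         "check the column mapping", call. = FALSE)
  }
  for (col in c("par", "height_m", "species", "season")) {
    if (!col %in% names(out)) {
      stop("missing required column: ", col,
           " (mapped from '", map[[col]], "')", call. = FALSE)
    }
  }
  num_cols <- intersect(c("fs", "fm_prime", "fo_prime", "par", "air_temp",
                          "rh", "vpd", "height_m", "ql", "npqt", "phi_psii",
                          "phi_no", "phi_npq"), names(out))
  bad <- rep(FALSE, nrow(out))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- bad | (is.na(v) & !is.na(out[[col]]) & out[[col]] != "")
    out[[col]] <- v
  }
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with unparseable numeric fields")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Derive a stable per-stage seed from the campaign seed (kept below 2^31).
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 1009L) %% 2147483629L
}

#' Run the full energy-partitioning report
#'
#' Chains every stage of the analysis on either a synthetic campaign or a
#' measurement file: yield computation and quality control, per-season strata
#' comparisons and deltas, 1-m vertical profiles, mixed-model driver
#' inference with VIF and variance-component R-squared, season-stratified
#' beta additive models with hierarchical deviance partitioning, and
#' breakpoint/phase analysis per season. Deterministic given the
#' configuration seed: each stochastic stage derives its own seed from it.
#'
#' @param config A [synthetic_config()]; ignored when `input` is given
#'   except for the seed.
#' @param input Optional path to a measurement CSV (see [read_records()]).
#' @param column_map Optional column mapping for `input`.
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV plus one machine-readable JSON bundle and the serialized
#'   configuration.
#' @param n_boot Bootstrap replicates for breakpoint uncertainty
#'   (default 200).
#' @param qc_tol Tolerance for [qc_filter()].
#' @param profile_vars Variables to profile vertically.
#' @param fit_gamms Fit the beta additive models and deviance partitioning
#'   (default `TRUE`; the slowest stage).
#' @return A list bundle (invisibly when `out_dir` is given) with elements
#'   `qc`, `records`, `strata`, `profiles`, `lmm`, `gamm`, `partition`,
#'   `phases`, `errors`.
#' @export
run_report <- function(config = synthetic_config(), input = NULL,
                       column_map = NULL, out_dir = NULL, n_boot = 200,
                       qc_tol = 1e-6,
                       profile_vars = c("par", "vpd", "phi_psii", "phi_no",
                                        "phi_npq", "ql", "npqt"),
                       fit_gamms = TRUE) {
  records <- if (is.null(input)) simulate_campaign(config)
             else read_records(input, column_map)
  records <- compute_yields(records, k_dark = config$k_dark)
  qc <- qc_filter(records, tol = qc_tol)
  kept <- qc$kept
  kept$stratum <- assign_stratum(kept$height_m)
  seasons <- sort(unique(as.character(kept$season)))
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  yields <- c("phi_psii", "phi_no", "phi_npq")
  state_vars <- intersect(c(yields, "ql", "npqt"), names(kept))

  strata <- list()
  profiles <- list()
  lmm <- list()
  for (ssn in seasons) {
    sub <- kept[kept$season == ssn, , drop = FALSE]
    for (v in state_vars) {
      strata[[paste(ssn, v, sep = ".")]] <- run_stage(
        paste("strata", ssn, v),
        list(compare = strata_compare(sub, v),
             deltas = strata_deltas(sub, v)))
    }
    for (v in intersect(profile_vars, names(sub))) {
      profiles[[paste(ssn, v, sep = ".")]] <- run_stage(
        paste("profile", ssn, v), vertical_profile(sub, v))
    }
    for (v in yields) {
      lmm[[paste(ssn, v, sep = ".")]] <- run_stage(
        paste("lmm", ssn, v), fit_lmm(sub, v))
    }
  }
  vifs <- run_stage("vif", lapply(stats::setNames(seasons, seasons),
                                  function(ssn) {
    vif(kept[kept$season == ssn, ], c("par", "vpd", "height_m"))
  }))

  gamm <- list(); partition <- list()
  if (fit_gamms) {
    for (v in yields) {
      gamm[[v]] <- run_stage(paste("gamm", v), fit_gamm(kept, v))
      partition[[v]] <- run_stage(
        paste("partition", v),
        hierarchical_partition(kept, v,
                               c("par", "vpd", "height_m", "species"),
                               family = "beta"))
    }
  }

  phases <- list()
  for (ssn in seasons) {
    phases[[ssn]] <- run_stage(
      paste("phases", ssn),
      phase_analysis(kept, season = ssn, n_boot = n_boot,
                     seed = .stage_seed(config$seed, paste0("phases_", ssn))))
  }

  bundle <- list(qc = qc, records = kept, strata = strata,
                 profiles = profiles, lmm = lmm, vif = vifs, gamm = gamm,
                 partition = partition, phases = phases, errors = errors,
                 seed = config$seed)
  if (length(errors)) {
    warning("stages failed: ", paste(names(errors), collapse = ", "),
            call. = FALSE)
  }
  if (!is.null(out_dir)) {
    .write_bundle(bundle, config, out_dir)
    return(invisible(bundle))
  }
  bundle
}

# Serialize the bundle: CSVs for tables, one JSON with every number the
# human-readable tables carry, plus the configuration for provenance.
.write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wcsv(bundle$qc$log, "qc_log")
  wcsv(bundle$records, "records_qc_passed")

  strata_tab <- do.call(rbind, lapply(names(bundle$strata), function(nm) {
    s <- bundle$strata[[nm]]
    if (is.null(s)) return(NULL)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(season = parts[1], variable = parts[2],
               stratum = names(s$deltas$means),
               mean = unname(s$deltas$means),
               letter = unname(s$compare$letters[names(s$deltas$means)]),
               kw_p = s$compare$kw_p, delta_pp_s1_to_s3 = s$deltas$delta_pp,
               row.names = NULL)
  }))
  if (!is.null(strata_tab)) wcsv(strata_tab, "strata_summary")

  lmm_tab <- do.call(rbind, lapply(names(bundle$lmm), function(nm) {
    f <- bundle$lmm[[nm]]
    if (is.null(f)) return(NULL)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cbind(data.frame(season = parts[1], response = parts[2]),
          f$coefficients,
          r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
          n = f$n)
  }))
  if (!is.null(lmm_tab)) wcsv(lmm_tab, "lmm_coefficients")

  part_tab <- do.call(rbind, lapply(names(bundle$partition), function(v) {
    p <- bundle$partition[[v]]
    if (is.null(p)) return(NULL)
    cbind(response = v, p,
          deviance_explained = attr(p, "deviance_explained"))
  }))
  if (!is.null(part_tab)) wcsv(part_tab, "deviance_partition")

  bp_tab <- do.call(rbind, lapply(names(bundle$phases), function(ssn) {
    ph <- bundle$phases[[ssn]]
    if (is.null(ph) || !nrow(ph$breakpoints)) return(NULL)
    cbind(season = ssn, ph$breakpoints,
          edf = ph$edf, deviance_explained = ph$deviance_explained)
  }))
  if (!is.null(bp_tab)) wcsv(bp_tab, "breakpoints")

  json <- list(
    seed = bundle$seed,
    qc = list(n_input = bundle$qc$n_input, n_kept = nrow(bundle$qc$kept),
              log = bundle$qc$log),
    strata = strata_tab, lmm = lmm_tab, vif = bundle$vif,
    partition = part_tab, breakpoints = bp_tab,
    phases = lapply(bundle$phases, function(ph) {
      if (is.null(ph)) NULL else ph$phases
    }),
    errors = bundle$errors)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
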