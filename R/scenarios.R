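#' Load a scenario registry from a YAML configuration file
#'
#' The configuration declares units (pmol/L, min), the activity-weight
#' block, a PK preset and a list of named secretion scenarios.  A scenario
#' either gives the square-wave parameters directly (`gamma0`, `gamma1`,
#' `tau1`, `period`, pulsatile fraction `r`, `provenance`) or derives from
#' another via `derive_from` plus `tonic_scale` (the tonic level is scaled,
#' pulses are left unchanged, and `r` is recomputed).
#'
#' Validation errors name the offending scenario; declared `r` values must
#' agree with the pattern's own AUC decomposition.
#'
#' @param path YAML file; defaults to the synthetic registry shipped with
#'   the package.
#' @return An object of class `pth_registry`: a named list of
#'   `pth_scenario` objects with attributes `activity`, `pk` and `units`.
#' @export
#' @examples
#' reg <- load_scenarios()
#' names(reg)
#' reg$healthy$stimulus
load_scenarios <- function(path = default_config_path()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) stop("config has no 'scenarios' block")
  units <- cfg$units
  if (!is.null(units)) {
    if (!identical(units$concentration, "pmol/L"))
      stop(sprintf("unsupported concentration unit '%s' (expected pmol/L)",
                   units$concentration))
    if (!identical(units$time, "min"))
      stop(sprintf("unsupported time unit '%s' (expected min)", units$time))
  }
  nm <- vapply(cfg$scenarios, function(s) s$name %||% NA_character_, character(1))
  if (anyNA(nm)) stop("every scenario must have a 'name'")
  if (anyDuplicated(nm))
    stop("duplicate scenario name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  reg <- list()
  for (s in cfg$scenarios) {
    if (!is.null(s$derive_from)) {
      base <- reg[[s$derive_from]]
      if (is.null(base))
        stop(sprintf("scenario '%s' derives from unknown scenario '%s'",
                     s$name, s$derive_from))
      sc <- s$tonic_scale %||% 1
      b <- base$stimulus
      g0 <- b$gamma0 * sc
      stim <- square_wave(g0, g0 + (b$gamma1 - b$gamma0), b$tau1, b$period)
      r <- auc_decomposition(stim, stim$period)$r
    } else {
      need <- c("gamma0", "gamma1", "tau1", "period", "r")
      miss <- need[!need %in% names(s)]
      if (length(miss))
        stop(sprintf("scenario '%s' is missing field(s): %s",
                     s$name, paste(miss, collapse = ", ")))
      if (s$gamma1 < s$gamma0)
        stop(sprintf("scenario '%s': gamma1 < gamma0", s$name))
      stim <- square_wave(s$gamma0, s$gamma1, s$tau1, s$period)
      r <- s$r
      r_own <- auc_decomposition(stim, stim$period)$r
      if (abs(r - r_own) > 1e-4)
        stop(sprintf("scenario '%s': declared r = %.6g disagrees with the pattern's own r = %.6g",
                     s$name, r, r_own))
    }
    prov <- s$provenance %||% ""
    if (!nzchar(prov))
      stop(sprintf("scenario '%s' has no provenance note", s$name))
    reg[[s$name]] <- structure(list(name = s$name, stimulus = stim, r = r,
                                    provenance = prov),
                               class = "pth_scenario")
  }
  structure(reg, class = c("pth_registry", "list"),
            activity = cfg$activity, pk = cfg$pk, units = units,
            kinetics = cfg$kinetics, source = normalizePath(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario registry back to YAML
#'
#' Inverse of [load_scenarios()]: the written file reloads to an identical
#' registry (derived scenarios are written in resolved form).
#'
#' @param registry a `pth_registry`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(registry, path) {
  stopifnot(inherits(registry, "pth_registry"))
  scen <- lapply(unclass(registry), function(s) {
    st <- s$stimulus
    list(name = s$name, gamma0 = st$gamma0, gamma1 = st$gamma1,
         tau1 = st$tau1, period = st$period, r = s$r,
         provenance = s$provenance)
  })
  cfg <- list(units = attr(registry, "units") %||%
                list(concentration = "pmol/L", time = "min"),
              activity = attr(registry, "activity"),
              pk = attr(registry, "pk"),
              scenarios = unname(scen))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @export
print.pth_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' (r = %.3f): ", x$name, x$r))
  print(x$stimulus)
  invisible(x)
}

#' @export
print.pth_registry <- function(x, ...) {
  cat(sprintf("scenario registry (%d scenarios):\n", length(x)))
  for (s in x)
    cat(sprintf("  %-22s gamma0 %7.3f  gamma1 %7.3f  tau1 %4.1f  T %6.2f  r %.3f\n",
                s$name, s$stimulus$gamma0, s$stimulus$gamma1,
                s$stimulus$tau1, s$stimulus$period, s$r))
  invisible(x)
}

#' Path of the shipped synthetic scenario configuration
#' @return File path of `scenarios_synthetic.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "scenarios_synthetic.yaml", package = "pthpulse",
              mustWork = TRUE)
}

#' Default activity coefficients from a registry's configuration
#'
#' @param params a [pth_kinetics()] object.
#' @param registry a `pth_registry` (its `activity` attribute supplies
#'   `a1`, `a3`, `a4`, `s`).
#' @return An [activity_coefficients()] object.
#' @export
default_coefficients <- function(params, registry = load_scenarios()) {
  act <- attr(registry, "activity")
  if (is.null(act)) stop("registry carries no activity-weight block")
  activity_coefficients(act$a1, act$a3, act$a4, params, s = act$s %||% 100)
}

#' Kinetic parameters from a registry's configuration
#'
#' Builds a [pth_kinetics()] object from the optional `kinetics` block of a
#' scenario configuration file (fields mirror the [pth_kinetics()]
#' arguments, with dissociation constants tagged by `conc_unit`); a
#' registry without that block yields the package defaults.
#'
#' @param registry a `pth_registry`.
#' @return A [pth_kinetics()] object.
#' @export
default_kinetics <- function(registry = load_scenarios()) {
  k <- attr(registry, "kinetics")
  if (is.null(k)) return(pth_kinetics())
  pth_kinetics(k1 = k$k1 %||% 0.012, k_minus1 = k$k_minus1 %||% 0.104,
               k2 = k$k2 %||% 0.222, k_minus2 = k$k_minus2 %||% 0.055,
               Kr = k$Kr %||% 1, Kd = k$Kd %||% 1000,
               off_rate_active = k$off_rate_active %||% 10,
               off_rate_inactive = k$off_rate_inactive %||% 10,
               conc_unit = k$conc_unit %||% "nM",
               detailed_balance = k$detailed_balance %||% TRUE)
}

#' Default PK preset from a registry's configuration
#'
#' @param registry a `pth_registry`.
#' @return A [pk_parameters()] object.
#' @export
default_pk <- function(registry = load_scenarios()) {
  p <- attr(registry, "pk")
  if (is.null(p)) stop("registry carries no PK block")
  pk_parameters(p$k_a, p$k_e, p$V_d, p$F,
                molar_mass = p$molar_mass %||% 4117.8,
                provenance = p$provenance %||% "")
}

#' Draw random physiological square-wave stimuli
#'
#' Fixture generator for property-style tests: tonic level, peak/tonic
#' ratio, on-phase and period are drawn uniformly from physiological
#' ranges (the defaults span tonic 1-10 pmol/L, peaks up to 10x tonic,
#' bursts of 1-30 min and periods up to 2 h).  Deterministic for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param n number of stimuli.
#' @param seed optional integer seed.
#' @param gamma0_range,amp_ratio_range,tau1_range,period_range ranges for
#'   `gamma0` (pmol/L), `gamma1/gamma0`, `tau1` (min) and the period (min);
#'   the period is drawn from `[max(tau1 + 1, period_range[1]),
#'   period_range[2]]` (an `NA` lower bound means `tau1 + 1`).
#' @return A [square_wave()] for `n = 1`, else a list of them.
#' @export
generate_test_stimulus <- function(n = 1, seed = NULL,
                                   gamma0_range = c(1, 10),
                                   amp_ratio_range = c(1, 10),
                                   tau1_range = c(1, 30),
                                   period_range = c(NA, 120)) {
  for (rg in list(gamma0_range, amp_ratio_range, tau1_range))
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[2] < rg[1])
      stop("invalid (empty) range")
  if (!is.finite(period_range[2])) stop("invalid (empty) range")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  out <- replicate(n, {
    g0 <- stats::runif(1, gamma0_range[1], gamma0_range[2])
    g1 <- g0 * stats::runif(1, amp_ratio_range[1], amp_ratio_range[2])
    t1 <- stats::runif(1, tau1_range[1], tau1_range[2])
    lo <- max(t1 + 1, if (is.finite(period_range[1])) period_range[1] else 0)
    if (lo >= period_range[2]) stop("invalid (empty) range: tau1 + 1 >= max period")
    Tp <- stats::runif(1, lo, period_range[2])
    square_wave(g0, g1, t1, Tp)
  }, simplify = FALSE)
  if (n == 1) out[[1]] else out
}

# deterministic polynomial hash of the deparsed snapshot (mod 2^31 - 1)
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run manifest
#'
#' Compact provenance record attached to result files: a deterministic
#' hash of the parameter snapshot, the package version, the adaptation-time
#' criterion and the binding off-rates in force.
#'
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @param tau_a_criterion the adaptation-time criterion used.
#' @param timestamp optional timestamp string; omitted by default so that
#'   repeated runs produce byte-identical outputs.
#' @return A list of class `run_manifest` with an `id` field.
#' @export
run_manifest <- function(params, coeffs, tau_a_criterion = exp(-1),
                         timestamp = NULL) {
  snap <- list(kinetics = unclass(params), coefficients = unclass(coeffs),
               tau_a_criterion = tau_a_criterion)
  m <- list(id = config_hash(snap),
            package = "pthpulse",
            version = as.character(utils::packageVersion("pthpulse")),
            tau_a_criterion = tau_a_criterion,
            off_rates = c(k_minusr = params$k_minusr, k_minusd = params$k_minusd),
            parameters = snap)
  if (!is.null(timestamp)) m$timestamp <- timestamp
  class(m) <- "run_manifest"
  m
}

#' Recompute a results table across the scenario registry
#'
#' `"table2"` compares the combined gland+injection responsiveness of the
#' one-simulation and separable superposition models across daily doses;
#' `"table3"` tabulates, per scenario, the baseline responsiveness, the
#' AUC-constrained maximum and the pattern targeting the healthy baseline
#' (cells whose target problem is infeasible are `NA` with a reason);
#' `"table4"` optimises the fractionation of daily injection doses and the
#' dose that fills the reference deficit of the `OP` scenario.
#'
#' Output is deterministic: identical inputs give byte-identical CSVs.
#'
#' @param table one of `"table2"`, `"table3"`, `"table4"`.
#' @param registry a `pth_registry`.
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @param pk a [pk_parameters()] object (needed for tables 2 and 4).
#' @param scenarios optional character vector restricting the scenarios.
#' @param doses daily doses (micrograms) for tables 2 and 4.
#' @param starts optional multistart override for the glandular problems
#'   (see [maximise_glandular()]).
#' @param path optional CSV output path; a manifest reference comment line
#'   and a header row are written.
#' @return The table as a data frame (full precision, plus `*_display`
#'   columns rounded to 3 decimals), invisibly also written to `path`.
#' @export
reproduce_table <- function(table = c("table2", "table3", "table4"),
                            registry, params, coeffs, pk = NULL,
                            scenarios = NULL, doses = c(0, 10, 20, 30),
                            starts = NULL, path = NULL) {
  table <- match.arg(table)
  if (table %in% c("table2", "table4") && is.null(pk))
    stop(sprintf("'%s' needs a PK preset", table))
  pick <- function(r, nm) {
    if (is.null(nm)) r else r[intersect(nm, names(r))]
  }
  df <- switch(table,
    table2 = {
      sel <- pick(registry, scenarios %||% c("healthy", "OP", "HP"))
      rows <- list()
      for (sc in sel) for (D in doses) {
        inj <- if (D > 0) injection_square_wave(D, pk, sc$stimulus$gamma0) else NULL
        m1 <- responsiveness_model1(sc$stimulus, inj, params, coeffs)
        m2 <- responsiveness_model2(sc$stimulus, inj, params, coeffs)
        rows[[length(rows) + 1L]] <-
          data.frame(scenario = sc$name, dose_ug = D,
                     alpha_R_model1 = m1$alpha_R_total,
                     alpha_R_model2 = m2$alpha_R_total,
                     alpha_R_inj = m2$alpha_R_inj)
      }
      do.call(rbind, rows)
    },
    table3 = {
      sel <- pick(registry, scenarios)
      ref <- cellular_responsiveness(registry$healthy$stimulus, params, coeffs)$alpha_R
      rows <- list()
      for (sc in sel) {
        base <- cellular_responsiveness(sc$stimulus, params, coeffs)$alpha_R
        mx <- maximise_glandular(sc, params, coeffs, starts = starts)
        tg <- target_glandular(sc, ref, params, coeffs, starts = starts)
        ok <- tg$feasible
        rows[[length(rows) + 1L]] <-
          data.frame(scenario = sc$name, alpha_R = base,
                     alpha_R_max = mx$alpha_R,
                     tau1_max = mx$stimulus$tau1, T_max = mx$stimulus$period,
                     gamma1_max = mx$stimulus$gamma1,
                     tau1_star = if (ok) tg$stimulus$tau1 else NA_real_,
                     T_star = if (ok) tg$stimulus$period else NA_real_,
                     gamma1_star = if (ok) tg$stimulus$gamma1 else NA_real_,
                     target_note = if (ok) "" else
                       sprintf("target %.4g outside attainable range (residual %.3g)",
                               ref, tg$residual))
      }
      do.call(rbind, rows)
    },
    table4 = {
      ref_sc <- registry[[scenarios %||% "OP"]] %||% registry$OP
      refR <- cellular_responsiveness(registry$healthy$stimulus, params, coeffs)$alpha_R
      illR <- cellular_responsiveness(ref_sc$stimulus, params, coeffs)$alpha_R
      rows <- list()
      for (D in setdiff(doses, 0)) {
        mx <- maximise_injection(D, pk, ref_sc$stimulus$gamma0, params, coeffs)
        rows[[length(rows) + 1L]] <-
          data.frame(column = sprintf("%g ug daily", D),
                     alpha_R_max = mx$alpha_R, D_max = mx$D_max,
                     tau1_max = mx$stimulus$tau1, T_max = mx$stimulus$period,
                     gamma1_max = mx$stimulus$gamma1)
      }
      tg <- target_injection_dose(refR, illR, pk, ref_sc$stimulus$gamma0,
                                  params, coeffs)
      inj <- injection_square_wave(max(tg$D_star, 1e-6), pk, ref_sc$stimulus$gamma0)
      rows[[length(rows) + 1L]] <-
        data.frame(column = "optimised daily dose",
                   alpha_R_max = tg$alpha_R_inj, D_max = tg$D_star,
                   tau1_max = inj$tau1, T_max = inj$period,
                   gamma1_max = inj$gamma1)
      do.call(rbind, rows)
    })
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[paste0(cn, "_display")]] <- round(df[[cn]], 3)
  if (!is.null(path)) {
    man <- run_manifest(params, coeffs)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# manifest: %s (pthpulse %s)", man$id, man$version), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  df
}
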