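#' Square-wave ligand stimulus
#'
#' Periodic plasma PTH profile: the concentration is `gamma1` during the
#' on-phase `[(n-1)T, (n-1)T + tau1)` of every period and `gamma0` (the
#' tonic level) during the off-phase; evaluation is right-continuous at the
#' switch points.
#'
#' @param gamma0 tonic concentration (pmol/L), `0 <= gamma0 <= gamma1`.
#' @param gamma1 pulse peak concentration (pmol/L).
#' @param tau1 on-phase duration (min), `0 < tau1 <= period`.
#' @param period pulse period `T` (min).
#' @return An object of class `square_wave` with fields `gamma0`, `gamma1`,
#'   `tau1`, `period` and derived `tau0 = period - tau1`.
#' @export
#' @examples
#' sw <- square_wave(3, 8, 5, 15)
#' stimulus_value(sw, c(0, 5.01, 15))
square_wave <- function(gamma0, gamma1, tau1, period) {
  vals <- c(gamma0 = gamma0, gamma1 = gamma1, tau1 = tau1, period = period)
  if (any(!is.finite(vals))) stop("square_wave parameters must be finite")
  if (gamma0 < 0 || gamma1 < gamma0)
    stop("need 0 <= gamma0 <= gamma1")
  if (tau1 <= 0 || tau1 > period)
    stop("need 0 < tau1 <= period")
  structure(list(gamma0 = gamma0, gamma1 = gamma1, tau1 = tau1,
                 period = period, tau0 = period - tau1),
            class = "square_wave")
}

#' @export
print.square_wave <- function(x, ...) {
  cat(sprintf(paste0("square-wave stimulus: gamma0 = %.4g, gamma1 = %.4g pmol/L; ",
                     "tau1 = %.4g, T = %.4g min (duty %.1f%%)\n"),
              x$gamma0, x$gamma1, x$tau1, x$period, 100 * x$tau1 / x$period))
  invisible(x)
}

#' Evaluate a stimulus at given times
#'
#' @param stimulus a [square_wave()].
#' @param t vector of times (min), `>= 0`.
#' @return Ligand concentrations (pmol/L); right-continuous at switches.
#' @export
stimulus_value <- function(stimulus, t) UseMethod("stimulus_value")

#' @export
stimulus_value.square_wave <- function(stimulus, t) {
  if (any(t < 0)) stop("'t' must be >= 0")
  tm <- t %% stimulus$period
  ifelse(tm < stimulus$tau1, stimulus$gamma1, stimulus$gamma0)
}

#' Tonic/pulsatile decomposition of the stimulus AUC
#'
#' Over a window `[0, s]` the integrated concentration splits as
#' `A = A_tonic + A_puls` with `A_tonic = gamma0 * s` and, for windows that
#' are whole multiples of the period, the closed form
#' `A = gamma0 * s + (gamma1 - gamma0) * tau1 * s / T`.  Non-multiple
#' windows are computed exactly from the partial period and flagged.
#'
#' @param stimulus a [square_wave()].
#' @param window window length `s` (min), `> 0`.
#' @return An object of class `auc_decomposition`: list with `A`, `A_tonic`,
#'   `A_puls` (pmol min/L), the pulsatile fraction `r = A_puls/A`, `window`,
#'   and `commensurate` (is `s` a whole number of periods?).
#' @export
#' @examples
#' auc_decomposition(square_wave(5, 10, 10, 50), 100)  # A = 600, r = 1/6
auc_decomposition <- function(stimulus, window) {
  stopifnot(inherits(stimulus, "square_wave"))
  if (!is.finite(window) || window <= 0) stop("'window' must be > 0")
  Tp <- stimulus$period
  k <- floor(window / Tp + 1e-12)
  rem <- window - k * Tp
  commensurate <- abs(rem) < 1e-9 * Tp
  on_time <- k * stimulus$tau1 + min(max(rem, 0), stimulus$tau1)
  A_tonic <- stimulus$gamma0 * window
  A_puls <- (stimulus$gamma1 - stimulus$gamma0) * on_time
  A <- A_tonic + A_puls
  structure(list(A = A, A_tonic = A_tonic, A_puls = A_puls,
                 r = if (A > 0) A_puls / A else 0,
                 window = window, commensurate = commensurate),
            class = "auc_decomposition")
}

#' @export
print.auc_decomposition <- function(x, ...) {
  cat(sprintf("AUC over %.5g min: A = %.6g = tonic %.6g + pulsatile %.6g (r = %.4f)%s\n",
              x$window, x$A, x$A_tonic, x$A_puls, x$r,
              if (x$commensurate) "" else "  [window not a whole number of periods]"))
  invisible(x)
}

#' One-compartment subcutaneous pharmacokinetic parameters
#'
#' Absorption from the injection site and first-order elimination from
#' plasma: `dD/dt = -k_a F D`, `dL/dt = (F k_a / V_d) D - k_e L`.
#'
#' @param k_a absorption rate constant (min^-1).
#' @param k_e elimination rate constant (min^-1).
#' @param V_d distribution volume (L).
#' @param F bioavailability, in `(0, 1]`.
#' @param molar_mass ligand molar mass (g/mol), used to convert microgram
#'   doses to pmol; default is PTH(1-34).
#' @param provenance free-text note on where the values come from.
#' @return An object of class `pk_parameters`.
#' @seealso [pk_preset()] for the shipped PTH(1-34) values.
#' @export
pk_parameters <- function(k_a, k_e, V_d, F, molar_mass = 4117.8,
                          provenance = "") {
  vals <- c(k_a = k_a, k_e = k_e, V_d = V_d, F = F, molar_mass = molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK parameters must be strictly positive")
  if (F > 1) stop("bioavailability 'F' cannot exceed 1")
  structure(list(k_a = k_a, k_e = k_e, V_d = V_d, F = F,
                 molar_mass = molar_mass, provenance = provenance),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("one-compartment sc PK: k_a = %g, k_e = %g min^-1; V_d = %g L; F = %g\n",
              x$k_a, x$k_e, x$V_d, x$F))
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

dose_ug_to_pmol <- function(D, pk) D * 1e6 / pk$molar_mass

#' Plasma concentration after a single subcutaneous dose
#'
#' Closed-form (Bateman) solution of the one-compartment model,
#' `L(t) = F k_a D / (V_d (k_a - k_e)) (exp(-k_e t) - exp(-k_a t))` after
#' converting the microgram dose to pmol; the equal-rate limit uses
#' `t exp(-k t)`.  The analytic area under the curve is
#' `F D / (V_d k_e)`.
#'
#' @param D dose (micrograms), `>= 0`.
#' @param pk a [pk_parameters()] object.
#' @param t times after injection (min).
#' @return Drug plasma concentrations (pmol/L, above any endogenous
#'   baseline).
#' @export
pk_concentration <- function(D, pk, t) {
  stopifnot(inherits(pk, "pk_parameters"))
  if (!is.finite(D) || D < 0) stop("dose 'D' must be >= 0")
  Dp <- dose_ug_to_pmol(D, pk)
  ka <- pk$k_a; ke <- pk$k_e
  if (abs(ka - ke) < 1e-10 * ka) {
    pk$F * ka^2 * Dp / pk$V_d * t * exp(-ka * t) / ka
  } else {
    pk$F * ka * Dp / (pk$V_d * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Analytic summary quantities of the single-dose PK curve
#'
#' @inheritParams pk_concentration
#' @return List with `auc` (pmol min/L), `t_max` (min) and `c_max` (pmol/L).
#' @export
pk_summary <- function(D, pk) {
  stopifnot(inherits(pk, "pk_parameters"))
  Dp <- dose_ug_to_pmol(D, pk)
  ka <- pk$k_a; ke <- pk$k_e
  t_max <- if (abs(ka - ke) < 1e-10 * ka) 1 / ka else log(ka / ke) / (ka - ke)
  list(auc = pk$F * Dp / (pk$V_d * ke),
       t_max = t_max,
       c_max = pk_concentration(D, pk, t_max))
}

#' Sampled PK curve
#'
#' @inheritParams pk_concentration
#' @param horizon curve length (min).
#' @param dt sampling step (min).
#' @return Data frame with `time_min` and `concentration_pmol_per_L`.
#' @export
pk_curve <- function(D, pk, horizon = 1440, dt = 1) {
  t <- seq(0, horizon, by = dt)
  data.frame(time_min = t,
             concentration_pmol_per_L = pk_concentration(D, pk, t))
}

#' Equal-AUC square-wave reduction of an injection PK curve
#'
#' Replaces the single-dose PK curve, riding on the tonic level `gamma0`,
#' by a rectangular pulse with the same peak and the same area above
#' `gamma0`: the peak is `gamma1 = gamma0 + max(L_PK)` and the on-phase is
#' `tau1 = A_PK / (gamma1 - gamma0)`.  Under linear kinetics `tau1` is
#' dose-independent and the area scales with the dose.
#'
#' @param D dose per injection (micrograms), `> 0`.
#' @param pk a [pk_parameters()] object.
#' @param gamma0 tonic baseline (pmol/L).
#' @param T_inj injection period (min); default once daily.
#' @return A [square_wave()] with period `T_inj`.
#' @export
injection_square_wave <- function(D, pk, gamma0, T_inj = 1440) {
  if (!is.finite(D) || D <= 0) stop("dose 'D' must be > 0")
  s <- pk_summary(D, pk)
  if (s$c_max <= 0)
    stop("PK peak does not rise above the tonic baseline; square-wave reduction infeasible")
  tau1 <- s$auc / s$c_max
  if (tau1 >= T_inj)
    stop(sprintf("reduced on-phase (%.4g min) is not shorter than the injection period (%g min)",
                 tau1, T_inj))
  square_wave(gamma0, gamma0 + s$c_max, tau1, T_inj)
}

#' Responsiveness of combined gland + injection stimulation, separable model
#'
#' The receptor system is simulated independently for the glandular square
#' wave and for the injection square wave, and the total cellular
#' responsiveness is the sum of the two components (additive
#' superposition).
#'
#' @param gland glandular [square_wave()].
#' @param inj injection [square_wave()] (e.g. from
#'   [injection_square_wave()]), or `NULL` for no injection.
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @param ... passed to [cellular_responsiveness()].
#' @return List of class `pth_combined` with components `alpha_R_gl`,
#'   `alpha_R_inj`, `alpha_R_total`, `model = "model2"` and the two
#'   component results.
#' @export
responsiveness_model2 <- function(gland, inj, params, coeffs, ...) {
  rg <- cellular_responsiveness(gland, params, coeffs, ...)
  if (is.null(inj)) {
    ri <- NULL
    aRi <- 0
  } else {
    ri <- cellular_responsiveness(inj, params, coeffs, ...)
    aRi <- ri$alpha_R
  }
  structure(list(alpha_R_gl = rg$alpha_R, alpha_R_inj = aRi,
                 alpha_R_total = rg$alpha_R + aRi,
                 model = "model2", gland = rg, injection = ri),
            class = "pth_combined")
}

#' Responsiveness of combined gland + injection stimulation, one simulation
#'
#' The summed ligand signal `L(t) = L_gl(t) + (L_inj(t) - gamma0)` (the
#' tonic baseline is counted once; set `baseline_correction = FALSE` for the
#' naive sum) is simulated over one injection period at its periodic steady
#' state, and the excess-activity integral is split between the two
#' stimulus components: the glandular share per gland period is the excess
#' integral over the last gland period of the injection cycle (where the
#' injection transient has washed out), and the injection share is the
#' remainder of the whole-cycle excess integral.  Each share is scaled into
#' a responsiveness with its own step response and period, so with no
#' injection the result reduces exactly to the glandular
#' [cellular_responsiveness()].  The glandular period is rescaled by less
#' than 2% if needed so that an integer number of gland pulses fits into
#' the injection period.
#'
#' @inheritParams responsiveness_model2
#' @param baseline_correction subtract the shared tonic level from the
#'   injection wave before summing (default `TRUE`).
#' @return List of class `pth_combined` with the component and total
#'   responsiveness values.
#' @export
responsiveness_model1 <- function(gland, inj, params, coeffs,
                                  baseline_correction = TRUE, ...) {
  if (is.null(inj)) {
    rg <- cellular_responsiveness(gland, params, coeffs, ...)
    return(structure(list(alpha_R_gl = rg$alpha_R, alpha_R_inj = 0,
                          alpha_R_total = rg$alpha_R, model = "model1",
                          gland = rg, injection = NULL),
                     class = "pth_combined"))
  }
  stopifnot(inherits(gland, "square_wave"), inherits(inj, "square_wave"))
  T_inj <- inj$period
  n_gl <- max(1L, round(T_inj / gland$period))
  T_gl <- T_inj / n_gl
  rescale <- abs(T_gl - gland$period) / gland$period
  if (rescale > 0.02)
    warning(sprintf("gland period rescaled by %.1f%% to commensurate with the injection period",
                    100 * rescale))
  gl <- square_wave(gland$gamma0, gland$gamma1, gland$tau1, T_gl)

  # breakpoints of the summed piecewise-constant signal over [0, T_inj]
  bp <- sort(unique(c(0, T_inj, inj$tau1,
                      as.vector(outer(c(0, gl$tau1), (seq_len(n_gl) - 1) * T_gl, "+")))))
  bp <- bp[bp >= 0 & bp <= T_inj]
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  base <- if (baseline_correction) gland$gamma0 else 0
  vals <- stimulus_value(gl, mid) + stimulus_value(inj, mid) - base
  seg <- data.frame(start = bp[-length(bp)], end = bp[-1], value = vals)

  x0 <- periodic_state_segments(seg, params)
  alpha0 <- basal_activity(coeffs, params, gamma0 = gland$gamma0)

  # exact activity integral per segment at the periodic steady state
  x <- as.numeric(x0)
  a <- coefficient_vector(coeffs)
  int_seg <- numeric(nrow(seg))
  for (s in seq_len(nrow(seg))) {
    fl <- kinetic_flow(rate_matrix(seg$value[s], params))
    dt <- seg$end[s] - seg$start[s]
    int_seg[s] <- drop(a %*% fl$J(dt) %*% x)
    x <- drop(fl$E(dt) %*% x)
  }
  excess <- int_seg - alpha0 * (seg$end - seg$start)
  total_excess <- sum(excess)
  # glandular share: excess over the last gland period (injection washed out)
  tail_start <- (n_gl - 1L) * T_gl
  in_tail <- seg$start >= tail_start - 1e-9
  aT_gl <- sum(excess[in_tail])
  aT_inj <- total_excess - n_gl * aT_gl

  sr_inj <- step_response(gland$gamma0, inj$gamma1, params, coeffs, ...)
  aR_inj <- aT_inj^2 / (sr_inj$alpha_T_step * T_inj)
  sr_gl <- step_response(gland$gamma0, gland$gamma1, params, coeffs, ...)
  aR_gl <- aT_gl^2 / (sr_gl$alpha_T_step * T_gl)

  structure(list(alpha_R_gl = aR_gl, alpha_R_inj = aR_inj,
                 alpha_R_total = aR_gl + aR_inj, model = "model1",
                 alpha_T_inj = aT_inj, alpha_T_gl = aT_gl,
                 alpha_T_total = total_excess,
                 gland_period = T_gl, segments = seg),
            class = "pth_combined")
}

#' @export
print.pth_combined <- function(x, ...) {
  cat(sprintf("combined responsiveness (%s): gland %.4g + injection %.4g = %.4g\n",
              x$model, x$alpha_R_gl, x$alpha_R_inj, x$alpha_R_total))
  invisible(x)
}
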