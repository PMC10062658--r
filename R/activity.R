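#' Exact-adaptation value of the complex-activity weight
#'
#' Given the weights of the active receptor (`a1`), inactive complex (`a3`)
#' and inactive receptor (`a4`), returns the active-complex weight `a2` for
#' which the steady-state scaled activity is independent of the (constant)
#' ligand level:
#' `a2 = (((a1 K1 + a4) / (K1 + 1)) (K2 + 1) - a3) / K2`.
#' Uniform weights are a fixed point of the construction: `a1 = a3 = a4 = c`
#' gives `a2 = c`.  Exactness of the adaptation additionally requires the
#' kinetics to satisfy detailed balance (the default of [pth_kinetics()]).
#'
#' @param a1,a3,a4 non-negative activity weights.
#' @param K1,K2 conversion equilibrium ratios (`k_minus1/k1`, `k_minus2/k2`).
#' @return The weight `a2 >= 0`.
#' @export
a2_exact_adaptation <- function(a1, a3, a4, K1, K2) {
  if (any(c(a1, a3, a4) < 0)) stop("activity weights must be non-negative")
  if (K1 <= 0 || K2 <= 0) stop("'K1' and 'K2' must be positive")
  a2 <- (((a1 * K1 + a4) / (K1 + 1)) * (K2 + 1) - a3) / K2
  if (a2 < 0)
    stop(sprintf(paste0("exact adaptation would need a negative a2 (%.4g) for ",
                        "a1 = %g, a3 = %g, a4 = %g; reduce a3"), a2, a1, a3, a4))
  a2
}

#' Activity coefficients with exact adaptation
#'
#' The scaled activity is the weighted sum
#' `alpha = a1 r_a + a2 c_a + a3 c_i + a4 r_i` of the receptor-state
#' fractions.  `a2` is always constructed by [a2_exact_adaptation()] so that
#' the activity adapts exactly to constant stimuli, and all four weights are
#' then multiplied by the scale factor `s`.
#'
#' The absolute scale of the weights is not identifiable from the receptor
#' model (every responsiveness summary is homogeneous of degree one in
#' them); the default scenario configuration anchors it so that the healthy
#' reference secretion pattern scores a cellular responsiveness of 0.939
#' activity units, matching published estimates for healthy adults.
#'
#' @param a1,a3,a4 non-negative weights before scaling.
#' @param params a [pth_kinetics()] object (supplies `K1`, `K2`).
#' @param s overall scale factor.
#' @return An object of class `activity_coefficients` with fields
#'   `a1`..`a4` (scaled) and `s`.
#' @export
activity_coefficients <- function(a1, a3, a4, params, s = 100) {
  stopifnot(inherits(params, "pth_kinetics"))
  if (s <= 0) stop("scale factor 's' must be positive")
  r <- kinetic_ratios(params)
  a2 <- a2_exact_adaptation(a1, a3, a4, r$K1, r$K2)
  structure(list(a1 = a1 * s, a2 = a2 * s, a3 = a3 * s, a4 = a4 * s, s = s),
            class = "activity_coefficients")
}

#' @export
print.activity_coefficients <- function(x, ...) {
  cat(sprintf("activity coefficients (scale s = %g): a = (%.5g, %.5g, %.5g, %.5g)\n",
              x$s, x$a1, x$a2, x$a3, x$a4))
  invisible(x)
}

coefficient_vector <- function(coeffs) {
  stopifnot(inherits(coeffs, "activity_coefficients"))
  c(coeffs$a1, coeffs$a2, coeffs$a3, coeffs$a4)
}

#' Scaled activity of a receptor state
#'
#' @param state a [receptor_state()].
#' @param coeffs an [activity_coefficients()] object.
#' @return The activity `a1 r_a + a2 c_a + a3 c_i + a4 r_i` (activity
#'   units); linear in both arguments.
#' @export
scaled_activity <- function(state, coeffs) {
  sum(coefficient_vector(coeffs) * as.numeric(state))
}

#' Basal activity
#'
#' Activity at the receptor equilibrium under the tonic ligand level.
#' With exact-adaptation coefficients (and detailed-balance kinetics) this
#' equals the steady-state activity under any constant stimulus, so the
#' basal activity is a unique reference value; the closed form at zero
#' ligand is `(a1 K1 + a4) / (K1 + 1)`.
#'
#' @param coeffs an [activity_coefficients()] object.
#' @param params a [pth_kinetics()] object.
#' @param gamma0 tonic ligand level (pmol/L) at which the reference is
#'   evaluated.
#' @return Basal activity `alpha_0` (activity units).
#' @export
basal_activity <- function(coeffs, params, gamma0 = 0) {
  scaled_activity(equilibrium_state(gamma0, params), coeffs)
}

#' Response to a step increase in ligand
#'
#' The receptor is equilibrated at `gamma0` and stepped to the constant
#' level `gamma1` at time zero.  Returned are the peak activity
#' `alpha_M_step = max_t alpha(t)`, the adaptation time `tau_a` and the
#' integrated step activity `alpha_T_step = tau_a * alpha_M_step`.
#'
#' The adaptation time is the first time after the activity peak at which
#' `|alpha(t) - alpha_s|` falls below `tau_a_criterion` times the peak
#' excursion `|alpha_M_step - alpha_s|`, where `alpha_s` is the post-step
#' steady-state activity; the criterion fraction (default `exp(-1)`;
#' common alternatives 0.05 and 0.02) is recorded in the result.
#'
#' @param gamma0 pre-step ligand level (pmol/L), `>= 0`.
#' @param gamma1 post-step level (pmol/L), `> gamma0`.
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @param tau_a_criterion relaxation fraction defining the adaptation time.
#' @return An object of class `step_response`: list with `alpha_M_step`,
#'   `t_peak`, `tau_a`, `alpha_T_step`, `alpha_s`, `alpha_0` and
#'   `tau_a_criterion`.
#' @export
step_response <- function(gamma0, gamma1, params, coeffs,
                          tau_a_criterion = exp(-1)) {
  if (!is.finite(gamma0) || gamma0 < 0) stop("'gamma0' must be >= 0")
  if (!is.finite(gamma1) || gamma1 <= gamma0)
    stop("'gamma1' must exceed 'gamma0' (step peak undefined otherwise)")
  if (tau_a_criterion <= 0 || tau_a_criterion >= 1)
    stop("'tau_a_criterion' must be in (0, 1)")
  a <- coefficient_vector(coeffs)
  x0 <- as.numeric(equilibrium_state(gamma0, params))
  K <- rate_matrix(gamma1, params)
  e <- eigen(K)
  w <- as.vector(a %*% e$vectors) * as.vector(solve(e$vectors, x0))
  lam <- e$values
  alpha_t <- function(t)
    vapply(t, function(tt) Re(sum(w * exp(lam * tt))), numeric(1))
  alpha_s <- scaled_activity(equilibrium_state(gamma1, params), coeffs)
  alpha_0 <- scaled_activity(as_state(x0), coeffs)

  # bracket the transient on the slowest non-zero timescale
  lam_nz <- lam[Mod(lam) > 1e-11]
  t_slow <- 1 / min(abs(Re(lam_nz)))
  grid <- c(seq(0, 2, by = 0.01),
            exp(seq(log(2.01), log(60 * t_slow), length.out = 3000)))
  av <- alpha_t(grid)
  im <- which.max(av)
  opt <- stats::optimize(function(t) -alpha_t(t),
                         c(grid[max(1L, im - 1L)], grid[min(length(grid), im + 1L)]))
  alpha_M <- max(-opt$objective, av[im])
  t_peak <- opt$minimum
  excursion <- abs(alpha_M - alpha_s)
  if (excursion < 1e-14 * abs(alpha_s)) {
    tau_a <- t_slow  # vanishing step: relaxation time of the slowest mode
  } else {
    thr <- tau_a_criterion * excursion
    idx <- which(grid > t_peak & abs(av - alpha_s) <= thr)[1]
    if (is.na(idx))
      stop("activity did not relax within the integration window")
    tau_a <- stats::uniroot(function(t) abs(alpha_t(t) - alpha_s) - thr,
                            lower = t_peak, upper = grid[idx],
                            tol = 1e-10)$root
  }
  structure(list(alpha_M_step = alpha_M, t_peak = t_peak, tau_a = tau_a,
                 alpha_T_step = tau_a * alpha_M, alpha_s = alpha_s,
                 alpha_0 = alpha_0, tau_a_criterion = tau_a_criterion),
            class = "step_response")
}

#' @export
print.step_response <- function(x, ...) {
  cat(sprintf(paste0("step response: alpha_M = %.5g at t = %.3g min; tau_a = %.4g min ",
                     "(criterion %.3g); alpha_T_step = %.5g\n"),
              x$alpha_M_step, x$t_peak, x$tau_a, x$tau_a_criterion, x$alpha_T_step))
  invisible(x)
}

#' Integrated activity over one pulse period
#'
#' The excess activity `alpha_T = int_0^T (alpha(t) - alpha_0) dt` at the
#' periodic steady state, computed by exact segment-wise quadrature of the
#' linear flow (the running integral of the matrix exponential), not by
#' discretised sampling.
#'
#' @param stimulus a [square_wave()].
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @return `alpha_T` (activity min).
#' @export
integrated_pulse_activity <- function(stimulus, params, coeffs) {
  stopifnot(inherits(stimulus, "square_wave"))
  a <- coefficient_vector(coeffs)
  seg <- one_period_segments(stimulus)
  x <- as.numeric(periodic_state_segments(seg, params))
  total <- 0
  for (s in seq_len(nrow(seg))) {
    fl <- kinetic_flow(rate_matrix(seg$value[s], params))
    dt <- seg$end[s] - seg$start[s]
    total <- total + drop(a %*% fl$J(dt) %*% x)
    x <- drop(fl$E(dt) %*% x)
  }
  alpha0 <- basal_activity(coeffs, params, gamma0 = stimulus$gamma0)
  total - alpha0 * stimulus$period
}

#' Cellular responsiveness of a pulsatile stimulus
#'
#' The long-term readout of pulsatile stimulation,
#' `alpha_R = (alpha_T / alpha_T_step) * (alpha_T / T)`:
#' the per-pulse integrated activity relative to the equivalent step
#' response, times the period-averaged integrated activity.  A constant
#' stimulus (`gamma1 = gamma0`) has `alpha_T = 0` and is returned as
#' `alpha_R = 0` with `degenerate = TRUE`.
#'
#' @inheritParams integrated_pulse_activity
#' @param tau_a_criterion passed to [step_response()].
#' @return An object of class `pth_responsiveness`: list with `alpha_0`,
#'   `alpha_T`, `alpha_M_step`, `tau_a`, `alpha_T_step`, `alpha_R`, the
#'   stimulus, the `tau_a_criterion` used and the `degenerate` flag.
#' @export
#' @examples
#' kin <- pth_kinetics()
#' cf <- activity_coefficients(1, 0, 0, kin)
#' cellular_responsiveness(square_wave(3.3, 8.3, 5, 15), kin, cf)
cellular_responsiveness <- function(stimulus, params, coeffs,
                                    tau_a_criterion = exp(-1)) {
  stopifnot(inherits(stimulus, "square_wave"))
  alpha0 <- basal_activity(coeffs, params, gamma0 = stimulus$gamma0)
  if (stimulus$gamma1 <= stimulus$gamma0 ||
      stimulus$tau1 >= stimulus$period) {
    return(structure(list(alpha_0 = alpha0, alpha_T = 0,
                          alpha_M_step = NA_real_, tau_a = NA_real_,
                          alpha_T_step = NA_real_, alpha_R = 0,
                          stimulus = stimulus,
                          tau_a_criterion = tau_a_criterion,
                          degenerate = TRUE),
                     class = "pth_responsiveness"))
  }
  aT <- integrated_pulse_activity(stimulus, params, coeffs)
  sr <- step_response(stimulus$gamma0, stimulus$gamma1, params, coeffs,
                      tau_a_criterion = tau_a_criterion)
  structure(list(alpha_0 = alpha0, alpha_T = aT,
                 alpha_M_step = sr$alpha_M_step, tau_a = sr$tau_a,
                 alpha_T_step = sr$alpha_T_step,
                 alpha_R = aT^2 / (sr$alpha_T_step * stimulus$period),
                 stimulus = stimulus, tau_a_criterion = tau_a_criterion,
                 degenerate = FALSE),
            class = "pth_responsiveness")
}

#' @export
print.pth_responsiveness <- function(x, ...) {
  s <- x$stimulus
  cat(sprintf("cellular responsiveness of (gamma0 %.4g, gamma1 %.4g, tau1 %.4g, T %.4g):\n",
              s$gamma0, s$gamma1, s$tau1, s$period))
  if (x$degenerate) {
    cat("  constant stimulus: alpha_R = 0\n")
  } else {
    cat(sprintf("  alpha_0 = %.5g  alpha_T = %.5g  alpha_M_step = %.5g\n",
                x$alpha_0, x$alpha_T, x$alpha_M_step))
    cat(sprintf("  tau_a = %.4g min (criterion %.3g)  alpha_T_step = %.5g\n",
                x$tau_a, x$tau_a_criterion, x$alpha_T_step))
    cat(sprintf("  alpha_R = %.5g\n", x$alpha_R))
  }
  invisible(x)
}

#' Serialise a responsiveness result to JSON
#'
#' All intermediates (`alpha_0`, `alpha_T`, `alpha_M_step`, `tau_a`,
#' `alpha_T_step`, `alpha_R`), the stimulus, the adaptation-time criterion
#' and a [run_manifest()] reference are written.
#'
#' @param x a `pth_responsiveness` object.
#' @param path output file.
#' @param manifest optional [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_responsiveness <- function(x, path, manifest = NULL) {
  stopifnot(inherits(x, "pth_responsiveness"))
  out <- list(stimulus = x$stimulus[c("gamma0", "gamma1", "tau1", "period")],
              alpha_0 = x$alpha_0, alpha_T = x$alpha_T,
              alpha_M_step = x$alpha_M_step, tau_a = x$tau_a,
              alpha_T_step = x$alpha_T_step, alpha_R = x$alpha_R,
              tau_a_criterion = x$tau_a_criterion,
              degenerate = x$degenerate)
  if (!is.null(manifest)) out$manifest <- unclass(manifest)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
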