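#' Reduce the AUC-constrained pattern problem to free variables
#'
#' Glandular-pattern optimisation fixes the total AUC (`A = A_ref` over a
#' window `s`) and the pulsatile fraction (`A_puls = r A`).  Those two
#' constraints pin the tonic level to `gamma0_ref` and the period to
#' `T = s tau1 (gamma1 - gamma0) / (r A_ref)`, leaving `(gamma1, tau1)`
#' free.  The reduction is infeasible when the implied period does not
#' exceed the on-phase.
#'
#' @param gamma1 pulse peak (pmol/L), `> gamma0_ref`.
#' @param tau1 on-phase (min), `> 0`.
#' @param gamma0_ref reference tonic level (pmol/L).
#' @param r pulsatile AUC fraction, in `(0, 1)`.
#' @param A_ref reference AUC over the window (pmol min/L).
#' @param s AUC window (min); the constraint set is invariant to `s` for
#'   whole-period windows.
#' @return A [square_wave()] satisfying both constraints.
#' @export
reduce_constraints <- function(gamma1, tau1, gamma0_ref, r, A_ref, s = 1440) {
  if (r <= 0 || r >= 1) stop("'r' must lie in (0, 1)")
  if (A_ref <= 0 || s <= 0 || tau1 <= 0) stop("'A_ref', 's', 'tau1' must be > 0")
  if (gamma1 <= gamma0_ref) stop("'gamma1' must exceed 'gamma0_ref'")
  Tp <- s * tau1 * (gamma1 - gamma0_ref) / (r * A_ref)
  if (Tp <= tau1)
    stop(sprintf(paste0("infeasible pattern: implied period %.4g min does not exceed ",
                        "tau1 = %.4g min (gamma1 = %.4g, r = %.4g, A_ref = %.6g, s = %g)"),
                 Tp, tau1, gamma1, r, A_ref, s))
  square_wave(gamma0_ref, gamma1, tau1, Tp)
}

#' Exhaustive grid search over a box (test oracle)
#'
#' Deterministic evaluation of `objective` on a regular grid, with ties
#' broken toward the lexicographically smallest point.
#'
#' @param objective function of a numeric vector, returning a scalar to
#'   maximise.
#' @param lower,upper box bounds (equal length).
#' @param resolution points per axis, `>= 2`.
#' @return List with `par` (best point), `value`, and `n_evaluated`.
#' @export
grid_oracle <- function(objective, lower, upper, resolution = 60) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            resolution >= 2)
  axes <- lapply(seq_along(lower), function(i)
    seq(lower[i], upper[i], length.out = resolution))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  vals <- apply(grid, 1L, function(p) {
    v <- objective(p)
    if (!is.finite(v)) -Inf else v
  })
  ord <- do.call(order, c(list(-vals), lapply(seq_along(lower), function(i) grid[, i])))
  best <- ord[1]
  list(par = unname(grid[best, ]), value = vals[best], n_evaluated = nrow(grid))
}

# shared constraint bundle for the glandular problems; r and A_ref are taken
# from the baseline pattern's closed-form decomposition (A = gamma0 s +
# (gamma1 - gamma0) tau1 s / T) so that the reduced constraints hold exactly
glandular_constraints <- function(scenario, s = 1440) {
  stopifnot(inherits(scenario, "pth_scenario"))
  base <- scenario$stimulus
  puls_rate <- (base$gamma1 - base$gamma0) * base$tau1 / base$period
  A_ref <- (base$gamma0 + puls_rate) * s
  list(gamma0 = base$gamma0, r = puls_rate / (base$gamma0 + puls_rate),
       A_ref = A_ref, s = s,
       q = puls_rate)   # pulsatile mean = tau1 (g1 - g0) / T
}

# multistart Nelder-Mead over theta = (log(gamma1 - gamma0), log tau1);
# infeasible patterns (T <= tau1) are handled by a smooth penalty.
glandular_search <- function(scenario, params, coeffs, objective_of_alphaR,
                             s = 1440, starts = NULL,
                             tau_a_criterion = exp(-1),
                             control = list(maxit = 2000, reltol = 1e-9)) {
  con <- glandular_constraints(scenario, s)
  fwd <- function(theta) {
    amp <- exp(theta[1]); tau1 <- exp(theta[2])
    Tp <- tau1 * amp / con$q
    list(amp = amp, tau1 = tau1, Tp = Tp)
  }
  neg_obj <- function(theta) {
    d <- fwd(theta)
    if (!all(is.finite(unlist(d))) || d$amp > 1e6 || d$tau1 > 1e5)
      return(1e6)
    if (d$Tp <= d$tau1 * (1 + 1e-9))
      return(1e3 * (1 + max(0, con$q - d$amp) / con$q))
    stim <- square_wave(con$gamma0, con$gamma0 + d$amp, d$tau1, d$Tp)
    aR <- cellular_responsiveness(stim, params, coeffs,
                                  tau_a_criterion = tau_a_criterion)$alpha_R
    objective_of_alphaR(aR)
  }
  if (is.null(starts)) {
    base <- scenario$stimulus
    starts <- expand.grid(amp = con$gamma0 * c(0.5, 2, 5), tau1 = c(5, 10, 20))
    starts <- rbind(starts,
                    data.frame(amp = base$gamma1 - base$gamma0, tau1 = base$tau1))
    starts <- starts[starts$amp > 0, , drop = FALSE]
  }
  trace <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- log(as.numeric(starts[i, c("amp", "tau1")]))
    o <- stats::optim(th0, neg_obj, method = "Nelder-Mead", control = control)
    trace[[i]] <- data.frame(start_amp = starts$amp[i], start_tau1 = starts$tau1[i],
                             amp = exp(o$par[1]), tau1 = exp(o$par[2]),
                             value = -o$value, convergence = o$convergence,
                             evaluations = o$counts[["function"]])
    if (o$value < 1e3 && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("no feasible pattern found from any start of the multistart grid")
  d <- fwd(best$par)
  stim <- square_wave(con$gamma0, con$gamma0 + d$amp, d$tau1, d$Tp)
  res <- cellular_responsiveness(stim, params, coeffs,
                                 tau_a_criterion = tau_a_criterion)
  list(stimulus = stim, responsiveness = res, constraints = con,
       objective_value = -best$value, converged = best$convergence == 0,
       trace = do.call(rbind, trace))
}

#' Maximise glandular responsiveness at fixed AUC
#'
#' Derivative-free (Nelder-Mead) multistart search over
#' `(gamma1, tau1)` (log-transformed for positivity) for the secretion
#' pattern with the largest cellular responsiveness among all square waves
#' with the scenario's total AUC and pulsatile fraction.  The scenario's
#' own baseline pattern is always included as a start, so the optimum is
#' never below the baseline.
#'
#' @param scenario a `pth_scenario` (see [load_scenarios()]).
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @param s AUC window (min).
#' @param starts data frame with columns `amp`, `tau1` overriding the
#'   default 3x3 multistart grid.
#' @param tau_a_criterion passed to [step_response()].
#' @param control passed to [stats::optim()].
#' @return An object of class `pth_opt` with the optimal stimulus, the
#'   achieved `alpha_R`, convergence/feasibility flags and the per-start
#'   trace.
#' @export
maximise_glandular <- function(scenario, params, coeffs, s = 1440,
                               starts = NULL, tau_a_criterion = exp(-1),
                               control = list(maxit = 2000, reltol = 1e-9)) {
  sr <- glandular_search(scenario, params, coeffs,
                         objective_of_alphaR = function(aR) -aR,
                         s = s, starts = starts,
                         tau_a_criterion = tau_a_criterion, control = control)
  structure(list(problem = "maximise_glandular", scenario = scenario$name,
                 stimulus = sr$stimulus, alpha_R = sr$responsiveness$alpha_R,
                 objective = sr$objective_value, converged = sr$converged,
                 feasible = TRUE, constraints = sr$constraints,
                 responsiveness = sr$responsiveness, trace = sr$trace),
            class = "pth_opt")
}

#' Find a glandular pattern achieving a target responsiveness
#'
#' Minimises `(alpha_R - target)^2` over the AUC-constrained pattern
#' family.  The problem is infeasible (flagged, not an error) when the
#' target lies outside the attainable range; feasibility is declared when
#' the final residual `|alpha_R - target|` is within `tol_target`.
#'
#' @inheritParams maximise_glandular
#' @param alphaR_target target responsiveness, `> 0`.
#' @param tol_target absolute feasibility tolerance on the residual.
#' @return A `pth_opt` object; `feasible` reports whether the target was
#'   met within `tol_target`.
#' @export
target_glandular <- function(scenario, alphaR_target, params, coeffs,
                             s = 1440, starts = NULL,
                             tau_a_criterion = exp(-1), tol_target = 1e-2,
                             control = list(maxit = 2000, reltol = 1e-9)) {
  if (alphaR_target <= 0) stop("'alphaR_target' must be > 0")
  sr <- glandular_search(scenario, params, coeffs,
                         objective_of_alphaR = function(aR) (aR - alphaR_target)^2,
                         s = s, starts = starts,
                         tau_a_criterion = tau_a_criterion, control = control)
  residual <- abs(sr$responsiveness$alpha_R - alphaR_target)
  structure(list(problem = "target_glandular", scenario = scenario$name,
                 target = alphaR_target, stimulus = sr$stimulus,
                 alpha_R = sr$responsiveness$alpha_R, residual = residual,
                 objective = sr$objective_value, converged = sr$converged,
                 feasible = residual <= tol_target, tol_target = tol_target,
                 constraints = sr$constraints,
                 responsiveness = sr$responsiveness, trace = sr$trace),
            class = "pth_opt")
}

# injection design at fixed daily drug AUC: tau1 and the peak come from the
# single-dose PK reduction, the period follows from AUC conservation.
injection_design <- function(D, D_ref, pk, gamma0, T_ref = 1440) {
  sw <- injection_square_wave(D, pk, gamma0, T_inj = T_ref)
  Tp <- T_ref * D / D_ref
  if (Tp <= sw$tau1) return(NULL)
  square_wave(gamma0, sw$gamma1, sw$tau1, Tp)
}

#' Optimal fractionation of a fixed daily injection dose
#'
#' Splits the reference daily dose `D_ref` into equal injections of size
#' `D` every `T = T_ref D / D_ref` minutes (which conserves the daily drug
#' AUC under linear PK) and maximises the injection responsiveness over
#' `D`.  The per-injection pulse shape `(gamma1, tau1)` follows from the
#' PK square-wave reduction.  A deterministic coarse grid over `D` brackets
#' the optimum, which is then refined by golden-section search.
#'
#' @param D_ref reference daily dose (micrograms).
#' @param pk a [pk_parameters()] object.
#' @param gamma0 tonic baseline of the recipient scenario (pmol/L).
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @param T_ref reference dosing period (min), default once daily.
#' @param n_grid bracketing grid size.
#' @param tau_a_criterion passed to [step_response()].
#' @return A `pth_opt` object with fields `D_max`, `stimulus` (the optimal
#'   injection square wave) and `alpha_R`.
#' @export
maximise_injection <- function(D_ref, pk, gamma0, params, coeffs,
                               T_ref = 1440, n_grid = 40,
                               tau_a_criterion = exp(-1)) {
  if (D_ref <= 0) stop("'D_ref' must be > 0")
  tau1_pk <- with(pk_summary(D_ref, pk), auc / c_max)
  D_lo <- D_ref * tau1_pk / T_ref * (1 + 1e-6)
  if (D_lo >= D_ref)
    stop("no feasible per-injection dose: reduced on-phase exceeds the daily period")
  aR_of <- function(D) {
    des <- injection_design(D, D_ref, pk, gamma0, T_ref)
    if (is.null(des)) return(-Inf)
    cellular_responsiveness(des, params, coeffs,
                            tau_a_criterion = tau_a_criterion)$alpha_R
  }
  Ds <- exp(seq(log(D_lo), log(D_ref), length.out = n_grid))
  vals <- vapply(Ds, aR_of, numeric(1))
  i <- which.max(vals)
  lo <- Ds[max(1L, i - 1L)]; hi <- Ds[min(length(Ds), i + 1L)]
  opt <- stats::optimize(aR_of, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), cbind(Ds, vals))
  best <- cand[which.max(cand[, 2]), ]
  des <- injection_design(best[1], D_ref, pk, gamma0, T_ref)
  structure(list(problem = "maximise_injection", D_ref = D_ref,
                 D_max = best[1], stimulus = des, alpha_R = best[2],
                 converged = TRUE, feasible = TRUE,
                 trace = data.frame(D = Ds, alpha_R = vals)),
            class = "pth_opt")
}

#' Daily injection dose filling a responsiveness deficit
#'
#' Finds the once-daily dose `D` whose injection responsiveness matches the
#' deficit `alphaR_ref - alphaR_ill` of a diseased scenario relative to the
#' reference, keeping the dosing period fixed.  A non-positive deficit
#' needs no drug and returns `D = 0`.
#'
#' @param alphaR_ref reference (healthy) responsiveness.
#' @param alphaR_ill responsiveness of the diseased scenario.
#' @param pk a [pk_parameters()] object.
#' @param gamma0 tonic baseline of the recipient scenario (pmol/L).
#' @param params a [pth_kinetics()] object.
#' @param coeffs an [activity_coefficients()] object.
#' @param T_inj dosing period (min), default once daily.
#' @param tol_target absolute feasibility tolerance on the residual.
#' @param D_max upper bound of the dose search (micrograms).
#' @param tau_a_criterion passed to [step_response()].
#' @return A `pth_opt` object with `D_star`, the achieved injection
#'   `alpha_R`, the residual and a feasibility flag.
#' @export
target_injection_dose <- function(alphaR_ref, alphaR_ill, pk, gamma0,
                                  params, coeffs, T_inj = 1440,
                                  tol_target = 1e-2, D_max = 200,
                                  tau_a_criterion = exp(-1)) {
  deficit <- alphaR_ref - alphaR_ill
  if (deficit <= 0) {
    return(structure(list(problem = "target_injection_dose", deficit = deficit,
                          D_star = 0, alpha_R_inj = 0, residual = abs(deficit),
                          converged = TRUE, feasible = TRUE),
                     class = "pth_opt"))
  }
  aR_of <- function(D) {
    if (D <= 0) return(0)
    sw <- injection_square_wave(D, pk, gamma0, T_inj = T_inj)
    cellular_responsiveness(sw, params, coeffs,
                            tau_a_criterion = tau_a_criterion)$alpha_R
  }
  opt <- stats::optimize(function(D) (aR_of(D) - deficit)^2,
                         c(1e-3, D_max), tol = 1e-7)
  aR <- aR_of(opt$minimum)
  structure(list(problem = "target_injection_dose", deficit = deficit,
                 D_star = opt$minimum, alpha_R_inj = aR,
                 residual = abs(aR - deficit), converged = TRUE,
                 feasible = abs(aR - deficit) <= tol_target,
                 tol_target = tol_target),
            class = "pth_opt")
}

#' @export
print.pth_opt <- function(x, ...) {
  cat("optimisation:", x$problem,
      if (!is.null(x$scenario)) paste0("(", x$scenario, ")"), "\n")
  if (!is.null(x$stimulus))
    cat(sprintf("  pattern: gamma1 = %.4g pmol/L, tau1 = %.4g min, T = %.4g min\n",
                x$stimulus$gamma1, x$stimulus$tau1, x$stimulus$period))
  if (!is.null(x$D_max)) cat(sprintf("  D_max = %.4g ug per injection\n", x$D_max))
  if (!is.null(x$D_star)) cat(sprintf("  D* = %.4g ug daily\n", x$D_star))
  if (!is.null(x$alpha_R)) cat(sprintf("  alpha_R = %.5g\n", x$alpha_R))
  if (!is.null(x$alpha_R_inj)) cat(sprintf("  alpha_R_inj = %.5g\n", x$alpha_R_inj))
  if (!is.null(x$target)) cat(sprintf("  target = %.5g, residual = %.3g\n",
                                      x$target, x$residual))
  cat(sprintf("  converged: %s; feasible: %s\n", x$converged, x$feasible))
  invisible(x)
}
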