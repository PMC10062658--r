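#' Plot a receptor trajectory
#'
#' Two stacked panels: the ligand stimulus and the four receptor-state
#' fractions.
#'
#' @param x a `pth_trajectory` from [simulate_trajectory()].
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.pth_trajectory <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$time_min, x$ligand_pmol_per_L, type = "s", xlab = "time (min)",
       ylab = "ligand (pmol/L)", ...)
  plot(x$time_min, x$r_a, type = "l", ylim = c(0, 1), xlab = "time (min)",
       ylab = "fraction of R_T", ...)
  lines(x$time_min, x$c_a, lty = 2)
  lines(x$time_min, x$c_i, lty = 3)
  lines(x$time_min, x$r_i, lty = 4)
  legend("topright", c("r_a", "c_a", "c_i", "r_i"), lty = 1:4, bty = "n")
  invisible(x)
}

#' Plot a square-wave stimulus
#'
#' @param x a [square_wave()].
#' @param periods number of periods to draw.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.square_wave <- function(x, periods = 3, ...) {
  t <- seq(0, periods * x$period, length.out = 400)
  plot(t, stimulus_value(x, t), type = "s", xlab = "time (min)",
       ylab = "ligand (pmol/L)", ...)
  invisible(x)
}

#' Scaled-activity time course along a trajectory
#'
#' @param trajectory a `pth_trajectory`.
#' @param coeffs an [activity_coefficients()] object.
#' @return Numeric vector of activities, one per trajectory sample.
#' @export
trajectory_activity <- function(trajectory, coeffs) {
  a <- coefficient_vector(coeffs)
  as.numeric(as.matrix(trajectory[, c("r_a", "c_a", "c_i", "r_i")]) %*% a)
}

#' @export
summary.pth_responsiveness <- function(object, ...) {
  d <- data.frame(alpha_0 = object$alpha_0, alpha_T = object$alpha_T,
                  alpha_M_step = object$alpha_M_step, tau_a = object$tau_a,
                  alpha_T_step = object$alpha_T_step, alpha_R = object$alpha_R,
                  tau_a_criterion = object$tau_a_criterion)
  class(d) <- c("summary.pth_responsiveness", "data.frame")
  d
}

#' @export
as.data.frame.pth_opt <- function(x, ...) {
  data.frame(problem = x$problem,
             scenario = x$scenario %||% NA_character_,
             alpha_R = x$alpha_R %||% x$alpha_R_inj,
             converged = x$converged, feasible = x$feasible)
}
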