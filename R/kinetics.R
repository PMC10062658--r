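#' Kinetic parameters of the two-state PTH1R receptor model
#'
#' The receptor is modelled with four species: active free receptor `R_a`,
#' inactive free receptor `R_i`, and the corresponding ligand-bound complexes
#' `C_a` and `C_i`.  Free receptors interconvert with first-order rates
#' `k1` (`R_a -> R_i`) and `k_minus1` (`R_i -> R_a`); complexes interconvert
#' with `k2` (`C_a -> C_i`) and `k_minus2` (`C_i -> C_a`).  Ligand binds the
#' active receptor with dissociation constant `Kr = k_minusr/kr` and the
#' inactive receptor with `Kd = k_minusd/kd`.
#'
#' Only the two dissociation constants, not the individual on/off rates, are
#' experimentally constrained, so the absolute off-rates are exposed as
#' calibration knobs: binding is assumed fast relative to the conformational
#' conversions (default off-rates 10 min^-1 against conversion rates of
#' 0.01--0.2 min^-1) and the on-rates follow as `kr = k_minusr/Kr`,
#' `kd = k_minusd/Kd`.
#'
#' By default `Kd` is derived from the thermodynamic consistency (detailed
#' balance) of the four-state cycle, `Kd = Kr * K2 / K1` with
#' `K1 = k_minus1/k1` and `K2 = k_minus2/k2`.  This is the unique choice for
#' which the steady state is an equilibrium and the exact-adaptation
#' construction of [activity_coefficients()] holds exactly; see the package
#' vignette.  Setting `detailed_balance = FALSE` uses the supplied `Kd`
#' (default 1000 nM) instead, which introduces a stationary cycle flux and
#' makes the steady-state activity drift with the ligand level.
#'
#' @param k1,k_minus1 conversion rates of the free receptor (min^-1).
#' @param k2,k_minus2 conversion rates of the bound complex (min^-1).
#' @param Kr dissociation constant of the active complex, in `conc_unit`.
#' @param Kd dissociation constant of the inactive complex, in `conc_unit`;
#'   ignored (and recomputed) when `detailed_balance = TRUE`.
#' @param off_rate_active,off_rate_inactive unbinding rates `k_minusr`,
#'   `k_minusd` (min^-1).
#' @param conc_unit unit in which `Kr` and `Kd` are given; concentrations are
#'   converted to pmol/L internally (1 nM = 1000 pmol/L).
#' @param detailed_balance logical; derive `Kd` from the cycle condition
#'   (default) or use the supplied value.
#'
#' @return An object of class `pth_kinetics`: a list of the eight first-order
#'   rate constants (`k1`, `k_minus1`, `k2`, `k_minus2`, `kr`, `k_minusr`,
#'   `kd`, `k_minusd`) in min^-1 and pmol^-1 L min^-1.  Derived ratios are
#'   never stored; use [kinetic_ratios()].
#' @seealso [rate_matrix()], [equilibrium_state()], [kinetic_ratios()]
#' @export
#' @examples
#' kin <- pth_kinetics()
#' kinetic_ratios(kin)$K1   # = 0.104 / 0.012
pth_kinetics <- function(k1 = 0.012, k_minus1 = 0.104,
                         k2 = 0.222, k_minus2 = 0.055,
                         Kr = 1, Kd = 1000,
                         off_rate_active = 10, off_rate_inactive = 10,
                         conc_unit = c("nM", "pmol/L"),
                         detailed_balance = TRUE) {
  conc_unit <- match.arg(conc_unit)
  rates <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
             off_rate_active = off_rate_active,
             off_rate_inactive = off_rate_inactive, Kr = Kr)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants and dissociation constants must be strictly positive")
  to_pmol <- if (conc_unit == "nM") 1000 else 1
  Kr_pmol <- Kr * to_pmol
  if (detailed_balance) {
    Kd_pmol <- Kr_pmol * (k_minus2 / k2) / (k_minus1 / k1)
  } else {
    if (!is.finite(Kd) || Kd <= 0) stop("'Kd' must be strictly positive")
    Kd_pmol <- Kd * to_pmol
  }
  out <- list(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
              k_minusr = off_rate_active, kr = off_rate_active / Kr_pmol,
              k_minusd = off_rate_inactive, kd = off_rate_inactive / Kd_pmol,
              detailed_balance = detailed_balance)
  class(out) <- "pth_kinetics"
  out
}

#' Derived equilibrium ratios of a kinetic parameter set
#'
#' @param params a [pth_kinetics()] object.
#' @return List with `K1 = k_minus1/k1`, `K2 = k_minus2/k2` (dimensionless)
#'   and the dissociation constants `Kr = k_minusr/kr`, `Kd = k_minusd/kd`
#'   in pmol/L.
#' @export
kinetic_ratios <- function(params) {
  stopifnot(inherits(params, "pth_kinetics"))
  list(K1 = params$k_minus1 / params$k1,
       K2 = params$k_minus2 / params$k2,
       Kr = params$k_minusr / params$kr,
       Kd = params$k_minusd / params$kd)
}

#' @export
print.pth_kinetics <- function(x, ...) {
  r <- kinetic_ratios(x)
  cat("Two-state receptor kinetics (min^-1; concentrations pmol/L)\n")
  cat(sprintf("  conversions: k1 = %g, k-1 = %g (K1 = %.4g); k2 = %g, k-2 = %g (K2 = %.4g)\n",
              x$k1, x$k_minus1, r$K1, x$k2, x$k_minus2, r$K2))
  cat(sprintf("  binding:     Kr = %g pmol/L (k-r = %g), Kd = %g pmol/L (k-d = %g)\n",
              r$Kr, x$k_minusr, r$Kd, x$k_minusd))
  cat(sprintf("  detailed balance: %s\n", x$detailed_balance))
  invisible(x)
}

#' Receptor-state vector
#'
#' Normalised fractions of the total receptor pool in the order
#' (`r_a`, `c_a`, `c_i`, `r_i`).  The conservation condition
#' `r_a + c_a + c_i + r_i = 1` is validated on construction.
#'
#' @param r_a,c_a,c_i,r_i fractions, each in `[0, 1]`.
#' @return A named numeric vector of class `receptor_state`.
#' @export
receptor_state <- function(r_a, c_a, c_i, r_i) {
  x <- c(r_a = r_a, c_a = c_a, c_i = c_i, r_i = r_i)
  if (any(!is.finite(x))) stop("non-finite receptor fractions")
  if (any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("receptor fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9)
    stop("receptor fractions must sum to 1 (conservation)")
  structure(x, class = "receptor_state")
}

state_names <- c("r_a", "c_a", "c_i", "r_i")

as_state <- function(x) {
  x <- as.numeric(x)
  names(x) <- state_names
  class(x) <- "receptor_state"
  x
}

#' @export
print.receptor_state <- function(x, ...) {
  cat("receptor state (fractions of R_T):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Rate matrix of the receptor system at a constant ligand level
#'
#' Coefficient matrix `K(L)` of the linear system `dx/dt = K(L) x` for the
#' state ordering (`r_a`, `c_a`, `c_i`, `r_i`).  Columns sum to zero
#' (conservation of total receptor) and off-diagonal entries are
#' non-negative (Metzler structure).
#'
#' @param L ligand concentration (pmol/L), `>= 0`.
#' @param params a [pth_kinetics()] object.
#' @return A 4x4 numeric matrix.
#' @export
rate_matrix <- function(L, params) {
  stopifnot(inherits(params, "pth_kinetics"))
  if (!is.finite(L) || L < 0) stop("ligand concentration 'L' must be >= 0")
  p <- params
  matrix(c(-p$k1 - p$kr * L, p$k_minusr,          0,                     p$k_minus1,
           p$kr * L,         -p$k2 - p$k_minusr,  p$k_minus2,            0,
           0,                p$k2,                -p$k_minus2 - p$k_minusd, p$kd * L,
           p$k1,             0,                   p$k_minusd,            -p$k_minus1 - p$kd * L),
         nrow = 4, ncol = 4, byrow = TRUE,
         dimnames = list(state_names, state_names))
}

# Eigen-decomposed flow of dx/dt = K x.  Returns closures for the propagator
# E(t) = exp(K t) and its running integral J(t) = int_0^t exp(K u) du; falls
# back to Matrix::expm() when the eigenvector basis is ill-conditioned.
kinetic_flow <- function(K) {
  e <- tryCatch(eigen(K), error = function(cond) NULL)
  ok <- !is.null(e) && rcond(abs(e$vectors)) > 1e-10
  if (ok) {
    V <- e$vectors
    Vi <- solve(V)
    lam <- e$values
    E <- function(t) Re(V %*% (exp(lam * t) * Vi))
    J <- function(t) {
      phi <- ifelse(abs(lam) < 1e-11, t, (exp(lam * t) - 1) / lam)
      Re(V %*% (phi * Vi))
    }
  } else {
    n <- nrow(K)
    E <- function(t) as.matrix(Matrix::expm(K * t))
    J <- function(t) {
      A <- matrix(0, 2L * n, 2L * n)
      A[seq_len(n), seq_len(n)] <- K * t
      A[seq_len(n), n + seq_len(n)] <- diag(n) * t
      as.matrix(Matrix::expm(A))[seq_len(n), n + seq_len(n), drop = FALSE]
    }
  }
  list(E = E, J = J, K = K)
}

#' Steady state of the receptor under a constant ligand level
#'
#' Null-space solution of [rate_matrix()] normalised to sum one.  The steady
#' state is unique: the reaction graph is strongly connected for `L > 0`,
#' and for `L = 0` the complexes empty and the free-receptor subsystem
#' equilibrates at `r_a / r_i = K1`.
#'
#' @inheritParams rate_matrix
#' @return A [receptor_state()].
#' @export
#' @examples
#' equilibrium_state(0, pth_kinetics())  # r_a = K1 / (1 + K1)
equilibrium_state <- function(L, params) {
  K <- rate_matrix(L, params)
  if (L == 0) {
    K1 <- params$k_minus1 / params$k1
    return(as_state(c(K1 / (1 + K1), 0, 0, 1 / (1 + K1))))
  }
  x <- qr.solve(rbind(K, rep(1, 4)), c(0, 0, 0, 0, 1))
  x[x < 0 & x > -1e-12] <- 0
  as_state(x / sum(x))
}

#' Advance the receptor state under a constant ligand level
#'
#' Exact propagation of the linear system by its matrix-exponential solution
#' `x(dt) = exp(K(L) dt) x(0)`; conservation is preserved to machine
#' precision.
#'
#' @param state a [receptor_state()].
#' @param L constant ligand concentration (pmol/L).
#' @param dt time step (min), `>= 0`.
#' @param params a [pth_kinetics()] object.
#' @return The propagated [receptor_state()].
#' @export
propagate <- function(state, L, dt, params) {
  if (!is.finite(dt) || dt < 0) stop("'dt' must be >= 0")
  if (dt == 0) return(as_state(as.numeric(state)))
  fl <- kinetic_flow(rate_matrix(L, params))
  as_state(drop(fl$E(dt) %*% as.numeric(state)))
}

# Piecewise-constant ligand segments covering [0, horizon].
# Generic: any object with a stimulus_segments method.
#' Decompose a stimulus into piecewise-constant segments
#'
#' @param stimulus a stimulus object (e.g. [square_wave()]).
#' @param horizon end of the time window (min).
#' @return A data frame with columns `start`, `end`, `value` covering
#'   `[0, horizon]`.
#' @export
stimulus_segments <- function(stimulus, horizon) UseMethod("stimulus_segments")

#' @export
stimulus_segments.square_wave <- function(stimulus, horizon) {
  stopifnot(horizon > 0)
  Tp <- stimulus$period
  n <- ceiling(horizon / Tp)
  starts <- rep(seq_len(n) - 1, each = 2) * Tp +
    rep(c(0, stimulus$tau1), n)
  vals <- rep(c(stimulus$gamma1, stimulus$gamma0), n)
  keep <- starts < horizon
  starts <- starts[keep]; vals <- vals[keep]
  ends <- c(starts[-1], horizon)
  ok <- ends > starts
  data.frame(start = starts[ok], end = pmin(ends[ok], horizon), value = vals[ok])
}

#' @export
stimulus_segments.pth_segments <- function(stimulus, horizon) {
  seg <- stimulus$segments
  seg <- seg[seg$start < horizon, , drop = FALSE]
  seg$end <- pmin(seg$end, horizon)
  seg
}

#' A stimulus given directly as piecewise-constant segments
#'
#' @param start,end,value vectors defining contiguous segments with
#'   non-negative ligand values.
#' @return An object of class `pth_segments` usable wherever a stimulus is
#'   accepted by [simulate_trajectory()].
#' @export
segment_stimulus <- function(start, end, value) {
  stopifnot(length(start) == length(end), length(end) == length(value))
  if (any(value < 0)) stop("stimulus values must be non-negative")
  if (any(end <= start)) stop("segments must have positive length")
  if (any(abs(start[-1] - end[-length(end)]) > 1e-9))
    stop("segments must be contiguous")
  structure(list(segments = data.frame(start = start, end = end, value = value)),
            class = "pth_segments")
}

#' Simulate a receptor trajectory under a piecewise-constant stimulus
#'
#' Propagates the receptor state exactly (matrix exponential per segment of
#' constant ligand) and samples it on a regular output grid.
#'
#' @param stimulus a [square_wave()] or [segment_stimulus()] object.
#' @param params a [pth_kinetics()] object.
#' @param horizon simulation length (min), `> 0`.
#' @param dt_out output sampling step (min).
#' @param init initial [receptor_state()]; defaults to the equilibrium at
#'   the stimulus value at `t = 0`.
#' @return A data frame of class `pth_trajectory` with columns `time_min`,
#'   `ligand_pmol_per_L`, `r_a`, `c_a`, `c_i`, `r_i`.
#' @export
simulate_trajectory <- function(stimulus, params, horizon, dt_out = 0.5,
                                init = NULL) {
  if (!is.finite(horizon) || horizon <= 0) stop("'horizon' must be > 0")
  seg <- stimulus_segments(stimulus, horizon)
  if (any(seg$value < 0)) stop("stimulus values must be non-negative")
  if (is.null(init)) init <- equilibrium_state(seg$value[1], params)
  times <- seq(0, horizon, by = dt_out)
  out <- matrix(NA_real_, nrow = length(times), ncol = 4,
                dimnames = list(NULL, state_names))
  lig <- numeric(length(times))
  x <- as.numeric(init)
  t_cur <- 0
  i <- 1L
  for (s in seq_len(nrow(seg))) {
    fl <- kinetic_flow(rate_matrix(seg$value[s], params))
    # advance to segment start (only relevant for the first partial step)
    if (t_cur < seg$start[s] - 1e-12) t_cur <- seg$start[s]
    idx <- which(times >= seg$start[s] - 1e-12 & times < seg$end[s] - 1e-12)
    Estep <- NULL; last_dt <- NA_real_
    for (j in idx) {
      dt <- times[j] - t_cur
      if (dt > 1e-13) {
        if (!identical(dt, last_dt)) { Estep <- fl$E(dt); last_dt <- dt }
        x <- drop(Estep %*% x)
        t_cur <- times[j]
      }
      out[j, ] <- x
      lig[j] <- seg$value[s]
      i <- j
    }
    # propagate across the remainder of the segment
    dt <- seg$end[s] - t_cur
    if (dt > 1e-13) {
      x <- drop(fl$E(dt) %*% x)
      t_cur <- seg$end[s]
    }
  }
  # final grid point coincides with the horizon
  if (times[length(times)] >= t_cur - 1e-12) {
    out[length(times), ] <- x
    lig[length(times)] <- seg$value[nrow(seg)]
  }
  traj <- data.frame(time_min = times, ligand_pmol_per_L = lig, out)
  class(traj) <- c("pth_trajectory", "data.frame")
  traj
}

#' Write a trajectory to CSV
#'
#' @param trajectory a `pth_trajectory` from [simulate_trajectory()].
#' @param path output file path.
#' @param manifest optional [run_manifest()]; its id is embedded as a
#'   leading comment line.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, manifest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest))
    writeLines(sprintf("# manifest: %s", manifest$id), con)
  utils::write.csv(as.data.frame(trajectory), con, row.names = FALSE)
  invisible(path)
}

#' Periodic steady state of the receptor under a square-wave stimulus
#'
#' The one-period map of the linear flow is `x -> M x` with
#' `M = exp(K(gamma0) tau0) exp(K(gamma1) tau1)`; because the propagators
#' preserve the receptor total, `M` has the simple eigenvalue 1 and the
#' periodic steady state is its normalised fixed vector.  The subdominant
#' eigenvalue modulus (the per-period contraction rate) must be `< 1`.
#'
#' @param stimulus a [square_wave()].
#' @param params a [pth_kinetics()] object.
#' @return The [receptor_state()] at the start of the on-phase, with the
#'   contraction rate in attribute `contraction`.
#' @export
periodic_steady_state <- function(stimulus, params) {
  stopifnot(inherits(stimulus, "square_wave"))
  seg <- one_period_segments(stimulus)
  periodic_state_segments(seg, params)
}

one_period_segments <- function(stim) {
  if (stim$tau1 >= stim$period)
    return(data.frame(start = 0, end = stim$period, value = stim$gamma1))
  data.frame(start = c(0, stim$tau1), end = c(stim$tau1, stim$period),
             value = c(stim$gamma1, stim$gamma0))
}

# fixed point of the one-period map over arbitrary constant-ligand segments
periodic_state_segments <- function(seg, params) {
  M <- diag(4)
  for (s in seq_len(nrow(seg))) {
    fl <- kinetic_flow(rate_matrix(seg$value[s], params))
    M <- fl$E(seg$end[s] - seg$start[s]) %*% M
  }
  ev <- eigen(M, only.values = TRUE)$values
  contraction <- sort(Mod(ev), decreasing = TRUE)[2]
  if (!is.finite(contraction) || contraction >= 1 - 1e-12)
    stop("one-period map is not contracting; cannot determine a periodic steady state")
  x <- qr.solve(rbind(M - diag(4), rep(1, 4)), c(0, 0, 0, 0, 1))
  res <- max(abs(M %*% x - x))
  if (res > 1e-10)
    stop(sprintf("periodic fixed point residual %.3g exceeds 1e-10", res))
  x[x < 0 & x > -1e-12] <- 0
  out <- as_state(x / sum(x))
  attr(out, "contraction") <- contraction
  out
}
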