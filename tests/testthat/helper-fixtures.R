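# shared fixtures: default (detailed-balance) kinetics, unit-scale
# exact-adaptation coefficients, and independent ODE oracles built on deSolve

kin <- pth_kinetics()
kin_printed <- pth_kinetics(detailed_balance = FALSE)
cf <- activity_coefficients(1, 0, 0, kin, s = 1)

# independent adaptive-solver propagation of dx/dt = K(L) x
ode_propagate <- function(state, L, dt, params, rtol = 1e-9) {
  K <- rate_matrix(L, params)
  sol <- deSolve::lsoda(y = as.numeric(state), times = c(0, dt),
                        func = function(t, y, p) list(K %*% y),
                        rtol = rtol, atol = 1e-13)
  as.numeric(sol[2, -1])
}

# segment-wise adaptive integration of a square wave over n periods,
# returning the state at the end
ode_periods <- function(stimulus, params, n_periods, init, rtol = 1e-9) {
  x <- as.numeric(init)
  seg <- pthpulse:::one_period_segments(stimulus)
  for (k in seq_len(n_periods))
    for (s in seq_len(nrow(seg)))
      x <- ode_propagate(x, seg$value[s], seg$end[s] - seg$start[s],
                         params, rtol = rtol)
  x
}

# dense activity sampling after a ligand step, via the adaptive solver
ode_step_activity <- function(gamma0, gamma1, params, coeffs, times,
                              rtol = 1e-10) {
  K <- rate_matrix(gamma1, params)
  x0 <- as.numeric(equilibrium_state(gamma0, params))
  sol <- deSolve::lsoda(y = x0, times = times,
                        func = function(t, y, p) list(K %*% y),
                        rtol = rtol, atol = 1e-14)
  a <- pthpulse:::coefficient_vector(coeffs)
  as.numeric(sol[, -1, drop = FALSE] %*% a)
}

# random physiological scenario wrapped as a pth_scenario
random_scenario <- function(seed) {
  st <- generate_test_stimulus(seed = seed)
  structure(list(name = sprintf("random_%d", seed), stimulus = st,
                 r = auc_decomposition(st, st$period)$r,
                 provenance = "test fixture"),
            class = "pth_scenario")
}

# closed-form AUC of a square wave over a window s (the mean-rate form the
# AUC constraints are expressed in; exact for whole-period windows)
closed_auc <- function(sw, s) {
  puls_rate <- (sw$gamma1 - sw$gamma0) * sw$tau1 / sw$period
  list(A = (sw$gamma0 + puls_rate) * s, A_puls = puls_rate * s)
}

# small multistart grid to keep optimiser tests fast
fast_starts <- function(scenario) {
  g0 <- scenario$stimulus$gamma0
  rbind(expand.grid(amp = g0 * c(1, 4), tau1 = c(5, 15)),
        data.frame(amp = scenario$stimulus$gamma1 - scenario$stimulus$gamma0,
                   tau1 = scenario$stimulus$tau1))
}
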