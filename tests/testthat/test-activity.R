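test_that("exact-adaptation weight construction is consistent", {
  r <- kinetic_ratios(kin)
  # uniform weights are a fixed point of the construction
  for (c0 in c(0, 0.3, 1, 2.7))
    expect_equal(a2_exact_adaptation(c0, c0, c0, r$K1, r$K2), c0,
                 tolerance = 1e-14)
  expect_equal(a2_exact_adaptation(0, 0, 0, r$K1, r$K2), 0)
  expect_error(a2_exact_adaptation(0, 5, 0, r$K1, r$K2), "a3")
})

test_that("steady-state activity is ligand-independent under detailed balance", {
  acts <- vapply(c(0, 1, 10, 100),
                 function(L) scaled_activity(equilibrium_state(L, kin), cf),
                 numeric(1))
  expect_lt(max(abs(acts - acts[1])), 1e-9)
  # with the printed inactive-complex dissociation constant the cycle has a
  # stationary flux and adaptation is only approximate
  cf_p <- activity_coefficients(1, 0, 0, kin_printed, s = 1)
  acts_p <- vapply(c(0, 1, 10, 100),
                   function(L) scaled_activity(equilibrium_state(L, kin_printed), cf_p),
                   numeric(1))
  expect_gt(max(abs(acts_p - acts_p[1])), 1e-3)
})

test_that("scaled activity is the expected weighted sum", {
  cu <- activity_coefficients(0.7, 0.7, 0.7, kin, s = 1)
  set.seed(3)
  for (i in 1:5) {
    x <- abs(rnorm(4)); x <- x / sum(x)
    expect_equal(scaled_activity(pthpulse:::as_state(x), cu), 0.7,
                 tolerance = 1e-12)
  }
  expect_equal(scaled_activity(pthpulse:::as_state(c(1, 0, 0, 0)), cf), cf$a1)
  r <- kinetic_ratios(kin)
  expect_equal(basal_activity(cf, kin, gamma0 = 0),
               (cf$a1 * r$K1 + cf$a4) / (r$K1 + 1), tolerance = 1e-9)
  # basal reference equals the steady-state activity at any constant level
  expect_equal(basal_activity(cf, kin, gamma0 = 0),
               scaled_activity(equilibrium_state(50, kin), cf),
               tolerance = 1e-9)
})

test_that("step response peak and adaptation match a dense oracle", {
  sr <- step_response(3.3, 8.3, kin, cf)
  expect_gt(sr$tau_a, 0)
  expect_identical(sr$alpha_T_step, sr$tau_a * sr$alpha_M_step)
  # peak height against dense adaptive-solver sampling
  times <- seq(0, 40, by = 0.002)
  av <- ode_step_activity(3.3, 8.3, kin, cf, times)
  expect_equal(sr$alpha_M_step, max(av), tolerance = 1e-3)
  expect_equal(sr$t_peak, times[which.max(av)], tolerance = 0.05)
  # vanishing step: no excursion beyond the basal activity
  sr0 <- step_response(5, 5 * (1 + 1e-9), kin, cf)
  expect_equal(sr0$alpha_M_step, sr0$alpha_0, tolerance = 1e-7)
  expect_error(step_response(5, 5, kin, cf), "exceed")
})

test_that("integrated pulse activity matches quadrature and scales linearly", {
  sw <- square_wave(3.3, 8.3, 5, 15)
  aT <- integrated_pulse_activity(sw, kin, cf)
  # trapezoid quadrature of the activity along an exactly propagated
  # trajectory over one period at the periodic steady state
  x0 <- periodic_steady_state(sw, kin)
  dt <- 0.001
  tr <- simulate_trajectory(sw, kin, horizon = sw$period, dt_out = dt,
                            init = x0)
  act <- trajectory_activity(tr, cf) - basal_activity(cf, kin, sw$gamma0)
  quad <- (sum(act) - (act[1] + act[length(act)]) / 2) * dt
  expect_equal(aT, quad, tolerance = 1e-6)
  # linearity in the coefficients
  cf3 <- activity_coefficients(3, 0, 0, kin, s = 1)
  expect_equal(integrated_pulse_activity(sw, kin, cf3), 3 * aT,
               tolerance = 1e-9)
  # constant stimulus integrates to zero (exact adaptation)
  expect_lt(abs(integrated_pulse_activity(square_wave(5, 5, 3, 12), kin, cf)),
            1e-9)
})

test_that("cellular responsiveness follows its defining identity", {
  sw <- square_wave(3.3, 8.3, 5, 15)
  res <- cellular_responsiveness(sw, kin, cf)
  expect_false(res$degenerate)
  expect_equal(res$alpha_R,
               res$alpha_T^2 / (res$alpha_T_step * sw$period),
               tolerance = 1e-12)
  expect_gt(res$alpha_T_step, res$alpha_T)  # step response dominates
  # degenerate stimulus: zero responsiveness, flagged
  res0 <- cellular_responsiveness(square_wave(4, 4, 3, 10), kin, cf)
  expect_true(res0$degenerate)
  expect_identical(res0$alpha_R, 0)
  # homogeneity of degree one in the coefficients
  cfc <- activity_coefficients(2.5, 0, 0, kin, s = 1)
  resc <- cellular_responsiveness(sw, kin, cfc)
  expect_equal(resc$alpha_R, 2.5 * res$alpha_R, tolerance = 1e-8)
  expect_equal(resc$alpha_M_step, 2.5 * res$alpha_M_step, tolerance = 1e-8)
  expect_equal(resc$tau_a, res$tau_a, tolerance = 1e-8)
})

test_that("per-period integral agrees with a long-run simulated rhythm", {
  sw <- square_wave(2.5, 9, 4, 12)
  aT <- integrated_pulse_activity(sw, kin, cf)
  # independent route: simulate the rhythm in from basal equilibrium (the
  # slowest receptor mode relaxes over ~80 min, so 120 periods suffice),
  # then integrate the activity over the last period by fine sampling
  n <- 120
  dt <- 0.004
  tr <- simulate_trajectory(sw, kin, horizon = n * sw$period, dt_out = dt,
                            init = equilibrium_state(sw$gamma0, kin))
  idx <- tr$time_min >= (n - 1) * sw$period
  act <- trajectory_activity(tr[idx, ], cf) - basal_activity(cf, kin, sw$gamma0)
  quad <- (sum(act) - (act[1] + act[length(act)]) / 2) * dt
  expect_equal(aT, quad, tolerance = 1e-4)
  # responsiveness is invariant to the phase origin of the pulse train:
  # integrating over [phi, phi + T] at the rhythm gives the same alpha_T
  phi <- 7.3
  idx2 <- tr$time_min >= (n - 2) * sw$period + phi &
          tr$time_min <= (n - 1) * sw$period + phi
  act2 <- trajectory_activity(tr[idx2, ], cf) - basal_activity(cf, kin, sw$gamma0)
  quad2 <- (sum(act2) - (act2[1] + act2[length(act2)]) / 2) * dt
  expect_equal(quad2, aT, tolerance = 1e-4)
})

test_that("responsiveness serialises with all intermediates", {
  sw <- square_wave(3.3, 8.3, 5, 15)
  res <- cellular_responsiveness(sw, kin, cf)
  f <- withr::local_tempfile(fileext = ".json")
  write_responsiveness(res, f, manifest = run_manifest(kin, cf))
  back <- jsonlite::read_json(f)
  expect_equal(back$alpha_R, res$alpha_R, tolerance = 1e-12)
  expect_equal(back$tau_a_criterion, exp(-1), tolerance = 1e-12)
  expect_true(!is.null(back$manifest$id))
})
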