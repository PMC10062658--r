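test_that("square-wave evaluation is periodic and right-continuous", {
  sw <- square_wave(2, 7, 4, 10)
  expect_identical(stimulus_value(sw, 0), 7)
  expect_identical(stimulus_value(sw, 4 + 1e-9), 2)
  set.seed(11)
  t <- runif(20, 0, 100)
  expect_equal(stimulus_value(sw, t), stimulus_value(sw, t + sw$period))
  expect_error(square_wave(5, 3, 2, 10), "gamma0 <= gamma1")
  expect_error(square_wave(2, 7, 12, 10), "tau1 <= period")
})

test_that("AUC decomposition matches the closed form and quadrature", {
  d <- auc_decomposition(square_wave(5, 10, 10, 50), 100)
  expect_equal(d$A, 600)
  expect_equal(d$A_puls, 100)
  expect_equal(d$r, 1 / 6)
  expect_true(d$commensurate)
  expect_equal(d$A, d$A_tonic + d$A_puls)
  # no pulses
  expect_equal(auc_decomposition(square_wave(5, 5, 10, 50), 100)$r, 0)
  # independent oracle: enumerate switch times and sum value * length
  set.seed(21)
  for (i in 1:10) {
    sw <- generate_test_stimulus(seed = 100 + i)
    s <- runif(1, 1, 6) * sw$period
    bp <- sort(unique(c(0, s,
                        outer(c(0, sw$tau1), (0:ceiling(s / sw$period)) * sw$period, "+"))))
    bp <- bp[bp >= 0 & bp <= s]
    mid <- (bp[-1] + bp[-length(bp)]) / 2
    oracle <- sum(stimulus_value(sw, mid) * diff(bp))
    d2 <- auc_decomposition(sw, s)
    expect_equal(d2$A, oracle, tolerance = 1e-9)
    if (!d2$commensurate) expect_false(d2$commensurate)
  }
})

test_that("PK curve matches the Bateman closed form and its analytic AUC", {
  pk <- pk_parameters(k_a = 0.05, k_e = 0.02, V_d = 80, F = 0.9)
  expect_equal(pk_concentration(0, pk, c(0, 10, 100)), c(0, 0, 0))
  # independent ODE integration of the two-compartment absorption system
  D <- 20
  Dp <- D * 1e6 / pk$molar_mass
  sol <- deSolve::lsoda(y = c(D = Dp, L = 0), times = seq(0, 600, by = 5),
                        func = function(t, y, p)
                          list(c(-pk$k_a * y[1],
                                 pk$F * pk$k_a / pk$V_d * y[1] - pk$k_e * y[2])),
                        rtol = 1e-11, atol = 1e-12)
  closed <- pk_concentration(D, pk, sol[, "time"])
  expect_equal(as.numeric(sol[, "L"]), closed, tolerance = 1e-8)
  # quadrature AUC vs analytic F D / (V_d k_e)
  tq <- seq(0, 4000, by = 0.05)
  cq <- pk_concentration(D, pk, tq)
  auc_q <- (sum(cq) - (cq[1] + cq[length(cq)]) / 2) * 0.05
  expect_equal(auc_q, pk_summary(D, pk)$auc, tolerance = 1e-6)
  # equal-rate limit is the continuous limit of the closed form
  pk_eq <- pk_parameters(k_a = 0.03, k_e = 0.03, V_d = 80, F = 0.9)
  pk_near <- pk_parameters(k_a = 0.03 * (1 + 1e-7), k_e = 0.03, V_d = 80, F = 0.9)
  expect_equal(pk_concentration(D, pk_eq, c(5, 30, 120)),
               pk_concentration(D, pk_near, c(5, 30, 120)), tolerance = 1e-5)
  expect_error(pk_concentration(-1, pk, 0), ">= 0")
})

test_that("injection square-wave reduction preserves peak and AUC", {
  pk <- pk_parameters(k_a = 0.05, k_e = 0.02, V_d = 80, F = 0.9)
  g0 <- 3
  sw <- injection_square_wave(20, pk, g0)
  s <- pk_summary(20, pk)
  expect_equal(sw$gamma1 - g0, s$c_max, tolerance = 1e-12)
  # same AUC above the tonic baseline, by construction and numerically
  expect_equal((sw$gamma1 - g0) * sw$tau1, s$auc, tolerance = 1e-9)
  # doubling the dose doubles the AUC and leaves the on-phase unchanged
  sw2 <- injection_square_wave(40, pk, g0)
  expect_equal((sw2$gamma1 - g0) * sw2$tau1, 2 * s$auc, tolerance = 1e-9)
  expect_equal(sw2$tau1, sw$tau1, tolerance = 1e-12)
  # reduction must fit into the dosing period
  expect_error(injection_square_wave(20, pk, g0, T_inj = 10), "not shorter")
})

test_that("separable superposition reduces and orders correctly", {
  gl <- square_wave(3.3, 8.3, 5, 15)
  pk <- pk_parameters(k_a = 0.05, k_e = 0.02, V_d = 80, F = 0.9)
  m0 <- responsiveness_model2(gl, NULL, kin, cf)
  base <- cellular_responsiveness(gl, kin, cf)
  expect_identical(m0$alpha_R_total, base$alpha_R)
  expect_identical(m0$alpha_R_inj, 0)
  # totals increase with the daily dose
  tot <- vapply(c(10, 20, 30), function(D) {
    inj <- injection_square_wave(D, pk, gl$gamma0)
    responsiveness_model2(gl, inj, kin, cf)$alpha_R_total
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("one-simulation superposition partitions the activity integral", {
  gl <- square_wave(3.3, 8.3, 5, 15)
  pk <- pk_parameters(k_a = 0.05, k_e = 0.02, V_d = 80, F = 0.9)
  # no injection: exact reduction to the glandular result
  m1_0 <- responsiveness_model1(gl, NULL, kin, cf)
  base <- cellular_responsiveness(gl, kin, cf)
  expect_identical(m1_0$alpha_R_total, base$alpha_R)
  for (D in c(10, 30)) {
    inj <- injection_square_wave(D, pk, gl$gamma0)
    m1 <- responsiveness_model1(gl, inj, kin, cf)
    # component integrals sum to the whole-cycle excess integral
    n_gl <- round(1440 / m1$gland_period)
    expect_equal(n_gl * m1$alpha_T_gl + m1$alpha_T_inj, m1$alpha_T_total,
                 tolerance = 1e-9 * max(1, abs(m1$alpha_T_total)))
    # the gland share recovers the gland-only rhythm in the washed-out tail
    expect_equal(m1$alpha_T_gl, integrated_pulse_activity(gl, kin, cf),
                 tolerance = 1e-4)
    # the two superposition models describe the same physics: same order of
    # magnitude; the separable model drops the gland x drug interaction
    m2 <- responsiveness_model2(gl, inj, kin, cf)
    expect_lt(abs(log(m1$alpha_R_total / m2$alpha_R_total)), log(2))
  }
  # totals keep the dose ordering under both models
  tot1 <- vapply(c(10, 30), function(D)
    responsiveness_model1(gl, injection_square_wave(D, pk, gl$gamma0),
                          kin, cf)$alpha_R_total, numeric(1))
  expect_true(all(diff(tot1) > 0))
})
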