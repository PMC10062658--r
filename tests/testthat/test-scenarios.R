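test_that("the shipped registry loads, validates and derives correctly", {
  reg <- load_scenarios()
  expect_s3_class(reg, "pth_registry")
  expect_true(all(c("healthy", "OP", "PMO", "GIO", "HP",
                    "hypocal1", "hypocal2", "hypercal",
                    "healthy_reduced_tonic") %in% names(reg)))
  # derived scenario: tonic reduced by 20%, pulse amplitude preserved
  h <- reg$healthy$stimulus; rt <- reg$healthy_reduced_tonic$stimulus
  expect_equal(rt$gamma0, 0.8 * h$gamma0, tolerance = 1e-12)
  expect_equal(rt$gamma1 - rt$gamma0, h$gamma1 - h$gamma0, tolerance = 1e-12)
  # roughly a third of healthy secretion is pulsatile
  expect_lt(abs(reg$healthy$r - 1 / 3), 0.05)
  # declared fractions agree with each pattern's own AUC decomposition
  for (s in reg)
    expect_equal(s$r, auc_decomposition(s$stimulus, s$stimulus$period)$r,
                 tolerance = 1e-4)
  expect_true(all(vapply(reg, function(s) nzchar(s$provenance), logical(1))))
})

test_that("registry validation rejects malformed configurations", {
  base <- yaml::read_yaml(default_config_path())
  bad <- withr::local_tempfile(fileext = ".yaml")

  cfg <- base
  cfg$scenarios <- c(cfg$scenarios, cfg$scenarios[1])  # duplicate name
  yaml::write_yaml(cfg, bad)
  expect_error(load_scenarios(bad), "duplicate")

  cfg <- base
  cfg$scenarios[[1]]$gamma1 <- NULL                    # missing field
  yaml::write_yaml(cfg, bad)
  expect_error(load_scenarios(bad), "missing field")

  cfg <- base
  cfg$scenarios[[3]]$gamma1 <- cfg$scenarios[[3]]$gamma0 - 1
  yaml::write_yaml(cfg, bad)
  expect_error(load_scenarios(bad), "gamma1 < gamma0")

  cfg <- base
  cfg$units$concentration <- "ng/mL"                   # unit mismatch
  yaml::write_yaml(cfg, bad)
  expect_error(load_scenarios(bad), "unsupported concentration unit")

  cfg <- base
  cfg$scenarios[[1]]$r <- 0.9                          # inconsistent fraction
  yaml::write_yaml(cfg, bad)
  expect_error(load_scenarios(bad), "disagrees")
})

test_that("registry round-trips losslessly through YAML", {
  reg <- load_scenarios()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenarios(reg, f)
  reg2 <- load_scenarios(f)
  expect_identical(names(reg), names(reg2))
  for (nm in names(reg)) {
    expect_equal(unclass(reg[[nm]]$stimulus), unclass(reg2[[nm]]$stimulus),
                 tolerance = 1e-12)
    expect_equal(reg[[nm]]$r, reg2[[nm]]$r, tolerance = 1e-12)
  }
  expect_equal(attr(reg, "activity"), attr(reg2, "activity"),
               tolerance = 1e-12)
})

test_that("the stimulus fixture generator is deterministic and valid", {
  a <- generate_test_stimulus(seed = 9)
  b <- generate_test_stimulus(seed = 9)
  expect_identical(unclass(a), unclass(b))
  # caller RNG state untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_test_stimulus(seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
  draws <- generate_test_stimulus(n = 200, seed = 17)
  for (sw in draws) {
    expect_true(sw$gamma0 >= 1 && sw$gamma0 <= 10)
    expect_true(sw$gamma1 >= sw$gamma0)
    expect_true(sw$tau1 > 0 && sw$tau1 <= sw$period)
    expect_true(sw$period <= 120)
  }
  # burst frequency within the physiological 3-7 per hour band when the
  # period range is restricted accordingly
  fast <- generate_test_stimulus(n = 50, seed = 23, tau1_range = c(1, 5),
                                 period_range = c(60 / 7, 20))
  freq <- vapply(fast, function(s) 60 / s$period, numeric(1))
  expect_true(all(freq >= 3 & freq <= 7))
  expect_error(generate_test_stimulus(seed = 1, gamma0_range = c(5, 1)),
               "invalid")
})

test_that("table reproduction is deterministic and embeds its manifest", {
  reg <- load_scenarios()
  cfd <- default_coefficients(kin, reg)
  pk <- default_pk(reg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  t2 <- reproduce_table("table2", reg, kin, cfd, pk,
                        scenarios = "OP", doses = c(0, 10), path = f1)
  reproduce_table("table2", reg, kin, cfd, pk,
                  scenarios = "OP", doses = c(0, 10), path = f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  expect_match(readLines(f1)[1], "^# manifest: [0-9a-f]{8}")
  # without an injection the two superposition models coincide exactly
  d0 <- t2[t2$dose_ug == 0, ]
  expect_identical(d0$alpha_R_model1, d0$alpha_R_model2)
  expect_true(all(t2$alpha_R_model2_display == round(t2$alpha_R_model2, 3)))
})

test_that("table4 reports the optimised fractionation and deficit dose", {
  reg <- load_scenarios()
  cfd <- default_coefficients(kin, reg)
  pk <- default_pk(reg)
  t4 <- reproduce_table("table4", reg, kin, cfd, pk, doses = 20)
  expect_identical(nrow(t4), 2L)
  expect_true(all(c("alpha_R_max", "D_max", "tau1_max", "T_max",
                    "gamma1_max") %in% names(t4)))
  opt <- t4[t4$column == "optimised daily dose", ]
  expect_gt(opt$D_max, 0)
  # the optimised daily dose fills the healthy-vs-OP deficit
  refR <- cellular_responsiveness(reg$healthy$stimulus, kin, cfd)$alpha_R
  illR <- cellular_responsiveness(reg$OP$stimulus, kin, cfd)$alpha_R
  expect_equal(opt$alpha_R_max, refR - illR, tolerance = 1e-2)
})

test_that("kinetics can be configured from the registry file with unit tags", {
  reg <- load_scenarios()
  expect_equal(unclass(default_kinetics(reg)), unclass(pth_kinetics()))
  cfg <- yaml::read_yaml(default_config_path())
  cfg$kinetics <- list(k1 = 0.02, Kr = 2, conc_unit = "nM",
                       detailed_balance = FALSE, Kd = 500)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  k2 <- default_kinetics(load_scenarios(f))
  expect_equal(k2$k1, 0.02)
  expect_equal(kinetic_ratios(k2)$Kr, 2000)   # nM declared, stored in pmol/L
  expect_equal(kinetic_ratios(k2)$Kd, 5e5)
})

test_that("run manifests are deterministic parameter snapshots", {
  m1 <- run_manifest(kin, cf)
  m2 <- run_manifest(kin, cf)
  expect_identical(m1$id, m2$id)
  m3 <- run_manifest(kin, cf, tau_a_criterion = 0.02)
  expect_false(identical(m1$id, m3$id))
  expect_identical(m1$off_rates, c(k_minusr = 10, k_minusd = 10))
})
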