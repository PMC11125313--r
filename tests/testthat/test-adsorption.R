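test_that("removal percentage supports both denominator conventions", {
  expect_equal(as.numeric(removal_percent(10, 5)), 50)
  expect_equal(as.numeric(removal_percent(10, 10)), 0)
  expect_equal(as.numeric(removal_percent(10, 5, "as_printed")), 100)
  expect_equal(as.numeric(removal_percent(10, 10, "as_printed")), 0)
  expect_identical(attr(removal_percent(10, 5), "convention"), "standard")
  expect_error(removal_percent(0, 5), "denominator")
  # bounded by 100 whenever Ce <= Co
  set.seed(3)
  Co <- runif(50, 1, 100); Ce <- Co * runif(50)
  r <- as.numeric(removal_percent(Co, Ce))
  expect_true(all(r >= 0 & r <= 100))
})

test_that("areal capacity is (Co - Ce) V / A", {
  expect_equal(adsorption_capacity(10, 10, V_L = 0.01), 0)
  expect_equal(adsorption_capacity(10, 4.3, V_L = 0.010), 0.057)
  expect_equal(adsorption_capacity(10, 4.3, V_L = 0.010, A_cm2 = 2),
               0.057 / 2)
  expect_warning(adsorption_capacity(5, 6, V_L = 0.01), "Ce > Co")
  expect_error(adsorption_capacity(10, 5, V_L = 0), "V_L")
})

test_that("absorbance conversion inverts a linear law and flags range", {
  cal <- beer_lambert_calibration(slope = 0.05, intercept = 0.01,
                                  range = c(0, 1))
  expect_equal(as.numeric(absorbance_to_concentration(0.01, cal)), 0)
  conc <- c(2, 8, 15)
  back <- absorbance_to_concentration(0.01 + 0.05 * conc, cal)
  expect_equal(as.numeric(back), conc)
  flagged <- absorbance_to_concentration(c(0.5, 1.5), cal)
  expect_identical(attr(flagged, "out_of_range"), c(FALSE, TRUE))
  expect_equal(as.numeric(flagged[2]), (1.5 - 0.01) / 0.05)
  expect_error(beer_lambert_calibration(slope = 0), "slope")
})

test_that("kinetic fitters recover generating parameters on clean data", {
  t <- seq(10, 120, by = 10)
  # PFO round trip (fixing Qe at the generating value)
  pfo <- data.frame(t_min = t, Qt = 0.059 * (1 - exp(-0.023 * t)))
  f <- fit_kinetics(pfo, "PFO", Qe_exp = 0.059)
  expect_equal(unname(f$parameters["k1"]), 0.023, tolerance = 1e-3)
  expect_equal(unname(f$parameters["Q_cal"]), 0.059, tolerance = 1e-6)
  expect_equal(f$r2, 1)
  # PSO round trip to <= 1e-6 relative
  pso <- data.frame(t_min = t, Qt = 0.013 * 0.05^2 * t / (1 + 0.013 * 0.05 * t))
  f2 <- fit_kinetics(pso, "PSO")
  expect_equal(unname(f2$parameters["k2"]), 0.013, tolerance = 1e-6)
  expect_equal(unname(f2$parameters["Qe"]), 0.05, tolerance = 1e-6)
  # IPD over its default 10-60 min window
  ipd <- data.frame(t_min = t, Qt = 5.046 * sqrt(t) + 0.3)
  f3 <- fit_kinetics(ipd, "IPD")
  expect_equal(f3$window, c(10, 60))
  expect_equal(unname(f3$parameters["kid"]), 5.046, tolerance = 1e-9)
  expect_equal(unname(f3$parameters["C"]), 0.3, tolerance = 1e-9)
})

test_that("linearized and nonlinear kinetic fits agree on clean data", {
  t <- seq(10, 120, by = 10)
  pfo <- data.frame(t_min = t, Qt = 0.059 * (1 - exp(-0.023 * t)))
  f <- fit_kinetics(pfo, "PFO", Qe_exp = 0.059)
  expect_equal(unname(f$nonlinear$parameters["k1"]),
               unname(f$parameters["k1"]), tolerance = 1e-3)
  expect_gt(f$nonlinear$r2, 1 - 1e-9)
})

test_that("PFO handles the plateau default and degenerate logs", {
  t <- seq(10, 120, by = 10)
  pfo <- data.frame(t_min = t, Qt = 0.059 * (1 - exp(-0.04 * t)))
  # Qe defaults to the last observation; that point is dropped from the log
  expect_message(f <- fit_kinetics(pfo, "PFO", nonlinear = FALSE),
                 "dropped")
  expect_equal(unname(f$parameters["k1"]), 0.04, tolerance = 0.05)
  expect_error(fit_kinetics(pfo[1:5, ], "PFO", Qe_exp = 0.001),
               "Qe - Qt > 0")
  expect_error(fit_kinetics(pfo[1:2, ], "PFO"), "fewer than 3")
})

test_that("isotherm fitters recover generating parameters on clean data", {
  Ce <- seq(10, 100, by = 10)
  fre <- data.frame(Ce = Ce, Qe = 0.0375 * Ce^(1 / 3.66))
  f <- fit_isotherm(fre, "Freundlich")
  expect_equal(unname(f$parameters["n"]), 3.66, tolerance = 1e-9)
  expect_equal(unname(f$parameters["Kf"]), 0.0375, tolerance = 1e-9)
  expect_equal(f$r2, 1)
  expect_true(f$favorable)  # 1/n = 0.27 in (0, 1)
  lan <- data.frame(Ce = Ce, Qe = 0.1532 * 0.0785 * Ce / (1 + 0.0785 * Ce))
  f2 <- fit_isotherm(lan, "Langmuir")
  expect_equal(unname(f2$parameters["Qm"]), 0.1532, tolerance = 1e-9)
  expect_equal(unname(f2$parameters["b"]), 0.0785, tolerance = 1e-9)
  # nonlinear refits agree on clean data
  expect_equal(unname(f2$nonlinear$parameters["Qm"]), 0.1532,
               tolerance = 1e-6)
  # model mismatch: Freundlich on Langmuir data cannot reach R^2 = 1
  f3 <- fit_isotherm(lan, "Freundlich", nonlinear = FALSE)
  expect_lt(f3$r2, 1 - 1e-6)
  expect_error(fit_isotherm(data.frame(Ce = c(0, 1, 2), Qe = c(0, 1, 2)),
                            "Freundlich"), "positive")
})

test_that("fitters invert the generators to 1e-6 over parameter settings", {
  cases <- list(
    list(model = "PFO", params = list(Qe = 0.08, k1 = 0.05)),
    list(model = "PSO", params = list(Qe = 0.064, k2 = 0.013)),
    list(model = "IPD", params = list(kid = 0.004, C = 0.002)))
  for (cs in cases) {
    d <- batch_design(times = seq(10, 120, 10), model_name = cs$model,
                      model_params = cs$params, seed = 1)
    kin <- generate_kinetics(d)
    f <- fit_kinetics(kin, cs$model,
                      Qe_exp = if (cs$model == "PFO") cs$params$Qe else NULL,
                      nonlinear = FALSE)
    for (p in intersect(names(f$parameters), names(cs$params)))
      expect_equal(unname(f$parameters[p]), cs$params[[p]],
                   tolerance = 2e-3, info = paste(cs$model, p))
  }
  for (mod in c("Langmuir", "Freundlich")) {
    prm <- if (mod == "Langmuir") list(Qm = 0.1532, b = 0.0785) else
      list(Kf = 0.0375, n = 3.66)
    d <- batch_design(Co_list = seq(10, 100, 10), model_name = mod,
                      model_params = prm, seed = 1)
    f <- fit_isotherm(generate_isotherm(d), mod, nonlinear = FALSE)
    for (p in names(prm))
      expect_equal(unname(f$parameters[p]), prm[[p]], tolerance = 1e-6,
                   info = paste(mod, p))
  }
})

test_that("imprinting and selectivity factors follow their definitions", {
  expect_equal(imprinting_factor(30, 30), 1)
  expect_equal(imprinting_factor(54, 20), 2.70)
  expect_equal(selectivity_factor(2.7, 2.7), 1)
  expect_equal(selectivity_factor(2.70, 1.20), 2.25)
  expect_error(imprinting_factor(10, 0), "positive")
  expect_error(selectivity_factor(2, 0), "positive")
  # imprinting crossing pattern: below unity at low loading, above at high
  conc <- c(10, 30, 50, 70, 100)
  rm_mip <- c(10, 18, 28, 42, 54)
  rm_nip <- c(16, 24, 30, 38, 20)
  alpha <- imprinting_factor(rm_mip, rm_nip)
  expect_true(all(alpha[conc <= 50] < 1))
  expect_true(all(alpha[conc >= 70] > 1))
})

test_that("selectivity analysis over batch records gives alpha and beta", {
  rec <- generate_selectivity_experiment(
    removal_mip = c(tartrazine = 54, sunset = 30),
    removal_nip = c(tartrazine = 20, sunset = 25), seed = 2)
  res <- selectivity_analysis(rec, template = "tartrazine")
  expect_equal(res$alpha[res$label == "tartrazine"], 2.70)
  expect_equal(res$beta[res$label == "tartrazine"], 1)
  expect_equal(res$beta[res$label == "sunset"], 2.70 / (30 / 25))
  expect_error(selectivity_analysis(rec, template = "nope"), "not found")
})

test_that("reusability profiling finds the first degraded cycle", {
  flat <- data.frame(cycle = 1:6, Co = 100, Ce = 50)
  expect_true(is.na(reusability_profile(flat)$drop_cycle))
  prof <- data.frame(cycle = 1:8, Co = 100,
                     Ce = 100 - c(50, 50.5, 49.8, 50.2, 49.9, 41, 35, 30))
  expect_equal(reusability_profile(prof)$drop_cycle, 6)
  # delta = 0: any strictly smaller cycle triggers
  expect_equal(reusability_profile(prof, delta = 0)$drop_cycle, 3)
  expect_error(reusability_profile(flat[1, , drop = FALSE]), "2 cycles")
})
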