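# membrane-charging model, permeabilisation geometry, dose accounting

test_that("charging time constant matches hand evaluation and scaling laws", {
  # hand evaluation: a = 10 um, C_m = 1 uF/cm2, sigma_i = 10 mS/cm,
  # sigma_e = 5 mS/cm -> 1e-5 * 1e-2 * (1 + 1) = 2e-7 s
  expect_equal(charging_time_constant(cell_model(10, 1, 10, 5))$tau_s, 2e-7)

  base <- charging_time_constant(hp_cell())$tau_s
  expect_equal(charging_time_constant(cell_model(radius_um = 28))$tau_s, 2 * base)
  expect_equal(charging_time_constant(cell_model(c_m_uF_cm2 = 2))$tau_s, 2 * base)

  # strictly decreasing in both conductivities
  expect_lt(charging_time_constant(cell_model(sigma_i_mS_cm = 20))$tau_s, base)
  expect_lt(charging_time_constant(cell_model(sigma_e_mS_cm = 3.2))$tau_s, base)

  # f_c is the plain reciprocal
  cc <- charging_time_constant(hp_cell())
  expect_equal(cc$f_c_hz, 1 / cc$tau_s)
})

test_that("study-parameter time constant agrees with the reported value to 5%", {
  tau <- charging_time_constant(hp_cell())$tau_s
  expect_lt(abs(tau - 5.98e-7) / 5.98e-7, 0.05)
})

test_that("polar steady-state voltage is E*a", {
  expect_equal(charging_time_constant(hp_cell(), 40)$v_pole_V, 56)
})

test_that("transmembrane voltage follows the cosine charging law", {
  hp <- hp_cell()
  # zero at t = 0 and at the equator
  expect_equal(as.numeric(transmembrane_voltage(hp, 40, c(0, 30, 60), 0)),
               c(0, 0, 0))
  expect_equal(as.numeric(transmembrane_voltage(hp, 40, 90, c(1, 10, 100))),
               c(0, 0, 0))
  # closed-form limit at the pole: -> E*a to 1e-6 relative at t = 20 tau
  tau_ns <- charging_time_constant(hp)$tau_ns
  vm_inf <- as.numeric(transmembrane_voltage(hp, 40, 0, 20 * tau_ns))
  expect_equal(vm_inf, 56, tolerance = 1e-6)
  # pole voltage at 25 ns, flagged above the 1 V threshold
  vm25 <- transmembrane_voltage(hp, 40, 0, 25)
  expect_equal(as.numeric(vm25), 2.3725, tolerance = 1e-3)
  expect_true(attr(vm25, "hypothetical"))
  # antisymmetry about the equator
  for (th in c(10, 45, 80)) {
    expect_equal(as.numeric(transmembrane_voltage(hp, 40, 180 - th, 40)),
                 -as.numeric(transmembrane_voltage(hp, 40, th, 40)))
  }
  # monotone in t at fixed theta, monotone decreasing in theta at fixed t
  ts <- as.numeric(transmembrane_voltage(hp, 40, 30, c(1, 5, 20, 80)))
  expect_true(all(diff(ts) > 0))
  ths <- as.numeric(transmembrane_voltage(hp, 40, c(0, 20, 50, 85), 40))
  expect_true(all(diff(ths) < 0))
  expect_error(transmembrane_voltage(hp, 40, 0, -1), "non-negative")
})

test_that("charging curve equals pointwise voltage evaluation", {
  hp <- hp_cell()
  theta <- seq(0, 90, by = 15)
  tt <- c(0, 5, 25, 50, 100)
  cur <- charging_curve(hp, 40, theta, tt)
  for (i in seq_along(theta)) {
    for (j in seq_along(tt)) {
      expect_equal(cur$v_m[i, j],
                   as.numeric(transmembrane_voltage(hp, 40, theta[i], tt[j])))
    }
  }
  # column at t = 0 is all zero and unflagged; flags monotone per row
  expect_equal(unname(cur$v_m[, 1]), rep(0, length(theta)))
  expect_false(any(cur$above_threshold[, 1]))
  for (i in seq_along(theta)) {
    expect_true(all(diff(as.integer(cur$above_threshold[i, ])) >= 0))
  }
  # degenerate 1x1 grid
  one <- charging_curve(hp, 40, 0, 0)
  expect_equal(as.vector(one$v_m), 0)
  expect_false(any(one$above_threshold))
  expect_error(charging_curve(hp, 40, numeric(), 1), "non-empty")
  expect_error(charging_curve(hp, 40, c(10, 0), 1), "sorted")
})

test_that("threshold azimuth inverts the charging law", {
  hp <- hp_cell()
  # weak field: threshold unreached
  expect_true(is.na(threshold_azimuth(hp, 0.1, 25)))
  # study conditions: ~77-78 deg at 50 ns, ~65 deg at 25 ns
  th50 <- threshold_azimuth(hp, 40, 50)
  th25 <- threshold_azimuth(hp, 40, 25)
  expect_true(th50 > 76 && th50 < 79)
  expect_lte(th50, 80)
  expect_true(th25 > 64 && th25 < 66)
  # strictly increasing in pulse duration while defined; unreached when
  # the pole never charges to threshold (10 ns here)
  expect_true(is.na(threshold_azimuth(hp, 40, 10)))
  ths <- vapply(c(25, 50, 100, 300), function(tt)
    threshold_azimuth(hp, 40, tt), numeric(1))
  expect_true(all(diff(ths) > 0))
  # self-consistency: voltage at theta* equals the threshold
  expect_equal(as.numeric(transmembrane_voltage(hp, 40, th50, 50)), 1,
               tolerance = 1e-10)
})

test_that("coverage fractions follow the cap geometry", {
  expect_equal(circumference_coverage(90), 1)
  expect_equal(circumference_coverage(45), 0.5)
  expect_equal(sphere_cap_coverage(90), 1)
  expect_equal(sphere_cap_coverage(60), 0.5)
  expect_lt(sphere_cap_coverage(1), 0.001)
  # ~2/3 of the circumference is above threshold within 25 ns
  c25 <- circumference_coverage(threshold_azimuth(hp_cell(), 40, 25))
  expect_equal(c25, 0.723, tolerance = 0.01)
  expect_gte(c25, 2 / 3)
  # monotone in theta*
  grid <- seq(5, 90, by = 5)
  expect_true(all(diff(circumference_coverage(grid)) > 0))
  expect_true(all(diff(sphere_cap_coverage(grid)) > 0))
  expect_error(circumference_coverage(95), "0, 90")
  expect_error(sphere_cap_coverage(0), "0, 90")
  # coverage non-decreasing in pulse duration at fixed field
  perm <- permeabilisation_summary(hp_cell(), 40, c(25, 50))
  expect_true(all(diff(perm$circumference_coverage) > 0))
  expect_true(all(diff(perm$cap_coverage) > 0))
})

test_that("specific energy reproduces the treatment doses and scaling", {
  p25 <- pulse_protocol(duration_ns = 25)
  p50 <- pulse_protocol(duration_ns = 50)
  expect_equal(specific_energy(p25)$W_J_g, 2, tolerance = 0.05)
  expect_equal(specific_energy(p50)$W_J_g, 4, tolerance = 0.05)
  # exact linear/quadratic scaling
  w <- specific_energy(p25)$W_J_kg
  expect_equal(specific_energy(pulse_protocol(duration_ns = 25,
                                              n_pulses = 64))$W_J_kg, 2 * w)
  expect_equal(specific_energy(p50)$W_J_kg, 2 * w)
  expect_equal(specific_energy(pulse_protocol(duration_ns = 25,
                                              sigma_e_mS_cm = 3.2))$W_J_kg,
               2 * w)
  expect_equal(specific_energy(pulse_protocol(field_kV_cm = 80,
                                              duration_ns = 25))$W_J_kg,
               4 * w)
  # zero pulses, zero dose
  expect_equal(specific_energy(pulse_protocol(duration_ns = 25,
                                              n_pulses = 0))$W_J_kg, 0)
})

test_that("residence pulse count follows flow-chamber kinematics", {
  expect_equal(residence_pulse_count(pulse_protocol(duration_ns = 25)), 32L)
  expect_equal(residence_pulse_count(pulse_protocol(duration_ns = 25,
                                                    freq_hz = 0)), 0L)
  expect_equal(residence_pulse_count(pulse_protocol(duration_ns = 25,
                                                    flow_ml_min = 7.5)), 16L)
  expect_error(
    residence_pulse_count(pulse_protocol(duration_ns = 25,
                                         flow_ml_min = NULL)),
    "flow rate"
  )
})

test_that("cell model validates its parameters", {
  expect_error(cell_model(radius_um = -1), "positive")
  expect_error(cell_model(radius_um = 0.01), "plausible")
  expect_error(cell_model(sigma_i_mS_cm = 0), "positive")
  expect_error(pulse_protocol(duration_ns = 25, n_pulses = 1.5), "integer")
})

test_that("the shipped configuration file reproduces the study setup", {
  cfg <- read_electro_config(
    system.file("extdata", "electro_default.yaml", package = "pefastax")
  )
  expect_equal(cfg$cell$radius_um, 14)
  expect_equal(vapply(cfg$protocols, function(p) p$n_pulses, integer(1)),
               c(32L, 32L))
  expect_equal(cfg$v_th, 1)
})
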