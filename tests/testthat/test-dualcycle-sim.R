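# Dual-cycle collection/release simulator: timing, envelope, kinetics,
# cyclic steady state, amplitudes and bandwidth.

test_that("duty cycle and modulation frequency follow the timing arithmetic", {
  expect_equal(duty_cycle(15, 10), 0.6)
  expect_equal(duty_cycle(7, 10), 7 / 17, tolerance = 1e-12)
  expect_equal(duty_cycle(0, 10), 0)
  expect_error(duty_cycle(0, 0), "period")
  expect_equal(modulation_frequency(default_spec), 0.020)
  expect_equal(modulation_frequency(cycle_spec(0.25, 0.25, 0.25, 0.25)), 1)
  dbl <- cycle_spec(30, 20, 30, 20)
  expect_equal(modulation_frequency(dbl), modulation_frequency(default_spec) / 2)
})

test_that("switch envelope labels phases with switch-on at cycle starts", {
  s <- default_spec
  expect_identical(switch_envelope(0, s), "cycle1_on")
  expect_identical(switch_envelope(s$T1, s), "cycle2_on")
  expect_identical(switch_envelope(s$t_on_1, s), "off")
  expect_identical(switch_envelope(s$T + 1, s), "cycle1_on")  # wraps
  # measure of the on-supports over one period
  t <- seq(0, s$T, by = 0.001)[-1]
  on_frac <- mean(switch_envelope(t, s) != "off")
  expect_equal(on_frac * s$T, s$t_on_1 + s$t_on_2, tolerance = 0.01)
})

test_that("simulated number profile is continuous with the analytic initial slope", {
  kin <- kinetic_model()
  tr <- simulate_number(default_spec, kin, n_cycles = 3, dt = 0.05)
  # no jumps beyond what the slew rate allows
  max_slew <- kin$dn1 * sum(kin$weights_c / kin$tau_c)
  expect_lt(max(abs(diff(tr$value))), 3 * max_slew * tr$dt)
  # initial collection rate: dn1 * sum(a_i / tau_i^c)
  fine <- simulate_number(default_spec, kin, n_cycles = 1, dt = 1e-3)
  expect_equal((fine$value[2] - fine$value[1]) / 1e-3, max_slew,
               tolerance = 1e-3)
  expect_error(simulate_number(default_spec, kin, dt = 2), "resolution")
})

test_that("long phases relax to their targets and probe scales with dn2", {
  slow <- cycle_spec(200, 200, 200, 200, f1 = 1e6, f2 = 2e6)
  kin <- kinetic_model(dn1 = 1, dn2 = 0.3)
  tr <- simulate_number(slow, kin, n_cycles = 1, dt = 0.2)
  # value just before switch-off is within 1% of dn1 (5 max tau = 100 s)
  v_end_c1 <- tr$value[which.min(abs(tr$time - 200))]
  expect_equal(v_end_c1, kin$dn1, tolerance = 0.01)
  # probe collection rate is 0.3-fold the control rate (full relaxation)
  i2 <- which.min(abs(tr$time - 400))
  rate1 <- (tr$value[2] - tr$value[1]) / tr$dt
  rate2 <- (tr$value[i2 + 1] - tr$value[i2]) / tr$dt
  expect_equal(rate2 / rate1, 0.3, tolerance = 0.01)
})

test_that("cyclic steady state: analytic fixed point, detection, convergence", {
  kin <- kinetic_model()
  st <- css_state(default_spec, kin)
  tr <- simulate_number(default_spec, kin, n_cycles = 3, dt = 0.1, init = st)
  iT <- which.min(abs(tr$time - default_spec$T))
  expect_equal(tr$value[1], tr$value[iT], tolerance = 1e-12)
  expect_identical(detect_css(tr), 1L)
  # uniform start: first dual cycle transient, later cycles cSS
  tr0 <- simulate_number(default_spec, kin, n_cycles = 5, dt = 0.1)
  expect_identical(detect_css(tr0), 2L)
  # boundary values converge geometrically to the fixed point
  b <- sapply(0:4, function(j)
    tr0$value[which.min(abs(tr0$time - j * default_spec$T))])
  gaps <- abs(b - sum(st))
  expect_true(all(diff(gaps) < 0))
  # non-convergence is signalled
  slow_kin <- kinetic_model(tau_c = c(3, 500), tau_r = c(3, 500))
  tr_s <- simulate_number(default_spec, slow_kin, n_cycles = 2, dt = 0.1)
  expect_warning(res <- detect_css(tr_s, tol = 1e-6), "not reached")
  expect_true(is.na(res))
})

test_that("cycle amplitude is zero for constant traces and saturates at dn", {
  kin <- kinetic_model(dn1 = 1, dn2 = 0.3)
  flat <- simulate_number(default_spec, kinetic_model(dn1 = 0, dn2 = 0),
                          n_cycles = 2, dt = 0.1)
  expect_equal(cycle_amplitude(flat, 1, 1), 0)
  # full-relaxation regime: amplitude -> dn per cycle
  slow <- cycle_spec(300, 300, 300, 300)
  tr <- simulate_number(slow, kin, n_cycles = 1, dt = 0.2)
  expect_equal(cycle_amplitude(tr, 1, 1), kin$dn1, tolerance = 0.01)
  expect_equal(cycle_amplitude(tr, 1, 2), kin$dn2, tolerance = 0.01)
  expect_error(cycle_amplitude(tr, 3, 1), "range error")
})

test_that("cSS amplitude is monotone non-increasing in modulation frequency", {
  kin <- kinetic_model()
  fm <- 10^seq(-3.5, 0.5, length.out = 9)
  amps <- vapply(fm, depspec:::.css_amplitude, numeric(1),
                 kin = kin, spec_template = default_spec, which = 1)
  expect_true(all(diff(amps) <= 1e-9))
  expect_equal(amps[1], kin$dn1, tolerance = 0.01)   # -> dn as f_m -> 0
  expect_lt(amps[length(amps)], 0.05 * kin$dn1)      # vanishing at high f_m
})

test_that("AM bandwidth scales inversely with the time constants", {
  kin <- kinetic_model(tau_c = c(0.3, 2), tau_r = c(0.3, 2))
  bw <- am_bandwidth(kin, default_spec)
  expect_gt(bw, 0.5); expect_lt(bw, 10)   # order 1 Hz for sub-second taus
  half <- kinetic_model(tau_c = c(0.15, 1), tau_r = c(0.15, 1))
  expect_equal(am_bandwidth(half, default_spec), 2 * bw, tolerance = 1e-2)
  # stricter cutoff shrinks the bandwidth
  expect_lt(am_bandwidth(kin, default_spec, cutoff = 0.8), bw)
})

test_that("time rescaling leaves the normalized trace invariant", {
  kin <- kinetic_model()
  kin2 <- kinetic_model(tau_c = 2 * kin$tau_c, tau_r = 2 * kin$tau_r)
  spec2 <- cycle_spec(30, 20, 30, 20, f1 = 1e6, f2 = 2e6)
  a <- simulate_number(default_spec, kin, n_cycles = 2, dt = 0.1)
  b <- simulate_number(spec2, kin2, n_cycles = 2, dt = 0.2)
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("fluorescence map is linear at small n and saturates smoothly", {
  map <- fluorescence_map(k_f = 1000, k_fc = 100, saturation = 1e4)
  expect_equal(fluorescence_from_number(0, map), 100)
  n <- 1e-4
  expect_equal((fluorescence_from_number(n, map) - 100) / n, 1000,
               tolerance = 1e-6)
  expect_equal(fluorescence_from_number(1e9, map), 1e4)
  # monotone
  ns <- seq(0, 100, length.out = 200)
  expect_true(all(diff(fluorescence_from_number(ns, map)) >= 0))
  expect_error(fluorescence_map(saturation = 50), "saturation")
})

test_that("DEP force scale follows the r^3 law and the Re[CM] ratio premise", {
  expect_equal(dep_force_scale(1e-7, 78, 0, 1e14), 0)
  f1 <- dep_force_scale(1e-7, 78, 0.5, 1e14)
  expect_equal(dep_force_scale(2e-7, 78, 0.5, 1e14), 8 * f1)
  r_a <- re_cm(1e6, p_star); r_b <- re_cm(3e6, p_star)
  expect_equal(dep_force_scale(1e-7, 78, r_b, 1e14) /
                 dep_force_scale(1e-7, 78, r_a, 1e14),
               r_b / r_a)
})
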