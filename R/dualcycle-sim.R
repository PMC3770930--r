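# Dual-cycle (control + probe) pulsed-DEP collection/release simulator.
# The particle-number model is a per-mode linear state-space system: each
# kinetic mode relaxes exponentially toward its phase target (a weighted
# initial-to-steady-state transition during collection, the baseline during
# release) and mode states are carried across phase boundaries, which makes
# the trace continuous and the cyclic steady state exactly solvable.

#' Dual-cycle timing specification
#'
#' Timing of one dual cycle: a control collection/release cycle (duration
#' `T1 = t_on_1 + t_off_1`, carrier `f1`) followed by a probe cycle
#' (`T2 = t_on_2 + t_off_2`, carrier `f2`). The modulation frequency is
#' `1/(T1 + T2)`.
#'
#' @param t_on_1,t_off_1 Control-cycle on/off durations, s (>= 0, T1 > 0).
#' @param t_on_2,t_off_2 Probe-cycle on/off durations, s (>= 0, T2 > 0).
#' @param f1,f2 Carrier frequencies, Hz (control, probe).
#' @param amplitude Ground-to-peak drive amplitude, V (informational).
#' @return An object of class `cycle_spec`.
#' @examples
#' spec <- cycle_spec(15, 10, 15, 10, f1 = 1e6, f2 = 2e6)
#' modulation_frequency(spec)  # 0.02 Hz
#' @export
cycle_spec <- function(t_on_1 = 15, t_off_1 = 10, t_on_2 = 15, t_off_2 = 10,
                       f1 = 1e6, f2 = 2e6, amplitude = 1) {
  durs <- c(t_on_1, t_off_1, t_on_2, t_off_2)
  if (any(!is.finite(durs)) || any(durs < 0)) stop("durations must be finite and >= 0")
  if (t_on_1 + t_off_1 <= 0 || t_on_2 + t_off_2 <= 0) stop("cycle periods must be > 0")
  if (f1 <= 0 || f2 <= 0) stop("carrier frequencies must be > 0")
  structure(list(t_on_1 = t_on_1, t_off_1 = t_off_1,
                 t_on_2 = t_on_2, t_off_2 = t_off_2,
                 f1 = f1, f2 = f2, amplitude = amplitude,
                 T1 = t_on_1 + t_off_1, T2 = t_on_2 + t_off_2,
                 T = t_on_1 + t_off_1 + t_on_2 + t_off_2),
            class = "cycle_spec")
}

#' @export
print.cycle_spec <- function(x, ...) {
  cat(sprintf("Dual-cycle spec: %g s on / %g s off (control, %.3g Hz), %g s on / %g s off (probe, %.3g Hz)\n",
              x$t_on_1, x$t_off_1, x$f1, x$t_on_2, x$t_off_2, x$f2))
  cat(sprintf("  period T = %g s, modulation frequency %g Hz, duty %0.3g / %0.3g\n",
              x$T, 1 / x$T, x$t_on_1 / x$T1, x$t_on_2 / x$T2))
  invisible(x)
}

#' Duty-cycle ratio
#'
#' Fraction of a cycle during which the DEP drive is on,
#' `eta = t_on / (t_on + t_off)`.
#'
#' @param t_on,t_off On/off durations, s; their sum must be > 0.
#' @return Ratio in \[0, 1\].
#' @examples
#' duty_cycle(15, 10)  # 0.6
#' @export
duty_cycle <- function(t_on, t_off) {
  if (any(t_on < 0) || any(t_off < 0)) stop("durations must be >= 0")
  if (any(t_on + t_off <= 0)) stop("cycle period must be > 0")
  t_on / (t_on + t_off)
}

#' Modulation frequency of a dual cycle
#'
#' Reciprocal of the total dual-cycle period `T = T1 + T2`.
#'
#' @param spec A [cycle_spec()] object.
#' @return Frequency in Hz.
#' @export
modulation_frequency <- function(spec) {
  stopifnot(inherits(spec, "cycle_spec"))
  1 / spec$T
}

#' Switching envelope phase label
#'
#' Labels each time point (wrapped modulo the dual-cycle period) by the
#' drive phase: `"cycle1_on"` on `[0, t_on_1)`, `"off"` on `[t_on_1, T1)`,
#' `"cycle2_on"` on `[T1, T1 + t_on_2)`, `"off"` elsewhere. Switch-on is at
#' the start of each cycle, so `t = 0` is `cycle1_on`.
#'
#' @param t Times, s (>= 0; wrapped modulo the period).
#' @param spec A [cycle_spec()] object.
#' @return Character vector of phase labels.
#' @export
switch_envelope <- function(t, spec) {
  stopifnot(inherits(spec, "cycle_spec"))
  if (any(t < 0)) stop("times must be >= 0")
  tm <- t %% spec$T
  out <- rep("off", length(t))
  out[tm < spec$t_on_1] <- "cycle1_on"
  out[tm >= spec$T1 & tm < spec$T1 + spec$t_on_2] <- "cycle2_on"
  out
}

#' Exponential-series collection/release kinetics
#'
#' Parameters of the mode-sum model of nanoparticle number near the
#' electrode array: `n_modes` modes with collection weights summing to one,
#' collection/release time constants, and the initial-to-steady-state
#' transitions `dn1` (control cycle) and `dn2` (probe cycle).
#'
#' Defaults follow a two-mode parameterization representative of sub-micron
#' sphere collection dynamics on tens-of-seconds drive cycles: weights
#' (0.7, 0.3), time constants (3, 20) s for both phases.
#'
#' @param dn1,dn2 Initial-to-collection-steady-state transitions (particle
#'   number units; may be normalized). `dn2 = 0.3 * dn1` reproduces a probe
#'   cycle whose shape matches the control scaled by 0.3.
#' @param weights_c,weights_r Non-negative mode weights for the collection
#'   and release phases, each summing to 1.
#' @param tau_c,tau_r Collection and release time constants, s (> 0).
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(dn1 = 1, dn2 = 0.3,
                          weights_c = c(0.7, 0.3), weights_r = weights_c,
                          tau_c = c(3, 20), tau_r = tau_c) {
  n <- length(weights_c)
  if (length(weights_r) != n || length(tau_c) != n || length(tau_r) != n)
    stop("weights and time-constant vectors must have equal length")
  if (any(weights_c < 0) || any(weights_r < 0)) stop("weights must be >= 0")
  if (abs(sum(weights_c) - 1) > 1e-8 || abs(sum(weights_r) - 1) > 1e-8)
    stop("weights must sum to 1 in each phase")
  if (any(tau_c <= 0) || any(tau_r <= 0)) stop("time constants must be > 0")
  structure(list(dn1 = dn1, dn2 = dn2, weights_c = weights_c,
                 weights_r = weights_r, tau_c = tau_c, tau_r = tau_r,
                 n_modes = n),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model: %d modes, dn1 = %g, dn2 = %s\n", x$n_modes,
              x$dn1, paste(signif(x$dn2, 4), collapse = ", ")))
  cat(sprintf("  weights_c = (%s), tau_c = (%s) s, tau_r = (%s) s\n",
              paste(x$weights_c, collapse = ", "),
              paste(x$tau_c, collapse = ", "),
              paste(x$tau_r, collapse = ", ")))
  invisible(x)
}

# Segment table of one dual cycle j (targets may depend on j via dn2).
# Each row: duration, per-mode tau and target. Mode states are deviations
# from the baseline, so the release phases relax them back to zero.
.cycle_segments <- function(spec, kin, dn2_j, baseline = 0) {
  zero <- numeric(kin$n_modes)
  list(
    list(dur = spec$t_on_1, tau = kin$tau_c, target = kin$weights_c * kin$dn1),
    list(dur = spec$t_off_1, tau = kin$tau_r, target = zero),
    list(dur = spec$t_on_2, tau = kin$tau_c, target = kin$weights_c * dn2_j),
    list(dur = spec$t_off_2, tau = kin$tau_r, target = zero)
  )
}

#' Simulate the dual-cycle nanoparticle-number profile
#'
#' Propagates each kinetic mode exactly (exponential relaxation toward the
#' phase target) through `n_cycles` dual cycles and samples the total
#' number `n(t) = baseline + sum of mode states` on a uniform grid. Mode
#' states are carried across phase boundaries so the profile is continuous.
#'
#' @param spec A [cycle_spec()] object.
#' @param kin A [kinetic_model()] object.
#' @param n_cycles Number of dual cycles to simulate (>= 1).
#' @param dt Sampling interval, s; must resolve the fastest mode
#'   (`dt <= min(tau)/10`).
#' @param init Per-mode initial states (default all zero, i.e. a uniform
#'   start); use [css_state()] to start at the cyclic steady state.
#' @param baseline Release-phase steady-state number (default 0).
#' @param dn2 Optional per-dual-cycle probe transitions (vector of length
#'   `n_cycles`, or scalar recycled); defaults to `kin$dn2`.
#' @return An object of class `dep_trace`: list with `time`, `value`, `dt`
#'   and the `spec` used.
#' @export
simulate_number <- function(spec, kin, n_cycles = 5, dt = 0.1, init = NULL,
                            baseline = 0, dn2 = NULL) {
  stopifnot(inherits(spec, "cycle_spec"), inherits(kin, "kinetic_model"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (dt > min(kin$tau_c, kin$tau_r) / 10)
    stop("resolution error: dt must be <= min(tau)/10")
  if (is.null(dn2)) dn2 <- kin$dn2
  dn2 <- rep_len(dn2, n_cycles)
  if (is.null(init)) init <- numeric(kin$n_modes)
  if (length(init) != kin$n_modes) stop("init must have one state per mode")

  n_t <- floor(n_cycles * spec$T / dt + 1e-9) + 1L
  t <- (seq_len(n_t) - 1) * dt
  vals <- rep(baseline, n_t)
  x <- init
  t0 <- 0
  for (j in seq_len(n_cycles)) {
    segs <- .cycle_segments(spec, kin, dn2[j], baseline)
    for (s in segs) {
      if (s$dur <= 0) next
      t1 <- t0 + s$dur
      last_seg <- abs(t1 - n_cycles * spec$T) < 1e-9 * spec$T
      idx <- which(t >= t0 - 1e-9 * dt & (t < t1 - 1e-9 * dt |
                                            (last_seg & t <= t1 + 1e-9 * dt)))
      if (length(idx)) {
        dtau <- outer(t[idx] - t0, s$tau, function(a, b) exp(-a / b))
        vals[idx] <- baseline +
          as.vector(dtau %*% (x - s$target)) + sum(s$target)
      }
      x <- s$target + (x - s$target) * exp(-s$dur / s$tau)
      t0 <- t1
    }
  }
  structure(list(time = t, value = vals, dt = dt, spec = spec),
            class = "dep_trace")
}

#' @export
print.dep_trace <- function(x, ...) {
  cat(sprintf("DEP trace: %d samples, dt = %g s, span %g s\n",
              length(x$time), x$dt, max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.dep_trace <- function(x, ...) {
  data.frame(time_s = x$time, value = x$value)
}

#' Cyclic-steady-state mode states
#'
#' Analytic fixed point of the per-mode affine recurrence across one dual
#' cycle: each mode's map is `x -> p x + q` with `p` the product of the
#' four segment decay factors; the fixed point is `q / (1 - p)`. Starting
#' [simulate_number()] from this state yields an exactly periodic trace.
#'
#' @inheritParams simulate_number
#' @param dn2 Probe transition used for the cycle (scalar; default `kin$dn2`).
#' @return Numeric vector of per-mode states at the start of the control
#'   collection phase.
#' @export
css_state <- function(spec, kin, baseline = 0, dn2 = NULL) {
  stopifnot(inherits(spec, "cycle_spec"), inherits(kin, "kinetic_model"))
  if (is.null(dn2)) dn2 <- kin$dn2[1]
  segs <- .cycle_segments(spec, kin, dn2, baseline)
  p <- rep(1, kin$n_modes)
  q <- numeric(kin$n_modes)
  for (s in segs) {
    e <- exp(-s$dur / s$tau)
    q <- e * q + (1 - e) * s$target
    p <- e * p
  }
  q / (1 - p)
}

#' Number fluctuation (amplitude) of one cycle
#'
#' Max minus min of the trace over the span of the designated cycle within
#' the `cycle_index`-th dual cycle (1-based).
#'
#' @param trace A `dep_trace` from [simulate_number()].
#' @param cycle_index Dual-cycle index, 1-based.
#' @param which 1 for the control cycle, 2 for the probe cycle.
#' @return Non-negative amplitude in trace units.
#' @export
cycle_amplitude <- function(trace, cycle_index, which = 1) {
  stopifnot(inherits(trace, "dep_trace"))
  spec <- trace$spec
  t0 <- (cycle_index - 1) * spec$T + if (which == 2) spec$T1 else 0
  t1 <- t0 + if (which == 2) spec$T2 else spec$T1
  if (t1 > max(trace$time) + 1e-9 * trace$dt)
    stop("range error: trace does not cover the requested cycle")
  idx <- trace$time >= t0 - 1e-9 * trace$dt & trace$time <= t1 + 1e-9 * trace$dt
  v <- trace$value[idx]
  max(v) - min(v)
}

#' Detect the onset of cyclic steady state
#'
#' Finds the first dual cycle `j` (1-based) whose start value matches the
#' start of cycle `j + 1` to within `tol` times that cycle's amplitude. A
#' trace that begins at the fixed point returns 1; if no cycle satisfies
#' the criterion, `NA` is returned with a warning.
#'
#' @param trace A `dep_trace` covering at least 2 full dual cycles.
#' @param spec The [cycle_spec()] used (defaults to the trace's own).
#' @param tol Relative tolerance on the boundary mismatch (default 0.05).
#' @return Integer dual-cycle index, or `NA_integer_`.
#' @export
detect_css <- function(trace, spec = trace$spec, tol = 0.05) {
  stopifnot(inherits(trace, "dep_trace"))
  J <- floor(max(trace$time) / spec$T + 1e-9)
  if (J < 2) stop("trace must cover at least 2 full dual cycles")
  boundary <- function(j) {
    trace$value[which.min(abs(trace$time - j * spec$T))]
  }
  for (j in seq_len(J - 1)) {
    amp <- max(cycle_amplitude(trace, j, 1), cycle_amplitude(trace, j, 2))
    if (amp == 0) return(j)
    if (abs(boundary(j - 1) - boundary(j)) <= tol * amp) return(j)
  }
  warning("cyclic steady state not reached within trace")
  NA_integer_
}

# cSS amplitude of the designated cycle at modulation frequency f_m, with
# the template's duty ratios preserved.
.css_amplitude <- function(f_m, kin, spec_template, which) {
  sc <- (1 / f_m) / spec_template$T
  spec <- cycle_spec(spec_template$t_on_1 * sc, spec_template$t_off_1 * sc,
                     spec_template$t_on_2 * sc, spec_template$t_off_2 * sc,
                     f1 = spec_template$f1, f2 = spec_template$f2)
  dt <- min(min(kin$tau_c, kin$tau_r) / 10, spec$T / 800)
  tr <- simulate_number(spec, kin, n_cycles = 1, dt = dt,
                        init = css_state(spec, kin))
  cycle_amplitude(tr, 1, which)
}

#' Amplitude-modulation bandwidth
#'
#' Largest modulation frequency at which the cyclic-steady-state amplitude
#' of the designated cycle still reaches `cutoff` times its ultra-low
#' modulation-frequency value (which equals the cycle's transition `dn`).
#' Found by bisection on `log10(f_m)`; the amplitude profile is asserted to
#' be non-increasing in `f_m` first.
#'
#' @param kin A [kinetic_model()] object.
#' @param spec_template A [cycle_spec()] whose duty ratios and cycle-period
#'   proportions are preserved while the period is rescaled.
#' @param cutoff Amplitude cut-off fraction in (0, 1), default 0.1.
#' @param which Cycle whose amplitude is tracked (1 or 2).
#' @return Bandwidth in Hz.
#' @export
am_bandwidth <- function(kin, spec_template, cutoff = 0.1, which = 1) {
  stopifnot(inherits(kin, "kinetic_model"), inherits(spec_template, "cycle_spec"))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  amp_ul <- if (which == 1) kin$dn1 else kin$dn2[1]
  if (amp_ul <= 0) stop("cycle transition must be > 0")
  f_lo <- 1 / (400 * max(kin$tau_c, kin$tau_r))
  f_hi <- 50 / min(kin$tau_c, kin$tau_r)
  grid <- 10^seq(log10(f_lo), log10(f_hi), length.out = 8)
  amps <- vapply(grid, .css_amplitude, numeric(1), kin = kin,
                 spec_template = spec_template, which = which)
  if (any(diff(amps) > 1e-3 * amp_ul))
    stop("diagnostic error: cSS amplitude is not monotone in f_m")
  target <- cutoff * amp_ul
  if (amps[1] < target) return(f_lo)
  if (amps[length(amps)] > target) stop("cutoff not reached below f_hi")
  lo <- log10(f_lo); hi <- log10(f_hi)
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (.css_amplitude(10^mid, kin, spec_template, which) >= target) lo <- mid
    else hi <- mid
    if (hi - lo < 1e-4) break
  }
  10^((lo + hi) / 2)
}

#' Fluorescence mapping of particle number
#'
#' Affine-plus-soft-limit map from particle number to fluorescence:
#' `F = k_fc + S * tanh(k_f * n / S)` with `S = saturation - k_fc`. Linear
#' (`F = k_fc + k_f n`) for small `n`, monotone, and bounded by
#' `saturation`.
#'
#' @param k_f Fluorescence per particle (> 0).
#' @param k_fc Intercept (background fluorescence).
#' @param saturation Soft-limit level, same units as the output
#'   (> `k_fc`).
#' @return An object of class `fluorescence_map`.
#' @export
fluorescence_map <- function(k_f = 1000, k_fc = 100, saturation = 1e4) {
  if (k_f <= 0) stop("k_f must be > 0")
  if (saturation <= k_fc) stop("saturation must exceed k_fc")
  structure(list(k_f = k_f, k_fc = k_fc, saturation = saturation),
            class = "fluorescence_map")
}

#' Apply a fluorescence map to a number trace
#'
#' @param trace A `dep_trace` (or bare numeric vector) of particle numbers.
#' @param map A [fluorescence_map()] object.
#' @return Object of the same type with fluorescence values.
#' @export
fluorescence_from_number <- function(trace, map) {
  stopifnot(inherits(map, "fluorescence_map"))
  S <- map$saturation - map$k_fc
  f <- function(n) map$k_fc + S * tanh(map$k_f * n / S)
  if (inherits(trace, "dep_trace")) {
    trace$value <- f(trace$value)
    trace
  } else {
    f(trace)
  }
}

#' Time-averaged DEP force scale on a nanosphere
#'
#' `F = pi * eps0 * eps_m * r^3 * Re[CM] * grad|E|^2`, the small-time
#' average for a peak-amplitude sinusoidal drive. Only relative magnitudes
#' matter downstream: the ratio of forces at two frequencies equals the
#' ratio of the Re\[CM\] values, which is the premise of the rate-ratio
#' method.
#'
#' @param radius Particle radius, m (> 0).
#' @param eps_m Relative medium permittivity.
#' @param re_cm Real part of the CM factor at the drive frequency.
#' @param grad_E2 Gradient of the squared field magnitude, V^2/m^3.
#' @return Force, N.
#' @export
dep_force_scale <- function(radius, eps_m, re_cm, grad_E2) {
  if (any(radius <= 0)) stop("radius must be > 0")
  pi * EPS0 * eps_m * radius^3 * re_cm * grad_E2
}
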