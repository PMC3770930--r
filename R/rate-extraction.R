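# Initial collection rates from traces and control/probe rate ratios.
# The rate ratio rho = (probe initial rate)/(control initial rate) cancels
# shared experimental factors (illumination, gain, local concentration),
# which is the core rationale of the dual-cycle method.

#' Collection-window index ranges of a trace
#'
#' Deterministic windowing from the known timing: for each dual cycle the
#' two collection windows start at the switch-on sample and span the
#' collection phase.
#'
#' @param trace A `dep_trace` (uniform sampling).
#' @param spec The [cycle_spec()] used (defaults to the trace's own).
#' @param n_cycles Number of dual cycles to window.
#' @return A `data.frame` with columns `cycle`, `which` (1 control /
#'   2 probe), `start`, `end` (sample indices, 1-based, inclusive).
#' @export
segment_collection_windows <- function(trace, spec = trace$spec, n_cycles) {
  stopifnot(inherits(trace, "dep_trace"))
  dt <- trace$dt
  need <- n_cycles * spec$T
  if (max(trace$time) + 1e-9 * dt < need - dt)
    stop("range error: trace shorter than the requested schedule")
  rows <- vector("list", 2L * n_cycles)
  for (j in seq_len(n_cycles)) {
    for (w in 1:2) {
      t0 <- (j - 1) * spec$T + if (w == 2) spec$T1 else 0
      len <- if (w == 2) spec$t_on_2 else spec$t_on_1
      start <- round(t0 / dt) + 1L
      end <- min(round((t0 + len) / dt), length(trace$time))
      rows[[2L * (j - 1L) + w]] <- data.frame(cycle = j, which = w,
                                              start = start, end = end)
    }
  }
  do.call(rbind, rows)
}

#' Initial collection rate by short-window linear fit
#'
#' Ordinary least-squares slope over the first `n_points` samples of a
#' collection window, in per-second units. Thirteen points is the default
#' working convention for 10 frames/s recordings; the short window makes
#' the linear fit a good approximation to the t = 0 derivative of the
#' exponential-series kinetics.
#'
#' @param values Window sample values (particle number or fluorescence).
#' @param dt Sampling interval, s.
#' @param n_points Number of leading samples fitted (default 13, >= 2).
#' @return An object of class `rate_estimate` with `slope`, `intercept`,
#'   `n_points` and `residual_sd`.
#' @export
initial_rate <- function(values, dt, n_points = 13) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (length(values) < n_points)
    stop("insufficient data: window shorter than n_points")
  y <- values[seq_len(n_points)]
  x <- (seq_len(n_points) - 1) * dt
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  rsd <- if (n_points > 2) sqrt(sum(res^2) / (n_points - 2)) else 0
  structure(list(slope = slope, intercept = intercept, n_points = n_points,
                 residual_sd = rsd),
            class = "rate_estimate")
}

#' Control/probe rate ratio
#'
#' `rho = probe$slope / control$slope`. Negative probe slopes (nDEP-like
#' response) pass through unmodified; a control slope at numerical-noise
#' level is an error because the ratio is then undefined.
#'
#' @param probe,control `rate_estimate` objects from [initial_rate()].
#' @return Dimensionless ratio.
#' @export
rate_ratio <- function(probe, control) {
  stopifnot(inherits(probe, "rate_estimate"), inherits(control, "rate_estimate"))
  scale <- max(abs(probe$slope), abs(control$slope), control$residual_sd)
  if (abs(control$slope) <= 1e3 * .Machine$double.eps * max(scale, 1))
    stop("undefined ratio: control slope at numerical-noise level")
  probe$slope / control$slope
}

#' Extract a rate-ratio dataset from dual-cycle traces
#'
#' For each trace and each retained dual cycle, fits the control and probe
#' initial rates and forms their ratio. With `css_only` the transient first
#' dual cycle is excluded, keeping only cycles at cyclic steady state (the
#' standard experimental convention: one transient cycle, the rest cSS).
#'
#' @param traces A list of `dep_trace` objects; each trace's probe carrier
#'   frequency is read from its `spec$f2` and the control from `spec$f1`.
#' @param css_only Drop the first (transient) dual cycle (default TRUE).
#' @param n_points Samples per linear fit, passed to [initial_rate()].
#' @return A `data.frame` of class `rate_ratio_table` with columns
#'   `frequency`, `replicate`, `rho`, `control_frequency`; one row per
#'   retained dual cycle per trace, replicates numbered in cycle order.
#' @export
extract_dataset <- function(traces, css_only = TRUE, n_points = 13) {
  if (inherits(traces, "dep_trace")) traces <- list(traces)
  out <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "dep_trace"))
    spec <- tr$spec
    J <- floor(max(tr$time) / spec$T + 1e-9)
    if (css_only && J < 2)
      stop("css_only requires at least 2 full dual cycles")
    win <- segment_collection_windows(tr, spec, J)
    first <- if (css_only) 2L else 1L
    keep <- first:J
    rho <- numeric(length(keep))
    for (k in seq_along(keep)) {
      j <- keep[k]
      wc <- win[win$cycle == j & win$which == 1, ]
      wp <- win[win$cycle == j & win$which == 2, ]
      rc <- initial_rate(tr$value[wc$start:wc$end], tr$dt, n_points)
      rp <- initial_rate(tr$value[wp$start:wp$end], tr$dt, n_points)
      rho[k] <- rate_ratio(rp, rc)
    }
    out[[i]] <- data.frame(frequency = spec$f2,
                           replicate = seq_along(keep),
                           rho = rho,
                           control_frequency = spec$f1)
  }
  res <- do.call(rbind, out)
  class(res) <- c("rate_ratio_table", "data.frame")
  res
}
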