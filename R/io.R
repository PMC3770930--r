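# File formats, run configuration, and the synthetic fixture generator.

#' Read a rate-ratio CSV
#'
#' Expects header `frequency_hz,replicate,rho[,control_frequency_hz]`;
#' leading `#` lines are treated as provenance comments and preserved in
#' the `provenance` attribute. Duplicate (frequency, replicate) pairs,
#' missing columns and non-numeric cells are schema errors naming the
#' offending row.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `rate_ratio_table` with columns
#'   `frequency`, `replicate`, `rho` and (if present) `control_frequency`.
#' @export
read_ratio_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  prov <- sub("^#\\s?", "", grep("^#", lines, value = TRUE))
  d <- utils::read.csv(text = lines, comment.char = "#",
                       colClasses = "character", check.names = FALSE)
  need <- c("frequency_hz", "replicate", "rho")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("schema error: missing columns ", paste(miss, collapse = ", "))
  if (nrow(d) == 0) {
    warning("header-only file: empty table")
    out <- data.frame(frequency = numeric(0), replicate = integer(0),
                      rho = numeric(0))
  } else {
    num <- function(col) {
      v <- suppressWarnings(as.numeric(d[[col]]))
      bad <- which(is.na(v) & !is.na(d[[col]]) & nzchar(d[[col]]))
      if (length(bad) || anyNA(v))
        stop(sprintf("schema error: non-numeric '%s' at row %d", col,
                     if (length(bad)) bad[1] else which(is.na(v))[1]))
      v
    }
    out <- data.frame(frequency = num("frequency_hz"),
                      replicate = as.integer(num("replicate")),
                      rho = num("rho"))
    if ("control_frequency_hz" %in% names(d))
      out$control_frequency <- num("control_frequency_hz")
    if (any(out$frequency <= 0))
      stop(sprintf("schema error: non-positive frequency at row %d",
                   which(out$frequency <= 0)[1]))
    dup <- duplicated(out[, c("frequency", "replicate")])
    if (any(dup))
      stop(sprintf("schema error: duplicate (frequency, replicate) at row %d",
                   which(dup)[1]))
  }
  attr(out, "provenance") <- prov
  class(out) <- c("rate_ratio_table", "data.frame")
  out
}

#' Write a rate-ratio CSV
#'
#' Numbers are serialized with 9 significant digits so that
#' `read_ratio_csv(write_ratio_csv(x))` round-trips; provenance is stored
#' as a leading `#` comment line.
#'
#' @param table A `rate_ratio_table` (or compatible `data.frame`).
#' @param path Output path.
#' @param provenance Optional character description written as a comment.
#' @return `path`, invisibly.
#' @export
write_ratio_csv <- function(table, path, provenance = NULL) {
  stopifnot(is.data.frame(table))
  cols <- c("frequency_hz", "replicate", "rho")
  body <- data.frame(frequency_hz = signif(table$frequency, 9),
                     replicate = table$replicate,
                     rho = signif(table$rho, 9))
  if (!is.null(table$control_frequency)) {
    body$control_frequency_hz <- signif(table$control_frequency, 9)
    cols <- c(cols, "control_frequency_hz")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(provenance)) provenance <- attr(table, "provenance")
  for (p in provenance) writeLines(paste("#", p), con)
  utils::write.csv(format(body, digits = 9, scientific = NA, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full run configuration
#'
#' Bundles every component needed to generate or simulate a dual-cycle
#' experiment. Defaults are the worked-example conditions: latex
#' nanospheres (26 mS/m) in a 2 mS/m medium, 15 s on / 10 s off in both
#' cycles with a 1 MHz control carrier, two-mode kinetics, and 15%
#' multiplicative conductivity noise on the probe cycle.
#'
#' @param dielectric A [dielectric_params()] object.
#' @param cycle A [cycle_spec()] object (its `f1` is the control carrier).
#' @param kinetics A [kinetic_model()] object; its `dn1`/`dn2` are
#'   overwritten by the spectrum weighting in [generate_fixture()].
#' @param fluorescence A [fluorescence_map()] object.
#' @param noise_sd Gaussian noise sd added to the fluorescence trace, in
#'   output units.
#' @param sigma_noise_frac Multiplicative conductivity noise applied to
#'   the probe cycle, per dual cycle.
#' @param seed Optional integer seed recorded with every generated output.
#' @return An object of class `run_config`.
#' @export
run_config <- function(dielectric = dielectric_params(26e-3, 2e-3, 2.55, 78),
                       cycle = cycle_spec(15, 10, 15, 10, f1 = 1e6, f2 = 2e6),
                       kinetics = kinetic_model(),
                       fluorescence = fluorescence_map(),
                       noise_sd = 5, sigma_noise_frac = 0.15, seed = NULL) {
  stopifnot(inherits(dielectric, "dielectric_params"),
            inherits(cycle, "cycle_spec"),
            inherits(kinetics, "kinetic_model"),
            inherits(fluorescence, "fluorescence_map"))
  if (noise_sd < 0 || sigma_noise_frac < 0) stop("noise levels must be >= 0")
  structure(list(dielectric = dielectric, cycle = cycle, kinetics = kinetics,
                 fluorescence = fluorescence, noise_sd = noise_sd,
                 sigma_noise_frac = sigma_noise_frac, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [run_config()] components: `dielectric` (sigma_p,
#' sigma_m, eps_p, eps_m), `cycle` (t_on_1, t_off_1, t_on_2, t_off_2, f1,
#' f2), `kinetics` (dn1, dn2, weights_c, tau_c, tau_r), `fluorescence`
#' (k_f, k_fc, saturation), plus scalars `noise_sd`, `sigma_noise_frac`,
#' `seed`. Missing sections fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(section, ctor) {
    if (is.null(y[[section]])) ctor() else do.call(ctor, y[[section]])
  }
  run_config(dielectric = pick("dielectric", dielectric_params),
             cycle = pick("cycle", cycle_spec),
             kinetics = pick("kinetics", kinetic_model),
             fluorescence = pick("fluorescence", fluorescence_map),
             noise_sd = if (is.null(y$noise_sd)) 5 else y$noise_sd,
             sigma_noise_frac = if (is.null(y$sigma_noise_frac)) 0.15
                                else y$sigma_noise_frac,
             seed = y$seed)
}

#' Generate a synthetic dual-cycle fixture set
#'
#' End-to-end stand-in for a dual-cycle recording session: for each probe
#' frequency, the control-cycle transition is weighted by
#' `Re[CM](f1; sigma_p)` and the probe-cycle transition by
#' `Re[CM](f2; sigma_i)` with a fresh noisy conductivity per dual cycle
#' (multiplicative noise, `sigma_noise_frac`); the number profile is
#' mapped to fluorescence and Gaussian trace noise added. Transitions are
#' normalized so the control transition is unity. Probe frequencies whose
#' spectrum value is non-positive are flagged with a warning (their ratio
#' will be <= 0).
#'
#' @param config A [run_config()] object.
#' @param probe_frequencies Probe carriers, Hz; default 7 log-spaced
#'   points over 1-4 MHz.
#' @param n_cycles Dual cycles per trace (default 5).
#' @param dt Sampling interval, s (default 0.1, i.e. 10 frames/s).
#' @return A list with `traces` (list of fluorescence `dep_trace`s, one
#'   per probe frequency) and `manifest` (true parameters: `sigma_p`,
#'   `sigma_m`, `eps_p`, `eps_m`, `m_equiv` — the fluorescence-scaled
#'   control normalization —, `probe_frequencies`, `seed`).
#' @export
generate_fixture <- function(config = run_config(),
                             probe_frequencies = 10^seq(log10(1e6), log10(4e6),
                                                        length.out = 7),
                             n_cycles = 5, dt = 0.1) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$dielectric
  f1 <- config$cycle$f1
  r1 <- re_cm(f1, p)
  if (r1 <= 0) stop("control frequency must sit in the pDEP band")
  traces <- vector("list", length(probe_frequencies))
  for (i in seq_along(probe_frequencies)) {
    f2 <- probe_frequencies[i]
    sig_i <- p$sigma_p * (1 + config$sigma_noise_frac * stats::rnorm(n_cycles))
    sig_i[sig_i < 0] <- 0
    r2 <- .re_cm(f2, sig_i, p$sigma_m, p$eps_p, p$eps_m)
    if (any(r2 <= 0))
      warning(sprintf("probe %.3g Hz has non-positive Re[CM]; ratio will be <= 0", f2))
    kin <- config$kinetics
    kin$dn1 <- 1
    spec_i <- config$cycle
    spec_i$f2 <- f2
    tr <- simulate_number(spec_i, kin, n_cycles = n_cycles, dt = dt,
                          dn2 = r2 / r1)
    tr <- fluorescence_from_number(tr, config$fluorescence)
    if (config$noise_sd > 0)
      tr$value <- tr$value + stats::rnorm(length(tr$value), sd = config$noise_sd)
    traces[[i]] <- tr
  }
  manifest <- list(sigma_p = p$sigma_p, sigma_m = p$sigma_m,
                   eps_p = p$eps_p, eps_m = p$eps_m,
                   control_frequency = f1,
                   m_equiv = 1 / r1,
                   probe_frequencies = probe_frequencies,
                   sigma_noise_frac = config$sigma_noise_frac,
                   noise_sd = config$noise_sd,
                   seed = config$seed)
  list(traces = traces, manifest = manifest)
}

#' Write a trace to CSV
#'
#' Two-column CSV `time_s,value`; seed and metadata may be recorded as a
#' leading comment.
#'
#' @param trace A `dep_trace`.
#' @param path Output path.
#' @param provenance Optional character comment lines.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, provenance = NULL) {
  stopifnot(inherits(trace, "dep_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance) writeLines(paste("#", p), con)
  utils::write.csv(data.frame(time_s = signif(trace$time, 9),
                              value = signif(trace$value, 9)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Inverse of [write_trace_csv()]; the cycle timing must be supplied since
#' a bare trace does not carry it.
#'
#' @param path Path to a `time_s,value` CSV.
#' @param spec The [cycle_spec()] describing the recording's timing.
#' @return A `dep_trace`.
#' @export
read_trace_csv <- function(path, spec) {
  stopifnot(inherits(spec, "cycle_spec"))
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "value") %in% names(d)))
    stop("schema error: expected columns time_s,value")
  dt <- if (nrow(d) > 1) d$time_s[2] - d$time_s[1] else NA_real_
  structure(list(time = d$time_s, value = d$value, dt = dt, spec = spec),
            class = "dep_trace")
}
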