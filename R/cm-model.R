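# Clausius-Mossotti spectrum: closed forms, crossover analysis, piecewise
# approximation and the surface-conductance relation for homogeneous spheres.

#' Vacuum permittivity (F/m)
#'
#' Module constant applied internally wherever permittivities enter; all
#' user-facing permittivities are relative (dimensionless).
#' @keywords internal
EPS0 <- 8.8541878128e-12

#' Dielectric parameters of a particle/medium pair
#'
#' Bundles the four scalars that determine the Clausius-Mossotti (CM)
#' spectrum of a homogeneous sphere: particle and medium conductivities
#' (S/m) and relative permittivities.
#'
#' @param sigma_p Particle conductivity, S/m (>= 0).
#' @param sigma_m Medium conductivity, S/m (>= 0).
#' @param eps_p Particle relative permittivity (> 0).
#' @param eps_m Medium relative permittivity (> 0).
#' @return An object of class `dielectric_params`.
#' @examples
#' latex <- dielectric_params(26e-3, 2e-3, 2.55, 78)
#' re_cm(1e6, latex)
#' @export
dielectric_params <- function(sigma_p, sigma_m, eps_p, eps_m) {
  stopifnot(length(sigma_p) == 1L, length(sigma_m) == 1L,
            length(eps_p) == 1L, length(eps_m) == 1L)
  if (!is.finite(sigma_p) || sigma_p < 0) stop("sigma_p must be finite and >= 0")
  if (!is.finite(sigma_m) || sigma_m < 0) stop("sigma_m must be finite and >= 0")
  if (!is.finite(eps_p) || eps_p <= 0) stop("eps_p must be finite and > 0")
  if (!is.finite(eps_m) || eps_m <= 0) stop("eps_m must be finite and > 0")
  structure(list(sigma_p = sigma_p, sigma_m = sigma_m,
                 eps_p = eps_p, eps_m = eps_m),
            class = "dielectric_params")
}

#' @export
print.dielectric_params <- function(x, ...) {
  cat("Dielectric parameters:\n")
  cat(sprintf("  sigma_p = %g S/m, sigma_m = %g S/m\n", x$sigma_p, x$sigma_m))
  cat(sprintf("  eps_p   = %g,     eps_m   = %g (relative)\n", x$eps_p, x$eps_m))
  fx <- crossover_frequency(x)
  if (is.na(fx)) cat("  no pDEP/nDEP crossover\n")
  else cat(sprintf("  crossover f_x = %.4g Hz\n", fx))
  invisible(x)
}

# Core Re[CM] evaluated from the complex permittivity quotient, vectorized
# over f and sigma_p (recycled). eps_* are relative; EPS0 applied here.
.re_cm <- function(f, sigma_p, sigma_m, eps_p, eps_m) {
  w <- 2 * pi * f
  ep <- complex(real = eps_p * EPS0, imaginary = -sigma_p / w)
  em <- complex(real = eps_m * EPS0, imaginary = -sigma_m / w)
  Re((ep - em) / (ep + 2 * em))
}

#' Real part of the Clausius-Mossotti factor
#'
#' Frequency-dependent effective polarizability contrast of a homogeneous
#' sphere in a lossy dielectric medium (single Maxwell-Wagner interfacial
#' relaxation). Bounded in \[-0.5, 1\]; its sign sets the direction of the
#' DEP force (positive: attraction to high-field regions).
#'
#' @param f Frequency in Hz (vectorized, all > 0).
#' @param params A [dielectric_params()] object.
#' @return Numeric vector of Re\[CM\] values in \[-0.5, 1\].
#' @export
re_cm <- function(f, params) {
  stopifnot(inherits(params, "dielectric_params"))
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequencies must be finite and > 0")
  .re_cm(f, params$sigma_p, params$sigma_m, params$eps_p, params$eps_m)
}

#' Low- and high-frequency limits of Re\[CM\]
#'
#' The low-frequency plateau is set by the conductivity contrast,
#' `(sigma_p - sigma_m)/(sigma_p + 2 sigma_m)`, the high-frequency plateau by
#' the permittivity contrast, `(eps_p - eps_m)/(eps_p + 2 eps_m)`. The
#' degenerate case `sigma_p = sigma_m = 0` is defined as 0 by continuity.
#'
#' @param params A [dielectric_params()] object.
#' @return A list with elements `low` and `high`, each in \[-0.5, 1\].
#' @export
cm_limits <- function(params) {
  stopifnot(inherits(params, "dielectric_params"))
  den <- params$sigma_p + 2 * params$sigma_m
  low <- if (den == 0) 0 else (params$sigma_p - params$sigma_m) / den
  high <- (params$eps_p - params$eps_m) / (params$eps_p + 2 * params$eps_m)
  list(low = low, high = high)
}

#' Crossover frequency of the DEP spectrum
#'
#' Frequency at which Re\[CM\] changes sign (the zero-force point between
#' positive and negative DEP). It exists only when the conductivity and
#' permittivity contrasts have opposite signs; absence is signalled by
#' `NA_real_`, not an error, since randomized parameter draws may
#' legitimately produce such sets.
#'
#' @param params A [dielectric_params()] object.
#' @return Crossover frequency in Hz, or `NA_real_` when none exists.
#' @export
crossover_frequency <- function(params) {
  stopifnot(inherits(params, "dielectric_params"))
  num <- (params$sigma_m - params$sigma_p) * (params$sigma_p + 2 * params$sigma_m)
  den <- (params$eps_p - params$eps_m) * (params$eps_p + 2 * params$eps_m) * EPS0^2
  if (den == 0) return(NA_real_)
  rad <- num / den
  if (rad <= 0) return(NA_real_)
  sqrt(rad) / (2 * pi)
}

#' Invert the crossover relation for particle conductivity
#'
#' Solves `(sigma_p - sigma_m)(sigma_p + 2 sigma_m) =
#' (2 pi f_x)^2 (eps_m - eps_p)(eps_p + 2 eps_m) eps0^2` for its positive
#' root, the unique physical solution:
#' `sigma_p = (-sigma_m + sqrt(9 sigma_m^2 + 4 K)) / 2`.
#'
#' @param f_x Observed crossover frequency, Hz (> 0).
#' @param sigma_m Medium conductivity, S/m (>= 0).
#' @param eps_p,eps_m Relative permittivities; a positive-to-negative DEP
#'   crossover requires `eps_p < eps_m`.
#' @return Particle conductivity, S/m.
#' @export
sigma_p_from_crossover <- function(f_x, sigma_m, eps_p, eps_m) {
  if (!is.finite(f_x) || f_x <= 0) stop("f_x must be finite and > 0")
  if (!is.finite(sigma_m) || sigma_m < 0) stop("sigma_m must be finite and >= 0")
  if (eps_p >= eps_m) {
    stop("inconsistent parameters: eps_p >= eps_m admits no pDEP-to-nDEP crossover")
  }
  K <- (2 * pi * f_x)^2 * (eps_m - eps_p) * (eps_p + 2 * eps_m) * EPS0^2
  (-sigma_m + sqrt(9 * sigma_m^2 + 4 * K)) / 2
}

#' Gradient of Re\[CM\] at the crossover
#'
#' Slope of Re\[CM\] with respect to `log10(f)` at the crossover frequency.
#' From the Maxwell-Wagner decomposition
#' `Re[CM](w) = B + (A - B)/(1 + w^2 tau^2)` with plateaus `A` (low) and `B`
#' (high), the slope at the zero is `ln(10) * 2AB/(A - B)`; it is always
#' non-positive at a pDEP-to-nDEP crossover.
#'
#' @param params A [dielectric_params()] object with a crossover.
#' @return Slope, dimensionless per decade of frequency.
#' @export
crossover_gradient <- function(params) {
  fx <- crossover_frequency(params)
  if (is.na(fx)) stop("undefined gradient: parameters have no crossover")
  lim <- cm_limits(params)
  log(10) * 2 * lim$low * lim$high / (lim$low - lim$high)
}

#' Three-line piecewise approximation of Re\[CM\]
#'
#' Approximates the spectrum on a log-frequency axis by two horizontal
#' plateau lines joined by the tangent ("diagonal") through the crossover
#' with slope [crossover_gradient()]. Breakpoints are the intersections of
#' the diagonal with the plateaus. Without a crossover a degenerate
#' two-plateau form (split at the Maxwell-Wagner relaxation frequency) is
#' returned.
#'
#' @param params A [dielectric_params()] object.
#' @return An object of class `piecewise_cm` with fields `low_limit`,
#'   `high_limit`, `crossover_freq`, `gradient`, `breakpoint_low`,
#'   `breakpoint_high`. Evaluate with `predict()`.
#' @export
piecewise_linear_cm <- function(params) {
  stopifnot(inherits(params, "dielectric_params"))
  lim <- cm_limits(params)
  fx <- crossover_frequency(params)
  if (is.na(fx)) {
    tau <- EPS0 * (params$eps_p + 2 * params$eps_m) /
      (params$sigma_p + 2 * params$sigma_m)
    fmw <- 1 / (2 * pi * tau)
    out <- list(low_limit = lim$low, high_limit = lim$high,
                crossover_freq = NA_real_, gradient = NA_real_,
                breakpoint_low = fmw, breakpoint_high = fmw)
  } else {
    g <- crossover_gradient(params)
    lx <- log10(fx)
    out <- list(low_limit = lim$low, high_limit = lim$high,
                crossover_freq = fx, gradient = g,
                breakpoint_low = 10^(lx + lim$low / g),
                breakpoint_high = 10^(lx + lim$high / g))
  }
  class(out) <- "piecewise_cm"
  out
}

#' @param object A `piecewise_cm` object.
#' @param f Frequencies (Hz) at which to evaluate the approximation.
#' @param ... Unused.
#' @rdname piecewise_linear_cm
#' @export
predict.piecewise_cm <- function(object, f, ...) {
  if (any(f <= 0)) stop("frequencies must be > 0")
  l <- log10(f)
  if (is.na(object$crossover_freq)) {
    ifelse(l < log10(object$breakpoint_low), object$low_limit, object$high_limit)
  } else {
    lx <- log10(object$crossover_freq)
    diag_val <- object$gradient * (l - lx)
    val <- pmin(object$low_limit, pmax(object$high_limit, diag_val))
    val
  }
}

#' @export
print.piecewise_cm <- function(x, ...) {
  cat("Piecewise-linear Re[CM] approximation:\n")
  cat(sprintf("  plateaus: %.4g (low) / %.4g (high)\n", x$low_limit, x$high_limit))
  if (is.na(x$crossover_freq)) {
    cat("  no crossover (degenerate two-plateau form)\n")
  } else {
    cat(sprintf("  crossover %.4g Hz, gradient %.4g per decade\n",
                x$crossover_freq, x$gradient))
    cat(sprintf("  breakpoints %.4g Hz / %.4g Hz\n",
                x$breakpoint_low, x$breakpoint_high))
  }
  invisible(x)
}

#' Particle conductivity from bulk and surface contributions
#'
#' For a sphere of radius `r`, `sigma_p = sigma_b + 2 K_s / r`, where `K_s`
#' is the surface conductance (S) that dominates for latex nanospheres.
#'
#' @param sigma_b Bulk conductivity, S/m (>= 0).
#' @param K_s Surface conductance, S (>= 0).
#' @param radius Particle radius, m (> 0).
#' @return Particle conductivity, S/m.
#' @examples
#' particle_conductivity(0, 1.3e-9, 100e-9)  # 26 mS/m
#' @export
particle_conductivity <- function(sigma_b, K_s, radius) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be finite and > 0")
  if (sigma_b < 0 || K_s < 0) stop("sigma_b and K_s must be >= 0")
  sigma_b + 2 * K_s / radius
}

#' Surface conductance from particle conductivity
#'
#' Algebraic inverse of [particle_conductivity()]:
#' `K_s = (sigma_p - sigma_b) * radius / 2`. A negative result (fitted
#' `sigma_p` below the assumed bulk term) is returned with a warning rather
#' than an error, flagging an unphysical combination.
#'
#' @param sigma_p Particle conductivity, S/m.
#' @param sigma_b Bulk conductivity, S/m (default 0).
#' @param radius Particle radius, m (> 0).
#' @return Surface conductance, S.
#' @export
surface_conductance <- function(sigma_p, sigma_b = 0, radius) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be finite and > 0")
  ks <- (sigma_p - sigma_b) * radius / 2
  if (ks < 0) warning("sigma_p < sigma_b: negative surface conductance is unphysical")
  ks
}
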