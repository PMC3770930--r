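# Shared fixtures: the latex-in-KCl worked-example parameter set and small
# helpers used across test files.

p_star <- dielectric_params(sigma_p = 26e-3, sigma_m = 2e-3,
                            eps_p = 2.55, eps_m = 78)

default_spec <- cycle_spec(15, 10, 15, 10, f1 = 1e6, f2 = 2e6)

# random dielectric parameter sets; about half have a crossover
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    dielectric_params(sigma_p = 10^runif(1, -4, 0),
                      sigma_m = 10^runif(1, -4, 0),
                      eps_p = runif(1, 2, 90),
                      eps_m = runif(1, 2, 90))
  })
}

# independent Re[CM] oracle: Maxwell-Wagner single-relaxation closed form,
# a different route than the package's complex quotient
re_cm_mw <- function(f, p) {
  A <- (p$sigma_p - p$sigma_m) / (p$sigma_p + 2 * p$sigma_m)
  B <- (p$eps_p - p$eps_m) / (p$eps_p + 2 * p$eps_m)
  tau <- 8.8541878128e-12 * (p$eps_p + 2 * p$eps_m) / (p$sigma_p + 2 * p$sigma_m)
  B + (A - B) / (1 + (2 * pi * f * tau)^2)
}
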