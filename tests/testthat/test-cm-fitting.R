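# Two-step bivariate CM fit: line initialization, Newton refinement,
# closed-form scale update, and agreement with a brute-force grid search.

make_samples <- function(sigma_p = 26e-3, m = 1.3, n_per = 1,
                         f = 10^seq(5, 8, length.out = 9)) {
  p <- dielectric_params(sigma_p, 2e-3, 2.55, 78)
  data.frame(frequency = rep(f, each = n_per),
             rho = rep(m * re_cm(f, p), each = n_per))
}

test_that("fit_line recovers an exact line and its zero", {
  f <- 10^seq(6, 6.6, length.out = 14)
  alpha <- 1.4 * log10(3.25e6)
  d <- data.frame(frequency = f, rho = alpha - 1.4 * log10(f))
  lf <- fit_line(d, c(1e6, 4e6))
  expect_equal(lf$alpha, alpha, tolerance = 1e-9)
  expect_equal(lf$beta, -1.4, tolerance = 1e-9)
  expect_equal(10^(-lf$alpha / lf$beta), 3.25e6, tolerance = 1e-9)
  expect_error(fit_line(d[1, , drop = FALSE], c(1e6, 4e6)), "insufficient")
})

test_that("initial_sigma inverts the line zero as a crossover", {
  lf <- structure(list(alpha = 1.4 * log10(3.25e6), beta = -1.4,
                       freq_window = c(1e6, 4e6), n_used = 10),
                  class = "line_fit")
  expect_equal(initial_sigma(lf, 2e-3, 2.55, 78), 19e-3, tolerance = 2e-3)
  # line zero at the true crossover returns the true conductivity
  fx <- crossover_frequency(p_star)
  lf2 <- structure(list(alpha = 1.4 * log10(fx), beta = -1.4,
                        freq_window = c(1e6, 1e7), n_used = 10),
                   class = "line_fit")
  expect_equal(initial_sigma(lf2, 2e-3, 2.55, 78), 26e-3, tolerance = 1e-9)
  # only the zero matters, not the steepness
  lf3 <- lf2; lf3$alpha <- 2.8 * log10(fx); lf3$beta <- -2.8
  expect_equal(initial_sigma(lf3, 2e-3, 2.55, 78),
               initial_sigma(lf2, 2e-3, 2.55, 78))
  lf_bad <- lf2; lf_bad$beta <- 0.5
  expect_error(initial_sigma(lf_bad, 2e-3, 2.55, 78), "decreasing")
})

test_that("initial_scale divides control ratios by the model plateau", {
  d <- data.frame(frequency = rep(1e3, 4), rho = rep(1, 4))
  m0 <- initial_scale(d, 26e-3, 1e3, 2e-3, 2.55, 78)
  expect_equal(m0, 1.25, tolerance = 1e-5)   # 1 / 0.8
  d2 <- d; d2$rho <- 2 * d2$rho
  expect_equal(initial_scale(d2, 26e-3, 1e3, 2e-3, 2.55, 78), 2 * m0)
  far <- data.frame(frequency = 1e9, rho = 1)
  expect_error(initial_scale(far, 26e-3, 1e3, 2e-3, 2.55, 78),
               "missing control")
})

test_that("SSE vanishes on exact data and is smooth in sigma", {
  d <- make_samples()
  expect_equal(cm_sse(26e-3, 1.3, d, 2e-3, 2.55, 78), 0)
  d2 <- d; d2$rho[5] <- d2$rho[5] + 0.1
  expect_equal(cm_sse(26e-3, 1.3, d2, 2e-3, 2.55, 78), 0.01)
  # second difference exists and is positive near the optimum
  h <- 1e-5
  s0 <- cm_sse(26e-3, 1.3, d2, 2e-3, 2.55, 78)
  sp <- cm_sse(26e-3 + h, 1.3, d2, 2e-3, 2.55, 78)
  sm <- cm_sse(26e-3 - h, 1.3, d2, 2e-3, 2.55, 78)
  expect_gt((sp - 2 * s0 + sm) / h^2, 0)
})

test_that("analytic SSE derivatives match central differences", {
  set.seed(3)
  d <- make_samples(m = 1.7, n_per = 2)
  d$rho <- d$rho + rnorm(nrow(d), sd = 0.05)
  for (sig in c(15e-3, 26e-3, 40e-3)) {
    st <- newton_step(sig, 1.7, d, 2e-3, 2.55, 78)
    h <- sig * 1e-6
    f <- function(s) cm_sse(s, 1.7, d, 2e-3, 2.55, 78)
    d1_num <- (f(sig + h) - f(sig - h)) / (2 * h)
    d2_num <- (f(sig + h) - 2 * f(sig) + f(sig - h)) / h^2
    expect_equal(st$d1, d1_num, tolerance = 1e-6)
    expect_equal(st$d2, d2_num, tolerance = 1e-3)  # second difference noise
  }
})

test_that("Newton iteration is stationary at the optimum and converges fast", {
  d <- make_samples()
  st <- newton_step(26e-3, 1.3, d, 2e-3, 2.55, 78)
  expect_equal(st$sigma, 26e-3, tolerance = 1e-10)
  # quadratic-style convergence from a distant start on noiseless data
  sig <- 15e-3
  errs <- numeric(5)
  for (k in 1:5) {
    sig <- newton_step(sig, 1.3, d, 2e-3, 2.55, 78)$sigma
    errs[k] <- abs(sig - 26e-3)
  }
  expect_lt(errs[5], 1e-10)
  expect_true(all(diff(log10(errs[errs > 0])) < 0))
})

test_that("update_scale is the exact least-squares scale", {
  d <- make_samples(m = 1.3)
  expect_equal(update_scale(26e-3, d, 2e-3, 2.55, 78), 1.3, tolerance = 1e-12)
  # stationarity of SSE in m at the result
  d$rho <- d$rho + 0.03
  m <- update_scale(26e-3, d, 2e-3, 2.55, 78)
  h <- 1e-7
  expect_lt(abs(cm_sse(26e-3, m + h, d, 2e-3, 2.55, 78) -
                cm_sse(26e-3, m - h, d, 2e-3, 2.55, 78)) / (2 * h), 1e-9)
  d2 <- d; d2$rho <- 3 * d2$rho
  expect_equal(update_scale(26e-3, d2, 2e-3, 2.55, 78), 3 * m)
})

test_that("fit recovers noiseless parameters exactly and is scale-equivariant", {
  d <- make_samples(sigma_p = 26e-3, m = 1.3)
  fit <- fit_cm(d, 2e-3, 2.55, 78, tol_sigma = 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$sigma_p, 26e-3, tolerance = 1e-6)
  expect_equal(fit$scale_m, 1.3, tolerance = 1e-6)
  expect_equal(fit$crossover_estimate, crossover_frequency(p_star),
               tolerance = 1e-6)
  # multiplying all rho by k scales m and leaves sigma unchanged
  d2 <- d; d2$rho <- 2.4 * d2$rho
  fit2 <- fit_cm(d2, 2e-3, 2.55, 78, tol_sigma = 1e-12)
  expect_equal(fit2$sigma_p, fit$sigma_p, tolerance = 1e-9)
  expect_equal(fit2$scale_m, 2.4 * fit$scale_m, tolerance = 1e-9)
  # initializer choice does not move the optimum on clean data
  fit3 <- fit_cm(d, 2e-3, 2.55, 78, tol_sigma = 1e-12,
                 init_method = "gradient")
  expect_equal(fit3$sigma_p, fit$sigma_p, tolerance = 1e-8)
})

test_that("noisy fits are unbiased within 10% median error", {
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    d <- make_samples(m = 1.7, n_per = 4,
                      f = 10^seq(log10(3e5), log10(3e7), length.out = 9))
    sig_i <- 26e-3 * (1 + 0.15 * rnorm(nrow(d)))
    d$rho <- 1.7 * depspec:::.re_cm(d$frequency, sig_i, 2e-3, 2.55, 78)
    fit <- fit_cm(d, 2e-3, 2.55, 78)
    abs(fit$sigma_p - 26e-3) / 26e-3
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("fitted optimum agrees with a dense 2D grid search", {
  set.seed(19)
  d <- make_samples(m = 1.7, n_per = 4,
                    f = 10^seq(log10(3e5), log10(3e7), length.out = 9))
  d$rho <- d$rho + rnorm(nrow(d), sd = 0.1)
  fit <- fit_cm(d, 2e-3, 2.55, 78, tol_sigma = 1e-10)
  sig_grid <- seq(0.5, 2, length.out = 1501) * 26e-3
  m_grid <- seq(1.2, 2.2, length.out = 801)
  sse_best <- Inf; best <- c(NA, NA)
  for (s in sig_grid) {
    R <- depspec:::.re_cm(d$frequency, s, 2e-3, 2.55, 78)
    sse_m <- vapply(m_grid, function(m) sum((d$rho - m * R)^2), numeric(1))
    i <- which.min(sse_m)
    if (sse_m[i] < sse_best) { sse_best <- sse_m[i]; best <- c(s, m_grid[i]) }
  }
  expect_equal(fit$sigma_p, best[1], tolerance = 2 * diff(sig_grid[1:2]) / best[1])
  expect_equal(fit$scale_m, best[2], tolerance = 2 * diff(m_grid[1:2]) / best[2])
  expect_lte(fit$sse, sse_best + 1e-10)
})

test_that("SSE decreases across accepted Newton iterations on noisy data", {
  set.seed(5)
  d <- make_samples(m = 1.7, n_per = 4)
  d$rho <- d$rho + rnorm(nrow(d), sd = 0.15)
  fit <- fit_cm(d, 2e-3, 2.55, 78)
  expect_true(fit$converged)
  expect_lte(fit$sse, cm_sse(fit$sigma_0, fit$m_0, d, 2e-3, 2.55, 78))
})
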