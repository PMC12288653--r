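test_that("effective_rank matches closed forms and validates its input", {
  expect_equal(effective_rank(rep(0.2, 5)), 5)
  expect_equal(effective_rank(c(1, 0, 0)), 1)
  expect_equal(effective_rank(c(0.5, 0.25, 0.25)), 2^1.5)
  expect_error(effective_rank(c(0.7, -0.1, 0.4)), "non-negative")
  expect_error(effective_rank(c(0.5, 0.4)), "sum to 1")
})

test_that("ensemble_effective_rank recovers degenerate and isotropic clouds", {
  line <- outer(seq(-1, 1, length.out = 50), c(1, 2, 3))
  expect_equal(as.numeric(ensemble_effective_rank(line)), 1, tolerance = 1e-9)
  iso <- withr::with_seed(5, matrix(stats::rnorm(1e4 * 10), 1e4, 10))
  expect_equal(as.numeric(ensemble_effective_rank(iso)), 10, tolerance = 0.02)
  expect_error(ensemble_effective_rank(matrix(1, 1, 3)), "at least 2")
})

test_that("an isotropic Jacobian preserves effective rank exactly (covariances)", {
  withr::with_seed(8, {
    B <- matrix(stats::rnorm(36), 6)
    sigma_e <- crossprod(B) / 6  # generic perturbation covariance
  })
  lam <- 1.7
  A <- diag(6) / lam            # response map of J = -lam I
  sigma_x <- A %*% sigma_e %*% t(A)
  expect_equal(covariance_effective_rank(sigma_x),
               covariance_effective_rank(sigma_e), tolerance = 1e-12)
  # under a gapped spectral model the response rank is strictly smaller
  mod <- spectral_model(6, gap = 100)
  Ainv <- -solve(mod$jacobian)
  sigma_x_gap <- Ainv %*% diag(6) %*% t(Ainv)
  expect_lt(covariance_effective_rank(sigma_x_gap),
            covariance_effective_rank(diag(6)))
})

test_that("uncontrolled_response follows the eigenvalue ratios", {
  expect_equal(uncontrolled_response(-2 * diag(4), c(1, 2, 0, -1)),
               c(1, 2, 0, -1) / 2)
  expect_equal(uncontrolled_response(spectral_model(3, 5), rep(0, 3)), rep(0, 3))
  mod <- spectral_model(5, gap = 20)
  r_slow <- uncontrolled_response(mod, c(1, 0, 0, 0, 0))
  r_fast <- uncontrolled_response(mod, c(0, 1, 0, 0, 0))
  expect_equal(sqrt(sum(r_slow^2)) / sqrt(sum(r_fast^2)), 20, tolerance = 1e-10)
})

test_that("controlled_response zeroes the sensed projection and handles edge geometries", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(3:8, 1)
      sys <- random_symmetric_system(n, seed = sample.int(1e6, 1))
      de <- stats::rnorm(n)
      s <- stats::rnorm(n); s <- s / sqrt(sum(s^2))
      a <- stats::rnorm(n); a <- a / sqrt(sum(a^2))
      dx <- controlled_response(sys, s, a, de)
      expect_lt(abs(sum(s * dx)), 1e-9 * max(1, sqrt(sum(dx^2))))
    }
  })
  mod <- spectral_model(6, gap = 10)
  de <- c(0.5, 1, -1, 0.2, 0, 0.3)
  de_t <- de / c(0.1, rep(1, 5))
  # a parallel to de means a~ parallel to de~: full cancellation
  a_par <- de / sqrt(sum(de^2))
  s <- de_t / sqrt(sum(de_t^2))
  expect_equal(controlled_response(mod, s, a_par, de), rep(0, 6),
               tolerance = 1e-10)
  # sensing orthogonal to the rescaled forcing leaves it untouched
  s_perp <- c(de_t[2], -de_t[1], 0, 0, 0, 0)
  s_perp <- s_perp / sqrt(sum(s_perp^2))
  a <- c(1, rep(0, 5))
  expect_equal(controlled_response(mod, s_perp, a, de), de_t, tolerance = 1e-9)
  # s = a = v0 cancels exactly the slow component
  v0 <- c(1, rep(0, 5))
  dx <- controlled_response(mod, v0, v0, de)
  expect_equal(dx, c(0, de[-1]), tolerance = 1e-12)
  # uncontrollable: action invisible to the sensor
  expect_error(
    controlled_response(mod, v0, c(0, 1, 0, 0, 0, 0), de),
    class = "softmodes_uncontrollable"
  )
})

test_that("expected_deviation has the documented limits", {
  # no slow-mode content: nothing to cancel, normalized value 1
  mod <- spectral_model(10, gap = 50)
  ens0 <- perturbation_ensemble(mean = 0, sd = c(0, rep(1, 9)))
  expect_equal(
    expected_deviation(mod, ens0, control_geometry(1, 1), normalized = TRUE),
    1, tolerance = 1e-12
  )
  # s = a = v0: closed form reduces to sqrt(sum_fast mu^2 + sd^2) / lambda
  mu <- c(0, 0.4, rep(0.1, 8))
  ens <- perturbation_ensemble(mean = mu, sd = 0.7)
  got <- expected_deviation(mod, ens, control_geometry(1, 1))
  expect_equal(got, sqrt(sum(mu[-1]^2) + 0.7^2 * 9), tolerance = 1e-12)
})

test_that("closed-form expectation agrees with Monte-Carlo", {
  mod <- spectral_model(20, gap = 10)
  ens <- perturbation_ensemble(mean = c(0, rep(0.25, 19)), sd = 1)
  g <- control_geometry(0.8, 0.6)
  cf <- expected_deviation(mod, ens, g)
  mc <- mc_expected_deviation(mod, ens, g, n_samples = 1e5, seed = 31)
  expect_lt(abs(cf - as.numeric(mc)), 3 * attr(mc, "se"))
  expect_lt(abs(cf - as.numeric(mc)) / cf, 0.01)
})

test_that("mc_expected_deviation is homogeneous and exact in degenerate cases", {
  mod <- spectral_model(8, gap = 5)
  # zero-mean: doubling all sd doubles the result
  ens1 <- perturbation_ensemble(mean = 0, sd = rep(0.5, 8))
  ens2 <- perturbation_ensemble(mean = 0, sd = rep(1.0, 8))
  g <- control_geometry(0.5, 0.5)
  # geometry degenerates to v0 when the mean is zero; supply explicit vectors
  s <- c(0.6, 0.8, rep(0, 6))
  a <- c(0.8, 0.6, rep(0, 6))
  m1 <- mc_expected_deviation(mod, ens1, list(s = s, a = a), 2e4, seed = 3)
  m2 <- mc_expected_deviation(mod, ens2, list(s = s, a = a), 2e4, seed = 3)
  expect_equal(as.numeric(m2) / as.numeric(m1), 2, tolerance = 1e-9)
  # mean-only ensemble with action parallel to the rescaled mean -> exact 0
  mu <- c(0.3, rep(0.2, 7))
  ens_mu <- perturbation_ensemble(mean = mu, sd = 0)
  a_par <- mu / sqrt(sum(mu^2))
  m0 <- mc_expected_deviation(mod, ens_mu, list(s = s, a = a_par), 100, seed = 1)
  expect_equal(as.numeric(m0), 0, tolerance = 1e-12)
})

test_that("optimal geometry aligns with the slow mode as the gap grows", {
  ens <- perturbation_ensemble(mean = c(0, rep(1 / sqrt(19), 19)), sd = 1)
  opt <- optimal_geometry(spectral_model(20, 100), ens)
  expect_gte(opt$alpha, 0.99)
  expect_gte(opt$beta, 0.99)
  # non-decreasing alignment over a gap grid
  alphas <- vapply(c(1, 3, 10, 30, 100), function(g) {
    optimal_geometry(spectral_model(20, g), ens)$alpha
  }, numeric(1))
  expect_true(all(diff(alphas) >= -1e-6))
})

test_that("optimal geometry at gap 1 matches a brute-force grid", {
  ens <- perturbation_ensemble(mean = c(0, rep(0.5, 9)), sd = 1)
  mod <- spectral_model(10, gap = 1)
  opt <- optimal_geometry(mod, ens)
  grid <- seq(0, 1, length.out = 101)
  vals <- outer(grid, grid, Vectorize(function(al, be) {
    tryCatch(expected_deviation(mod, ens, control_geometry(al, be)),
             error = function(e) Inf)
  }))
  expect_lte(opt$value, min(vals) + 1e-4)
  # at gap 1 the mean direction, not the (arbitrary) slow mode, is optimal
  expect_lt(opt$alpha, 0.05)
})

test_that("gap benefit is bounded, zero without slow content, and grows with N", {
  ens0 <- perturbation_ensemble(mean = 0, sd = c(0, rep(1, 7)))
  expect_equal(as.numeric(gap_benefit(8, ens0)), 0, tolerance = 1e-6)
  mk_ens <- function(n) perturbation_ensemble(mean = c(0, rep(1 / sqrt(n - 1), n - 1)), sd = 1)
  b2 <- as.numeric(gap_benefit(2, mk_ens(2)))
  b50 <- as.numeric(gap_benefit(50, mk_ens(50)))
  expect_gt(b50, b2)
  for (b in c(b2, b50)) {
    expect_gte(b, 0)
    expect_lte(b, 1)
  }
})

test_that("theory_sweep returns the tidy documented columns", {
  df <- theory_sweep(gaps = c(1, 10), n_dims_vec = c(5, 8))
  expect_named(df, c("gap", "n_dims", "alpha_opt", "beta_opt", "dev_norm"))
  expect_equal(nrow(df), 4)
  expect_true(all(df$dev_norm >= 0 & df$dev_norm <= 1 + 1e-9))
})
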