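test_that("apply_mutation perturbs multiplicatively and keeps invariants", {
  net <- random_network(8, seed = 30)
  spec0 <- mutation_spec(magnitude = 0, n_mutations = 1, seed = 1)
  mut0 <- apply_mutation(net, spec0, 1)
  expect_identical(mut0$k_mat, net$k_mat)
  expect_identical(mut0$K_mat, net$K_mat)
  spec <- mutation_spec(magnitude = 0.3, n_mutations = 5, seed = 1)
  for (i in 1:5) {
    mut <- apply_mutation(net, spec, i)
    expect_true(all(mut$K_mat > 0))
    expect_identical(mut$k_mat != 0, net$k_mat != 0)
    expect_identical(mut$n_wt, net$n_wt)  # ancestral reference retained
  }
  # deterministic per (seed, draw)
  expect_identical(apply_mutation(net, spec, 3), apply_mutation(net, spec, 3))
  # mutational deviation is zero at magnitude 0
  expect_equal(softmodes:::mutational_deviation(mut0), rep(0, 8),
               tolerance = 1e-9)
})

test_that("mean mutational deviation grows with mutation magnitude", {
  net <- random_network(8, seed = 31)
  mean_dev <- vapply(c(0.01, 0.05, 0.1), function(mag) {
    spec <- mutation_spec(magnitude = mag, n_mutations = 30, seed = 2)
    devs <- vapply(1:30, function(i) {
      d <- softmodes:::mutational_deviation(apply_mutation(net, spec, i))
      if (is.null(d)) NA_real_ else sqrt(sum(d^2))
    }, numeric(1))
    mean(devs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_dev) > 0))
})

test_that("alignment score hits its analytic limits", {
  # identical deviation sets are perfectly aligned
  X <- matrix(rnorm(50), 10, 5)
  expect_equal(softmodes:::mean_abs_cos(X, X) <= 1, TRUE)
  expect_equal(diag(abs((X / sqrt(rowSums(X^2))) %*% t(X / sqrt(rowSums(X^2))))),
               rep(1, 10), tolerance = 1e-12)
  # strong gap channels both perturbation kinds onto the slow mode
  expect_gt(alignment_score(spectral_model(20, gap = 100), n_draws = 100), 0.9)
  # no gap: random-vector baseline E|cos| ~ sqrt(2 / (pi N)) at N = 100
  base <- alignment_score(spectral_model(100, gap = 1), n_draws = 200)
  expect_equal(base, sqrt(2 / (pi * 100)), tolerance = 0.15)
})

test_that("deviation clouds align with the slow mode when the gap is large", {
  for (gap in c(30, 100)) {
    mod <- spectral_model(10, gap = gap)
    de <- withr::with_seed(40 + gap, matrix(stats::rnorm(200 * 10), 200, 10))
    dx <- t(-solve(mod$jacobian, t(de)))
    pc1 <- svd(scale(dx, scale = FALSE), nu = 0, nv = 1)$v[, 1]
    angle <- acos(min(abs(sum(pc1 * c(1, rep(0, 9)))), 1)) * 180 / pi
    expect_lt(angle, 10)
  }
})

test_that("a gapped network's slow-mode controller buffers mutations too", {
  net_gap <- make_gap_network(seed = 41, n_genes = 8)
  expect_gt(mode_gap(jacobian_at(net_gap)), 2)
  ctrl_gap <- slow_mode_controller(net_gap)
  net_flat <- random_network(8, seed = 42)
  ctrl_flat <- slow_mode_controller(net_flat)
  res <- dual_buffering_experiment(
    net_gap, ctrl_gap, net_flat, ctrl_flat,
    mutation_spec(magnitude = 0.05, n_mutations = 40, seed = 3),
    env_sd = 0.1, seed = 4
  )
  r <- setNames(res$ratio, paste(res$network, res$condition))
  expect_lt(r[["gap environmental"]], 1)
  expect_lt(r[["gap mutational"]], 1)
  # without a gap the one-channel controller barely buffers mutations
  expect_gt(r[["no_gap mutational"]], r[["gap mutational"]])
  expect_true(all(res$ratio >= 0))
  expect_equal(res$n_used + res$n_excluded, rep(40L, 4))
})

test_that("knocking out the slow-mode controller lowers response dimensionality", {
  net <- make_gap_network(seed = 43, n_genes = 8)
  ctrl <- slow_mode_controller(net)
  res <- knockout_dimensionality_experiment(net, ctrl, env_sd = 0.05,
                                            n_perturbations = 150, seed = 5)
  expect_gt(res$pc1_share_knockout, res$pc1_share_controlled)
  expect_lt(res$effective_rank_knockout, res$effective_rank_controlled)
  expect_equal(sum(res$variance_fractions_controlled), 1, tolerance = 1e-9)
  expect_equal(sum(res$variance_fractions_knockout), 1, tolerance = 1e-9)
  expect_gte(res$effective_rank_knockout, 1)
})

test_that("paired draws are shared between controlled and knockout arms", {
  # with a zero-gain controller both arms see identical deviations,
  # so every paired ratio is exactly 1
  net <- random_network(6, seed = 44)
  ctrl0 <- knockout(slow_mode_controller(net))
  res <- knockout_dimensionality_experiment(net, ctrl0, n_perturbations = 20,
                                            seed = 6)
  expect_equal(res$pc1_share_controlled, res$pc1_share_knockout,
               tolerance = 1e-12)
})

test_that("ODE and linearized experiment routes agree for small perturbations", {
  net <- make_gap_network(seed = 45, n_genes = 6, target_gap = 3)
  ctrl <- slow_mode_controller(net)
  de <- withr::with_seed(7, stats::rnorm(6, sd = 0.01))
  d_lin <- softmodes:::environmental_deviation(net, de, ctrl, "linearized")
  d_ode <- softmodes:::environmental_deviation(net, de, ctrl, "ode")
  expect_lt(sqrt(sum((d_lin - d_ode)^2)) / sqrt(sum(d_ode^2)), 0.1)
  spec <- mutation_spec(magnitude = 0.01, n_mutations = 1, seed = 8)
  mut <- apply_mutation(net, spec, 1)
  m_lin <- softmodes:::mutational_deviation(mut, ctrl, "linearized")
  m_ode <- softmodes:::mutational_deviation(mut, ctrl, "ode")
  expect_lt(sqrt(sum((m_lin - m_ode)^2)) / sqrt(sum(m_ode^2)), 0.1)
})
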