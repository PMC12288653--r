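test_that("rhs reproduces the hand-computed scalar balance", {
  net <- one_gene_network()
  # production 2*1/(1+1) exactly balances decay at n = 1
  expect_equal(network_rhs(net, 1), 0)
  # multiplicative forcing adds delta_e * n on top of the balance
  expect_equal(network_rhs(net, 1, env_forcing(0.1)), 0.1)
  expect_equal(network_rhs(net, 1, env_forcing(0.1, "additive")), 0.1)
  # zero state is absorbing: no production, no decay
  net8 <- random_network(8, seed = 5)
  expect_equal(network_rhs(net8, rep(0, 8)), rep(0, 8))
})

test_that("rhs and constructors reject inconsistent shapes", {
  net <- random_network(4, seed = 1)
  expect_error(network_rhs(net, rep(1, 3)), "state length")
  expect_error(network_rhs(net, rep(1, 4), env_forcing(rep(0.1, 5))),
               "forcing length")
  expect_error(gene_network(matrix(1, 2, 3), matrix(1, 2, 3)), "square")
  expect_error(gene_network(matrix(1, 2, 2), matrix(c(1, -1, 1, 1), 2)),
               "strictly positive")
  expect_error(gene_network(matrix(1, 2, 2), matrix(1, 2, 2), decay = c(1, 0)),
               "strictly positive")
})

test_that("find_fixed_point solves the closed-form scalar root and flags degeneracy", {
  net <- find_fixed_point(one_gene_network(), guess = 0.5)
  expect_equal(net$n_wt, 1, tolerance = 1e-9)
  # pure decay: only fixed point is the origin
  expect_error(
    find_fixed_point(gene_network(matrix(0, 2, 2), matrix(1, 2, 2))),
    class = "softmodes_degenerate_fp"
  )
  expect_error(find_fixed_point(one_gene_network(), guess = -1), "positive")
})

test_that("fixed-point residual < 1e-10 by substitution on seeded networks", {
  for (seed in 1:10) {
    net <- random_network(8, seed = seed)
    expect_lt(sqrt(sum(network_rhs(net, net$n_wt)^2)), 1e-10)
    expect_true(all(net$n_wt >= 0))
  }
})

test_that("analytic Jacobian matches hand cases and finite differences", {
  net <- find_fixed_point(one_gene_network())
  expect_equal(jacobian_at(net)$jacobian, matrix(-0.5), tolerance = 1e-12)
  # pure decay limit: J = -diag(gamma); bypass the fixed-point solver
  net0 <- gene_network(matrix(0, 3, 3), matrix(1, 3, 3), decay = c(1, 2, 3))
  expect_equal(jacobian_at(net0, state = rep(1, 3))$jacobian,
               -diag(c(1, 2, 3)))
  # central finite differences on seeded networks
  for (seed in 1:20) {
    net <- random_network(6, seed = 100 + seed)
    J <- jacobian_at(net)$jacobian
    h <- 1e-5
    Jfd <- vapply(1:6, function(b) {
      e <- replace(rep(0, 6), b, h)
      (network_rhs(net, net$n_wt + e) - network_rhs(net, net$n_wt - e)) / (2 * h)
    }, numeric(6))
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("linear_system sorts eigenvalues by ascending |Re| and checks residuals", {
  sys <- random_symmetric_system(7, seed = 3)
  re <- abs(Re(sys$eigvals))
  expect_true(all(diff(re) >= -1e-12))
  expect_true(sys$stable)
  for (i in 1:7) {
    resid <- sys$jacobian %*% sys$eigvecs[, i] - sys$eigvals[i] * sys$eigvecs[, i]
    expect_lt(max(Mod(resid)), 1e-8)
    expect_equal(sum(Mod(sys$eigvecs[, i])^2), 1, tolerance = 1e-10)
  }
})

test_that("mode_gap covers degenerate, gapped and tied spectra", {
  expect_equal(mode_gap(linear_system(-diag(c(1, 1, 1)))), 1)
  expect_equal(mode_gap(linear_system(-diag(c(0.05, 1, 2)))), 20)
  expect_equal(mode_gap(linear_system(-diag(c(0.1, 0.1, 3)))), 1)
  expect_error(mode_gap(linear_system(matrix(-1))), "1-dimensional")
  expect_error(mode_gap(linear_system(diag(c(1, -2)))), "stable")
})

test_that("mode_gap is invariant under uniform rescaling of rates", {
  for (seed in 1:5) {
    sys <- random_symmetric_system(6, seed = seed)
    for (c_scale in c(0.1, 3, 42)) {
      expect_equal(mode_gap(linear_system(c_scale * sys$jacobian)),
                   mode_gap(sys), tolerance = 1e-9)
    }
  }
})

test_that("random_network is stable, interior, and deterministic in the seed", {
  net1 <- random_network(10, seed = 7)
  net2 <- random_network(10, seed = 7)
  expect_identical(net1$k_mat, net2$k_mat)
  expect_identical(net1$n_wt, net2$n_wt)
  expect_true(jacobian_at(net1)$stable)
  expect_true(all(net1$n_wt > 1e-6))
  expect_true(all(net1$K_mat > 0))
  # every gene has at least one incoming interaction
  expect_true(all(rowSums(net1$k_mat != 0) >= 1))
})
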