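test_that("fitness cost vanishes with the perturbations (mean_rate normalizer)", {
  net <- random_network(6, seed = 5)
  costs <- vapply(c(0.1, 0.01, 0.001), function(sd) {
    fitness_cost(net, NULL, fitness_config(env_sd = sd,
                                           stiffness_norm = "mean_rate"),
                 seed = 1)
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_lt(costs[3], 1e-3)
})

test_that("fitness cost is invariant under uniform rescaling of all rates", {
  # rescaling time: J -> cJ. Realized directly on a linear fixture through
  # both normalizers by scaling decay and interaction strengths together.
  net <- random_network(6, seed = 15)
  net_fast <- gene_network(3 * net$k_mat, net$K_mat, decay = 3 * net$decay)
  net_fast <- find_fixed_point(net_fast, guess = net$n_wt)
  expect_equal(net_fast$n_wt, net$n_wt, tolerance = 1e-8)
  for (norm in c("uncontrolled", "mean_rate")) {
    cfg <- fitness_config(stiffness_norm = norm)
    c1 <- fitness_cost(net, NULL, cfg, seed = 7)
    c3 <- fitness_cost(net_fast, NULL, cfg, seed = 7)
    expect_equal(c3, c1, tolerance = 1e-6)
  }
})

test_that("unstable or uncontrollable systems get infinite cost", {
  net <- random_network(6, seed = 5)
  # an isotropically drawn multi-channel controller destabilizes this loop
  bad <- random_controller(6, 6, seed = 2)
  cl <- closed_loop_matrix(jacobian_at(net)$jacobian, bad)
  stopifnot(max(Re(eigen(cl, only.values = TRUE)$values)) > 0)
  expect_identical(fitness_cost(net, bad, seed = 1), Inf)
})

test_that("linearized and ODE fitness agree for small perturbations", {
  net <- random_network(6, seed = 3)
  ctrl <- slow_mode_controller(net)
  sd_small <- 0.01 * min(net$n_wt)
  draws <- withr::with_seed(9, matrix(stats::rnorm(10 * 6, sd = sd_small), 10, 6))
  c_lin <- fitness_cost(net, ctrl, fitness_config(eval_mode = "linearized"),
                        draws = draws)
  c_ode <- fitness_cost(net, ctrl, fitness_config(eval_mode = "ode"),
                        draws = draws)
  expect_lt(abs(c_lin - c_ode) / c_ode, 0.1)
})

test_that("propose respects invariants, bounds, and determinism", {
  net <- random_network(8, seed = 2)
  ctrl <- random_controller(8, 2, seed = 2)
  # zero proposal scale: unchanged
  same <- propose(net, ctrl, proposal_sd = 0)
  expect_identical(same$network, net)
  expect_identical(same$controller, ctrl)
  withr::with_seed(4, {
    for (i in 1:20) {
      pr <- propose(net, ctrl, proposal_sd = 0.3)
      expect_true(all(pr$network$K_mat > 0))
      expect_true(all(pr$network$k_mat >= 0))
      expect_true(all(pr$network$k_mat <= 5))
      expect_true(all(pr$network$K_mat <= 50))
      # sparsity pattern preserved
      expect_identical(pr$network$k_mat != 0, net$k_mat != 0)
      s <- pr$controller$sense_mat
      expect_equal(s %*% t(s), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(colSums(pr$controller$action_mat^2), c(1, 1),
                   tolerance = 1e-10)
    }
  })
  p1 <- withr::with_seed(11, propose(net, ctrl))
  p2 <- withr::with_seed(11, propose(net, ctrl))
  expect_identical(p1, p2)
})

test_that("anneal is bit-reproducible and keeps best-so-far elitism", {
  net <- random_network(6, seed = 6)
  ctrl <- random_controller(6, 1, seed = 6, action = "aligned")
  fit <- fitness_config(n_env_samples = 10)
  cfg <- anneal_config(n_steps = 120, seed = 99)
  tr1 <- anneal(net, ctrl, fit, cfg)
  tr2 <- anneal(net, ctrl, fit, cfg)
  expect_identical(tr1$trace, tr2$trace)
  expect_identical(tr1$best_network, tr2$best_network)
  # elitism: the best cost is the minimum over evaluated current costs
  expect_lte(tr1$best_cost, min(tr1$trace$cost))
  # and re-evaluating the stored best parameters reproduces a finite cost
  expect_true(is.finite(fitness_cost(tr1$best_network, tr1$best_controller,
                                     fit, seed = 1)))
})

test_that("acceptance of cost-increasing moves falls off with delta at fixed T", {
  net <- random_network(8, seed = 12)
  ctrl <- random_controller(8, 1, seed = 12, action = "aligned")
  fit <- fitness_config(n_env_samples = 10)
  T_fix <- 0.02
  tr <- anneal(net, ctrl, fit,
               anneal_config(n_steps = 800, T_init = T_fix, T_final = T_fix,
                             seed = 77))
  up <- subset(tr$trace, is.finite(delta_cost) & delta_cost > 0)
  expect_gt(nrow(up), 40)
  bins <- cut(up$delta_cost, breaks = stats::quantile(up$delta_cost, 0:4 / 4),
              include.lowest = TRUE)
  acc_rate <- tapply(up$accepted, bins, mean)
  # monotone decrease from the smallest-delta bin to the largest
  expect_gt(acc_rate[1], acc_rate[4])
})

test_that("selection lowers the homeostasis cost in a short k=1 run", {
  net <- random_network(8, seed = 20)
  ctrl <- random_controller(8, 1, seed = 20, action = "aligned")
  tr <- anneal(net, ctrl, fitness_config(n_env_samples = 15),
               anneal_config(n_steps = 400, seed = 21))
  expect_lt(tr$best_cost, tr$initial_cost)
})
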