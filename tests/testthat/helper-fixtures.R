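# Fixtures are built in code; nothing is read from disk.

# The scalar balance 2n/(n+1) = n has the interior root n* = 1.
one_gene_network <- function() {
  gene_network(matrix(2), matrix(1), decay = 1)
}

# A Michaelis-Menten network with a genuine eigenvalue mode gap, obtained
# without evolution: scaling all half-saturation constants pushes the
# network out of saturation toward the critical point where the Perron
# mode of the interaction Jacobian goes soft. Deterministic given the seed.
make_gap_network <- function(seed = 1L, n_genes = 8L, target_gap = 5,
                             max_scale = 64) {
  base <- random_network(n_genes, seed = seed)
  best <- base
  sc <- 1
  while (sc <= max_scale) {
    sc <- sc * 2
    cand <- tryCatch(
      find_fixed_point(gene_network(base$k_mat, base$K_mat * sc, base$decay)),
      error = function(e) NULL
    )
    if (is.null(cand)) break
    sys <- jacobian_at(cand)
    if (!sys$stable) break
    best <- cand
    if (mode_gap(sys) >= target_gap) break
  }
  best
}

# Unit vector along the (real) slowest eigendirection.
slow_vec <- function(network) {
  v <- Re(jacobian_at(network)$eigvecs[, 1])
  v / sqrt(sum(v^2))
}

# k = 1 controller sensing and acting on the slow mode.
slow_mode_controller <- function(network, c_p = 1, c_i = 1) {
  v0 <- slow_vec(network)
  pi_controller(matrix(v0, 1), matrix(v0), c_p = c_p, c_i = c_i)
}

# Random stable symmetric linear system with prescribed decay-rate range.
random_symmetric_system <- function(n, seed, rate_range = c(0.5, 2)) {
  withr::with_seed(seed, {
    V <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
    lam <- stats::runif(n, rate_range[1], rate_range[2])
    linear_system(-V %*% (lam * t(V)))
  })
}

# Exact linear ODE solution x(t) = exp(Mt) x0 + M^{-1}(exp(Mt) - I) f via
# eigendecomposition; the independent oracle for the RK45 integrator.
expm_solution <- function(M, x0, f, t) {
  eg <- eigen(M)
  co <- solve(eg$vectors, cbind(x0, f))
  ex <- exp(eg$values * t)
  y <- ex * co[, 1] + (ex - 1) / eg$values * co[, 2]
  Re(eg$vectors %*% y)
}
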