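# Nonlinear Michaelis-Menten gene network: construction, dynamics, fixed
# points, Jacobians and eigenmode structure.

#' Construct a Michaelis-Menten gene regulatory network
#'
#' The network follows saturating production kinetics with linear decay:
#' \deqn{\frac{dn_a}{dt} = \sum_b k_{ab} \frac{n_b}{n_b + K_{ab}} - \gamma_a n_a}
#' where `k_mat` holds the interaction strengths \eqn{k_{ab}} (rate units),
#' `K_mat` the half-saturation constants \eqn{K_{ab}} (concentration units,
#' strictly positive) and `decay` the per-gene degradation rates
#' \eqn{\gamma_a}. The linear decay term guarantees that generic parameter
#' draws admit stable interior fixed points; environmental forcing is
#' modelled as a multiplicative perturbation of this rate (see
#' [env_forcing()]).
#'
#' @param k_mat N x N numeric matrix of interaction strengths; entry
#'   `k_mat[a, b]` is the maximal rate at which gene `b` drives production of
#'   gene `a`. Zero entries mean no interaction.
#' @param K_mat N x N numeric matrix of half-saturation constants, all
#'   entries strictly positive. A scalar is recycled.
#' @param decay length-N vector (or scalar) of linear degradation rates,
#'   strictly positive. Defaults to 1 for every gene.
#' @param n_wt optional length-N wild-type fixed point. Usually left `NULL`
#'   and filled in by [find_fixed_point()].
#' @return An object of class `gene_network`.
#' @seealso [random_network()], [find_fixed_point()], [jacobian_at()]
#' @export
gene_network <- function(k_mat, K_mat, decay = 1, n_wt = NULL) {
  k_mat <- as.matrix(k_mat)
  n <- nrow(k_mat)
  if (ncol(k_mat) != n) {
    stop("`k_mat` must be square, got ", n, " x ", ncol(k_mat), call. = FALSE)
  }
  if (length(K_mat) == 1L) K_mat <- matrix(K_mat, n, n)
  K_mat <- as.matrix(K_mat)
  if (!all(dim(K_mat) == c(n, n))) {
    stop("`K_mat` must match the dimensions of `k_mat`", call. = FALSE)
  }
  if (any(!is.finite(K_mat)) || any(K_mat <= 0)) {
    stop("`K_mat` entries must be finite and strictly positive", call. = FALSE)
  }
  decay <- rep_len(as.numeric(decay), n)
  if (any(!is.finite(decay)) || any(decay <= 0)) {
    stop("`decay` entries must be finite and strictly positive", call. = FALSE)
  }
  if (!is.null(n_wt)) {
    n_wt <- as.numeric(n_wt)
    if (length(n_wt) != n) stop("`n_wt` must have length ", n, call. = FALSE)
    if (any(n_wt < 0)) stop("`n_wt` entries must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_genes = n, k_mat = k_mat, K_mat = K_mat, decay = decay,
      n_wt = n_wt, fp_tol = 1e-10
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network>", x$n_genes, "genes,",
      sum(x$k_mat != 0), "nonzero interactions\n")
  if (!is.null(x$n_wt)) {
    cat("  wild-type fixed point set; ||n_wt|| =",
        format(sqrt(sum(x$n_wt^2)), digits = 4), "\n")
  } else {
    cat("  wild-type fixed point not yet solved\n")
  }
  invisible(x)
}

#' Environmental forcing specification
#'
#' A static (quenched) environmental perturbation applied to every gene. In
#' `multiplicative` mode (the default, matching the model's
#' \eqn{\delta e_a(t) n_a} term) the forcing perturbs the per-gene rate,
#' contributing \eqn{\delta e_a n_a} to the derivative; in `additive` mode it
#' contributes \eqn{\delta e_a} directly.
#'
#' @param delta_e length-N numeric vector of forcing strengths (rate units).
#' @param mode `"multiplicative"` or `"additive"`.
#' @return An object of class `env_forcing`.
#' @export
env_forcing <- function(delta_e, mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  delta_e <- as.numeric(delta_e)
  if (any(!is.finite(delta_e))) stop("`delta_e` must be finite", call. = FALSE)
  structure(list(delta_e = delta_e, mode = mode), class = "env_forcing")
}

check_forcing <- function(network, forcing) {
  if (is.null(forcing)) return(NULL)
  if (!inherits(forcing, "env_forcing")) forcing <- env_forcing(forcing)
  if (length(forcing$delta_e) != network$n_genes) {
    stop("forcing length ", length(forcing$delta_e),
         " does not match network size ", network$n_genes, call. = FALSE)
  }
  forcing
}

#' Time derivative of the network state
#'
#' Evaluates the full right-hand side
#' \deqn{\dot n_a = \sum_b k_{ab}\frac{n_b}{n_b+K_{ab}} - \gamma_a n_a
#'   + \delta e_a n_a - \sum_i g^{(i)}_a I_i}
#' with the forcing term present only when `forcing` is supplied and the
#' controller action \eqn{I_i = c_p (s_i\cdot\delta n) + c_i y_i} present only
#' when `controller` is supplied (`integrals` carries the accumulated
#' \eqn{y_i = \int s_i\cdot\delta n\,dt}). Production terms are evaluated at
#' `max(state, 0)` so transiently negative numerical states cannot generate
#' spurious repression.
#'
#' @param network a [gene_network()].
#' @param state length-N state vector (expression levels).
#' @param forcing optional [env_forcing()] (or bare numeric vector, treated
#'   as multiplicative).
#' @param controller optional [pi_controller()].
#' @param integrals length-k vector of controller integral accumulators
#'   (defaults to zeros).
#' @param n_ref reference state for the controller error signal; defaults to
#'   the network's wild-type fixed point.
#' @return length-N vector of time derivatives.
#' @export
network_rhs <- function(network, state, forcing = NULL, controller = NULL,
                        integrals = NULL, n_ref = network$n_wt) {
  state <- as.numeric(state)
  if (length(state) != network$n_genes) {
    stop("state length ", length(state), " does not match network size ",
         network$n_genes, call. = FALSE)
  }
  forcing <- check_forcing(network, forcing)
  n_pos <- pmax(state, 0)
  # denom[a, b] = K_ab + n_b
  denom <- network$K_mat + matrix(n_pos, network$n_genes, network$n_genes, byrow = TRUE)
  prod_term <- rowSums(network$k_mat * matrix(n_pos, network$n_genes,
                                              network$n_genes, byrow = TRUE) / denom)
  dn <- prod_term - network$decay * state
  if (!is.null(forcing)) {
    dn <- dn + if (forcing$mode == "multiplicative") forcing$delta_e * state else forcing$delta_e
  }
  if (!is.null(controller)) {
    if (is.null(n_ref)) {
      stop("controller supplied but the network has no wild-type reference; ",
           "run find_fixed_point() first", call. = FALSE)
    }
    if (is.null(integrals)) integrals <- numeric(controller$k_channels)
    terms <- control_terms(controller, state - n_ref, integrals)
    dn <- dn - terms$action
  }
  dn
}

#' Solve for the interior fixed point of the uncontrolled network
#'
#' Finds \eqn{n^*} with zero derivative under zero forcing and no controller,
#' by damped fixed-point iteration (production/decay balance) polished with
#' Newton steps using the analytic Jacobian. The converged point is stored as
#' the network's wild-type reference `n_wt`.
#'
#' @param network a [gene_network()].
#' @param guess optional positive starting vector; defaults to the
#'   production/decay balance at saturation.
#' @param tol residual norm required for convergence (default `1e-10`).
#' @param max_iter iteration cap.
#' @return The network with `n_wt` set and an attribute `fp_residual` giving
#'   the achieved residual norm.
#' @section Errors: a network whose only fixed point is the origin (e.g.
#'   `k_mat = 0`) triggers an error of class `softmodes_degenerate_fp`;
#'   failure to converge raises an ordinary error.
#' @export
find_fixed_point <- function(network, guess = NULL, tol = network$fp_tol,
                             max_iter = 500L) {
  n <- network$n_genes
  if (is.null(guess)) {
    guess <- pmax(rowSums(network$k_mat) / network$decay, 0.1)
  }
  guess <- as.numeric(guess)
  if (length(guess) != n) stop("`guess` must have length ", n, call. = FALSE)
  if (any(guess <= 0)) stop("`guess` entries must be positive", call. = FALSE)

  if (all(network$k_mat == 0)) {
    stop_degenerate_fp("network has no production (k_mat = 0); the only fixed point is the origin")
  }

  x <- guess
  f <- network_rhs(network, x)
  # damped fixed-point iteration n <- production(n) / gamma to reach the
  # basin, then Newton with the analytic Jacobian
  for (i in seq_len(50L)) {
    if (sqrt(sum(f^2)) < 1e-3) break
    prod_term <- f + network$decay * x
    x_new <- 0.5 * x + 0.5 * prod_term / network$decay
    x <- pmax(x_new, 1e-12)
    f <- network_rhs(network, x)
  }
  for (i in seq_len(max_iter)) {
    res <- sqrt(sum(f^2))
    if (res < tol) break
    J <- mm_jacobian(network, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      stop("fixed-point solver hit a singular Jacobian", call. = FALSE)
    }
    lam <- 1
    repeat {
      x_try <- x + lam * step
      if (all(x_try > -1e-9)) {
        f_try <- network_rhs(network, pmax(x_try, 0))
        if (sqrt(sum(f_try^2)) < res || lam < 1e-6) {
          x <- pmax(x_try, 0)
          f <- f_try
          break
        }
      }
      lam <- lam / 2
      if (lam < 1e-10) {
        stop("fixed-point solver failed to converge (line search collapsed)",
             call. = FALSE)
      }
    }
  }
  res <- sqrt(sum(f^2))
  if (res >= tol) {
    stop("fixed-point solver failed to reach tolerance ", tol,
         " (residual ", format(res), ")", call. = FALSE)
  }
  if (sqrt(sum(x^2)) < 1e-6) {
    stop_degenerate_fp("fixed-point solver converged to the origin")
  }
  network$n_wt <- x
  attr(network, "fp_residual") <- res
  network
}

stop_degenerate_fp <- function(msg) {
  stop(structure(
    class = c("softmodes_degenerate_fp", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Analytic Jacobian of the uncontrolled, unforced dynamics at `state`:
# J[a, b] = k_ab K_ab / (n_b + K_ab)^2 - gamma_a delta_ab.
mm_jacobian <- function(network, state) {
  n_pos <- pmax(state, 0)
  denom <- network$K_mat + matrix(n_pos, network$n_genes, network$n_genes, byrow = TRUE)
  J <- network$k_mat * network$K_mat / denom^2
  diag(J) <- diag(J) - network$decay
  J
}

#' Linearize the network at a state
#'
#' Computes the analytic Jacobian
#' \eqn{J_{ab} = k_{ab} K_{ab}/(n_b+K_{ab})^2 - \gamma_a \delta_{ab}}
#' of the uncontrolled, unforced dynamics and packages it as a
#' [linear_system()] with its eigendecomposition.
#'
#' @param network a [gene_network()].
#' @param state state at which to linearize; defaults to the wild-type fixed
#'   point.
#' @return A [linear_system()].
#' @export
jacobian_at <- function(network, state = network$n_wt) {
  if (is.null(state)) {
    stop("no state supplied and the network has no wild-type fixed point",
         call. = FALSE)
  }
  state <- as.numeric(state)
  if (length(state) != network$n_genes) {
    stop("state length does not match network size", call. = FALSE)
  }
  if (any(state < 0)) stop("state entries must be non-negative", call. = FALSE)
  linear_system(mm_jacobian(network, state))
}

#' Linear system around a fixed point
#'
#' Wraps a Jacobian matrix together with its eigenvalues and eigenvectors.
#' Eigenvalues are sorted by ascending magnitude of their real part, so the
#' slowest (softest) mode comes first; complex conjugate pairs stay adjacent.
#' Eigenvectors are normalized to unit Euclidean norm. The system is flagged
#' stable when every eigenvalue has a strictly negative real part.
#'
#' @param jacobian square numeric matrix.
#' @return An object of class `linear_system` with fields `jacobian`,
#'   `eigvals`, `eigvecs`, `stable`, `n_dims`.
#' @export
linear_system <- function(jacobian) {
  jacobian <- as.matrix(jacobian)
  if (nrow(jacobian) != ncol(jacobian)) {
    stop("`jacobian` must be square", call. = FALSE)
  }
  eg <- eigen(jacobian)
  ord <- order(abs(Re(eg$values)), Im(eg$values))
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  nrm <- sqrt(colSums(Mod(vecs)^2))
  vecs <- sweep(vecs, 2, nrm, "/")
  structure(
    list(
      jacobian = jacobian, eigvals = vals, eigvecs = vecs,
      stable = all(Re(vals) < 0), n_dims = nrow(jacobian)
    ),
    class = "linear_system"
  )
}

#' @export
print.linear_system <- function(x, ...) {
  cat("<linear_system>", x$n_dims, "dims,",
      if (x$stable) "stable" else "UNSTABLE", "\n")
  cat("  slowest eigenvalues:",
      paste(format(utils::head(x$eigvals, 3), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Mode gap of a linear system
#'
#' The ratio \eqn{|\mathrm{Re}\,\lambda_1| / |\mathrm{Re}\,\lambda_0|} of the
#' second-slowest to the slowest relaxation rate. A large mode gap means the
#' slowest eigendirection is a pronounced soft mode: perturbations relax
#' quickly onto it and linger along it. Always at least 1; equal to 1 when
#' the two slowest modes are tied. Invariant under uniform rescaling of all
#' rates.
#'
#' @param system a [linear_system()] or [spectral_model()].
#' @return positive scalar `>= 1`.
#' @export
mode_gap <- function(system) {
  if (inherits(system, "spectral_model")) {
    return(system$lambda_fast / system$lambda_slow)
  }
  if (!inherits(system, "linear_system")) {
    stop("`system` must be a linear_system or spectral_model", call. = FALSE)
  }
  if (system$n_dims < 2) {
    stop("mode gap is undefined for a 1-dimensional system", call. = FALSE)
  }
  if (!system$stable) {
    stop("mode gap is defined only for stable systems", call. = FALSE)
  }
  re <- abs(Re(system$eigvals))
  re[2] / re[1]
}

#' Draw a random stable Michaelis-Menten network
#'
#' Interaction strengths \eqn{k_{ab}} are sampled uniformly on `k_range`
#' with an independent Bernoulli(`sparsity`) presence mask (every gene is
#' guaranteed at least one incoming interaction); half-saturation constants
#' are log-uniform on `K_range`. Candidate networks are rejected and redrawn
#' until one with a stable interior fixed point is found.
#'
#' @param n_genes number of genes N.
#' @param sparsity probability that any given interaction is present.
#' @param k_range range of nonzero interaction strengths.
#' @param K_range range (log-uniform) of half-saturation constants.
#' @param decay per-gene degradation rate (scalar or length-N).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param max_tries rejection-sampling cap.
#' @return A stable [gene_network()] with `n_wt` solved.
#' @export
random_network <- function(n_genes, sparsity = 0.5, k_range = c(0.5, 1.5),
                           K_range = c(0.1, 10), decay = 1, seed = 1L,
                           max_tries = 500L) {
  stopifnot(n_genes >= 1, sparsity > 0, sparsity <= 1)
  withr::with_seed(as_seed_int(seed), {
    for (try in seq_len(max_tries)) {
      mask <- matrix(stats::runif(n_genes^2) < sparsity, n_genes, n_genes)
      empty <- rowSums(mask) == 0
      if (any(empty)) {
        mask[cbind(which(empty), sample.int(n_genes, sum(empty), replace = TRUE))] <- TRUE
      }
      k_mat <- matrix(stats::runif(n_genes^2, k_range[1], k_range[2]),
                      n_genes, n_genes) * mask
      K_mat <- matrix(exp(stats::runif(n_genes^2, log(K_range[1]), log(K_range[2]))),
                      n_genes, n_genes)
      net <- gene_network(k_mat, K_mat, decay = decay)
      net <- tryCatch(find_fixed_point(net), error = function(e) NULL)
      if (is.null(net) || any(net$n_wt <= 1e-6)) next
      sys <- jacobian_at(net)
      if (sys$stable) return(net)
    }
  })
  stop("no stable interior fixed point found in ", max_tries, " draws",
       call. = FALSE)
}
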