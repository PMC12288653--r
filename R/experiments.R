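# The two in-silico prediction experiments: dual buffering of environmental
# and mutational perturbations, and dimensionality reduction of the
# perturbation response after controller knockout.

#' Mutational perturbation specification
#'
#' Mutations are modelled as small multiplicative changes `(1 + eps)`,
#' `eps ~ N(0, magnitude)`, to the nonzero interaction parameters of the
#' network. Homeostasis of a mutant is always judged against the ancestral
#' (pre-mutation) wild-type fixed point.
#'
#' @param magnitude standard deviation of the relative parameter change
#'   (>= 0).
#' @param n_mutations number of independent mutational draws (>= 1).
#' @param target which parameter set to perturb: `"both"`, `"k_mat"` or
#'   `"K_mat"`.
#' @param seed integer seed; draw `i` is deterministic given `(seed, i)`.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(magnitude = 0.05, n_mutations = 100L,
                          target = c("both", "k_mat", "K_mat"), seed = 1L) {
  target <- match.arg(target)
  stopifnot(magnitude >= 0, n_mutations >= 1)
  structure(
    list(magnitude = magnitude, n_mutations = as.integer(n_mutations),
         target = target, seed = as_seed_int(seed)),
    class = "mutation_spec"
  )
}

#' Apply one mutational draw to a network
#'
#' Multiplies the targeted nonzero parameters by `(1 + eps)` with seeded
#' `eps ~ N(0, magnitude)` (factors truncated below at 0.05 so
#' half-saturation constants stay positive). The ancestral wild-type fixed
#' point `n_wt` is retained as the homeostasis reference; the mutant's own
#' fixed point generally shifts away from it.
#'
#' @param network a [gene_network()] with `n_wt` set.
#' @param spec a [mutation_spec()].
#' @param draw_index which independent draw (1-based).
#' @return the mutated [gene_network()] (same `n_wt`).
#' @export
apply_mutation <- function(network, spec, draw_index = 1L) {
  withr::with_seed(derive_seed(spec$seed, paste0("mutation-", draw_index)), {
    if (spec$target %in% c("both", "k_mat")) {
      nz <- which(network$k_mat != 0)
      fac <- pmax(1 + stats::rnorm(length(nz), sd = spec$magnitude), 0.05)
      network$k_mat[nz] <- network$k_mat[nz] * fac
    }
    if (spec$target %in% c("both", "K_mat")) {
      idx <- seq_along(network$K_mat)
      fac <- pmax(1 + stats::rnorm(length(idx), sd = spec$magnitude), 0.05)
      network$K_mat[idx] <- network$K_mat[idx] * fac
    }
  })
  network
}

# Deviation from the ancestral wild type caused by a mutation, with an
# optional controller referenced to the ancestral state. Linearized route:
# the mutant dynamics at the ancestral point act as a static forcing
# f = rhs_mutant(n_wt), and the response uses the mutant Jacobian there.
# Returns NULL when the (closed-loop) system is unstable or uncontrollable.
mutational_deviation <- function(mutant, controller = NULL,
                                 eval_mode = "linearized") {
  if (eval_mode == "linearized") {
    J <- mm_jacobian(mutant, mutant$n_wt)
    if (any(Re(eigen(J, only.values = TRUE)$values) >= 0)) return(NULL)
    if (!is.null(controller) && !is_knocked_out(controller)) {
      cl <- closed_loop_matrix(J, controller)
      if (any(Re(eigen(cl, only.values = TRUE)$values) >= 0)) return(NULL)
    }
    f <- network_rhs(mutant, mutant$n_wt)
    dx <- closed_loop_deviation(J, matrix(f, ncol = 1), controller)
    if (is.null(dx)) return(NULL)
    drop(dx)
  } else {
    dev <- tryCatch(steady_state_deviation(mutant, controller = controller),
                    error = function(e) NULL)
    if (is.null(dev) || !isTRUE(attr(dev, "converged"))) return(NULL)
    dev
  }
}

# Deviation caused by a quenched multiplicative environmental forcing de.
environmental_deviation <- function(network, de, controller = NULL,
                                    eval_mode = "linearized") {
  if (eval_mode == "linearized") {
    J <- mm_jacobian(network, network$n_wt)
    if (!is.null(controller) && !is_knocked_out(controller)) {
      cl <- closed_loop_matrix(J, controller)
      if (any(Re(eigen(cl, only.values = TRUE)$values) >= 0)) return(NULL)
    }
    f <- de * network$n_wt
    dx <- closed_loop_deviation(J, matrix(f, ncol = 1), controller)
    if (is.null(dx)) return(NULL)
    drop(dx)
  } else {
    dev <- tryCatch(
      steady_state_deviation(network, env_forcing(de), controller),
      error = function(e) NULL
    )
    if (is.null(dev) || !isTRUE(attr(dev, "converged"))) return(NULL)
    dev
  }
}

# Paired controlled / knocked-out deviation norms for one condition.
paired_norms <- function(network, controller, draws = NULL, mut_spec = NULL,
                         eval_mode = "linearized") {
  ko <- knockout(controller)
  n_draws <- if (is.null(draws)) mut_spec$n_mutations else nrow(draws)
  on_norm <- off_norm <- rep(NA_real_, n_draws)
  for (i in seq_len(n_draws)) {
    if (is.null(draws)) {
      mut <- apply_mutation(network, mut_spec, i)
      d_on <- mutational_deviation(mut, controller, eval_mode)
      d_off <- mutational_deviation(mut, ko, eval_mode)
    } else {
      d_on <- environmental_deviation(network, draws[i, ], controller, eval_mode)
      d_off <- environmental_deviation(network, draws[i, ], ko, eval_mode)
    }
    if (!is.null(d_on) && !is.null(d_off)) {
      on_norm[i] <- sqrt(sum(d_on^2))
      off_norm[i] <- sqrt(sum(d_off^2))
    }
  }
  keep <- !is.na(on_norm)
  list(controlled = on_norm[keep], knockout = off_norm[keep],
       n_excluded = sum(!keep))
}

#' Dual-buffering experiment
#'
#' Tests the prediction that a low-complexity controller selected to buffer
#' environmental perturbations also buffers mutational perturbations --
#' but only on a network with a pronounced mode gap, whose soft mode
#' channels both kinds of perturbation. For each of the four cells
#' {gap, no-gap} x {environmental, mutational}, paired deviation norms are
#' computed with the network's controller active and knocked out (the same
#' perturbation draws in both arms), and the buffering ratio
#' `mean(controlled) / mean(knockout)` is reported. A ratio well below 1
#' means the controller buffers that kind of perturbation.
#'
#' @param net_gap,ctrl_gap evolved network with a mode gap and its
#'   co-selected controller.
#' @param net_nogap,ctrl_nogap a no-gap network and a controller selected
#'   for environmental robustness on it.
#' @param mut_spec a [mutation_spec()].
#' @param env_sd standard deviation of environmental forcing entries.
#' @param n_env environmental draws (defaults to `mut_spec$n_mutations`).
#' @param eval_mode `"linearized"` or `"ode"`.
#' @param seed seed for the environmental draws.
#' @return An object of class `buffering_result`: a data.frame with columns
#'   `network`, `condition`, `ratio`, `mean_controlled`, `mean_knockout`,
#'   `n_used`, `n_excluded`.
#' @export
dual_buffering_experiment <- function(net_gap, ctrl_gap, net_nogap,
                                      ctrl_nogap, mut_spec = mutation_spec(),
                                      env_sd = 0.1, n_env = NULL,
                                      eval_mode = c("linearized", "ode"),
                                      seed = 1L) {
  eval_mode <- match.arg(eval_mode)
  if (is.null(n_env)) n_env <- mut_spec$n_mutations
  rows <- list()
  for (lab in c("gap", "no_gap")) {
    net <- if (lab == "gap") net_gap else net_nogap
    ctrl <- if (lab == "gap") ctrl_gap else ctrl_nogap
    draws <- withr::with_seed(
      derive_seed(seed, paste0("dual-env-", lab)),
      matrix(stats::rnorm(n_env * net$n_genes, sd = env_sd),
             n_env, net$n_genes)
    )
    for (cond in c("environmental", "mutational")) {
      pn <- if (cond == "environmental") {
        paired_norms(net, ctrl, draws = draws, eval_mode = eval_mode)
      } else {
        paired_norms(net, ctrl, mut_spec = mut_spec, eval_mode = eval_mode)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        network = lab, condition = cond,
        ratio = mean(pn$controlled) / mean(pn$knockout),
        mean_controlled = mean(pn$controlled),
        mean_knockout = mean(pn$knockout),
        n_used = length(pn$controlled), n_excluded = pn$n_excluded
      )
    }
  }
  structure(do.call(rbind, rows), class = c("buffering_result", "data.frame"))
}

#' Controller-knockout dimensionality experiment
#'
#' Draws many high-dimensional environmental perturbations, computes the
#' steady-state responses with the controller active and knocked out (same
#' draws, paired), and compares the PCA structure of the two response
#' clouds. On a network whose controller senses and restores along the
#' slow mode, the knockout exposes the soft mode: perturbations pile up
#' along one direction, so the first principal component captures a larger
#' share and the effective rank drops -- the counterintuitive prediction
#' that removing a controller reduces response dimensionality.
#'
#' @param network a [gene_network()] with `n_wt` set.
#' @param controller the co-evolved [pi_controller()].
#' @param env_sd standard deviation of forcing entries.
#' @param n_perturbations number of environmental draws.
#' @param eval_mode `"linearized"` or `"ode"`.
#' @param seed seed for the draws.
#' @return An object of class `dimensionality_result`: list with
#'   `variance_fractions_controlled`, `variance_fractions_knockout`,
#'   `effective_rank_controlled`, `effective_rank_knockout`,
#'   `pc1_share_controlled`, `pc1_share_knockout`, `n_used`, `n_excluded`.
#' @export
knockout_dimensionality_experiment <- function(network, controller,
                                               env_sd = 0.1,
                                               n_perturbations = 200L,
                                               eval_mode = c("linearized", "ode"),
                                               seed = 1L) {
  eval_mode <- match.arg(eval_mode)
  ko <- knockout(controller)
  draws <- withr::with_seed(
    derive_seed(seed, "knockout-dim-env"),
    matrix(stats::rnorm(n_perturbations * network$n_genes, sd = env_sd),
           n_perturbations, network$n_genes)
  )
  on_states <- off_states <- matrix(NA_real_, n_perturbations, network$n_genes)
  for (i in seq_len(n_perturbations)) {
    d_on <- environmental_deviation(network, draws[i, ], controller, eval_mode)
    d_off <- environmental_deviation(network, draws[i, ], ko, eval_mode)
    if (!is.null(d_on) && !is.null(d_off)) {
      on_states[i, ] <- d_on
      off_states[i, ] <- d_off
    }
  }
  keep <- !is.na(on_states[, 1])
  on_states <- on_states[keep, , drop = FALSE]
  off_states <- off_states[keep, , drop = FALSE]
  r_on <- ensemble_effective_rank(on_states)
  r_off <- ensemble_effective_rank(off_states)
  p_on <- attr(r_on, "variance_fractions")
  p_off <- attr(r_off, "variance_fractions")
  structure(
    list(
      variance_fractions_controlled = p_on,
      variance_fractions_knockout = p_off,
      effective_rank_controlled = as.numeric(r_on),
      effective_rank_knockout = as.numeric(r_off),
      pc1_share_controlled = p_on[1],
      pc1_share_knockout = p_off[1],
      n_used = sum(keep), n_excluded = sum(!keep)
    ),
    class = "dimensionality_result"
  )
}

#' @export
print.dimensionality_result <- function(x, ...) {
  cat("<dimensionality_result> n =", x$n_used, "perturbations\n")
  cat("  PC1 share:      controlled", format(x$pc1_share_controlled, digits = 3),
      "| knockout", format(x$pc1_share_knockout, digits = 3), "\n")
  cat("  effective rank: controlled",
      format(x$effective_rank_controlled, digits = 3),
      "| knockout", format(x$effective_rank_knockout, digits = 3), "\n")
  invisible(x)
}

# Mean absolute cosine similarity between all pairs of rows of two matrices.
mean_abs_cos <- function(X, Y) {
  Xn <- X / pmax(sqrt(rowSums(X^2)), 1e-300)
  Yn <- Y / pmax(sqrt(rowSums(Y^2)), 1e-300)
  mean(abs(Xn %*% t(Yn)))
}

#' Alignment of mutational and environmental perturbation responses
#'
#' Mean absolute cosine similarity between the uncontrolled deviation
#' vectors caused by mutational draws and those caused by environmental
#' draws. A soft mode channels both kinds of perturbation along itself, so
#' the score approaches 1 as the mode gap grows; without a gap it falls to
#' the random-vector baseline `E|cos| ~ sqrt(2 / (pi N))`.
#'
#' @param x a [gene_network()] (with `n_wt`), [spectral_model()], or
#'   [linear_system()].
#' @param ... passed to methods.
#' @return scalar in `[0, 1]`.
#' @export
alignment_score <- function(x, ...) UseMethod("alignment_score")

#' @rdname alignment_score
#' @param mut_spec a [mutation_spec()] (network method).
#' @param env_sd environmental forcing scale (network method).
#' @param n_env number of environmental draws.
#' @param seed seed for the environmental draws.
#' @export
alignment_score.gene_network <- function(x, mut_spec = mutation_spec(),
                                         env_sd = 0.1, n_env = 100L,
                                         seed = 1L, ...) {
  mut_devs <- lapply(seq_len(mut_spec$n_mutations), function(i) {
    mutational_deviation(apply_mutation(x, mut_spec, i))
  })
  mut_devs <- do.call(rbind, Filter(Negate(is.null), mut_devs))
  draws <- withr::with_seed(
    derive_seed(seed, "alignment-env"),
    matrix(stats::rnorm(n_env * x$n_genes, sd = env_sd), n_env, x$n_genes)
  )
  J <- mm_jacobian(x, x$n_wt)
  env_devs <- t(-solve(J, t(draws) * x$n_wt))
  mean_abs_cos(mut_devs, env_devs)
}

#' @rdname alignment_score
#' @param n_draws number of draws per perturbation kind (spectral /
#'   linear-system methods); forcings are isotropic standard normal.
#' @export
alignment_score.spectral_model <- function(x, n_draws = 100L, seed = 1L, ...) {
  alignment_linear(x, n_draws, seed)
}

#' @rdname alignment_score
#' @export
alignment_score.linear_system <- function(x, n_draws = 100L, seed = 1L, ...) {
  alignment_linear(x, n_draws, seed)
}

alignment_linear <- function(system, n_draws, seed) {
  n <- if (inherits(system, "spectral_model")) system$n_dims else system$n_dims
  dg <- withr::with_seed(derive_seed(seed, "alignment-mut"),
                         matrix(stats::rnorm(n_draws * n), n_draws, n))
  de <- withr::with_seed(derive_seed(seed, "alignment-env"),
                         matrix(stats::rnorm(n_draws * n), n_draws, n))
  X <- t(neg_jinv(system, t(dg)))
  Y <- t(neg_jinv(system, t(de)))
  mean_abs_cos(X, Y)
}
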