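# In-silico evolution: simulated-annealing MCMC on network (and controller)
# parameters under selection for homeostasis.

#' Fitness evaluation configuration
#'
#' The fitness cost of a (network, controller) pair is its failure to
#' maintain homeostasis: the residual deviation from the wild-type fixed
#' point, averaged over `n_env_samples` quenched environmental draws
#' (`de` entries `N(0, env_sd)`, applied multiplicatively), normalized by
#' the overall stiffness of the system so that evolution cannot win by
#' simply rescaling all rates. Two stiffness normalizers are provided:
#'
#' * `"uncontrolled"` (default): the mean controlled deviation norm divided
#'   by the mean *uncontrolled* deviation norm on the same draws. The
#'   uncontrolled response `-J^{-1} de` is the system's compliance, so this
#'   is a direct stiffness normalization; it is also the analytic theory's
#'   normalized expected deviation, the quantity whose decrease with mode
#'   gap defines the fitness benefit of a soft mode.
#' * `"mean_rate"`: the mean deviation relative to `||n_wt||`, multiplied
#'   by the mean relaxation rate `mean_i |Re lambda_i|` of the open-loop
#'   Jacobian.
#' * `"none"`: the mean deviation relative to `||n_wt||`, unnormalized.
#'
#' Both normalizers are invariant under a uniform rescaling of all rates;
#' only `"uncontrolled"` rewards channeling perturbations into a soft mode
#' that the controller cancels, which is why it is the default for the
#' evolution experiments (see the methods vignette).
#'
#' @param n_env_samples environmental draws per evaluation (>= 1).
#' @param env_sd standard deviation of each forcing entry (> 0).
#' @param eval_mode `"linearized"` (closed-form steady state of the
#'   linearized closed loop; fast, the default) or `"ode"` (full nonlinear
#'   integration).
#' @param stiffness_norm `"uncontrolled"`, `"mean_rate"` or `"none"`
#'   (logical `TRUE`/`FALSE` map to the first/last).
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(n_env_samples = 20L, env_sd = 0.1,
                           eval_mode = c("linearized", "ode"),
                           stiffness_norm = "uncontrolled") {
  eval_mode <- match.arg(eval_mode)
  if (isTRUE(stiffness_norm)) stiffness_norm <- "uncontrolled"
  if (isFALSE(stiffness_norm)) stiffness_norm <- "none"
  stiffness_norm <- match.arg(stiffness_norm,
                              c("uncontrolled", "mean_rate", "none"))
  stopifnot(is.numeric(n_env_samples), is.numeric(env_sd),
            n_env_samples >= 1, env_sd > 0)
  structure(
    list(n_env_samples = as.integer(n_env_samples), env_sd = env_sd,
         eval_mode = eval_mode, stiffness_norm = stiffness_norm),
    class = "fitness_config"
  )
}

#' Annealing schedule configuration
#'
#' Geometric cooling from `T_init` to `T_final` over `n_steps` Metropolis
#' steps. Proposals apply multiplicative log-normal jitter to a random
#' subset of the nonzero interaction parameters (and, when
#' `mutate_controller` is on, additive jitter to the controller's sensing
#' and action vectors followed by re-normalization).
#'
#' @param n_steps number of annealing steps (>= 1).
#' @param T_init,T_final initial and final temperatures,
#'   `T_init >= T_final > 0`.
#' @param cooling cooling schedule; only `"geometric"` is implemented.
#' @param proposal_sd relative scale of parameter perturbations.
#' @param mutate_prob probability that any given eligible parameter is
#'   jittered in a proposal.
#' @param mutate_network propose changes to `k_mat` / `K_mat`?
#' @param mutate_controller propose changes to the controller's sensing and
#'   action vectors?
#' @param k_bounds,K_bounds allowed ranges for the interaction strengths and
#'   half-saturation constants; proposals are clipped to them. Biochemical
#'   rates are bounded, and without these bounds a multiplicative random
#'   walk drifts to astronomically large interaction strengths whose
#'   Jacobians amplify perturbations through non-normal (shear) structure
#'   rather than a slow eigenmode (see the methods vignette).
#' @param seed integer seed; the whole run is bit-reproducible given it.
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(n_steps = 2000L, T_init = 0.05, T_final = 1e-4,
                          cooling = "geometric", proposal_sd = 0.1,
                          mutate_prob = 0.2, mutate_network = TRUE,
                          mutate_controller = TRUE, k_bounds = c(0.02, 5),
                          K_bounds = c(0.05, 50), global_prob = 0.2,
                          seed = 1L) {
  cooling <- match.arg(cooling, "geometric")
  stopifnot(is.numeric(n_steps), is.numeric(T_init), is.numeric(T_final),
            is.numeric(proposal_sd), is.numeric(mutate_prob),
            n_steps >= 1, T_init >= T_final, T_final > 0, proposal_sd >= 0,
            length(k_bounds) == 2, length(K_bounds) == 2, K_bounds[1] > 0)
  structure(
    list(n_steps = as.integer(n_steps), T_init = T_init, T_final = T_final,
         cooling = cooling, proposal_sd = proposal_sd,
         mutate_prob = mutate_prob, mutate_network = mutate_network,
         mutate_controller = mutate_controller, k_bounds = k_bounds,
         K_bounds = K_bounds, global_prob = global_prob,
         seed = as_seed_int(seed)),
    class = "anneal_config"
  )
}

# Steady-state deviation of the linearized closed loop for one or more
# forcing vectors (columns of f_mat):
#   J dx + f - c_i G y = 0,  S dx = 0
# With de~ = -J^{-1} f and A~ = -J^{-1} G:  dx = de~ - A~ z, (S A~) z = S de~.
# Returns NULL when the sensed projections cannot be actuated.
closed_loop_deviation <- function(jacobian, f_mat, controller = NULL) {
  de_t <- -solve(jacobian, f_mat)
  if (is_knocked_out(controller) || controller$c_i == 0) {
    return(de_t)
  }
  S <- controller$sense_mat
  A_t <- -solve(jacobian, controller$action_mat)
  M <- S %*% A_t
  z <- tryCatch(solve(M, S %*% de_t), error = function(e) NULL)
  if (is.null(z)) return(NULL)
  de_t - A_t %*% z
}

#' Homeostasis fitness cost
#'
#' Evaluates the cost described in [fitness_config()]. Networks without a
#' stable interior fixed point, and controlled systems whose linearized
#' closed loop is unstable or uncontrollable, receive infinite cost (they
#' are auto-rejected during annealing).
#'
#' @param network a [gene_network()] (`n_wt` solved, or solvable).
#' @param controller optional [pi_controller()].
#' @param fit_cfg a [fitness_config()].
#' @param seed seed for the environmental draws (ignored when `draws` is
#'   given).
#' @param draws optional pre-drawn `n_env_samples` x N matrix of `de`
#'   vectors, for common-random-number comparisons.
#' @return scalar cost `>= 0` (possibly `Inf`).
#' @export
fitness_cost <- function(network, controller = NULL,
                         fit_cfg = fitness_config(), seed = 1L,
                         draws = NULL) {
  if (is.null(network$n_wt)) {
    network <- tryCatch(find_fixed_point(network), error = function(e) NULL)
    if (is.null(network)) return(Inf)
  }
  if (is.null(draws)) {
    draws <- withr::with_seed(
      derive_seed(seed, "fitness-env"),
      matrix(stats::rnorm(fit_cfg$n_env_samples * network$n_genes,
                          sd = fit_cfg$env_sd),
             fit_cfg$n_env_samples, network$n_genes)
    )
  }
  sys <- jacobian_at(network)
  if (!sys$stable) return(Inf)
  if (!is.null(controller) && !is_knocked_out(controller)) {
    cl <- closed_loop_matrix(sys$jacobian, controller)
    if (any(Re(eigen(cl, only.values = TRUE)$values) >= 0)) return(Inf)
  }
  f_mat <- t(draws) * network$n_wt  # multiplicative forcing, linearized
  if (fit_cfg$eval_mode == "linearized") {
    dx <- closed_loop_deviation(sys$jacobian, f_mat, controller)
    if (is.null(dx)) return(Inf)
    norms <- sqrt(colSums(dx^2))
  } else {
    norms <- apply(draws, 1, function(de) {
      dev <- steady_state_deviation(network, env_forcing(de), controller)
      sqrt(sum(dev^2))
    })
  }
  switch(
    fit_cfg$stiffness_norm,
    uncontrolled = {
      norms0 <- if (fit_cfg$eval_mode == "linearized") {
        sqrt(colSums(solve(sys$jacobian, f_mat)^2))
      } else {
        apply(draws, 1, function(de) {
          sqrt(sum(steady_state_deviation(network, env_forcing(de))^2))
        })
      }
      mean(norms) / mean(norms0)
    },
    mean_rate = mean(norms) / sqrt(sum(network$n_wt^2)) *
      mean(abs(Re(sys$eigvals))),
    none = mean(norms) / sqrt(sum(network$n_wt^2))
  )
}

#' Propose a parameter perturbation
#'
#' Applies multiplicative log-normal jitter `exp(N(0, proposal_sd))` to a
#' random subset (each eligible entry independently with probability
#' `mutate_prob`) of the nonzero `k_mat` and `K_mat` entries, and -- when
#' controller mutation is enabled -- additive Gaussian jitter to the
#' sensing rows (re-orthonormalized) and action columns (re-normalized to
#' unit length). Consumes the current RNG stream, so proposals are
#' deterministic given the RNG state. `proposal_sd = 0` returns the inputs
#' unchanged.
#'
#' @param network a [gene_network()].
#' @param controller optional [pi_controller()].
#' @param proposal_sd jitter scale.
#' @param mutate_prob per-entry mutation probability.
#' @param mutate_network,mutate_controller which components to perturb.
#' @param k_bounds,K_bounds clipping ranges for the network parameters (see
#'   [anneal_config()]).
#' @param global_prob probability that a network move is a coordinated
#'   global one -- a single shared log-normal factor applied to all of
#'   `k_mat` or all of `K_mat` -- instead of independent per-entry jitter.
#'   Global moves let the chain walk efficiently along the
#'   saturation/criticality axis of the Michaelis-Menten kinetics.
#' @return list with perturbed `network` (its `n_wt` cleared, to be
#'   re-solved) and `controller`.
#' @export
propose <- function(network, controller = NULL, proposal_sd = 0.1,
                    mutate_prob = 0.2, mutate_network = TRUE,
                    mutate_controller = TRUE, k_bounds = c(0.02, 5),
                    K_bounds = c(0.05, 50), global_prob = 0.2) {
  if (proposal_sd == 0) return(list(network = network, controller = controller))
  if (mutate_network) {
    if (stats::runif(1) < global_prob) {
      fac <- exp(stats::rnorm(1, sd = proposal_sd))
      if (stats::runif(1) < 0.5) {
        nz <- which(network$k_mat != 0)
        network$k_mat[nz] <- pmin(pmax(network$k_mat[nz] * fac,
                                       k_bounds[1]), k_bounds[2])
      } else {
        network$K_mat[] <- pmin(pmax(network$K_mat * fac,
                                     K_bounds[1]), K_bounds[2])
      }
    } else {
      nz <- which(network$k_mat != 0)
      hit <- nz[stats::runif(length(nz)) < mutate_prob]
      if (length(hit)) {
        network$k_mat[hit] <- pmin(pmax(
          network$k_mat[hit] * exp(stats::rnorm(length(hit), sd = proposal_sd)),
          k_bounds[1]), k_bounds[2])
      }
      all_idx <- seq_along(network$K_mat)
      hit <- all_idx[stats::runif(length(all_idx)) < mutate_prob]
      if (length(hit)) {
        network$K_mat[hit] <- pmin(pmax(
          network$K_mat[hit] * exp(stats::rnorm(length(hit), sd = proposal_sd)),
          K_bounds[1]), K_bounds[2])
      }
    }
    network$n_wt <- NULL
  }
  if (mutate_controller && !is.null(controller)) {
    k <- controller$k_channels
    n <- controller$n_genes
    s <- controller$sense_mat +
      matrix(stats::rnorm(k * n, sd = proposal_sd), k, n)
    s <- orthonormal_rows(s)
    a <- controller$action_mat +
      matrix(stats::rnorm(n * k, sd = proposal_sd), n, k)
    a <- sweep(a, 2, pmax(sqrt(colSums(a^2)), 1e-12), "/")
    controller <- pi_controller(s, a, c_p = controller$c_p,
                                c_i = controller$c_i)
  }
  list(network = network, controller = controller)
}

#' Evolve a network by simulated annealing under selection for homeostasis
#'
#' Metropolis MCMC with acceptance probability `min(1, exp(-dcost / T))`
#' and geometric cooling. At every step a fresh set of environmental draws
#' is shared between the evaluation of the current and the proposed
#' parameters (common random numbers), so acceptance decisions are not
#' dominated by sampling noise. Proposals whose network loses its stable
#' interior fixed point, or whose closed loop goes unstable, have infinite
#' cost and are rejected automatically. The best-so-far parameters are
#' retained (elitism). Bit-reproducible given the seed in `anneal_cfg`.
#'
#' @param network starting [gene_network()] (must be stable).
#' @param controller starting [pi_controller()] (optional).
#' @param fit_cfg a [fitness_config()].
#' @param anneal_cfg an [anneal_config()].
#' @return An object of class `evolution_trace`: list with `trace` (a
#'   data.frame with columns `step`, `cost`, `accepted`, `temperature`,
#'   `mode_gap`), `best_network`, `best_controller`, `best_cost`,
#'   `final_network`, `final_controller`, `initial_cost`, `acceptance_rate`.
#' @export
anneal <- function(network, controller = NULL, fit_cfg = fitness_config(),
                   anneal_cfg = anneal_config()) {
  if (is.null(network$n_wt)) network <- find_fixed_point(network)
  n_steps <- anneal_cfg$n_steps
  temp_at <- function(step) {
    if (n_steps == 1L) return(anneal_cfg$T_init)
    anneal_cfg$T_init *
      (anneal_cfg$T_final / anneal_cfg$T_init)^((step - 1) / (n_steps - 1))
  }
  step_v <- seq_len(n_steps)
  cost_v <- numeric(n_steps)
  acc_v <- logical(n_steps)
  temp_v <- numeric(n_steps)
  gap_v <- numeric(n_steps)
  dcost_v <- numeric(n_steps)

  withr::with_seed(anneal_cfg$seed, {
    cur_net <- network
    cur_ctrl <- controller
    cur_sys <- jacobian_at(cur_net)
    initial_cost <- fitness_cost(cur_net, cur_ctrl, fit_cfg,
                                 seed = anneal_cfg$seed)
    best <- list(network = cur_net, controller = cur_ctrl,
                 cost = initial_cost)
    for (step in step_v) {
      Tcur <- temp_at(step)
      draws <- matrix(stats::rnorm(fit_cfg$n_env_samples * cur_net$n_genes,
                                   sd = fit_cfg$env_sd),
                      fit_cfg$n_env_samples, cur_net$n_genes)
      cost_cur <- fitness_cost(cur_net, cur_ctrl, fit_cfg, draws = draws)
      # when both components are evolvable, mutate one per step so that a
      # good network move is never vetoed by a bad controller move riding
      # along with it (and vice versa)
      mut_net <- anneal_cfg$mutate_network
      mut_ctrl <- anneal_cfg$mutate_controller && !is.null(cur_ctrl)
      if (mut_net && mut_ctrl) {
        if (stats::runif(1) < 0.7) mut_ctrl <- FALSE else mut_net <- FALSE
      }
      prop <- propose(cur_net, cur_ctrl,
                      proposal_sd = anneal_cfg$proposal_sd,
                      mutate_prob = anneal_cfg$mutate_prob,
                      mutate_network = mut_net,
                      mutate_controller = mut_ctrl,
                      k_bounds = anneal_cfg$k_bounds,
                      K_bounds = anneal_cfg$K_bounds,
                      global_prob = anneal_cfg$global_prob)
      prop_net <- tryCatch(
        if (is.null(prop$network$n_wt)) {
          find_fixed_point(prop$network, guess = cur_net$n_wt)
        } else prop$network,
        error = function(e) NULL
      )
      cost_prop <- if (is.null(prop_net)) Inf else {
        fitness_cost(prop_net, prop$controller, fit_cfg, draws = draws)
      }
      delta <- cost_prop - cost_cur
      u <- stats::runif(1)
      accept <- is.finite(cost_prop) &&
        (cost_prop <= cost_cur || u < exp(-delta / Tcur))
      if (accept) {
        cur_net <- prop_net
        cur_ctrl <- prop$controller
        cur_sys <- jacobian_at(cur_net)
        cost_cur <- cost_prop
      }
      if (cost_cur < best$cost) {
        best <- list(network = cur_net, controller = cur_ctrl,
                     cost = cost_cur)
      }
      cost_v[step] <- cost_cur
      acc_v[step] <- accept
      temp_v[step] <- Tcur
      gap_v[step] <- if (cur_net$n_genes >= 2) mode_gap(cur_sys) else NA_real_
      dcost_v[step] <- delta
    }
  })
  structure(
    list(
      trace = data.frame(step = step_v, cost = cost_v, accepted = acc_v,
                         temperature = temp_v, mode_gap = gap_v,
                         delta_cost = dcost_v),
      best_network = best$network, best_controller = best$controller,
      best_cost = best$cost, final_network = cur_net,
      final_controller = cur_ctrl, initial_cost = initial_cost,
      acceptance_rate = mean(acc_v),
      fit_cfg = fit_cfg, anneal_cfg = anneal_cfg
    ),
    class = "evolution_trace"
  )
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat("<evolution_trace>", nrow(x$trace), "steps; cost",
      format(x$initial_cost, digits = 4), "->",
      format(x$trace$cost[nrow(x$trace)], digits = 4),
      "; final mode gap", format(x$trace$mode_gap[nrow(x$trace)], digits = 4),
      "; acceptance", format(x$acceptance_rate, digits = 3), "\n")
  invisible(x)
}
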