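# Analytic linear theory of integral feedback around a fixed point:
# uncontrolled and controlled steady-state responses, effective rank,
# closed-form expected deviations, and optimal sensing/action geometry.
#
# Conventions. The linear dynamics are d(dx)/dt = J dx + de with J stable.
# Decay rates are lambda_i = |Re eigenvalue_i| > 0. The uncontrolled
# steady-state offset is dx = -J^{-1} de. With a single integral-feedback
# channel sensing s . dx and acting along a, the steady state satisfies
# s . dx = 0 and
#     dx = de~ - ((s . de~) / (s . a~)) a~,
# with the rescaled vectors de~ = -J^{-1} de and a~ = -J^{-1} a (in the
# eigenbasis these divide each component by its decay rate). This algebraic
# form is basis-free and is cross-validated against direct ODE integration
# of the closed loop in the test suite.

#' Single-slow-mode spectral model
#'
#' An idealized stable linear system with one slow mode (decay rate
#' `lambda_slow`) and `n_dims - 1` fast modes sharing the decay rate
#' `lambda_fast`; the mode gap is `lambda_fast / lambda_slow`. The basis is
#' orthonormal with the slow eigenvector first, so the Jacobian is
#' `J = -V diag(lambda) V^T` (symmetric, stable).
#'
#' @param n_dims system dimension N (>= 2).
#' @param gap mode gap `lambda_fast / lambda_slow` (>= 1).
#' @param lambda_fast decay rate of the fast modes (default 1, rate units).
#' @param basis optional N x N orthonormal matrix with the slow mode as its
#'   first column; identity by default.
#' @return An object of class `spectral_model` with fields `n_dims`,
#'   `lambda` (length-N decay rates, slow first), `lambda_slow`,
#'   `lambda_fast`, `basis`, `jacobian`.
#' @export
spectral_model <- function(n_dims, gap, lambda_fast = 1, basis = NULL) {
  stopifnot(n_dims >= 2, gap >= 1, lambda_fast > 0)
  lambda_slow <- lambda_fast / gap
  if (is.null(basis)) {
    basis <- diag(n_dims)
  } else {
    basis <- as.matrix(basis)
    if (max(abs(crossprod(basis) - diag(n_dims))) > 1e-8) {
      stop("`basis` must be orthonormal", call. = FALSE)
    }
  }
  lambda <- c(lambda_slow, rep(lambda_fast, n_dims - 1L))
  structure(
    list(
      n_dims = n_dims, lambda = lambda, lambda_slow = lambda_slow,
      lambda_fast = lambda_fast, basis = basis,
      jacobian = -basis %*% (lambda * t(basis))
    ),
    class = "spectral_model"
  )
}

#' @export
print.spectral_model <- function(x, ...) {
  cat("<spectral_model> N =", x$n_dims, ", mode gap =",
      format(x$lambda_fast / x$lambda_slow, digits = 4), "\n")
  invisible(x)
}

slow_mode <- function(model) model$basis[, 1L]

sys_jacobian <- function(system) {
  if (inherits(system, c("spectral_model", "linear_system"))) {
    return(system$jacobian)
  }
  if (is.matrix(system)) return(system)
  stop("`system` must be a spectral_model, linear_system, or Jacobian matrix",
       call. = FALSE)
}

# -J^{-1} %*% v (v may be a matrix of columns)
neg_jinv <- function(system, v) {
  if (inherits(system, "spectral_model")) {
    V <- system$basis
    return(V %*% ((crossprod(V, v)) / system$lambda))
  }
  -solve(sys_jacobian(system), v)
}

#' Gaussian perturbation ensemble
#'
#' Environmental (or mutational) perturbation vectors with independent
#' normal entries, `de_i ~ N(mean_i, sd_i^2)`, in the coordinates of the
#' system they are applied to.
#'
#' @param mean length-N mean vector (scalar recycled).
#' @param sd length-N componentwise standard deviations (scalar recycled),
#'   all `>= 0`.
#' @param n_dims optional explicit dimension when both `mean` and `sd` are
#'   scalars.
#' @return An object of class `perturbation_ensemble`.
#' @export
perturbation_ensemble <- function(mean = 0, sd = 1, n_dims = NULL) {
  n <- max(length(mean), length(sd), n_dims %||% 0L)
  if (n < 1) stop("cannot infer ensemble dimension", call. = FALSE)
  mean <- rep_len(as.numeric(mean), n)
  sd <- rep_len(as.numeric(sd), n)
  if (any(sd < 0)) stop("`sd` entries must be non-negative", call. = FALSE)
  structure(list(mean = mean, sd = sd, n_dims = n),
            class = "perturbation_ensemble")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw perturbation vectors from an ensemble
#'
#' @param ensemble a [perturbation_ensemble()].
#' @param n_samples number of draws.
#' @param seed integer seed (deterministic draws).
#' @return `n_samples` x N matrix, one draw per row.
#' @export
draw_perturbations <- function(ensemble, n_samples, seed = 1L) {
  withr::with_seed(as_seed_int(seed), {
    z <- matrix(stats::rnorm(n_samples * ensemble$n_dims),
                n_samples, ensemble$n_dims)
    sweep(z, 2, ensemble$sd, "*") +
      matrix(ensemble$mean, n_samples, ensemble$n_dims, byrow = TRUE)
  })
}

#' Steady-state response of the uncontrolled system
#'
#' The static offset `dx = -J^{-1} de` that balances a constant forcing
#' `de`: soft directions (small decay rates) respond proportionally more.
#'
#' @param system a [spectral_model()], [linear_system()], or Jacobian matrix.
#' @param delta_e forcing vector (or matrix with one forcing per column).
#' @return response vector (or matrix of columns).
#' @export
uncontrolled_response <- function(system, delta_e) {
  if (inherits(system, "linear_system") && !system$stable) {
    stop("system is not stable", call. = FALSE)
  }
  drop(neg_jinv(system, as.matrix(delta_e)))
}

#' Steady-state response under single-channel integral feedback
#'
#' Implements the algebraic closed-loop steady state
#' `dx = de~ - ((s . de~)/(s . a~)) a~` with `de~ = -J^{-1} de` and
#' `a~ = -J^{-1} a`. The integral action drives the sensed projection to
#' zero: every returned response satisfies `s . dx = 0` (up to roundoff).
#' The proportional gain affects transients only, not this steady state.
#'
#' @param system a [spectral_model()], [linear_system()], or Jacobian matrix.
#' @param s unit sensing vector.
#' @param a unit action vector.
#' @param delta_e forcing vector (or matrix with one forcing per column).
#' @return response vector (or matrix of columns).
#' @section Errors: `s . a~ = 0` means the sensed projection cannot be
#'   actuated (integral windup, no steady state); this raises an error of
#'   class `softmodes_uncontrollable`.
#' @export
controlled_response <- function(system, s, a, delta_e) {
  s <- as.numeric(s)
  a <- as.numeric(a)
  de <- as.matrix(delta_e)
  a_t <- drop(neg_jinv(system, a))
  denom <- sum(s * a_t)
  if (abs(denom) < 1e-12 * sqrt(sum(s^2) * sum(a_t^2))) {
    stop(structure(
      class = c("softmodes_uncontrollable", "error", "condition"),
      list(message = "uncontrollable configuration: s . (-J^{-1} a) = 0",
           call = NULL)
    ))
  }
  de_t <- neg_jinv(system, de)
  drop(de_t - outer(a_t, drop(crossprod(de_t, s)) / denom))
}

#' Effective rank of a variance-fraction vector
#'
#' `exp` of the Shannon entropy (natural log) of the fractions of variance
#' explained: a continuous measure of dimensionality that equals m for m
#' equal fractions and 1 for a single nonzero fraction.
#'
#' @param variance_fractions non-negative vector summing to 1 (tolerance
#'   `1e-9`); zero entries contribute nothing.
#' @return scalar in `[1, length(variance_fractions)]`.
#' @export
effective_rank <- function(variance_fractions) {
  p <- as.numeric(variance_fractions)
  if (any(p < 0)) stop("variance fractions must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("variance fractions must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  nz <- p[p > 0]
  exp(-sum(nz * log(nz)))
}

#' Effective rank of a sample cloud
#'
#' Mean-centers the samples, computes PCA variance fractions by
#' eigendecomposition of the covariance, and applies [effective_rank()].
#' The mean direction deliberately does not enter the rank statistic.
#'
#' @param samples matrix with one sample per row (at least 2 rows).
#' @return scalar effective rank, with attribute `variance_fractions`.
#' @export
ensemble_effective_rank <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) {
    stop("need at least 2 samples", call. = FALSE)
  }
  centered <- sweep(samples, 2, colMeans(samples))
  ev <- pmax(svd(centered, nu = 0, nv = 0)$d^2, 0)
  if (sum(ev) <= 0) {
    p <- c(1, rep(0, length(ev) - 1L))
  } else {
    p <- ev / sum(ev)
  }
  structure(effective_rank(p), variance_fractions = p)
}

#' Effective rank of a covariance matrix
#'
#' Exact version of [ensemble_effective_rank()] operating on a covariance
#' (its eigenvalue fractions) instead of finite samples.
#'
#' @param sigma_mat symmetric positive semi-definite matrix.
#' @return scalar effective rank.
#' @export
covariance_effective_rank <- function(sigma_mat) {
  ev <- pmax(eigen(sigma_mat, symmetric = TRUE, only.values = TRUE)$values, 0)
  effective_rank(ev / sum(ev))
}

#' Sensing/action geometry in the slow-mode / mean-perturbation plane
#'
#' Parameterizes unit sensing and action vectors as combinations of the
#' slow eigenvector and the mean-perturbation direction:
#' `s = alpha v0 + sqrt(1 - alpha^2) mu_hat` and
#' `a = beta v0 + sqrt(1 - beta^2) mu_hat`, where `mu_hat` is the unit
#' vector along the component of the ensemble mean orthogonal to the slow
#' mode (so `s` and `a` are exactly unit vectors). When the mean has no
#' component off the slow mode, the geometry degenerates to `s = a = v0`
#' for every `(alpha, beta)`.
#'
#' @param alpha sensing weight on the slow mode, in `[0, 1]`.
#' @param beta action weight on the slow mode, in `[0, 1]`.
#' @return An object of class `control_geometry`.
#' @export
control_geometry <- function(alpha, beta) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("`alpha` and `beta` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "control_geometry")
}

#' Resolve a geometry into explicit sensing/action vectors
#'
#' @param model a [spectral_model()].
#' @param ensemble a [perturbation_ensemble()] providing the mean direction.
#' @param geometry a [control_geometry()].
#' @return list with unit vectors `s`, `a` and the direction `mu_hat` (zero
#'   vector when the mean has no off-slow-mode component).
#' @export
geometry_vectors <- function(model, ensemble, geometry) {
  v0 <- slow_mode(model)
  mu <- ensemble$mean
  mu_perp <- mu - sum(mu * v0) * v0
  nrm <- sqrt(sum(mu_perp^2))
  if (nrm < 1e-12) {
    return(list(s = v0, a = v0, mu_hat = numeric(model$n_dims)))
  }
  mu_hat <- mu_perp / nrm
  list(
    s = geometry$alpha * v0 + sqrt(1 - geometry$alpha^2) * mu_hat,
    a = geometry$beta * v0 + sqrt(1 - geometry$beta^2) * mu_hat,
    mu_hat = mu_hat
  )
}

# Closed-loop response matrix A with dx = A de, plus the uncontrolled A0.
response_matrix <- function(model, s, a) {
  n <- model$n_dims
  a_t <- drop(neg_jinv(model, a))
  denom <- sum(s * a_t)
  if (abs(denom) < 1e-12 * sqrt(sum(s^2) * sum(a_t^2))) return(NULL)
  P <- diag(n) - outer(a_t, s) / denom
  P %*% neg_jinv(model, diag(n))
}

# E ||A de||^2 for de ~ N(mu, diag(sd^2)) (exact).
expected_sq_norm <- function(A, mu, sd) {
  sum((A %*% mu)^2) + sum((A * rep(sd, each = nrow(A)))^2)
}

#' Closed-form expected deviation under integral feedback
#'
#' Exact expectation of the squared controlled steady-state deviation over
#' the Gaussian perturbation ensemble, reported as the root-mean-square
#' norm `sqrt(E ||dx||^2)` (the primary statistic; the plain mean norm
#' `E ||dx||` has no simple closed form and is available through
#' [mc_expected_deviation()]). With `normalized = TRUE` the value is
#' divided by the uncontrolled expectation `sqrt(E ||-J^{-1} de||^2)`,
#' giving the dimensionless robustness measure that decreases with mode
#' gap. With `s = a = v0` the closed form reduces to
#' `sqrt(sum_{i != 0} (mu_i^2 + sigma_i^2)) / lambda_fast`: the soft mode
#' is cancelled exactly and only the fast modes remain.
#'
#' @param model a [spectral_model()].
#' @param ensemble a [perturbation_ensemble()] in the model's coordinates.
#' @param geometry a [control_geometry()], or a list with explicit unit
#'   vectors `s` and `a`.
#' @param normalized divide by the uncontrolled expectation?
#' @return scalar expected deviation (rms norm).
#' @export
expected_deviation <- function(model, ensemble, geometry,
                               normalized = FALSE) {
  if (ensemble$n_dims != model$n_dims) {
    stop("ensemble dimension does not match the model", call. = FALSE)
  }
  if (inherits(geometry, "control_geometry")) {
    geometry <- geometry_vectors(model, ensemble, geometry)
  }
  A <- response_matrix(model, geometry$s, geometry$a)
  if (is.null(A)) {
    stop(structure(
      class = c("softmodes_uncontrollable", "error", "condition"),
      list(message = "uncontrollable geometry: s . (-J^{-1} a) = 0",
           call = NULL)
    ))
  }
  val <- sqrt(expected_sq_norm(A, ensemble$mean, ensemble$sd))
  if (normalized) {
    A0 <- neg_jinv(model, diag(model$n_dims))
    val <- val / sqrt(expected_sq_norm(A0, ensemble$mean, ensemble$sd))
  }
  val
}

#' Monte-Carlo expected deviation
#'
#' Sample-based estimate of the expected controlled deviation norm; the
#' independent check on [expected_deviation()]'s closed form. `statistic =
#' "rms"` estimates `sqrt(E ||dx||^2)` (comparable to the closed form,
#' standard error by the delta method); `"mean"` estimates `E ||dx||`.
#'
#' @param model a [spectral_model()].
#' @param ensemble a [perturbation_ensemble()].
#' @param geometry a [control_geometry()] or list with `s`, `a`.
#' @param n_samples number of Monte-Carlo draws (>= 1).
#' @param seed integer seed.
#' @param statistic `"rms"` or `"mean"`.
#' @param normalized divide by the matching uncontrolled statistic
#'   (estimated on the same draws)?
#' @return scalar estimate with attribute `se` (standard error).
#' @export
mc_expected_deviation <- function(model, ensemble, geometry, n_samples = 1e4,
                                  seed = 1L, statistic = c("rms", "mean"),
                                  normalized = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(n_samples >= 1)
  if (inherits(geometry, "control_geometry")) {
    geometry <- geometry_vectors(model, ensemble, geometry)
  }
  A <- response_matrix(model, geometry$s, geometry$a)
  if (is.null(A)) stop("uncontrollable geometry", call. = FALSE)
  de <- t(draw_perturbations(ensemble, n_samples, seed))
  sq <- colSums((A %*% de)^2)
  est <- function(sq_norms) {
    if (statistic == "rms") {
      m <- mean(sq_norms)
      se_m <- stats::sd(sq_norms) / sqrt(length(sq_norms))
      val <- sqrt(m)
      list(value = val, se = if (val > 0) se_m / (2 * val) else se_m)
    } else {
      nr <- sqrt(sq_norms)
      list(value = mean(nr), se = stats::sd(nr) / sqrt(length(nr)))
    }
  }
  out <- est(sq)
  if (normalized) {
    sq0 <- colSums(neg_jinv(model, de)^2)
    base <- est(sq0)
    out$value <- out$value / base$value
    out$se <- out$se / base$value
  }
  structure(out$value, se = out$se)
}

#' Optimal sensing/action geometry
#'
#' Minimizes the closed-form expected deviation over `(alpha, beta)` in
#' `[0, 1]^2` by a warm-start grid (default 21 x 21) followed by bounded
#' local optimization from the best grid points. Deterministic. In the
#' large-gap limit the optimum aligns both vectors with the slow mode
#' (`alpha* = beta* = 1`); at gap 1 it aligns them with the mean
#' perturbation direction instead.
#'
#' @param model a [spectral_model()].
#' @param ensemble a [perturbation_ensemble()].
#' @param grid_n warm-start grid resolution per axis.
#' @param tol optimizer convergence tolerance.
#' @return list with `alpha`, `beta`, `value` (expected rms deviation at the
#'   optimum), `normalized` (same, normalized by the uncontrolled
#'   expectation) and `converged`.
#' @export
optimal_geometry <- function(model, ensemble, grid_n = 21L, tol = 1e-6) {
  A0 <- neg_jinv(model, diag(model$n_dims))
  base <- sqrt(expected_sq_norm(A0, ensemble$mean, ensemble$sd))
  obj <- function(par) {
    g <- geometry_vectors(model, ensemble, control_geometry(par[1], par[2]))
    A <- response_matrix(model, g$s, g$a)
    if (is.null(A)) return(1e6 * base)
    sqrt(expected_sq_norm(A, ensemble$mean, ensemble$sd))
  }
  grid <- seq(0, 1, length.out = grid_n)
  vals <- outer(grid, grid, Vectorize(function(al, be) obj(c(al, be))))
  ord <- order(vals)[seq_len(3L)]
  starts <- lapply(ord, function(i) {
    c(grid[(i - 1L) %% grid_n + 1L], grid[(i - 1L) %/% grid_n + 1L])
  })
  best <- NULL
  converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(factr = tol / .Machine$double.eps)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) {
    i <- which.min(vals)
    best <- list(par = c(grid[(i - 1L) %% grid_n + 1L],
                         grid[(i - 1L) %/% grid_n + 1L]),
                 value = min(vals))
    converged <- FALSE
  }
  list(
    alpha = best$par[1], beta = best$par[2], value = best$value,
    normalized = best$value / base, converged = converged
  )
}

#' Fitness benefit of a mode gap
#'
#' The normalized expected deviation (at its own optimal geometry) of a
#' gap-`gap_lo` system minus that of a gap-`gap_hi` system: how much
#' robustness, on a 0-1 scale, a pronounced soft mode buys a
#' single-channel integral controller. Increases with the dimensionality
#' of the system.
#'
#' @param n_dims system dimension.
#' @param ensemble a [perturbation_ensemble()] (same for both gaps).
#' @param gap_lo,gap_hi the two mode gaps compared (defaults 1 and 100).
#' @param lambda_fast shared fast decay rate.
#' @return scalar benefit in `[0, 1]`, with attributes `normalized_lo` and
#'   `normalized_hi`.
#' @export
gap_benefit <- function(n_dims, ensemble, gap_lo = 1, gap_hi = 100,
                        lambda_fast = 1) {
  lo <- optimal_geometry(spectral_model(n_dims, gap_lo, lambda_fast), ensemble)
  hi <- optimal_geometry(spectral_model(n_dims, gap_hi, lambda_fast), ensemble)
  structure(lo$normalized - hi$normalized,
            normalized_lo = lo$normalized, normalized_hi = hi$normalized)
}

#' Sweep the linear theory over mode gaps and dimensions
#'
#' Computes the optimal geometry and normalized expected deviation on a
#' grid of mode gaps and system sizes, for export as a tidy table.
#'
#' @param gaps vector of mode gaps.
#' @param n_dims_vec vector of system dimensions.
#' @param mean_norm norm of the ensemble mean, placed along an equal-weight
#'   direction orthogonal to the slow mode.
#' @param sd isotropic ensemble standard deviation.
#' @param lambda_fast shared fast decay rate.
#' @return data.frame with columns `gap`, `n_dims`, `alpha_opt`, `beta_opt`,
#'   `dev_norm` (normalized expected deviation at the optimum).
#' @export
theory_sweep <- function(gaps = c(1, 3, 10, 30, 100), n_dims_vec = 20,
                         mean_norm = 1, sd = 1, lambda_fast = 1) {
  rows <- list()
  for (n in n_dims_vec) {
    mu <- c(0, rep(mean_norm / sqrt(n - 1), n - 1L))
    ens <- perturbation_ensemble(mean = mu, sd = sd, n_dims = n)
    for (g in gaps) {
      opt <- optimal_geometry(spectral_model(n, g, lambda_fast), ens)
      rows[[length(rows) + 1L]] <- data.frame(
        gap = g, n_dims = n, alpha_opt = opt$alpha, beta_opt = opt$beta,
        dev_norm = opt$normalized
      )
    }
  }
  do.call(rbind, rows)
}
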