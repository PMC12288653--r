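# Adaptive Dormand-Prince RK45 integration. No ODE-solver package is assumed;
# this self-contained stepper (embedded 5(4) pair, PI step-size control) is
# validated in the test suite against matrix-exponential solutions of linear
# systems and against linearization oracles for the nonlinear network.

# Butcher tableau, Dormand & Prince (1980).
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_a <- list(
  numeric(0),
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

#' Integrate an ODE with an adaptive Runge-Kutta 4(5) scheme
#'
#' Dormand-Prince embedded pair with proportional-integral step-size control.
#' Suitable for the moderately stiff relaxation dynamics that arise here
#' (rate ratios of order the mode gap); not an implicit stiff solver.
#'
#' @param f derivative function `f(t, y)` returning a numeric vector.
#' @param y0 initial state.
#' @param t0,t1 integration interval, `t1 > t0`.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param max_steps cap on accepted+rejected steps.
#' @param stop_fn optional `function(t, y, dydt)` returning `TRUE` to end the
#'   integration early (evaluated after each accepted step).
#' @param record if `FALSE`, only the final state is kept.
#' @return list with `times`, `states` (one row per recorded time), `y_end`,
#'   `success`, `stopped_early`, and `message`.
#' @keywords internal
#' @export
ode_rk45 <- function(f, y0, t0, t1, rtol = 1e-8, atol = 1e-10,
                     max_steps = 500000L, stop_fn = NULL, record = TRUE) {
  y <- as.numeric(y0)
  t <- t0
  stopifnot(t1 > t0)
  k <- vector("list", 7L)
  k[[1]] <- f(t, y)
  if (any(!is.finite(k[[1]]))) {
    return(list(times = t0, states = matrix(y, 1), y_end = y, success = FALSE,
                stopped_early = FALSE,
                message = sprintf("non-finite derivative at t = %g", t0)))
  }
  # initial step from the derivative scale
  scale0 <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y / scale0)^2))
  d1 <- sqrt(mean((k[[1]] / scale0)^2))
  h <- if (d1 > 1e-10) 0.01 * d0 / d1 else 1e-6
  h <- min(max(h, 1e-10), t1 - t0)

  times <- if (record) numeric(512L) else NULL
  states <- if (record) matrix(NA_real_, 512L, length(y)) else NULL
  n_rec <- 0L
  push <- function(t, y) {
    n_rec <<- n_rec + 1L
    if (record) {
      if (n_rec > length(times)) {
        times <<- c(times, numeric(length(times)))
        states <<- rbind(states, matrix(NA_real_, nrow(states), ncol(states)))
      }
      times[n_rec] <<- t
      states[n_rec, ] <<- y
    }
  }
  push(t, y)

  err_prev <- 1
  stopped <- FALSE
  msg <- "completed"
  success <- TRUE
  for (step in seq_len(max_steps)) {
    if (t >= t1 - 1e-14 * max(1, abs(t1))) break
    h <- min(h, t1 - t)
    for (i in 2:7) {
      yi <- y
      ai <- .dp_a[[i]]
      for (j in seq_along(ai)) yi <- yi + h * ai[j] * k[[j]]
      k[[i]] <- f(t + .dp_c[i] * h, yi)
    }
    y5 <- y
    for (j in 1:7) if (.dp_b5[j] != 0) y5 <- y5 + h * .dp_b5[j] * k[[j]]
    err_vec <- numeric(length(y))
    for (j in 1:7) {
      d <- .dp_b5[j] - .dp_b4[j]
      if (d != 0) err_vec <- err_vec + h * d * k[[j]]
    }
    if (any(!is.finite(y5))) {
      success <- FALSE
      msg <- sprintf("solution blew up near t = %g", t)
      break
    }
    scale <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean((err_vec / scale)^2))
    if (err <= 1) {
      t <- t + h
      y <- y5
      k[[1]] <- k[[7]]  # FSAL
      push(t, y)
      if (!is.null(stop_fn) && isTRUE(stop_fn(t, y, k[[1]]))) {
        stopped <- TRUE
        break
      }
      # PI controller on the step size
      fac <- 0.9 * err^(-0.7 / 5) * err_prev^(0.4 / 5)
      err_prev <- max(err, 1e-10)
      h <- h * min(5, max(0.2, fac))
    } else {
      # rejected: k[[1]] still holds f(t, y) for the retry
      h <- h * min(1, max(0.1, 0.9 * err^(-1 / 5)))
    }
    if (h < 1e-13 * max(1, abs(t))) {
      success <- FALSE
      msg <- sprintf("step size underflow at t = %g", t)
      break
    }
    if (step == max_steps) {
      success <- FALSE
      msg <- "max_steps exceeded"
    }
  }
  list(
    times = if (record) times[seq_len(n_rec)] else t,
    states = if (record) states[seq_len(n_rec), , drop = FALSE] else matrix(y, 1),
    y_end = y, success = success, stopped_early = stopped, message = msg
  )
}

#' Simulate a (possibly controlled, forced) network trajectory
#'
#' Integrates the augmented system of N expression levels plus k controller
#' integral accumulators (started at zero) over `t_span`. States are clipped
#' at zero inside the right-hand side, so trajectories never go negative.
#'
#' @param network a [gene_network()].
#' @param t_span length of integration time (from 0) or `c(t0, t1)`.
#' @param init initial state; defaults to the wild-type fixed point.
#' @param forcing optional [env_forcing()].
#' @param controller optional [pi_controller()].
#' @param rtol,atol integrator tolerances.
#' @return An object of class `trajectory`: list with `times` (length T),
#'   `states` (T x N matrix), `integrals` (T x k matrix, zero columns when
#'   uncontrolled).
#' @export
simulate_network <- function(network, t_span, init = network$n_wt,
                             forcing = NULL, controller = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  if (is.null(init)) {
    stop("no initial state: supply `init` or solve the fixed point first",
         call. = FALSE)
  }
  init <- as.numeric(init)
  if (any(init < 0)) stop("initial state must be non-negative", call. = FALSE)
  if (length(t_span) == 1L) t_span <- c(0, t_span)
  if (diff(t_span) <= 0) stop("`t_span` must be positive", call. = FALSE)
  forcing <- check_forcing(network, forcing)
  n <- network$n_genes
  k <- if (is.null(controller)) 0L else controller$k_channels
  n_ref <- network$n_wt

  f <- function(t, y) {
    state <- y[seq_len(n)]
    if (k > 0L) {
      ints <- y[n + seq_len(k)]
      dn <- network_rhs(network, state, forcing, controller, ints, n_ref = n_ref)
      dy <- drop(controller$sense_mat %*% (state - n_ref))
      c(dn, dy)
    } else {
      network_rhs(network, state, forcing)
    }
  }
  sol <- ode_rk45(f, c(init, numeric(k)), t_span[1], t_span[2],
                  rtol = rtol, atol = atol)
  if (!sol$success) {
    stop("integration failed: ", sol$message, call. = FALSE)
  }
  structure(
    list(
      times = sol$times,
      states = pmax(sol$states[, seq_len(n), drop = FALSE], 0),
      integrals = sol$states[, n + seq_len(k), drop = FALSE]
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$times), "time points,",
      ncol(x$states), "genes,", ncol(x$integrals), "controller channels\n")
  invisible(x)
}

#' Steady-state deviation from the wild-type fixed point
#'
#' Integrates the (controlled, forced) dynamics from the wild-type fixed
#' point until the state derivative norm falls below
#' `tol_factor * ||n_wt||` or `t_max` is reached, and returns the terminal
#' deviation `n(final) - n_wt`. By default `t_max` is 1000 relaxation times
#' of the slowest open-loop mode.
#'
#' @param network a [gene_network()] with `n_wt` set.
#' @param forcing optional [env_forcing()].
#' @param controller optional [pi_controller()].
#' @param t_max integration horizon; default `1e3 / |Re lambda_0|`.
#' @param tol_factor steady-state declaration threshold relative to
#'   `||n_wt||` (default `1e-8`).
#' @return length-N deviation vector with attribute `converged` (logical);
#'   non-convergence within `t_max` is flagged, not an error.
#' @export
steady_state_deviation <- function(network, forcing = NULL, controller = NULL,
                                   t_max = NULL, tol_factor = 1e-8) {
  if (is.null(network$n_wt)) {
    stop("network has no wild-type fixed point; run find_fixed_point()",
         call. = FALSE)
  }
  forcing <- check_forcing(network, forcing)
  n <- network$n_genes
  n_wt <- network$n_wt
  if (is.null(t_max)) {
    sys <- jacobian_at(network)
    t_max <- 1e3 / abs(Re(sys$eigvals[1]))
  }
  thresh <- tol_factor * sqrt(sum(n_wt^2))
  k <- if (is.null(controller)) 0L else controller$k_channels
  f <- function(t, y) {
    state <- y[seq_len(n)]
    if (k > 0L) {
      ints <- y[n + seq_len(k)]
      c(network_rhs(network, state, forcing, controller, ints, n_ref = n_wt),
        drop(controller$sense_mat %*% (state - n_wt)))
    } else {
      network_rhs(network, state, forcing)
    }
  }
  stop_fn <- function(t, y, dydt) {
    sqrt(sum(dydt[seq_len(n)]^2)) < thresh
  }
  sol <- ode_rk45(f, c(n_wt, numeric(k)), 0, t_max, stop_fn = stop_fn,
                  record = FALSE)
  if (!sol$success) {
    stop("integration failed: ", sol$message, call. = FALSE)
  }
  dev <- pmax(sol$y_end[seq_len(n)], 0) - n_wt
  attr(dev, "converged") <- sol$stopped_early ||
    sqrt(sum(f(0, sol$y_end)[seq_len(n)]^2)) < thresh
  dev
}

#' Export a trajectory as CSV
#'
#' Columns `time`, `n_0 ... n_{N-1}`, `I_0 ... I_{k-1}`.
#'
#' @param trajectory a [simulate_network()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(trajectory, path) {
  n <- ncol(trajectory$states)
  k <- ncol(trajectory$integrals)
  df <- data.frame(time = trajectory$times, trajectory$states)
  names(df) <- c("time", paste0("n_", seq_len(n) - 1L))
  if (k > 0L) {
    ints <- as.data.frame(trajectory$integrals)
    names(ints) <- paste0("I_", seq_len(k) - 1L)
    df <- cbind(df, ints)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
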