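# k-channel proportional-integral controllers sensing linear projections of
# the deviation from the wild-type state.

#' Construct a k-channel proportional-integral controller
#'
#' Each channel i senses a linear projection \eqn{s_i \cdot \delta n} of the
#' deviation from the set point and contributes an integrated error signal
#' \deqn{I_i = c_p\, (s_i \cdot \delta n) + c_i \int s_i \cdot \delta n \, dt,}
#' which drives a restorative action \eqn{-\sum_i g^{(i)} I_i} through the
#' channel's action vector \eqn{g^{(i)}} (column i of `action_mat`). The
#' number of channels k is the controller's complexity: k = N allows full
#' observability of the state, k = 1 mimics hub-style signaling (cAMP,
#' (p)ppGpp) where diverse stresses are compressed into one scalar.
#'
#' Sensing rows are required to be orthonormal (rank k, unit rows) so the k
#' channels carry k non-redundant measurements; each channel has its own
#' action column so that a complex controller is not crippled to rank-1
#' actuation.
#'
#' @param sense_mat k x N matrix of sensing vectors (rows; orthonormalized
#'   internally if nearly so, rejected if rank-deficient).
#' @param action_mat N x k matrix of action vectors (columns).
#' @param c_p proportional gain (>= 0), shared across channels.
#' @param c_i integral gain (>= 0), shared across channels.
#' @return An object of class `pi_controller`.
#' @export
pi_controller <- function(sense_mat, action_mat, c_p = 1, c_i = 1) {
  sense_mat <- as.matrix(sense_mat)
  action_mat <- as.matrix(action_mat)
  k <- nrow(sense_mat)
  n <- ncol(sense_mat)
  if (k > n) {
    stop("controller complexity k = ", k, " exceeds system size N = ", n,
         call. = FALSE)
  }
  if (!all(dim(action_mat) == c(n, k))) {
    stop("`action_mat` must be ", n, " x ", k, call. = FALSE)
  }
  if (c_p < 0 || c_i < 0) stop("gains must be non-negative", call. = FALSE)
  row_norms <- sqrt(rowSums(sense_mat^2))
  if (any(row_norms < 1e-12)) stop("sensing rows must be nonzero", call. = FALSE)
  sense_mat <- sense_mat / row_norms
  gram <- sense_mat %*% t(sense_mat)
  if (max(abs(gram - diag(k))) > 1e-8) {
    if (qr(sense_mat)$rank < k) {
      stop("sensing rows must be linearly independent (rank k)", call. = FALSE)
    }
    stop("sensing rows must be orthonormal; use orthonormal_rows()",
         call. = FALSE)
  }
  structure(
    list(
      k_channels = k, n_genes = n, sense_mat = sense_mat,
      action_mat = action_mat, c_p = c_p, c_i = c_i
    ),
    class = "pi_controller"
  )
}

#' @export
print.pi_controller <- function(x, ...) {
  cat("<pi_controller> k =", x$k_channels, "channels on", x$n_genes,
      "genes; c_p =", x$c_p, ", c_i =", x$c_i,
      if (x$c_p == 0 && x$c_i == 0) "(knocked out)" else "", "\n")
  invisible(x)
}

#' Orthonormalize the rows of a matrix
#'
#' Gram-Schmidt via QR; used to turn independent sensing directions into the
#' orthonormal rows [pi_controller()] requires.
#'
#' @param m k x N matrix with linearly independent rows (k <= N).
#' @return k x N matrix with orthonormal rows spanning the same row space.
#' @export
orthonormal_rows <- function(m) {
  m <- as.matrix(m)
  qr_dec <- qr(t(m))
  if (qr_dec$rank < nrow(m)) {
    stop("rows are not linearly independent", call. = FALSE)
  }
  q <- qr.Q(qr_dec)[, seq_len(nrow(m)), drop = FALSE]
  # fix signs so the result is a rotation of the input, not a reflection
  sgn <- sign(diag(qr.R(qr_dec)))
  sgn[sgn == 0] <- 1
  t(q) * sgn
}

#' Draw a random controller
#'
#' Sensing rows are drawn isotropically (standard Gaussian) and
#' orthonormalized. Action columns are either drawn isotropically and
#' normalized to unit length (`action = "isotropic"`), or set to the
#' corresponding sensing directions (`action = "aligned"`, i.e.
#' `g^(i) = s_i`), which makes each channel push back against exactly what
#' it senses and gives a closed loop that starts out stable -- the natural
#' starting point for evolution runs, where an isotropically drawn action
#' almost always destabilizes a many-channel loop. Deterministic given the
#' seed.
#'
#' @param n_genes system size N.
#' @param k number of channels, `1 <= k <= n_genes`.
#' @param seed integer seed.
#' @param c_p,c_i gains (defaults 1).
#' @param action `"isotropic"` or `"aligned"`.
#' @return A [pi_controller()].
#' @export
random_controller <- function(n_genes, k, seed = 1L, c_p = 1, c_i = 1,
                              action = c("isotropic", "aligned")) {
  action <- match.arg(action)
  if (k < 1 || k > n_genes) {
    stop("need 1 <= k <= N; got k = ", k, ", N = ", n_genes, call. = FALSE)
  }
  withr::with_seed(as_seed_int(seed), {
    s <- orthonormal_rows(matrix(stats::rnorm(k * n_genes), k, n_genes))
    a <- if (action == "aligned") t(s) else {
      a <- matrix(stats::rnorm(n_genes * k), n_genes, k)
      sweep(a, 2, sqrt(colSums(a^2)), "/")
    }
    pi_controller(s, a, c_p = c_p, c_i = c_i)
  })
}

#' Evaluate the controller on a deviation
#'
#' Computes the sensed projections, the integrated error signals
#' \eqn{I_i = c_p (s_i\cdot\delta n) + c_i y_i}, the restorative action
#' \eqn{\sum_i g^{(i)} I_i}, and the time derivative of the integral
#' accumulators (which is just the sensed projection, for use in the
#' augmented ODE).
#'
#' @param controller a [pi_controller()].
#' @param delta_n length-N deviation from the set point.
#' @param integral_state length-k vector of accumulated integrals
#'   \eqn{y_i = \int s_i\cdot\delta n\,dt}.
#' @return list with fields `sensed` (k-vector), `I` (k-vector), `action`
#'   (N-vector) and `integral_deriv` (k-vector, equal to `sensed`).
#' @export
control_terms <- function(controller, delta_n, integral_state) {
  delta_n <- as.numeric(delta_n)
  integral_state <- as.numeric(integral_state)
  if (length(delta_n) != controller$n_genes) {
    stop("deviation length does not match controller size", call. = FALSE)
  }
  if (length(integral_state) != controller$k_channels) {
    stop("integral state length does not match number of channels", call. = FALSE)
  }
  sensed <- drop(controller$sense_mat %*% delta_n)
  I <- controller$c_p * sensed + controller$c_i * integral_state
  action <- drop(controller$action_mat %*% I)
  list(sensed = sensed, I = I, action = action, integral_deriv = sensed)
}

#' Knock out a controller
#'
#' Sets both gains to zero so the action is identically zero, while keeping
#' the sensing/action structure for bookkeeping. Idempotent.
#'
#' @param controller a [pi_controller()].
#' @return The knocked-out controller.
#' @export
knockout <- function(controller) {
  controller$c_p <- 0
  controller$c_i <- 0
  controller
}

is_knocked_out <- function(controller) {
  is.null(controller) || (controller$c_p == 0 && controller$c_i == 0)
}

#' Closed-loop matrix of the linearized controlled system
#'
#' Builds the (N+k) x (N+k) matrix of the augmented linear dynamics
#' \deqn{\dot{\delta x} = (J - c_p G S)\,\delta x - c_i G y, \qquad
#'       \dot y = S\,\delta x}
#' with sensing matrix S (k x N) and action matrix G (N x k). Its
#' eigenvalues decide closed-loop stability.
#'
#' @param jacobian N x N open-loop Jacobian.
#' @param controller a [pi_controller()].
#' @return (N+k) x (N+k) numeric matrix.
#' @export
closed_loop_matrix <- function(jacobian, controller) {
  n <- nrow(jacobian)
  k <- controller$k_channels
  S <- controller$sense_mat
  G <- controller$action_mat
  rbind(
    cbind(jacobian - controller$c_p * G %*% S, -controller$c_i * G),
    cbind(S, matrix(0, k, k))
  )
}
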