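## Steady-state Kalman filter decoder.
##
## State x = (px, py, vx, vy, 1): cursor position, velocity, constant term.
## Dynamics prior  x_{t+1} = A_tilde x_t + w_t,  w ~ N(0, W)
## Observation     y_t     = C x_t + q_t,        q ~ N(0, Q)
## Decode          x_{t+1} = A x_t + K y_t,      A = (I - K C) A_tilde
## Perturbed       x_{t+1} = A x_t + R5(theta) K y_t
## where R5 is block-diagonal with R(theta) on the position and velocity
## blocks and 1 on the constant.

#' Planar rotation matrix
#'
#' \deqn{R(\theta) = \begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta & \cos\theta\end{pmatrix}}
#'
#' @param theta angle in radians, counter-clockwise positive.
#' @return 2x2 orthogonal matrix with determinant 1.
#' @export
rotation_matrix <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("theta must be a finite scalar angle", call. = FALSE)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Block-diagonal state-space rotation
#'
#' The 5x5 perturbation applied to the Kalman gain: R(theta) on the position
#' block, R(theta) on the velocity block, 1 on the constant term.
#'
#' @param theta angle in radians.
#' @return 5x5 orthogonal matrix.
#' @export
rotation_block5 <- function(theta) {
  R <- rotation_matrix(theta)
  out <- diag(5)
  out[1:2, 1:2] <- R
  out[3:4, 3:4] <- R
  out
}

#' Prescribed cursor kinematics matrix
#'
#' Position integrates velocity over one bin; velocity persists with damping
#' factor `alpha`; the constant term is carried through unchanged.
#'
#' @param bin_width bin width in seconds.
#' @param alpha per-bin velocity persistence in \[0, 1).
#' @return 5x5 matrix.
#' @export
kinematics_prior <- function(bin_width = 0.1, alpha = 0.8) {
  A <- diag(5)
  A[1, 3] <- bin_width
  A[2, 4] <- bin_width
  A[3, 3] <- alpha
  A[4, 4] <- alpha
  A
}

#' Fit the linear observation model from passive data
#'
#' Least-squares fit of `counts ~ C state`; `Q` is the symmetrized residual
#' covariance. The state matrix must include the constant-1 component and have
#' full column rank.
#'
#' @param states 5 x bins matrix of state vectors.
#' @param counts units x bins matrix of spike counts.
#' @return list with `C` (units x 5) and `Q` (units x units).
#' @export
fit_observation_model <- function(states, counts) {
  stopifnot(is.matrix(states), is.matrix(counts))
  if (ncol(states) != ncol(counts))
    stop("states and counts must have the same number of bins", call. = FALSE)
  if (ncol(states) <= nrow(states))
    stop("need more bins than state dimensions to fit C", call. = FALSE)
  X <- t(states)                       # bins x 5
  if (qr(X)$rank < ncol(X))
    stop("state matrix is rank deficient; passive trajectories must span ",
         "positions and velocities (plus the constant)", call. = FALSE)
  Y <- t(counts)                       # bins x units
  Ct <- qr.solve(X, Y)                 # 5 x units
  resid <- Y - X %*% Ct
  Q <- crossprod(resid) / (nrow(X) - ncol(X))
  Q <- (Q + t(Q)) / 2
  list(C = t(Ct), Q = Q)
}

#' Steady-state Kalman gain by Riccati iteration
#'
#' Iterates the discrete Riccati recursion for the prediction-error covariance
#' \eqn{\Sigma \leftarrow \tilde A (\Sigma - \Sigma C' (C \Sigma C' + Q)^{-1}
#' C \Sigma) \tilde A' + W} from \eqn{\Sigma_0 = W} until the Frobenius change
#' falls below `tol`, then returns \eqn{K = \Sigma C' (C \Sigma C' + Q)^{-1}}.
#'
#' @param A_tilde 5x5 kinematics prior.
#' @param C units x 5 observation matrix.
#' @param W 5x5 process-noise covariance (PSD).
#' @param Q units x units observation-noise covariance (PSD).
#' @param tol Frobenius-norm convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return list with `K` (5 x units), converged covariance `Sigma`,
#'   iteration count `iterations`, and final change `residual`.
#' @export
steady_state_gain <- function(A_tilde, C, W, Q, tol = 1e-10, max_iter = 1e5) {
  stopifnot(nrow(A_tilde) == ncol(A_tilde), ncol(C) == nrow(A_tilde),
            all(dim(W) == dim(A_tilde)), nrow(Q) == nrow(C), ncol(Q) == nrow(C))
  Sigma <- W
  Ct <- t(C)
  for (it in seq_len(max_iter)) {
    S <- C %*% Sigma %*% Ct + Q
    K <- Sigma %*% Ct %*% solve(S)
    Sigma_new <- A_tilde %*% (Sigma - K %*% C %*% Sigma) %*% t(A_tilde) + W
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    delta <- sqrt(sum((Sigma_new - Sigma)^2))
    Sigma <- Sigma_new
    if (delta < tol) {
      S <- C %*% Sigma %*% Ct + Q
      K <- Sigma %*% Ct %*% solve(S)
      return(list(K = K, Sigma = Sigma, iterations = it, residual = delta))
    }
  }
  stop(sprintf("Riccati iteration did not converge in %d iterations (last change %.3g)",
               as.integer(max_iter), delta), call. = FALSE)
}

#' Derived closed-loop dynamics matrix
#'
#' `A = (I - K C) A_tilde`.
#'
#' @param A_tilde kinematics prior.
#' @param K steady-state gain.
#' @param C observation matrix.
#' @return 5x5 matrix.
#' @export
derived_dynamics <- function(A_tilde, K, C) {
  if (ncol(K) != nrow(C) || nrow(K) != nrow(A_tilde) || ncol(C) != ncol(A_tilde))
    stop("shape mismatch among A_tilde, K, C", call. = FALSE)
  (diag(nrow(A_tilde)) - K %*% C) %*% A_tilde
}

#' Fit a complete Kalman decoder from passive-observation data
#'
#' Convenience constructor: fits (C, Q) from the passive set, builds the
#' kinematics prior and process noise, computes the steady-state gain and the
#' derived dynamics.
#'
#' Observations are mean-centered: the per-unit mean calibration count `y0`
#' is stored in the model and subtracted before the gain is applied, so the
#' rotated gain acts on the movement-coding part of the activity rather than
#' on the baseline pattern (rotating the baseline contribution would inject a
#' constant velocity bias that no directional strategy could compensate).
#'
#' @param passive output of [passive_observation_set()].
#' @param alpha velocity persistence of the kinematics prior.
#' @param velocity_noise process-noise variance on each velocity component.
#' @param center_observations subtract mean calibration counts before
#'   decoding (recommended; see Details).
#' @param tol,max_iter Riccati convergence controls.
#' @return object of class `kalman_model` with elements `A_tilde`, `C`, `Q`,
#'   `W`, `K`, `A`, `Sigma`, `y0`, `bin_width`, `n_units`.
#' @export
fit_kalman_decoder <- function(passive, alpha = 0.8, velocity_noise = 1,
                               center_observations = TRUE,
                               tol = 1e-10, max_iter = 1e5) {
  y0 <- if (center_observations) rowMeans(passive$counts) else
    rep(0, nrow(passive$counts))
  obs <- fit_observation_model(passive$states, passive$counts - y0)
  A_tilde <- kinematics_prior(passive$bin_width, alpha)
  W <- diag(c(0, 0, velocity_noise, velocity_noise, 0))
  ss <- steady_state_gain(A_tilde, obs$C, W, obs$Q, tol = tol, max_iter = max_iter)
  A <- derived_dynamics(A_tilde, ss$K, obs$C)
  structure(list(A_tilde = A_tilde, C = obs$C, Q = obs$Q, W = W,
                 K = ss$K, A = A, Sigma = ss$Sigma, y0 = y0,
                 riccati_iterations = ss$iterations,
                 bin_width = passive$bin_width, n_units = nrow(obs$C),
                 alpha = alpha, velocity_noise = velocity_noise),
            class = "kalman_model")
}

#' @export
print.kalman_model <- function(x, ...) {
  cat("Steady-state Kalman filter decoder\n")
  cat(sprintf("  units: %d   bin width: %g s   velocity damping: %g\n",
              x$n_units, x$bin_width, x$alpha))
  cat(sprintf("  Riccati iterations to convergence: %d\n", x$riccati_iterations))
  invisible(x)
}

#' One decoding step
#'
#' Unperturbed: `x' = A x + K y`. With an imposed rotation `theta` (radians),
#' the gain is premultiplied by the block-diagonal rotation:
#' `x' = A x + R5(theta) K y`. The constant component is restored to exactly 1
#' after the update.
#'
#' @param model a `kalman_model`.
#' @param x current 5-vector state (constant component 1).
#' @param y per-unit observation vector (counts per bin).
#' @param theta imposed rotation in radians; 0 disables the perturbation.
#' @return next state 5-vector.
#' @export
decode_step <- function(model, x, y, theta = 0) {
  stopifnot(inherits(model, "kalman_model"))
  if (length(x) != 5L) stop("state must have length 5", call. = FALSE)
  if (length(y) != model$n_units)
    stop(sprintf("observation has length %d but the decoder expects %d units",
                 length(y), model$n_units), call. = FALSE)
  Ky <- model$K %*% (y - (model$y0 %||% 0))
  if (theta != 0) Ky <- rotation_block5(theta) %*% Ky
  xn <- as.numeric(model$A %*% x + Ky)
  xn[5] <- 1
  xn
}

#' Serialize a Kalman decoder to JSON
#'
#' Writes all matrices as nested numeric arrays at full precision (17
#' significant digits), so a round trip is lossless to printed precision.
#'
#' @param model a `kalman_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kalman_model <- function(model, path) {
  stopifnot(inherits(model, "kalman_model"))
  payload <- lapply(model, function(el) if (is.matrix(el)) unclass(el) else el)
  payload$class <- "kalman_model"
  jsonlite::write_json(payload, path, digits = 17, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a Kalman decoder from JSON
#'
#' @param path file written by [write_kalman_model()].
#' @return a `kalman_model`.
#' @export
read_kalman_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- c("A_tilde", "C", "Q", "W", "K", "A", "Sigma")
  payload$y0 <- as.numeric(payload$y0)
  for (m in mats) payload[[m]] <- as.matrix(payload[[m]])
  payload$class <- NULL
  structure(payload, class = "kalman_model")
}
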