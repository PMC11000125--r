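## Minimal fully connected networks and Adam optimizer used by the PPO
## trainer. Layout follows the usual actor-critic recipe: two tanh hidden
## layers of `width` units for each of the policy and value networks,
## orthogonal weight initialization (gain sqrt(2) for hidden layers, a small
## gain for the policy head, 1 for the value head), and a state-independent
## log standard deviation for the Gaussian policy.

orthogonal_init <- function(rows, cols, gain = 1) {
  a <- matrix(stats::rnorm(rows * cols), max(rows, cols), min(rows, cols))
  qr_ <- qr(a)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q * rep(d, each = nrow(q))
  if (rows < cols) q <- t(q)
  gain * q[seq_len(rows), seq_len(cols), drop = FALSE]
}

mlp_init <- function(n_in, width, n_out, out_gain) {
  list(W1 = orthogonal_init(width, n_in, sqrt(2)), b1 = rep(0, width),
       W2 = orthogonal_init(width, width, sqrt(2)), b2 = rep(0, width),
       W3 = orthogonal_init(n_out, width, out_gain), b3 = rep(0, n_out))
}

## Batched forward pass. X is n x n_in; returns hidden activations so the
## same code serves backprop and activation capture.
mlp_forward <- function(net, X) {
  H1 <- tanh(X %*% t(net$W1) + rep(net$b1, each = nrow(X)))
  H2 <- tanh(H1 %*% t(net$W2) + rep(net$b2, each = nrow(X)))
  out <- H2 %*% t(net$W3) + rep(net$b3, each = nrow(X))
  list(H1 = H1, H2 = H2, out = out)
}

## Single-observation forward pass (rollout hot path).
mlp_forward1 <- function(net, x) {
  h1 <- tanh(as.numeric(net$W1 %*% x) + net$b1)
  h2 <- tanh(as.numeric(net$W2 %*% h1) + net$b2)
  list(h2 = h2, out = as.numeric(net$W3 %*% h2) + net$b3)
}

## Backward pass given the gradient G (n x n_out) of the loss wrt `out`.
mlp_backward <- function(net, X, fwd, G) {
  dW3 <- t(G) %*% fwd$H2
  db3 <- colSums(G)
  G2 <- (G %*% net$W3) * (1 - fwd$H2^2)
  dW2 <- t(G2) %*% fwd$H1
  db2 <- colSums(G2)
  G1 <- (G2 %*% net$W2) * (1 - fwd$H1^2)
  dW1 <- t(G1) %*% X
  db1 <- colSums(G1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (k in names(params)) {
    state[[k]]$m <- beta1 * state[[k]]$m + (1 - beta1) * grads[[k]]
    state[[k]]$v <- beta2 * state[[k]]$v + (1 - beta2) * grads[[k]]^2
    mhat <- state[[k]]$m / (1 - beta1^t)
    vhat <- state[[k]]$v / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Global gradient-norm clipping across a list of gradient lists.
clip_grads <- function(grad_lists, max_norm) {
  total <- sqrt(sum(vapply(grad_lists, function(gl)
    sum(vapply(gl, function(g) sum(g^2), numeric(1))), numeric(1))))
  if (is.finite(total) && total > max_norm && total > 0) {
    sc <- max_norm / total
    grad_lists <- lapply(grad_lists, function(gl) lapply(gl, function(g) g * sc))
  }
  grad_lists
}
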