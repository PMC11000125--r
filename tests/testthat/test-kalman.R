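test_that("rotation matrices satisfy the exact identities", {
  expect_equal(rotation_matrix(0), diag(2), tolerance = 1e-12)
  expect_equal(as.numeric(rotation_matrix(pi / 2) %*% c(1, 0)), c(0, 1),
               tolerance = 1e-12)
  th <- 50 * pi / 180
  expect_equal(rotation_matrix(th) %*% rotation_matrix(-th), diag(2),
               tolerance = 1e-12)
  R <- rotation_matrix(0.83)
  expect_equal(t(R) %*% R, diag(2), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_error(rotation_matrix(Inf), "finite")
  B <- rotation_block5(th)
  expect_equal(t(B) %*% B, diag(5), tolerance = 1e-12)
  expect_equal(det(B), 1, tolerance = 1e-12)
  expect_equal(rotation_block5(0), diag(5), tolerance = 1e-12)
})

test_that("observation-model fit is exact on linear data and validates input", {
  set.seed(2)
  C0 <- matrix(rnorm(8 * 5), 8, 5)
  X <- rbind(matrix(rnorm(4 * 60), 4, 60), 1)
  Y <- C0 %*% X
  fit <- fit_observation_model(X, Y)
  expect_equal(fit$C, C0, tolerance = 1e-9)
  expect_lt(max(abs(fit$Q)), 1e-18)
  expect_error(fit_observation_model(X[, 1:4], Y[, 1:4]), "more bins")
  Xdef <- rbind(matrix(rnorm(3 * 60), 3, 60), 0, 1)  # zero row: rank deficient
  expect_error(fit_observation_model(Xdef, Y), "rank deficient")
})

test_that("C estimate improves with more passive reaches", {
  m <- fix_tuning()
  C_true <- analytic_C(m)
  err <- sapply(c(5L, 80L), function(nr) {
    pas <- passive_observation_set(m, n_reaches = nr, seed = 31)
    fit <- fit_observation_model(pas$states, pas$counts)
    ## velocity columns carry the directional code; compare those
    sqrt(mean((fit$C[, 3:4] - C_true[, 3:4])^2))
  })
  expect_lt(err[2], err[1])
})

test_that("steady-state gain matches a brute-force Riccati oracle", {
  ## scalar: no process noise, Sigma_0 = W = 0 -> K = 0
  sc <- steady_state_gain(matrix(1), matrix(1), matrix(0), matrix(1))
  expect_equal(as.numeric(sc$K), 0)

  set.seed(4)
  A <- matrix(rnorm(25, sd = 0.3), 5, 5); diag(A) <- 0.6
  C <- matrix(rnorm(3 * 5), 3, 5)
  W <- crossprod(matrix(rnorm(25, sd = 0.4), 5, 5)) / 5
  Q <- crossprod(matrix(rnorm(9, sd = 0.6), 3, 3)) / 3 + diag(3) * 0.1
  got <- steady_state_gain(A, C, W, Q)
  ## independent long-run iteration, no convergence short-circuit
  Sigma <- W
  for (i in 1:1e5) {
    S <- C %*% Sigma %*% t(C) + Q
    K <- Sigma %*% t(C) %*% solve(S)
    Sigma <- A %*% (Sigma - K %*% C %*% Sigma) %*% t(A) + W
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  K_oracle <- Sigma %*% t(C) %*% solve(C %*% Sigma %*% t(C) + Q)
  expect_equal(got$K, K_oracle, tolerance = 1e-8)
  ## fixed point: one more Riccati step changes Sigma by < 1e-9 (Frobenius)
  S1 <- with(got, {
    K1 <- Sigma %*% t(C) %*% solve(C %*% Sigma %*% t(C) + Q)
    A %*% (Sigma - K1 %*% C %*% Sigma) %*% t(A) + W
  })
  expect_lt(sqrt(sum((S1 - got$Sigma)^2)), 1e-9)
  ## inflating observation noise attenuates the gain: exact elementwise in
  ## the scalar case, and in norm (overall and per state row) for the
  ## multivariate system, where individual entries may reshuffle slightly
  s1 <- steady_state_gain(matrix(0.9), matrix(1), matrix(1), matrix(1))
  s100 <- steady_state_gain(matrix(0.9), matrix(1), matrix(1), matrix(100))
  expect_lt(abs(as.numeric(s100$K)), abs(as.numeric(s1$K)))
  got100 <- steady_state_gain(A, C, W, Q * 100)
  expect_lt(sqrt(sum(got100$K^2)), sqrt(sum(got$K^2)))
  for (r in 1:5) expect_lte(sqrt(sum(got100$K[r, ]^2)),
                            sqrt(sum(got$K[r, ]^2)) + 1e-12)
})

test_that("derived dynamics follows A = (I - KC) A_tilde", {
  A_tilde <- kinematics_prior()
  C <- matrix(rnorm(40 * 5), 40, 5)
  expect_equal(derived_dynamics(A_tilde, matrix(0, 5, 40), C), A_tilde)
  ## KC = I  =>  A = 0
  K <- cbind(diag(5), matrix(0, 5, 35))
  C_id <- rbind(diag(5), matrix(0, 35, 5))
  expect_equal(derived_dynamics(A_tilde, K, C_id),
               matrix(0, 5, 5), tolerance = 1e-12)
  set.seed(6)
  K2 <- matrix(rnorm(5 * 40, sd = 0.05), 5, 40)
  expect_equal(derived_dynamics(A_tilde, K2, C),
               (diag(5) - K2 %*% C) %*% A_tilde)
  expect_error(derived_dynamics(A_tilde, K2[, 1:10], C), "shape")
})

test_that("decode step applies the rotated gain and restores the constant", {
  m <- fix_tuning()
  pas <- passive_observation_set(m, n_reaches = 5L, seed = 12)
  dec <- fit_kalman_decoder(pas)
  x <- c(1, 2, 0.5, -0.3, 1)
  y <- rpois(m$n_units, 2)
  expect_equal(decode_step(dec, x, y, theta = 0), decode_step(dec, x, y))
  expect_equal(decode_step(dec, x, y)[5], 1)
  expect_error(decode_step(dec, x, y[1:5]), "units")
  expect_error(decode_step(dec, x[1:3], y), "length 5")

  ## with raw (uncentered) observations, y = 0 reduces to x' = A x
  dec_raw <- fit_kalman_decoder(pas, center_observations = FALSE)
  expect_equal(decode_step(dec_raw, x, rep(0, m$n_units)),
               { v <- as.numeric(dec_raw$A %*% x); v[5] <- 1; v })

  ## linearity of the observation contribution
  y1 <- rpois(m$n_units, 2); y2 <- rpois(m$n_units, 3)
  base <- decode_step(dec, x, rep(0, m$n_units))
  d12 <- decode_step(dec, x, y1 + y2) - base
  d1 <- decode_step(dec, x, y1) - base
  d2 <- decode_step(dec, x, y2) - base
  expect_equal(d12[1:4], (d1 + d2)[1:4], tolerance = 1e-9)

  ## rotation preserves the speed of the gain output
  Ky <- dec$K %*% (y - dec$y0)
  rot <- rotation_block5(1.1) %*% Ky
  expect_equal(sqrt(sum(rot[3:4]^2)), sqrt(sum(Ky[3:4]^2)), tolerance = 1e-12)

  ## theta = 90 deg rotates the gain contribution by a quarter turn
  contrib0 <- decode_step(dec, x, y, 0) - as.numeric(dec$A %*% x)
  contrib90 <- decode_step(dec, x, y, pi / 2) - as.numeric(dec$A %*% x)
  expect_equal(contrib90[3:4],
               as.numeric(rotation_matrix(pi / 2) %*% contrib0[3:4]),
               tolerance = 1e-10)
})

test_that("decoder JSON round trip is lossless", {
  dec <- fix_kalman()
  path <- tempfile(fileext = ".json")
  write_kalman_model(dec, path)
  back <- read_kalman_model(path)
  for (nm in c("A_tilde", "C", "Q", "W", "K", "A")) {
    expect_equal(unclass(back[[nm]]), unclass(dec[[nm]]),
                 tolerance = 1e-15, ignore_attr = TRUE)
  }
  expect_equal(back$y0, dec$y0, tolerance = 1e-15)
  unlink(path)
})
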