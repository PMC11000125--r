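test_that("PCA matches a covariance eigendecomposition oracle", {
  set.seed(8)
  X <- matrix(rnorm(10 * 500), 10, 500)
  basis <- fit_pca(X, 2L)
  S <- stats::cov(t(X)) * (500 - 1) / 500   # ML covariance, matches SVD scaling
  eig <- eigen(S, symmetric = TRUE)
  for (j in 1:2) {
    v <- eig$vectors[, j]
    i <- which.max(abs(v)); if (v[i] < 0) v <- -v
    expect_equal(basis$components[, j], v, tolerance = 1e-8)
    expect_equal(basis$singular_values[j] / sqrt(500),
                 sqrt(eig$values[j]), tolerance = 1e-8)
  }
  ## orthonormality and ordering
  expect_equal(crossprod(basis$components), diag(2), tolerance = 1e-10)
  expect_true(all(diff(basis$singular_values) <= 1e-10))
})

test_that("PCA handles degenerate and complete cases", {
  ## colinear data: PC1 along the line, second singular value 0
  t_ <- seq(-1, 1, length.out = 50)
  line <- outer(c(3, 4, 0), t_) + c(1, 1, 1)
  basis <- fit_pca(line, 2L)
  expect_equal(abs(sum(basis$components[, 1] * c(3, 4, 0) / 5)), 1,
               tolerance = 1e-10)
  expect_lt(basis$singular_values[2], 1e-10)
  expect_error(fit_pca(matrix(1, 4, 10)), "constant")
  ## full-rank reconstruction
  set.seed(1)
  X <- matrix(rnorm(6 * 40), 6, 40)
  b6 <- fit_pca(X, 6L)
  sc <- project(b6, X)$scores
  expect_equal(b6$components %*% sc, X - rowMeans(X), tolerance = 1e-10)
})

test_that("projection centers, diagonalizes, and allows foreign bases", {
  set.seed(2)
  X <- matrix(rnorm(8 * 200), 8, 200)
  basis <- fit_pca(X, 3L)
  expect_equal(as.numeric(project(basis, matrix(basis$mean, ncol = 1))$scores),
               rep(0, 3), tolerance = 1e-12)
  sc <- project(basis, X)$scores
  cv <- stats::cov(t(sc))
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-8)
  Y <- matrix(rnorm(8 * 50), 8, 50)
  expect_silent(project(basis, Y))
  expect_error(project(basis, Y[1:5, ]), "dimension")
})

test_that("centroid geometry and adjacent gaps behave circularly", {
  sc <- matrix(c(1, 1, 1, 1, -2, -2, -2, -2), nrow = 2,
               dimnames = NULL)  # two clusters: (1,1) and (-2,-2)
  cen <- target_centroids(sc, target = c(1, 1, 2, 2), n_targets = 2L)
  expect_equal(cen$angle_deg[cen$target == 1], 45)
  expect_equal(circ_diff_deg(cen$angle_deg[2], cen$angle_deg[1]), 180)
  expect_error(target_centroids(sc, target = c(1, 1, 2, 2), n_targets = 3L),
               "target")

  octagon <- sapply(seq(0, 315, by = 45) * pi / 180,
                    function(a) c(cos(a), sin(a)))
  ceno <- target_centroids(cbind(octagon, octagon),
                           target = rep(1:8, 2), n_targets = 8L)
  gaps <- adjacent_centroid_angles(ceno)
  expect_equal(gaps, rep(45, 8), tolerance = 1e-10)

  set.seed(5)
  for (i in 1:20) {
    ang <- sort(runif(8, -180, 180))
    fake <- data.frame(target = 1:8, angle_deg = ang)
    expect_equal(sum(adjacent_centroid_angles(fake)), 360, tolerance = 1e-9)
  }
})

test_that("angular displacement uses the circular convention", {
  base <- data.frame(target = 1:8, angle_deg = seq(-180, 135, by = 45) + 1)
  same <- centroid_angular_displacement(base, base)
  expect_equal(same$per_target$displacement_deg, rep(0, 8))
  expect_equal(same$mean_deg, 0)
  rot <- base; rot$angle_deg <- wrap_angle_deg(base$angle_deg - 50)
  d <- centroid_angular_displacement(base, rot)
  expect_equal(d$mean_deg, -50)
  expect_equal(d$sd_deg, 0)
  b <- data.frame(target = 1, angle_deg = 179)
  a <- data.frame(target = 1, angle_deg = -179)
  expect_equal(centroid_angular_displacement(b, a)$per_target$displacement_deg, 2)
  expect_error(centroid_angular_displacement(base, base[1:4, ]), "roster|targets")
})

test_that("displacement regression recovers exact and null slopes", {
  th <- c(-110, -90, -50, 50, 90, 110)
  ## exact inputs make lm warn about a perfect fit; the contract is the
  ## coefficients, not the warning
  r <- suppressWarnings(regress_displacement(-th, th))
  expect_equal(r$slope, -1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  r0 <- regress_displacement(rep(0, 6), th)
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_error(regress_displacement(c(1, 2), c(10, 20)), "3 distinct")
})

test_that("normalized differences follow the session-mean normalization", {
  expect_equal(normalized_difference(c(5, 7), c(5, 7)), c(0, 0))
  expect_equal(normalized_difference(c(10, 20, 30), c(0, 0, 0)),
               c(0.5, 1.0, 1.5))
  d1 <- normalized_difference(c(10, 20, 30), c(4, 5, 6))
  d2 <- normalized_difference(2 * c(10, 20, 30), 2 * c(4, 5, 6))
  expect_equal(d1, d2)
  expect_equal(normalized_difference(c(4, 5, 6), c(10, 20, 30)),
               (c(4, 5, 6) - c(10, 20, 30)) / mean(c(4, 5, 6)))
  expect_error(normalized_difference(c(1, -1), c(0, 0)), "zero")
})

test_that("swapping baseline and rotated negates d when rosters share the mean", {
  ## antisymmetry of the numerator: with the same normalizing condition the
  ## sign flips exactly
  fb <- c(12, 8, 15); fr <- c(9, 10, 14)
  d_fwd <- normalized_difference(fb, fr)
  d_rev <- normalized_difference(fr, fb)
  expect_equal(d_fwd * mean(fb), -d_rev * mean(fr))
})

test_that("absolute cosine similarity is sign-invariant and bounded", {
  v <- c(1, 2, 3)
  expect_equal(abs_cosine_similarity(v, v), 1)
  expect_equal(abs_cosine_similarity(v, -v), 1)
  expect_equal(abs_cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(abs_cosine_similarity(v, c(0, 0, 0)), "zero")
  set.seed(3)
  for (i in 1:50) {
    a <- rnorm(10); b <- rnorm(10)
    s <- abs_cosine_similarity(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_gt(abs_cosine_similarity(v, 3.7 * v), 1 - 1e-12)
})

test_that("manifold report is exact on identical data and propagates ids", {
  set.seed(9)
  X <- matrix(rpois(20 * 300, 4), 20, 300)
  rep_ <- manifold_preservation_report(list(X), list(X))
  expect_equal(rep_$sim_mean, 1)
  expect_equal(rep_$sim_pc1, 1)
  expect_equal(rep_$sim_pc2, 1)
  expect_equal(rep_$mean_abs_d, 0)
  expect_error(manifold_preservation_report(list(X), list(matrix(1, 20, 10))),
               "pair 1")
  shared <- manifold_preservation_report(list(X), list(X + 0), mode = "shared_basis")
  expect_equal(shared$sim_pc1, 1)
})

test_that("one-way ANOVA matches a hand-coded sum-of-squares oracle", {
  g_id <- compare_group_means(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(g_id$F, 0, tolerance = 1e-12)
  expect_equal(g_id$p, 1, tolerance = 1e-12)

  set.seed(10)
  big <- compare_group_means(list(rnorm(50, 0), rnorm(50, 10)))
  expect_lt(big$p, 0.001)

  groups <- list(c(1.2, 0.8, 1.5, 1.1), c(2.0, 2.3, 1.7), c(0.2, 0.5, 0.1, 0.4, 0.3))
  got <- compare_group_means(groups)
  ## brute-force sums of squares
  all_v <- unlist(groups); gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1; dfw <- length(all_v) - length(groups)
  F_oracle <- (ssb / dfb) / (ssw / dfw)
  expect_equal(got$F, F_oracle, tolerance = 1e-10)
  expect_equal(got$p, stats::pf(F_oracle, dfb, dfw, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(compare_group_means(list(c(1, 2))), "2 groups")
})

test_that("identically distributed before/after gives near-zero displacement", {
  ses <- fix_session_50()
  act0 <- session_activity(ses, thetas_deg = 0)
  n <- ncol(act0$values)
  odd <- seq(1, n, by = 2); even <- seq(2, n, by = 2)
  split_act <- function(idx) structure(list(values = act0$values[, idx],
                                            target = act0$target[idx],
                                            theta_deg = act0$theta_deg[idx]),
                                       class = "activity_matrix")
  d <- activity_displacement(split_act(odd), split_act(even))
  expect_lt(abs(d$displacement$mean_deg), 5)
})

test_that("baseline centroids are arranged in the targets' cyclic order", {
  ses <- fix_session_50()
  disp <- session_displacement(ses)
  cen <- disp$centroids_before
  steps <- circ_diff_deg(cen$angle_deg[c(2:8, 1)], cen$angle_deg)
  ## counter-clockwise progression in target order after orientation fix
  expect_true(all(steps > 0))
  expect_equal(sum(steps), 360, tolerance = 1e-9)
  ## and the rotated block's centroids are displaced by about -theta
  expect_lt(abs(disp$displacement$mean_deg - (-50)), 10)
})
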