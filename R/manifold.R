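## Low-dimensional manifold analysis: PCA of the units x observations
## activity matrix, per-target centroid geometry in the PC1-PC2 plane,
## centroid angular displacement under imposed rotations, normalized
## activity differences, and cosine-similarity comparisons of manifolds
## fit separately before and after a perturbation.

#' Fit a PCA basis to an activity matrix
#'
#' Mean-centers the observations (columns) and takes the singular value
#' decomposition. Component signs are fixed by the
#' largest-magnitude-loading-positive rule so bases are comparable across
#' fits.
#'
#' @param activity an `activity_matrix` (see [session_activity()]) or a
#'   plain units x observations matrix.
#' @param n_components number of components to retain (default 2: the task
#'   is two-dimensional and activity in this plane is isomorphic with it).
#' @return a `pca_basis`: `mean` (per-unit), `components` (units x
#'   n_components, orthonormal columns), `singular_values` (non-increasing).
#' @export
fit_pca <- function(activity, n_components = 2L) {
  X <- if (inherits(activity, "activity_matrix")) activity$values else activity
  stopifnot(is.matrix(X))
  if (ncol(X) <= n_components)
    stop("need more observations than components", call. = FALSE)
  if (n_components < 2L) stop("n_components must be >= 2", call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  if (all(abs(Xc) < 1e-12))
    stop("activity matrix is constant; PCA is undefined", call. = FALSE)
  sv <- svd(Xc, nu = n_components, nv = 0)
  comps <- sv$u
  ## sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(comps))) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(list(mean = mu, components = comps,
                 singular_values = sv$d[seq_len(n_components)],
                 n_obs = ncol(X)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA basis: %d units, %d components, %d observations\n",
              length(x$mean), ncol(x$components), x$n_obs))
  cat("  singular values:", format(x$singular_values, digits = 4), "\n")
  invisible(x)
}

#' Project activity onto a PCA basis
#'
#' Scores are `components' (values - mean)`; labels are carried through.
#' Projecting with a basis fit on other data is permitted (shared-basis
#' mode).
#'
#' @param basis a `pca_basis`.
#' @param activity an `activity_matrix` or plain matrix with matching unit
#'   dimension.
#' @return list with `scores` (components x observations) and the labels of
#'   `activity` when present.
#' @export
project <- function(basis, activity) {
  X <- if (inherits(activity, "activity_matrix")) activity$values else activity
  if (nrow(X) != length(basis$mean))
    stop("unit dimension of activity does not match the basis", call. = FALSE)
  scores <- t(basis$components) %*% (X - basis$mean)
  out <- list(scores = scores)
  if (inherits(activity, "activity_matrix")) {
    out$target <- activity$target
    out$theta_deg <- activity$theta_deg
  }
  out
}

#' Per-target centroids in the PC1-PC2 plane
#'
#' @param scores components x observations score matrix (or the list from
#'   [project()]).
#' @param target per-observation target labels (taken from `scores` when it
#'   is a [project()] result).
#' @param n_targets expected number of targets.
#' @return a `centroid_set`: data.frame with `target`, `pc1`, `pc2`,
#'   `angle_deg` (atan2(PC2, PC1) in (-180, 180]), `n_obs`.
#' @export
target_centroids <- function(scores, target = NULL, n_targets = 8L) {
  if (is.list(scores) && !is.null(scores$scores)) {
    target <- target %||% scores$target
    scores <- scores$scores
  }
  stopifnot(!is.null(target), ncol(scores) == length(target))
  ids <- sort(unique(target))
  missing <- setdiff(seq_len(n_targets), ids)
  if (length(missing) > 0L)
    stop("no observations for target(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(ids, function(k) {
    sel <- target == k
    if (sum(sel) < 2L)
      stop("target ", k, " has fewer than 2 observations", call. = FALSE)
    ctr <- rowMeans(scores[1:2, sel, drop = FALSE])
    data.frame(target = k, pc1 = ctr[1], pc2 = ctr[2],
               angle_deg = wrap_angle_deg(rad2deg(atan2(ctr[2], ctr[1]))),
               n_obs = sum(sel))
  })
  structure(do.call(rbind, rows), class = c("centroid_set", "data.frame"))
}

#' Angular gaps between adjacent centroids
#'
#' Sorts the centroids by angle and returns the consecutive circular
#' differences; the gaps always sum to 360 degrees.
#'
#' @param centroids a `centroid_set`.
#' @return numeric vector of gaps in degrees (one per centroid).
#' @export
adjacent_centroid_angles <- function(centroids) {
  ang <- sort(centroids$angle_deg)
  if (anyDuplicated(ang))
    stop("coincident centroid angles; adjacent gaps are undefined", call. = FALSE)
  gaps <- diff(c(ang, ang[1] + 360))
  gaps
}

#' Centroid angular displacement between two conditions
#'
#' Per-target circular difference (after minus before) of centroid angles in
#' a shared PC1-PC2 plane, wrapped to (-180, 180], with the circular mean and
#' standard deviation across targets.
#'
#' @param before,after `centroid_set`s over the same target roster.
#' @return list with `per_target` (data.frame: target, displacement_deg),
#'   `mean_deg` (circular mean), `sd_deg`.
#' @export
centroid_angular_displacement <- function(before, after) {
  if (!identical(sort(before$target), sort(after$target)))
    stop("before/after centroid sets cover different targets", call. = FALSE)
  b <- before[order(before$target), ]
  a <- after[order(after$target), ]
  d <- circ_diff_deg(a$angle_deg, b$angle_deg)
  m <- circ_mean_deg(d)
  list(per_target = data.frame(target = b$target, displacement_deg = d),
       mean_deg = m,
       sd_deg = stats::sd(circ_diff_deg(d, m)))
}

#' Regression of mean centroid displacement on imposed rotation
#'
#' Ordinary least squares of mean angular displacement (signed degrees) on
#' the imposed decoder rotation angle. Adaptation that exactly cancels the
#' rotation gives slope -1.
#'
#' @param displacements per-condition mean displacements (degrees).
#' @param thetas_deg imposed rotations (signed degrees, counter-clockwise
#'   positive).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, and the
#'   underlying `lm` fit.
#' @export
regress_displacement <- function(displacements, thetas_deg) {
  if (length(displacements) != length(thetas_deg))
    stop("displacements and thetas differ in length", call. = FALSE)
  if (length(unique(thetas_deg)) < 3L)
    stop("need at least 3 distinct rotation angles", call. = FALSE)
  fit <- stats::lm(displacements ~ thetas_deg)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) >= 2L && ncol(sm$coefficients) >= 4L)
    sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, fit = fit)
}

#' Normalized per-unit activity difference
#'
#' \deqn{d_i = \frac{\bar f_{b,i} - \bar f_{r,i}}{\frac{1}{N}\sum_j \bar f_{b,j}}}
#' the difference between baseline and post-rotation temporal means,
#' normalized by the session-mean baseline activity.
#'
#' @param baseline_means,rotated_means per-unit temporally averaged activity
#'   for the same unit roster.
#' @return per-unit vector of normalized differences.
#' @export
normalized_difference <- function(baseline_means, rotated_means) {
  if (length(baseline_means) != length(rotated_means))
    stop("unit rosters differ", call. = FALSE)
  denom <- mean(baseline_means)
  if (abs(denom) < .Machine$double.eps)
    stop("session-mean baseline activity is zero; normalization undefined",
         call. = FALSE)
  (baseline_means - rotated_means) / denom
}

#' Absolute cosine similarity
#'
#' `|v_b . v_a| / (||v_b|| ||v_a||)`; sign-invariant, as required when
#' comparing principal components whose sign is arbitrary. Scaling either
#' vector (e.g. principal components by their singular values) cannot change
#' the value; the scaling is nevertheless applied upstream so that reported
#' vectors match what is compared.
#'
#' @param v_before,v_after nonzero numeric vectors of equal length.
#' @return scalar in \[0, 1\].
#' @export
abs_cosine_similarity <- function(v_before, v_after) {
  nb <- sqrt(sum(v_before^2)); na <- sqrt(sum(v_after^2))
  if (nb == 0 || na == 0) stop("cosine similarity undefined for zero vectors",
                               call. = FALSE)
  abs(sum(v_before * v_after)) / (nb * na)
}

## Fit separate 2-component bases before/after and compare mean + scaled PCs.
compare_manifolds_once <- function(before, after) {
  pb <- fit_pca(before, 2L)
  pa <- fit_pca(after, 2L)
  Xb <- if (inherits(before, "activity_matrix")) before$values else before
  Xa <- if (inherits(after, "activity_matrix")) after$values else after
  mb <- rowMeans(Xb); ma <- rowMeans(Xa)
  spc_b <- pb$components %*% diag(pb$singular_values / sqrt(pb$n_obs))
  spc_a <- pa$components %*% diag(pa$singular_values / sqrt(pa$n_obs))
  list(sim_mean = abs_cosine_similarity(mb, ma),
       sim_pc1 = abs_cosine_similarity(spc_b[, 1], spc_a[, 1]),
       sim_pc2 = abs_cosine_similarity(spc_b[, 2], spc_a[, 2]),
       d_mean = normalized_difference(mb, ma),
       d_pc1 = normalized_difference(abs(spc_b[, 1]), abs(spc_a[, 1])),
       d_pc2 = normalized_difference(abs(spc_b[, 2]), abs(spc_a[, 2])))
}

#' Manifold-preservation report over session pairs
#'
#' For each before/after pair of activity matrices, fits PCA separately on
#' the two conditions (`separate_basis` mode, the manifold-preservation
#' question) or once on the pooled data (`shared_basis`), then computes the
#' absolute cosine similarity of the mean activity and of the first two
#' principal components scaled by their singular values, together with
#' normalized-difference summaries (both mean |d_i| and mean d_i are
#' reported).
#'
#' @param before_list,after_list lists of `activity_matrix` (or plain
#'   matrices), paired by position.
#' @param mode `"separate_basis"` or `"shared_basis"`.
#' @return a `manifold_report`: data.frame with one row per pair
#'   (`sim_mean`, `sim_pc1`, `sim_pc2`, `mean_abs_d`, `mean_d`,
#'   `mean_abs_d_pc1`, `mean_abs_d_pc2`).
#' @export
manifold_preservation_report <- function(before_list, after_list,
                                         mode = c("separate_basis", "shared_basis")) {
  mode <- match.arg(mode)
  if (length(before_list) != length(after_list) || length(before_list) < 1L)
    stop("need >= 1 paired before/after sessions", call. = FALSE)
  rows <- lapply(seq_along(before_list), function(i) {
    res <- tryCatch({
      b <- before_list[[i]]; a <- after_list[[i]]
      if (mode == "shared_basis") {
        ## one basis for both conditions: PC directions are common by
        ## construction (their similarity is exactly 1; scaling by
        ## per-condition singular values cannot change a cosine), so the
        ## informative entries are the mean similarity and the normalized
        ## differences.
        Xb <- if (inherits(b, "activity_matrix")) b$values else b
        Xa <- if (inherits(a, "activity_matrix")) a$values else a
        basis <- fit_pca(cbind(Xb, Xa), 2L)
        mb <- rowMeans(Xb); ma <- rowMeans(Xa)
        sd_b <- apply(t(basis$components) %*% (Xb - basis$mean), 1, stats::sd)
        sd_a <- apply(t(basis$components) %*% (Xa - basis$mean), 1, stats::sd)
        spc_b <- basis$components %*% diag(sd_b)
        spc_a <- basis$components %*% diag(sd_a)
        list(sim_mean = abs_cosine_similarity(mb, ma),
             sim_pc1 = abs_cosine_similarity(spc_b[, 1], spc_a[, 1]),
             sim_pc2 = abs_cosine_similarity(spc_b[, 2], spc_a[, 2]),
             d_mean = normalized_difference(mb, ma),
             d_pc1 = normalized_difference(abs(spc_b[, 1]), abs(spc_a[, 1])),
             d_pc2 = normalized_difference(abs(spc_b[, 2]), abs(spc_a[, 2])))
      } else compare_manifolds_once(b, a)
    }, error = function(e) stop("session pair ", i, ": ", conditionMessage(e),
                                call. = FALSE))
    data.frame(pair = i,
               sim_mean = res$sim_mean, sim_pc1 = res$sim_pc1,
               sim_pc2 = res$sim_pc2,
               mean_abs_d = mean(abs(res$d_mean)), mean_d = mean(res$d_mean),
               mean_abs_d_pc1 = mean(abs(res$d_pc1)),
               mean_abs_d_pc2 = mean(abs(res$d_pc2)))
  })
  structure(do.call(rbind, rows), class = c("manifold_report", "data.frame"))
}

#' One-way ANOVA across groups of normalized differences
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
compare_group_means <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"])
}

## Orient a score plane so that the baseline centroids run counter-clockwise
## in increasing target order: the handedness of an SVD plane is arbitrary,
## and a reflected plane would flip the sign of every angular displacement.
## Returns +1 (keep) or -1 (flip PC2).
plane_orientation <- function(centroids) {
  b <- centroids[order(centroids$target), ]
  steps <- circ_diff_deg(b$angle_deg[c(2:nrow(b), 1)], b$angle_deg)
  if (sum(steps > 0) >= sum(steps < 0)) 1 else -1
}

#' Shared-basis centroid displacement between two activity conditions
#'
#' Fits one PCA on the pooled before/after activity (shared-basis mode),
#' orients the plane so the baseline centroids run counter-clockwise in
#' target order (the handedness of an SVD plane is arbitrary and would
#' otherwise randomize the sign of the displacement), computes per-condition
#' centroids and the per-target and mean angular displacement.
#'
#' @param before,after `activity_matrix` objects over the same targets.
#' @return list with `displacement` (see
#'   [centroid_angular_displacement()]), `centroids_before`,
#'   `centroids_after`, `basis`.
#' @export
activity_displacement <- function(before, after) {
  pooled <- structure(list(values = cbind(before$values, after$values),
                           target = c(before$target, after$target),
                           theta_deg = c(before$theta_deg, after$theta_deg)),
                      class = "activity_matrix")
  basis <- fit_pca(pooled, 2L)
  sc_b <- project(basis, before)
  sc_a <- project(basis, after)
  cen_b <- target_centroids(sc_b)
  if (plane_orientation(cen_b) < 0) {
    basis$components[, 2] <- -basis$components[, 2]
    sc_b$scores[2, ] <- -sc_b$scores[2, ]
    sc_a$scores[2, ] <- -sc_a$scores[2, ]
    cen_b <- target_centroids(sc_b)
  }
  cen_a <- target_centroids(sc_a)
  list(displacement = centroid_angular_displacement(cen_b, cen_a),
       centroids_before = cen_b, centroids_after = cen_a, basis = basis)
}

#' Centroid displacement analysis for one rotation session
#'
#' Convenience wrapper around [activity_displacement()] for a
#' baseline-then-rotation `session_record`.
#'
#' @param session a `session_record` whose schedule contains a theta = 0
#'   block and one rotated block.
#' @param theta_deg the rotated block's angle (taken from the schedule when
#'   unique).
#' @return as [activity_displacement()], plus `theta_deg`.
#' @export
session_displacement <- function(session, theta_deg = NULL) {
  thetas <- vapply(session$schedule, `[[`, numeric(1), "theta_deg")
  if (is.null(theta_deg)) {
    nz <- setdiff(thetas, 0)
    if (length(nz) != 1L)
      stop("session has no unique rotated block; pass theta_deg", call. = FALSE)
    theta_deg <- nz
  }
  out <- activity_displacement(session_activity(session, thetas_deg = 0),
                               session_activity(session, thetas_deg = theta_deg))
  out$theta_deg <- theta_deg
  out
}

#' Plot per-target centroids in the PC1-PC2 plane
#'
#' @param x a `centroid_set`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.centroid_set <- function(x, ...) {
  graphics::plot(x$pc1, x$pc2, pch = 18, cex = 1.6,
                 col = grDevices::hcl.colors(nrow(x), "Dark 2"),
                 xlab = "PC1", ylab = "PC2", asp = 1, ...)
  graphics::text(x$pc1, x$pc2, labels = x$target, pos = 3, cex = 0.8)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  invisible(x)
}
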