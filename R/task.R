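#' Center-out task configuration
#'
#' Eight targets radially distributed at uniform 45-degree separation and
#' fixed distance from the center. A trial succeeds when the cursor stays
#' within `target_radius` of the cued target for `hold_bins` consecutive bins
#' before the `max_bins_per_trial` timeout.
#'
#' @param target_distance center-to-target distance (workspace units).
#' @param target_radius acceptance radius (must be < distance).
#' @param hold_bins consecutive in-target bins required (>= 1).
#' @param max_bins_per_trial timeout in bins (100 bins of 100 ms = 10 s).
#' @param bin_width bin width in seconds.
#' @param intent_speed intended movement speed while outside the target
#'   (units/s).
#' @return a `task_config` object.
#' @export
task_config <- function(target_distance = 10, target_radius = 1.5,
                        hold_bins = 2L, max_bins_per_trial = 100L,
                        bin_width = 0.1, intent_speed = 6) {
  stopifnot(target_radius < target_distance, hold_bins >= 1L)
  angles <- seq(0, 315, by = 45)
  structure(list(n_targets = 8L, target_angles_deg = angles,
                 target_distance = target_distance, target_radius = target_radius,
                 hold_bins = as.integer(hold_bins),
                 max_bins_per_trial = as.integer(max_bins_per_trial),
                 bin_width = bin_width, intent_speed = intent_speed),
            class = "task_config")
}

target_position <- function(config, target_id) {
  phi <- deg2rad(config$target_angles_deg[target_id])
  config$target_distance * c(cos(phi), sin(phi))
}

#' Run one closed-loop trial
#'
#' Per bin: the agent forms an intent pointing from the current cursor
#' position to the target at constant speed (zero speed once inside the
#' target), re-aims it according to `policy`, the population emits spike
#' counts, and the decoder updates the cursor with the block's imposed
#' rotation.
#'
#' @param config a [task_config()].
#' @param tuning a `tuning_model`.
#' @param kalman a `kalman_model`.
#' @param policy an [adaptation_policy()]; its `imposed_rotation` is also the
#'   decoder perturbation applied during the trial.
#' @param target_id target index in 1..8.
#' @param noise sample Poisson counts (`TRUE`) or use noise-free expected
#'   counts (`FALSE`).
#' @return a `trial_record`: per-bin `counts` (units x bins), `states`
#'   (5 x bins, state before each decode step), `moving` flags, `success`,
#'   `duration_bins`, `target_id`, `theta_deg`.
#' @export
run_trial <- function(config, tuning, kalman, policy, target_id, noise = TRUE) {
  if (!is.numeric(target_id) || length(target_id) != 1L ||
      target_id < 1 || target_id > config$n_targets)
    stop("target_id must index one of the 8 targets", call. = FALSE)
  tgt <- target_position(config, target_id)
  theta <- policy$imposed_rotation
  x <- c(0, 0, 0, 0, 1)
  nmax <- config$max_bins_per_trial
  counts <- matrix(0L, tuning$n_units, nmax)
  states <- matrix(0, 5L, nmax)
  moving <- logical(nmax)
  hold <- 0L
  success <- FALSE
  b <- 0L
  while (b < nmax) {
    b <- b + 1L
    pos <- x[1:2]
    delta <- tgt - pos
    dist <- sqrt(sum(delta^2))
    in_target <- dist <= config$target_radius
    v_int <- if (in_target) c(0, 0) else config$intent_speed * delta / dist
    intent <- reaim(intent_state(v_int), policy)
    rates <- expected_rates(tuning, intent)
    y <- if (noise) sample_spikes(rates, tuning$bin_width) else rates * tuning$bin_width
    states[, b] <- x
    counts[, b] <- y
    moving[b] <- !in_target
    x <- decode_step(kalman, x, y, theta)
    if (sqrt(sum((tgt - x[1:2])^2)) <= config$target_radius) {
      hold <- hold + 1L
      if (hold >= config$hold_bins) { success <- TRUE; break }
    } else hold <- 0L
  }
  structure(list(target_id = target_id,
                 theta_deg = rad2deg(theta),
                 counts = counts[, seq_len(b), drop = FALSE],
                 states = states[, seq_len(b), drop = FALSE],
                 moving = moving[seq_len(b)],
                 success = success, duration_bins = b),
            class = "trial_record")
}

#' Run a baseline-then-rotation session
#'
#' Executes a schedule of blocks. Each block fixes an imposed decoder
#' rotation and a compensation fraction; targets are cycled in balanced
#' pseudorandom order within the block. All trials, including failures, are
#' recorded.
#'
#' @param config a [task_config()].
#' @param tuning a `tuning_model`.
#' @param kalman a `kalman_model`.
#' @param schedule list of blocks, each a list with `theta_deg`,
#'   `trials_per_target`, and `compensation` (re-aiming fraction).
#' @param seed integer seed for target order and spiking noise.
#' @param noise Poisson noise on (default) or off.
#' @return a `session_record`: list of trials plus block bookkeeping.
#' @export
run_session <- function(config, tuning, kalman, schedule, seed = NULL, noise = TRUE) {
  if (length(schedule) == 0L) stop("schedule must contain at least one block", call. = FALSE)
  with_seed(seed, {
    trials <- list()
    block_label <- character(0)
    for (bi in seq_along(schedule)) {
      blk <- schedule[[bi]]
      pol <- adaptation_policy(blk$compensation %||% 1, blk$theta_deg)
      order <- sample(rep(seq_len(config$n_targets), blk$trials_per_target))
      for (tg in order) {
        tr <- run_trial(config, tuning, kalman, pol, tg, noise = noise)
        tr$block <- bi
        trials[[length(trials) + 1L]] <- tr
      }
      block_label[bi] <- sprintf("theta=%g", blk$theta_deg)
    }
    structure(list(trials = trials, schedule = schedule, config = config,
                   seed = seed, n_units = tuning$n_units,
                   block_label = block_label),
              class = "session_record")
  })
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Closed-loop BCI session: %d trials, %d blocks, %d units\n",
              length(x$trials), length(x$schedule), x$n_units))
  for (bi in seq_along(x$schedule)) {
    tr <- Filter(function(t) t$block == bi, x$trials)
    succ <- mean(vapply(tr, `[[`, logical(1), "success"))
    cat(sprintf("  block %d (%s): %d trials, success %.0f%%\n",
                bi, x$block_label[bi], length(tr), 100 * succ))
  }
  invisible(x)
}

#' Per-condition success rates
#'
#' @param session a `session_record`.
#' @return data.frame with `theta_deg`, `n_trials`, `success_rate`.
#' @export
session_success <- function(session) {
  th <- vapply(session$trials, `[[`, numeric(1), "theta_deg")
  sc <- vapply(session$trials, `[[`, logical(1), "success")
  agg <- tapply(sc, th, mean)
  data.frame(theta_deg = as.numeric(names(agg)),
             n_trials = as.integer(table(th)),
             success_rate = as.numeric(agg))
}

#' Trial-duration summary per condition
#'
#' Mean and standard deviation of successful-trial durations in seconds,
#' per imposed rotation. Conditions with no successful trial are excluded
#' with a warning.
#'
#' @param session a `session_record`.
#' @return data.frame with `theta_deg`, `n_success`, `mean_s`, `sd_s`.
#' @export
trial_duration_summary <- function(session) {
  th <- vapply(session$trials, `[[`, numeric(1), "theta_deg")
  sc <- vapply(session$trials, `[[`, logical(1), "success")
  du <- vapply(session$trials, `[[`, numeric(1), "duration_bins")
  out <- lapply(sort(unique(th)), function(t) {
    ok <- th == t & sc
    if (!any(ok)) {
      warning(sprintf("condition theta=%g has no successful trials; excluded", t),
              call. = FALSE)
      return(NULL)
    }
    secs <- du[ok] * session$config$bin_width
    data.frame(theta_deg = t, n_success = sum(ok),
               mean_s = mean(secs), sd_s = stats::sd(secs))
  })
  do.call(rbind, out)
}

#' Extract the population-activity matrix from a session
#'
#' Collects per-bin spike counts into the units x observations matrix used by
#' the manifold analysis, with per-observation target and condition labels.
#' By default only successful trials contribute and only movement-epoch bins
#' (cursor outside the target) are kept.
#'
#' @param session a `session_record`.
#' @param thetas_deg restrict to these imposed rotations (default all).
#' @param successful_only drop failed trials.
#' @param moving_only drop hold-period bins.
#' @return an `activity_matrix`: list with `values` (units x obs), `target`
#'   and `theta_deg` per-observation labels.
#' @export
session_activity <- function(session, thetas_deg = NULL, successful_only = TRUE,
                             moving_only = TRUE) {
  keep <- vapply(session$trials, function(tr) {
    (!successful_only || tr$success) &&
      (is.null(thetas_deg) || any(abs(tr$theta_deg - thetas_deg) < 1e-9))
  }, logical(1))
  trs <- session$trials[keep]
  if (length(trs) == 0L) stop("no trials match the requested conditions", call. = FALSE)
  vals <- list(); tgt <- list(); th <- list()
  for (tr in trs) {
    sel <- if (moving_only) tr$moving else rep(TRUE, ncol(tr$counts))
    if (!any(sel)) next
    vals[[length(vals) + 1L]] <- tr$counts[, sel, drop = FALSE]
    tgt[[length(tgt) + 1L]] <- rep(tr$target_id, sum(sel))
    th[[length(th) + 1L]] <- rep(tr$theta_deg, sum(sel))
  }
  structure(list(values = do.call(cbind, vals),
                 target = unlist(tgt), theta_deg = unlist(th)),
            class = "activity_matrix")
}

#' Write session artifacts as plain-text files
#'
#' Writes the spike-count matrix CSV (one row per bin: unit counts, then
#' `target_id`, `trial_id`, `theta_deg`, `success`, `moving`), a trials CSV,
#' and a JSON manifest with seeds and configuration.
#'
#' @param session a `session_record`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named list of written paths, invisibly.
#' @export
write_session <- function(session, dir, prefix = "session") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); meta <- list()
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    df <- as.data.frame(t(tr$counts))
    names(df) <- sprintf("unit_%03d", seq_len(nrow(tr$counts)))
    df$target_id <- tr$target_id
    df$trial_id <- i
    df$theta_deg <- tr$theta_deg
    df$success <- tr$success
    df$moving <- tr$moving
    rows[[i]] <- df
    meta[[i]] <- data.frame(trial_id = i, target_id = tr$target_id,
                            theta_deg = tr$theta_deg, success = tr$success,
                            duration_bins = tr$duration_bins)
  }
  counts_path <- file.path(dir, paste0(prefix, "_counts.csv"))
  trials_path <- file.path(dir, paste0(prefix, "_trials.csv"))
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.json"))
  utils::write.csv(do.call(rbind, rows), counts_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, meta), trials_path, row.names = FALSE)
  jsonlite::write_json(list(seed = session$seed, n_units = session$n_units,
                            bin_width = session$config$bin_width,
                            schedule = session$schedule),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(counts = counts_path, trials = trials_path, manifest = manifest_path))
}

#' Read an activity matrix from a spike-count CSV
#'
#' Reads the columnar dialect written by [write_session()] (also used for
#' reinforcement-learning activations): unit/activation columns followed by
#' label columns.
#'
#' @param path CSV path.
#' @param successful_only,moving_only row filters (applied when the columns
#'   are present).
#' @return an `activity_matrix`.
#' @export
read_activity_csv <- function(path, successful_only = TRUE, moving_only = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  label_cols <- intersect(c("target_id", "trial_id", "theta_deg", "success", "moving"),
                          names(df))
  unit_cols <- setdiff(names(df), label_cols)
  keep <- rep(TRUE, nrow(df))
  if (successful_only && "success" %in% names(df)) keep <- keep & df$success
  if (moving_only && "moving" %in% names(df)) keep <- keep & df$moving
  df <- df[keep, , drop = FALSE]
  structure(list(values = t(as.matrix(df[, unit_cols, drop = FALSE])),
                 target = df$target_id,
                 theta_deg = if ("theta_deg" %in% names(df)) df$theta_deg else
                   rep(NA_real_, nrow(df))),
            class = "activity_matrix")
}
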