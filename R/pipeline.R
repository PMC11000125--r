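## End-to-end experiment orchestration: simulate the adapting-agent sessions
## across a rotation series, train/retrain the RL agent, and run the manifold
## analysis on both, from a single validated config with derived per-stage
## seeds and a checksummed run manifest.

experiment_defaults <- function() {
  list(
    rotations_deg = c(50, -50, 90, -90, 110, -110),
    compensation = 1,
    n_units = 40L,
    trials_per_target = 20L,
    sessions_per_rotation = 3L,
    n_baseline_sessions = 10L,
    master_seed = 1L,
    include_rl = TRUE,
    rl_rotations_deg = c(50, -50, 110, -110),
    rl_baseline_steps = 300000L,
    rl_retrain_steps = 150000L,
    rl_episodes_per_target = 20L,
    out_dir = NULL
  )
}

#' Validate and normalize an experiment configuration
#'
#' Fills defaults, converts rotations given in 0-360 convention to signed
#' degrees (e.g. 310 becomes -50), checks ranges, and derives per-stage seeds
#' from the master seed. Unknown keys are an error.
#'
#' @param config named list of overrides of the defaults (see
#'   [run_experiment()]).
#' @return normalized `experiment_config` with all defaults filled and a
#'   `seeds` element.
#' @export
validate_config <- function(config = list()) {
  defaults <- experiment_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errors <- character(0)
  if (length(unknown) > 0L)
    errors <- c(errors, paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  cfg$rotations_deg <- wrap_angle_deg(cfg$rotations_deg)
  cfg$rl_rotations_deg <- wrap_angle_deg(cfg$rl_rotations_deg)
  if (length(cfg$rotations_deg) == 0L)
    errors <- c(errors, "rotation list must not be empty")
  if (any(cfg$rotations_deg == 0))
    errors <- c(errors, "rotations must be nonzero (baseline blocks are implicit)")
  if (cfg$compensation < 0 || cfg$compensation > 1)
    errors <- c(errors, "compensation must lie in [0, 1]")
  if (cfg$n_units < 3) errors <- c(errors, "n_units must be >= 3")
  if (length(errors) > 0L)
    stop(paste(errors, collapse = "; "), call. = FALSE)
  cfg$seeds <- list(
    gaps = derive_seed(cfg$master_seed, "gaps"),
    rotation = derive_seed(cfg$master_seed, "rotation"),
    rl = derive_seed(cfg$master_seed, "rl"))
  structure(cfg, class = "experiment_config")
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(json, f)
  unname(tools::md5sum(f))
}

## One adapting-agent session: fresh population + decoder + baseline block
## followed (optionally) by a rotation block.
simulate_nhp_session <- function(theta_deg, cfg, seed) {
  tun <- make_tuning(cfg$n_units, seed = derive_seed(seed, "tuning"))
  pas <- passive_observation_set(tun, n_reaches = 10L,
                                 seed = derive_seed(seed, "passive"))
  kal <- fit_kalman_decoder(pas)
  sched <- list(list(theta_deg = 0, trials_per_target = cfg$trials_per_target,
                     compensation = cfg$compensation))
  if (theta_deg != 0)
    sched[[2]] <- list(theta_deg = theta_deg,
                       trials_per_target = cfg$trials_per_target,
                       compensation = cfg$compensation)
  run_session(task_config(), tun, kal, sched,
              seed = derive_seed(seed, "session"))
}

#' Pooled adjacent-centroid gap distribution over baseline sessions
#'
#' Simulates `n_sessions` independent baseline sessions and pools the 8
#' circular gaps between angularly adjacent per-target PCA centroids.
#'
#' @param cfg a validated `experiment_config` (or overrides list).
#' @param n_sessions number of sessions (defaults to the config value).
#' @param seed base seed (defaults to the derived stage seed).
#' @return list with `gaps` (pooled degrees), `mean`, `sd`, `n_sessions`.
#' @export
baseline_gap_distribution <- function(cfg = list(), n_sessions = NULL, seed = NULL) {
  if (!inherits(cfg, "experiment_config")) cfg <- validate_config(cfg)
  n_sessions <- n_sessions %||% cfg$n_baseline_sessions
  seed <- seed %||% cfg$seeds$gaps
  gaps <- unlist(lapply(seq_len(n_sessions), function(i) {
    ses <- simulate_nhp_session(0, cfg, derive_seed(seed, paste0("s", i)))
    act <- session_activity(ses)
    cen <- target_centroids(project(fit_pca(act), act))
    adjacent_centroid_angles(cen)
  }))
  list(gaps = gaps, mean = mean(gaps), sd = stats::sd(gaps),
       n_sessions = n_sessions)
}

#' Rotation series for the adapting agent
#'
#' For every rotation in the config, simulates `sessions_per_rotation`
#' baseline-then-rotation sessions, measures the shared-basis centroid
#' angular displacement per session, regresses the per-rotation mean
#' displacement on the imposed angle, and runs the separate-basis
#' manifold-preservation report on the before/after activity.
#'
#' @param cfg a validated `experiment_config` (or overrides list).
#' @param seed base seed (defaults to the derived stage seed).
#' @return list with `per_session` (data.frame), `per_theta` means,
#'   `regression` (see [regress_displacement()]), `preservation` (a
#'   `manifold_report`), and `norm_diff` (per-session mean |d_i| of unit
#'   means).
#' @export
nhp_rotation_series <- function(cfg = list(), seed = NULL) {
  if (!inherits(cfg, "experiment_config")) cfg <- validate_config(cfg)
  seed <- seed %||% cfg$seeds$rotation
  rows <- list(); before <- list(); after <- list()
  for (th in cfg$rotations_deg) {
    for (s in seq_len(cfg$sessions_per_rotation)) {
      sid <- derive_seed(seed, sprintf("th%g_s%d", th, s))
      ses <- simulate_nhp_session(th, cfg, sid)
      disp <- session_displacement(ses, th)
      rows[[length(rows) + 1L]] <-
        data.frame(theta_deg = th, session = s,
                   mean_displacement_deg = disp$displacement$mean_deg,
                   sd_displacement_deg = disp$displacement$sd_deg)
      before[[length(before) + 1L]] <- session_activity(ses, thetas_deg = 0)
      after[[length(after) + 1L]] <- session_activity(ses, thetas_deg = th)
    }
  }
  per_session <- do.call(rbind, rows)
  per_theta <- stats::aggregate(mean_displacement_deg ~ theta_deg,
                                per_session, mean)
  reg <- regress_displacement(per_theta$mean_displacement_deg,
                              per_theta$theta_deg)
  pres <- manifold_preservation_report(before, after, mode = "separate_basis")
  pres$theta_deg <- per_session$theta_deg
  list(per_session = per_session, per_theta = per_theta, regression = reg,
       preservation = pres)
}

#' Rotation series for the reinforcement-learning agent
#'
#' Trains the baseline policy, retrains it for every RL rotation in the
#' config, collects last-hidden-layer activations before and after, and runs
#' the same displacement and preservation analyses as for the adapting
#' agent.
#'
#' @param cfg a validated `experiment_config` (or overrides list).
#' @param seed base seed (defaults to the derived stage seed).
#' @param verbose print training progress.
#' @return list with `baseline_eval`, `per_theta` (data.frame: theta,
#'   retrained success, mean displacement), `regression`, `preservation`.
#' @export
rl_rotation_series <- function(cfg = list(), seed = NULL, verbose = FALSE) {
  if (!inherits(cfg, "experiment_config")) cfg <- validate_config(cfg)
  seed <- seed %||% cfg$seeds$rl
  base <- train_agent(total_steps = cfg$rl_baseline_steps,
                      seed = derive_seed(seed, "baseline"), verbose = verbose)
  acts_before <- collect_activations(base, cfg$rl_episodes_per_target,
                                     theta_deg = 0,
                                     seed = derive_seed(seed, "acts0"))
  rows <- list(); before <- list(); after <- list()
  for (th in cfg$rl_rotations_deg) {
    ret <- retrain_rotated(base, th, total_steps = cfg$rl_retrain_steps,
                           seed = derive_seed(seed, paste0("re", th)),
                           verbose = verbose)
    acts_after <- collect_activations(ret, cfg$rl_episodes_per_target,
                                      theta_deg = th,
                                      seed = derive_seed(seed, paste0("acts", th)))
    disp <- activity_displacement(acts_before, acts_after)
    rows[[length(rows) + 1L]] <-
      data.frame(theta_deg = th, retrained_success = ret$eval$success_rate,
                 mean_displacement_deg = disp$displacement$mean_deg)
    before[[length(before) + 1L]] <- acts_before
    after[[length(after) + 1L]] <- acts_after
  }
  per_theta <- do.call(rbind, rows)
  reg <- if (length(unique(per_theta$theta_deg)) >= 3L)
    regress_displacement(per_theta$mean_displacement_deg, per_theta$theta_deg)
  else NULL
  pres <- manifold_preservation_report(before, after, mode = "separate_basis")
  pres$theta_deg <- per_theta$theta_deg
  list(baseline_eval = base$eval, per_theta = per_theta, regression = reg,
       preservation = pres)
}

#' Run the full comparative experiment
#'
#' Executes the three stages (baseline gap distribution, adapting-agent
#' rotation series, RL rotation series), compares the normalized
#' mean-activity differences of the two agents by one-way ANOVA, and writes
#' a results JSON, tidy CSV tables, and a checksummed run manifest to
#' `out_dir`. A stage whose output file already exists with the same config
#' hash is skipped and reloaded.
#'
#' @param config named list of overrides: `rotations_deg`, `compensation`,
#'   `n_units`, `trials_per_target`, `sessions_per_rotation`,
#'   `n_baseline_sessions`, `master_seed`, `include_rl`,
#'   `rl_rotations_deg`, `rl_baseline_steps`, `rl_retrain_steps`,
#'   `rl_episodes_per_target`, `out_dir`.
#' @param verbose print stage progress.
#' @return list with the stage results and the manifest, invisibly when
#'   writing to disk.
#' @export
run_experiment <- function(config = list(), verbose = FALSE) {
  cfg <- validate_config(config)
  hash <- config_hash(cfg)
  out_dir <- cfg$out_dir
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  load_or_run <- function(stage, fun) {
    path <- if (persist) file.path(out_dir, paste0("stage_", stage, ".json")) else NULL
    if (persist && file.exists(path)) {
      prev <- jsonlite::read_json(path, simplifyVector = TRUE)
      if (identical(prev$config_hash, hash)) {
        if (verbose) message("stage ", stage, ": reusing existing output")
        return(prev$result)
      }
    }
    if (verbose) message("stage ", stage, ": running")
    res <- fun()
    if (persist)
      jsonlite::write_json(list(config_hash = hash, result = res), path,
                           auto_unbox = TRUE, digits = NA, force = TRUE,
                           dataframe = "columns")
    res
  }

  gaps <- load_or_run("gaps", function() {
    g <- baseline_gap_distribution(cfg)
    list(mean = g$mean, sd = g$sd, n_sessions = g$n_sessions, gaps = g$gaps)
  })
  nhp <- load_or_run("rotation", function() {
    r <- nhp_rotation_series(cfg)
    list(per_session = r$per_session, per_theta = r$per_theta,
         slope = r$regression$slope, intercept = r$regression$intercept,
         r_squared = r$regression$r_squared, p_value = r$regression$p_value,
         preservation = as.data.frame(r$preservation))
  })
  rl <- if (isTRUE(cfg$include_rl)) load_or_run("rl", function() {
    r <- rl_rotation_series(cfg, verbose = verbose)
    list(baseline_success = r$baseline_eval$success_rate,
         per_theta = r$per_theta,
         slope = if (is.null(r$regression)) NA else r$regression$slope,
         r_squared = if (is.null(r$regression)) NA else r$regression$r_squared,
         preservation = as.data.frame(r$preservation))
  }) else NULL

  anova_res <- if (!is.null(rl)) {
    common <- intersect(unique(nhp$preservation$theta_deg),
                        unique(rl$preservation$theta_deg))
    if (length(common) > 0) {
      g1 <- nhp$preservation$mean_abs_d[nhp$preservation$theta_deg %in% common]
      g2 <- rl$preservation$mean_abs_d[rl$preservation$theta_deg %in% common]
      if (length(g1) >= 2 && length(g2) >= 2) {
        a <- compare_group_means(list(adapting = g1, rl = g2))
        list(F = a$F, p = a$p)
      } else NULL
    } else NULL
  } else NULL

  results <- list(config_hash = hash, gaps = gaps, nhp = nhp, rl = rl,
                  anova_mean_abs_d = anova_res)
  if (persist) {
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "columns")
    utils::write.csv(as.data.frame(nhp$per_session),
                     file.path(out_dir, "nhp_displacements.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(nhp$preservation),
                     file.path(out_dir, "nhp_preservation.csv"), row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(list(config_hash = hash, files = manifest,
                              timestamp = format(Sys.time(), tz = "UTC")),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, dataframe = "rows")
    results$manifest <- manifest
    return(invisible(results))
  }
  results
}
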