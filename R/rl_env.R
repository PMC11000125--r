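## Virtual center-out reinforcement-learning task.
##
## Dynamics (dimensionless step, dt = 1):
##   v_{t+1} = 0.1 * v_t + action
##   x_{t+1} = x_t + dt * v_{t+1}
## Reward:
##   20 - 0.5 * dd - |action|^2   when the step reaches the target
##      - 0.5 * dd - |action|^2   otherwise
## where dd is the change in cursor-target distance produced by the step.
## In a rotated environment the executed action is R(theta) * action.

#' Reinforcement-learning environment configuration
#'
#' @param dt integration step (dimensionless, 1).
#' @param velocity_decay persistence of the previous velocity (0.1).
#' @param target_distance center-to-target distance.
#' @param target_radius acceptance radius.
#' @param max_steps episode step limit.
#' @param success_reward reward granted on reaching the target (20).
#' @param distance_coeff coefficient on the distance change (0.5).
#' @param action_penalty_coeff coefficient on the squared action magnitude (1).
#' @param action_clip maximum action magnitude the environment executes.
#' @param position_uses_new_velocity if `TRUE` (default) position updates
#'   with the post-action velocity, so the action affects the same step's
#'   distance change; `FALSE` uses the pre-action velocity.
#' @return an `env_config` object.
#' @export
env_config <- function(dt = 1, velocity_decay = 0.1, target_distance = 10,
                       target_radius = 1, max_steps = 100L,
                       success_reward = 20, distance_coeff = 0.5,
                       action_penalty_coeff = 1, action_clip = 5,
                       position_uses_new_velocity = TRUE) {
  structure(list(dt = dt, velocity_decay = velocity_decay,
                 target_distance = target_distance, target_radius = target_radius,
                 max_steps = as.integer(max_steps),
                 success_reward = success_reward, distance_coeff = distance_coeff,
                 action_penalty_coeff = action_penalty_coeff,
                 action_clip = action_clip,
                 position_uses_new_velocity = position_uses_new_velocity,
                 n_targets = 8L, target_angles_deg = seq(0, 315, by = 45)),
            class = "env_config")
}

#' Reset the environment
#'
#' Cursor at the origin with zero velocity; the target is the requested one
#' or drawn uniformly.
#'
#' @param config an [env_config()].
#' @param target_id target index in 1..8, or `NULL` for uniform random.
#' @return an `env_state` list: `pos`, `vel`, `target`, `target_id`,
#'   `step_count`.
#' @export
env_reset <- function(config, target_id = NULL) {
  if (is.null(target_id)) target_id <- sample.int(config$n_targets, 1L)
  if (target_id < 1 || target_id > config$n_targets)
    stop("target_id must be in 1..", config$n_targets, call. = FALSE)
  phi <- deg2rad(config$target_angles_deg[target_id])
  list(pos = c(0, 0), vel = c(0, 0),
       target = config$target_distance * c(cos(phi), sin(phi)),
       target_id = as.integer(target_id), step_count = 0L)
}

#' Advance the environment one step
#'
#' @param state an `env_state`.
#' @param action finite 2-vector; magnitudes above `action_clip` are scaled
#'   down to the clip before execution.
#' @param config an [env_config()].
#' @param theta_deg imposed rotation of the executed action in degrees
#'   (0 for the unrotated environment).
#' @return list with `state` (next state), `reward`, `done`, `reached`.
#' @export
env_step <- function(state, action, config, theta_deg = 0) {
  if (!is.numeric(action) || length(action) != 2L || !all(is.finite(action)))
    stop("action must be a finite 2-vector", call. = FALSE)
  a_norm <- sqrt(sum(action^2))
  if (a_norm > config$action_clip) action <- action * (config$action_clip / a_norm)
  eff <- if (theta_deg != 0) as.numeric(rotation_matrix(deg2rad(theta_deg)) %*% action)
         else action
  v_new <- config$velocity_decay * state$vel + eff
  x_new <- state$pos + config$dt * (if (config$position_uses_new_velocity) v_new
                                    else state$vel)
  d_old <- sqrt(sum((state$target - state$pos)^2))
  d_new <- sqrt(sum((state$target - x_new)^2))
  dd <- d_new - d_old
  reached <- d_new <= config$target_radius
  reward <- (if (reached) config$success_reward else 0) -
    config$distance_coeff * dd - config$action_penalty_coeff * sum(action^2)
  step_count <- state$step_count + 1L
  done <- reached || step_count >= config$max_steps
  list(state = list(pos = x_new, vel = v_new, target = state$target,
                    target_id = state$target_id, step_count = step_count),
       reward = reward, done = done, reached = reached)
}

## Observation fed to the policy/value networks: position, velocity, and
## target-relative position, with position-like components scaled by the
## target distance so entries are O(1).
env_observation <- function(state, config) {
  c(state$pos / config$target_distance, state$vel,
    (state$target - state$pos) / config$target_distance)
}
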