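## Proximal policy optimization for the virtual center-out task, written
## directly against the environment in rl_env.R: clipped surrogate objective,
## generalized advantage estimation, minibatch Adam updates, Gaussian policy
## with state-independent log standard deviation, separate policy and value
## networks (two tanh layers of 128 units each).

#' PPO hyperparameters
#'
#' Defaults follow the customary PPO recipe (rollout 2048, 10 epochs of
#' minibatch 64, learning rate 3e-4, discount 0.99, GAE 0.95, clip 0.2,
#' value coefficient 0.5, gradient-norm clip 0.5); only the network width is
#' task-specific (two hidden layers of 128 units).
#'
#' @param n_steps rollout length per update.
#' @param batch_size minibatch size.
#' @param n_epochs optimization epochs per rollout.
#' @param gamma discount factor.
#' @param gae_lambda generalized-advantage-estimation lambda.
#' @param clip_range PPO clipping parameter.
#' @param learning_rate Adam step size.
#' @param ent_coef entropy bonus coefficient.
#' @param vf_coef value-loss coefficient.
#' @param max_grad_norm global gradient-norm clip.
#' @param hidden_width hidden-layer width (128 units, two layers).
#' @param init_log_std initial log standard deviation of the Gaussian policy.
#' @return list of hyperparameters.
#' @export
ppo_hyperparams <- function(n_steps = 2048L, batch_size = 64L, n_epochs = 10L,
                            gamma = 0.99, gae_lambda = 0.95, clip_range = 0.2,
                            learning_rate = 3e-4, ent_coef = 0, vf_coef = 0.5,
                            max_grad_norm = 0.5, hidden_width = 128L,
                            init_log_std = 0) {
  as.list(environment())
}

new_ppo_agent <- function(config, hp) {
  n_in <- length(env_observation(env_reset(config, 1L), config))
  list(policy = mlp_init(n_in, hp$hidden_width, 2L, 0.01),
       value = mlp_init(n_in, hp$hidden_width, 1L, 1),
       log_std = rep(hp$init_log_std, 2L),
       hp = hp, config = config, n_in = n_in,
       opt_t = 0L, total_steps_trained = 0L)
}

policy_logp <- function(mu, log_std, actions) {
  sd2 <- exp(2 * log_std)
  -0.5 * rowSums((actions - mu)^2 / rep(sd2, each = nrow(mu))) -
    sum(log_std) - log(2 * pi)
}

## Collect one on-policy rollout of hp$n_steps transitions.
collect_rollout <- function(agent, theta_deg, carry) {
  hp <- agent$hp; config <- agent$config
  n <- hp$n_steps
  obs <- matrix(0, n, agent$n_in)
  actions <- matrix(0, n, 2L)
  rewards <- numeric(n); dones <- logical(n); reached <- logical(n)
  state <- carry %||% env_reset(config)
  sd_vec <- exp(agent$log_std)
  for (t in seq_len(n)) {
    o <- env_observation(state, config)
    fw <- mlp_forward1(agent$policy, o)
    a <- fw$out + sd_vec * stats::rnorm(2L)
    st <- env_step(state, a, config, theta_deg)
    obs[t, ] <- o
    actions[t, ] <- a
    rewards[t] <- st$reward
    dones[t] <- st$done
    reached[t] <- st$reached
    state <- if (st$done) env_reset(config) else st$state
  }
  last_obs <- env_observation(state, config)
  list(obs = obs, actions = actions, rewards = rewards, dones = dones,
       reached = reached, carry = state, last_obs = last_obs)
}

compute_gae <- function(rewards, dones, values, last_value, gamma, lam) {
  n <- length(rewards)
  adv <- numeric(n)
  next_adv <- 0
  next_value <- last_value
  for (t in n:1) {
    nonterm <- 1 - as.numeric(dones[t])
    delta <- rewards[t] + gamma * next_value * nonterm - values[t]
    next_adv <- delta + gamma * lam * nonterm * next_adv
    adv[t] <- next_adv
    next_value <- values[t]
  }
  adv
}

ppo_update <- function(agent, roll, opt) {
  hp <- agent$hp
  vals <- as.numeric(mlp_forward(agent$value, roll$obs)$out)
  last_val <- mlp_forward1(agent$value, roll$last_obs)$out
  adv <- compute_gae(roll$rewards, roll$dones, vals, last_val,
                     hp$gamma, hp$gae_lambda)
  returns <- adv + vals
  logp_old <- {
    fw <- mlp_forward(agent$policy, roll$obs)
    policy_logp(fw$out, agent$log_std, roll$actions)
  }
  n <- nrow(roll$obs)
  for (ep in seq_len(hp$n_epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = hp$batch_size)) {
      idx <- perm[start:min(start + hp$batch_size - 1L, n)]
      X <- roll$obs[idx, , drop = FALSE]
      A <- roll$actions[idx, , drop = FALSE]
      adv_b <- adv[idx]
      adv_b <- (adv_b - mean(adv_b)) / (stats::sd(adv_b) + 1e-8)
      ret_b <- returns[idx]
      lp_old <- logp_old[idx]
      m <- length(idx)

      fw <- mlp_forward(agent$policy, X)
      mu <- fw$out
      lp <- policy_logp(mu, agent$log_std, A)
      ratio <- exp(lp - lp_old)
      r_cl <- pmin(pmax(ratio, 1 - hp$clip_range), 1 + hp$clip_range)
      use_unclipped <- ratio * adv_b <= r_cl * adv_b
      dlogp <- -(ratio * adv_b * use_unclipped) / m

      sd2 <- exp(2 * agent$log_std)
      resid <- (A - mu) / rep(sd2, each = m)
      Gmu <- dlogp * resid            # n x 2, grad wrt mu
      g_logstd <- colSums(dlogp * ((A - mu) * resid - 1)) -
        hp$ent_coef * rep(1, 2L)
      gp <- mlp_backward(agent$policy, X, fw, Gmu)

      fv <- mlp_forward(agent$value, X)
      v <- as.numeric(fv$out)
      Gv <- matrix(hp$vf_coef * 2 * (v - ret_b) / m, ncol = 1L)
      gv <- mlp_backward(agent$value, X, fv, Gv)

      gl <- clip_grads(list(gp, gv, list(log_std = g_logstd)), hp$max_grad_norm)
      agent$opt_t <- agent$opt_t + 1L
      sp <- adam_step(agent$policy, gl[[1]], opt$policy, agent$opt_t, hp$learning_rate)
      agent$policy <- sp$params; opt$policy <- sp$state
      sv <- adam_step(agent$value, gl[[2]], opt$value, agent$opt_t, hp$learning_rate)
      agent$value <- sv$params; opt$value <- sv$state
      sl <- adam_step(list(log_std = agent$log_std), gl[[3]], opt$log_std,
                      agent$opt_t, hp$learning_rate)
      agent$log_std <- sl$params$log_std; opt$log_std <- sl$state
    }
  }
  list(agent = agent, opt = opt)
}

#' Evaluate a policy's reach success rate
#'
#' Deterministic (mean-action) episodes balanced across the 8 targets.
#'
#' @param agent a `ppo_agent`.
#' @param n_episodes total episodes (divided evenly across targets).
#' @param theta_deg environment rotation during evaluation.
#' @return list with `success_rate`, `mean_steps` (successful episodes), and
#'   the per-episode table.
#' @export
evaluate_policy <- function(agent, n_episodes = 200L, theta_deg = 0) {
  config <- agent$config
  per <- ceiling(n_episodes / config$n_targets)
  rows <- list()
  for (tg in seq_len(config$n_targets)) {
    for (e in seq_len(per)) {
      state <- env_reset(config, tg)
      reached <- FALSE
      repeat {
        a <- mlp_forward1(agent$policy, env_observation(state, config))$out
        st <- env_step(state, a, config, theta_deg)
        state <- st$state
        if (st$done) { reached <- st$reached; break }
      }
      rows[[length(rows) + 1L]] <- data.frame(target = tg, episode = e,
                                              reached = reached,
                                              steps = state$step_count)
    }
  }
  tab <- do.call(rbind, rows)
  list(success_rate = mean(tab$reached),
       mean_steps = mean(tab$steps[tab$reached]),
       episodes = tab)
}

ppo_optimize <- function(agent, theta_deg, total_steps, log_every = 10L,
                         verbose = FALSE) {
  opt <- list(policy = adam_init(agent$policy), value = adam_init(agent$value),
              log_std = adam_init(list(log_std = agent$log_std)))
  carry <- NULL
  steps_done <- 0L
  log <- list()
  iter <- 0L
  while (steps_done < total_steps) {
    iter <- iter + 1L
    roll <- collect_rollout(agent, theta_deg, carry)
    carry <- roll$carry
    upd <- ppo_update(agent, roll, opt)
    agent <- upd$agent; opt <- upd$opt
    steps_done <- steps_done + agent$hp$n_steps
    ep_ends <- which(roll$dones)
    log[[iter]] <- data.frame(steps = steps_done,
                              mean_reward = mean(roll$rewards),
                              episode_success = if (length(ep_ends) > 0)
                                mean(roll$reached[ep_ends]) else NA_real_)
    if (verbose && iter %% log_every == 0L)
      message(sprintf("  PPO %d/%d steps, rollout success %.2f",
                      steps_done, total_steps, log[[iter]]$episode_success))
  }
  agent$total_steps_trained <- agent$total_steps_trained + steps_done
  agent$training_log <- rbind(agent$training_log, do.call(rbind, log))
  agent
}

#' Train a PPO agent on the unrotated center-out environment
#'
#' Trains until the step budget is exhausted, then evaluates the
#' deterministic policy over `eval_episodes` balanced episodes; falling short
#' of `success_threshold` is an error (reporting the achieved rate), since
#' downstream analyses assume a proficient baseline agent.
#'
#' @param config an [env_config()].
#' @param total_steps training step budget.
#' @param seed integer seed controlling initialization, exploration noise,
#'   and target order.
#' @param hyperparams a [ppo_hyperparams()] list.
#' @param eval_episodes evaluation episodes after training.
#' @param success_threshold required deterministic success rate.
#' @param verbose print progress.
#' @return a `ppo_agent` object.
#' @export
train_agent <- function(config = env_config(), total_steps = 300000L,
                        seed = NULL, hyperparams = ppo_hyperparams(),
                        eval_episodes = 200L, success_threshold = 0.95,
                        verbose = FALSE) {
  with_seed(seed, {
    agent <- new_ppo_agent(config, hyperparams)
    agent <- ppo_optimize(agent, 0, total_steps, verbose = verbose)
    ev <- evaluate_policy(agent, eval_episodes, 0)
    if (ev$success_rate < success_threshold)
      stop(sprintf(paste0("training ended below the required success rate: ",
                          "%.3f < %.3f after %d steps"),
                   ev$success_rate, success_threshold, total_steps), call. = FALSE)
    agent$eval <- ev
    agent$theta_deg <- 0
    class(agent) <- "ppo_agent"
    agent
  })
}

#' Retrain a trained agent in a rotated environment
#'
#' Continues PPO optimization of an existing agent with the action rotated
#' by `theta_deg`, until the step budget is exhausted; the retrained policy
#' must reach `success_threshold` in the rotated environment or an error is
#' raised.
#'
#' By the end of baseline training the policy's exploration noise has
#' typically annealed to near zero; a near-deterministic policy cannot
#' discover the rotated action mapping (large rotations reverse the sign of
#' the required corrections). Retraining therefore restores the exploration
#' standard deviation to its initial value before continuing optimization
#' (`reset_log_std`).
#'
#' @param agent a trained `ppo_agent`.
#' @param theta_deg imposed action rotation in degrees.
#' @param total_steps retraining step budget.
#' @param seed integer seed.
#' @param eval_episodes,success_threshold as in [train_agent()].
#' @param reset_log_std restore exploration noise before retraining.
#' @param verbose print progress.
#' @return the retrained `ppo_agent` (with `theta_deg` recorded).
#' @export
retrain_rotated <- function(agent, theta_deg, total_steps = 150000L,
                            seed = NULL, eval_episodes = 200L,
                            success_threshold = 0.95, reset_log_std = TRUE,
                            verbose = FALSE) {
  stopifnot(inherits(agent, "ppo_agent"))
  with_seed(seed, {
    if (reset_log_std) agent$log_std <- rep(agent$hp$init_log_std, 2L)
    agent <- ppo_optimize(agent, theta_deg, total_steps, verbose = verbose)
    ev <- evaluate_policy(agent, eval_episodes, theta_deg)
    if (ev$success_rate < success_threshold)
      stop(sprintf(paste0("retraining at theta=%g ended below the required ",
                          "success rate: %.3f < %.3f after %d steps"),
                   theta_deg, ev$success_rate, success_threshold, total_steps),
           call. = FALSE)
    agent$eval <- ev
    agent$theta_deg <- theta_deg
    class(agent) <- "ppo_agent"
    agent
  })
}

#' @export
print.ppo_agent <- function(x, ...) {
  cat("PPO agent (2 x 128 tanh policy and value networks)\n")
  cat(sprintf("  trained steps: %d   environment rotation: %g deg\n",
              x$total_steps_trained, x$theta_deg %||% 0))
  if (!is.null(x$eval))
    cat(sprintf("  deterministic success: %.1f%% (mean %.1f steps)\n",
                100 * x$eval$success_rate, x$eval$mean_steps))
  invisible(x)
}

#' Record last-hidden-layer activations during rollouts
#'
#' Runs `episodes_per_target` episodes per target and records the
#' post-nonlinearity activations of the second hidden layer of the policy
#' network at every step — the analog of the firing rates driving the cursor.
#'
#' @param agent a trained `ppo_agent`.
#' @param episodes_per_target episodes per target (> 0).
#' @param theta_deg environment rotation during the rollouts.
#' @param deterministic use mean actions (default) or sample.
#' @param seed integer seed (relevant for stochastic rollouts and shared by
#'   both modes for reproducibility).
#' @param successful_only keep only episodes that reach the target.
#' @return an `activity_matrix`: `values` (128 x steps), per-step `target`
#'   and `theta_deg` labels.
#' @export
collect_activations <- function(agent, episodes_per_target = 20L, theta_deg = 0,
                                deterministic = TRUE, seed = NULL,
                                successful_only = TRUE) {
  stopifnot(inherits(agent, "ppo_agent"))
  if (episodes_per_target < 1L) stop("need at least one episode per target",
                                     call. = FALSE)
  config <- agent$config
  with_seed(seed, {
    acts <- list(); tgt <- list()
    sd_vec <- exp(agent$log_std)
    for (tg in seq_len(config$n_targets)) {
      for (e in seq_len(episodes_per_target)) {
        state <- env_reset(config, tg)
        ep_acts <- list()
        reached <- FALSE
        repeat {
          fw <- mlp_forward1(agent$policy, env_observation(state, config))
          ep_acts[[length(ep_acts) + 1L]] <- fw$h2
          a <- if (deterministic) fw$out else fw$out + sd_vec * stats::rnorm(2L)
          st <- env_step(state, a, config, theta_deg)
          state <- st$state
          if (st$done) { reached <- st$reached; break }
        }
        if (!successful_only || reached) {
          acts[[length(acts) + 1L]] <- do.call(cbind, ep_acts)
          tgt[[length(tgt) + 1L]] <- rep(tg, length(ep_acts))
        }
      }
    }
    if (length(acts) == 0L)
      stop("no successful episodes to record activations from", call. = FALSE)
    structure(list(values = do.call(cbind, acts), target = unlist(tgt),
                   theta_deg = rep(theta_deg, length(unlist(tgt)))),
              class = "activity_matrix")
  })
}

#' Write an activation matrix in the spike-count CSV dialect
#'
#' @param activations an `activity_matrix` from [collect_activations()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activations <- function(activations, path) {
  df <- as.data.frame(t(activations$values))
  names(df) <- sprintf("unit_%03d", seq_len(nrow(activations$values)))
  df$target_id <- activations$target
  df$theta_deg <- activations$theta_deg
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
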