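test_that("environment dynamics follow the update equations exactly", {
  cfg <- env_config()
  st <- env_reset(cfg, 1L)
  st$vel <- c(1, 0)
  out <- env_step(st, c(0, 1), cfg)
  expect_equal(out$state$vel, c(0.1, 1))
  expect_equal(out$state$pos, c(0.1, 1))  # position uses the new velocity
  cfg_old <- env_config(position_uses_new_velocity = FALSE)
  out_old <- env_step(st, c(0, 1), cfg_old)
  expect_equal(out_old$state$pos, c(1, 0))  # dt * v_t
  expect_error(env_step(st, c(NA, 1), cfg), "finite")
  expect_error(env_step(st, c(1, 2, 3), cfg), "2-vector")
})

test_that("reward matches the worked substitutions", {
  cfg <- env_config()
  ## reaching step with zero distance change and zero action: exactly 20
  st <- env_reset(cfg, 1L)
  st$pos <- st$target
  out <- env_step(st, c(0, 0), cfg)
  expect_true(out$reached)
  expect_identical(out$reward, 20)
  ## non-reaching step: dd = -1, |action|^2 = 0.25 -> 0.25
  st2 <- env_reset(cfg, 1L)   # target (10, 0), cursor origin, d_old = 10
  st2$vel <- c(5, 0)          # v' = 0.5 + 0.5 = 1, x' = (1, 0), dd = -1
  out2 <- env_step(st2, c(0.5, 0), cfg)
  expect_false(out2$reached)
  expect_equal(out2$reward, 0.25)
})

test_that("reset places the cursor at the origin and balances random targets", {
  cfg <- env_config()
  st <- env_reset(cfg, 4L)
  expect_equal(st$pos, c(0, 0))
  expect_equal(st$vel, c(0, 0))
  expect_equal(st$target_id, 4L)
  expect_equal(sqrt(sum(st$target^2)), cfg$target_distance)
  expect_error(env_reset(cfg, 9L), "target_id")
  set.seed(13)
  ids <- replicate(8000, env_reset(cfg)$target_id)
  expect_true(all(abs(table(ids) - 1000) <= 150))
})

test_that("the rotated environment is equivariant to counter-rotated actions", {
  cfg <- env_config()
  set.seed(6)
  actions <- matrix(rnorm(2 * 30), 30, 2)
  th <- 70
  Rinv <- rotation_matrix(-th * pi / 180)
  s0 <- env_reset(cfg, 3L); s1 <- env_reset(cfg, 3L)
  for (t in 1:30) {
    o0 <- env_step(s0, actions[t, ], cfg, theta_deg = 0)
    o1 <- env_step(s1, as.numeric(Rinv %*% actions[t, ]), cfg, theta_deg = th)
    expect_equal(o1$state$pos, o0$state$pos, tolerance = 1e-12)
    expect_equal(o1$state$vel, o0$state$vel, tolerance = 1e-12)
    s0 <- o0$state; s1 <- o1$state
    if (o0$done) break
  }
})

test_that("distance rewards telescope to half the net approach", {
  cfg <- env_config(action_penalty_coeff = 0, max_steps = 40L)
  st <- env_reset(cfg, 2L)
  d0 <- sqrt(sum(st$target^2))
  set.seed(4)
  total <- 0
  for (t in 1:40) {
    out <- env_step(st, rnorm(2, sd = 0.3), cfg)
    total <- total + out$reward - (if (out$reached) cfg$success_reward else 0)
    st <- out$state
    if (out$done) break
  }
  dT <- sqrt(sum((st$target - st$pos)^2))
  expect_equal(total, 0.5 * (d0 - dT), tolerance = 1e-10)
})

test_that("actions above the clip are scaled to the clip magnitude", {
  cfg <- env_config()
  st <- env_reset(cfg, 1L)
  out <- env_step(st, c(30, 40), cfg)     # |a| = 50 -> scaled to 5
  expect_equal(sqrt(sum(out$state$vel^2)), 5, tolerance = 1e-12)
  expect_equal(out$state$vel, c(3, 4), tolerance = 1e-12)
})

fix_small_agent <- function() fix_cached("small_agent", function()
  train_agent(env_config(), total_steps = 8192L, seed = 3,
              eval_episodes = 40L, success_threshold = 0))

test_that("short PPO training improves over a random policy", {
  cfg <- env_config()
  agent <- fix_small_agent()
  ## a random-initialization policy essentially never reaches the target
  set.seed(99)
  raw <- bcimanifold:::new_ppo_agent(cfg, ppo_hyperparams())
  class(raw) <- "ppo_agent"; raw$config <- cfg
  ev0 <- evaluate_policy(raw, 40L)
  expect_lt(ev0$success_rate, 0.2)
  log <- agent$training_log
  expect_gt(mean(tail(log$mean_reward, 2)), mean(head(log$mean_reward, 2)))
  expect_gt(agent$eval$success_rate, ev0$success_rate)
})

test_that("activation capture is shaped, labeled, and reproducible", {
  agent <- fix_small_agent()
  acts <- collect_activations(agent, episodes_per_target = 1L, seed = 5,
                              successful_only = FALSE)
  expect_equal(nrow(acts$values), 128L)
  expect_equal(length(acts$target), ncol(acts$values))
  expect_setequal(unique(acts$target), 1:8)
  acts2 <- collect_activations(agent, episodes_per_target = 1L, seed = 5,
                               successful_only = FALSE)
  expect_identical(acts$values, acts2$values)
  expect_error(collect_activations(agent, episodes_per_target = 0L), "episode")
  ## CSV dialect round trip
  path <- tempfile(fileext = ".csv")
  write_activations(acts, path)
  back <- read_activity_csv(path, successful_only = FALSE, moving_only = FALSE)
  expect_equal(back$values, acts$values, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(path)
})
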