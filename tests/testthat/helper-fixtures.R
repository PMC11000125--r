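## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fix_cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fix_tuning <- function() fix_cached("tuning", function() make_tuning(40L, seed = 7))

fix_kalman <- function() fix_cached("kalman", function() {
  pas <- passive_observation_set(fix_tuning(), n_reaches = 10L, seed = 8)
  fit_kalman_decoder(pas)
})

## Analytic observation matrix for a tuning model: counts are exactly linear
## in the state, rate_i = b_i + m_i g (v . u_i), scaled by the bin width.
analytic_C <- function(tun) {
  cbind(0, 0,
        tun$modulation * tun$speed_gain * cos(tun$preferred_direction),
        tun$modulation * tun$speed_gain * sin(tun$preferred_direction),
        tun$baseline) * tun$bin_width
}

## Small baseline+rotation session shared across manifold tests.
fix_session_50 <- function() fix_cached("session50", function() {
  sched <- list(list(theta_deg = 0, trials_per_target = 10L, compensation = 1),
                list(theta_deg = 50, trials_per_target = 10L, compensation = 1))
  run_session(task_config(), fix_tuning(), fix_kalman(), sched, seed = 21)
})
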