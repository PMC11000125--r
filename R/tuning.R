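#' Build a cosine-tuned synthetic population
#'
#' Constructs the generative model standing in for the recorded motor-cortical
#' population: each unit fires at
#' \deqn{r_i = b_i + m_i \, g \, s \, \cos(\phi - \mathrm{pd}_i)}
#' where \eqn{\phi} and \eqn{s} are the intended movement direction and speed,
#' \eqn{b_i} the baseline rate (Hz), \eqn{m_i} the modulation depth (Hz) and
#' \eqn{g} a dimensionless speed gain. Preferred directions are drawn uniformly
#' on the circle. Baselines are raised where needed so that the expected rate
#' is non-negative for every intent with speed up to `max_speed`.
#'
#' @param n_units number of units; at least 3 are required so that a 2-D
#'   intent is observable from the population (two units can be collinear).
#' @param seed integer seed; the model is fully reproducible from it.
#' @param rate_ranges list with elements `baseline` and `modulation`, each a
#'   length-2 numeric range in Hz from which per-unit values are drawn.
#' @param speed_gain dimensionless coupling of intended speed into modulation.
#' @param max_speed largest intended speed (workspace units/s) the
#'   non-negativity guarantee covers.
#' @param bin_width bin width in seconds (0.1 corresponds to 100 ms bins).
#' @return an object of class `tuning_model`.
#' @export
make_tuning <- function(n_units = 40L, seed = NULL,
                        rate_ranges = list(baseline = c(5, 25), modulation = c(5, 15)),
                        speed_gain = 0.1, max_speed = 6, bin_width = 0.1) {
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 3)
    stop("n_units must be >= 3: observing a 2-D intent requires at least ",
         "3 non-collinear tuned units", call. = FALSE)
  n_units <- as.integer(n_units)
  with_seed(seed, {
    pd <- stats::runif(n_units, 0, 2 * pi)
    baseline <- stats::runif(n_units, rate_ranges$baseline[1], rate_ranges$baseline[2])
    modulation <- stats::runif(n_units, rate_ranges$modulation[1], rate_ranges$modulation[2])
    ## non-negativity for all intents with speed <= max_speed
    floor_rate <- modulation * speed_gain * max_speed
    baseline <- pmax(baseline, floor_rate)
    structure(list(n_units = n_units, baseline = baseline,
                   modulation = modulation, preferred_direction = pd,
                   speed_gain = speed_gain, max_speed = max_speed,
                   bin_width = bin_width, seed = seed),
              class = "tuning_model")
  })
}

#' @export
print.tuning_model <- function(x, ...) {
  cat("Cosine-tuned Poisson population\n")
  cat(sprintf("  units: %d   bin width: %g s   speed gain: %g\n",
              x$n_units, x$bin_width, x$speed_gain))
  cat(sprintf("  baseline: %.1f-%.1f Hz   modulation: %.1f-%.1f Hz\n",
              min(x$baseline), max(x$baseline), min(x$modulation), max(x$modulation)))
  invisible(x)
}

#' Intended-movement state
#'
#' @param velocity intended 2-vector velocity (units/s); direction and speed
#'   are derived from it.
#' @return list with `intended_velocity`, `intended_direction` (radians) and
#'   `intended_speed`.
#' @export
intent_state <- function(velocity) {
  stopifnot(is.numeric(velocity), length(velocity) == 2L, all(is.finite(velocity)))
  list(intended_velocity = as.numeric(velocity),
       intended_direction = atan2(velocity[2], velocity[1]),
       intended_speed = sqrt(sum(velocity^2)))
}

#' Expected firing rates for an intent
#'
#' @param model a `tuning_model`.
#' @param intent an intent as returned by [intent_state()].
#' @return per-unit expected rate vector in Hz (all non-negative by the
#'   construction invariant of [make_tuning()]).
#' @export
expected_rates <- function(model, intent) {
  stopifnot(inherits(model, "tuning_model"))
  r <- model$baseline + model$modulation * model$speed_gain * intent$intended_speed *
    cos(intent$intended_direction - model$preferred_direction)
  pmax(r, 0)
}

#' Sample Poisson spike counts for one bin
#'
#' @param rates per-unit rates in Hz, all non-negative.
#' @param bin_width bin width in seconds.
#' @return integer vector of counts, one per unit.
#' @export
sample_spikes <- function(rates, bin_width = 0.1) {
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  stats::rpois(length(rates), rates * bin_width)
}

#' Re-aiming policy
#'
#' The compensation strategy attributed to the subjects: aim the intended
#' movement at an angle that counteracts the imposed decoder rotation. With
#' full compensation (`fraction = 1`) and an imposed rotation `theta`, the
#' intended direction is rotated by `-theta` so that the rotated decoder
#' output lands back on the target direction.
#'
#' @param fraction compensation fraction in \[0, 1\]; 0 means no re-aiming.
#' @param theta_deg imposed decoder rotation in degrees (counter-clockwise
#'   positive).
#' @return an `adaptation_policy` object.
#' @export
adaptation_policy <- function(fraction = 1, theta_deg = 0) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0 || fraction > 1)
    stop("compensation fraction must lie in [0, 1]", call. = FALSE)
  structure(list(compensation_fraction = fraction,
                 imposed_rotation = deg2rad(theta_deg)),
            class = "adaptation_policy")
}

#' Apply re-aiming to an intent
#'
#' Rotates the intended direction by `-fraction * theta`; speed is unchanged.
#'
#' @param intent an intent toward the target, from [intent_state()].
#' @param policy an [adaptation_policy()].
#' @return the re-aimed intent.
#' @export
reaim <- function(intent, policy) {
  stopifnot(inherits(policy, "adaptation_policy"))
  shift <- -policy$compensation_fraction * policy$imposed_rotation
  phi <- intent$intended_direction + shift
  v <- intent$intended_speed * c(cos(phi), sin(phi))
  intent_state(v)
}

#' Passive-observation data for decoder fitting
#'
#' Generates the decoder-calibration data: the cursor moves along straight
#' prescribed trajectories from the center to each peripheral target at
#' constant speed, with a brief zero-speed hold at the endpoint, while spike
#' counts are sampled from the population with intent equal to the prescribed
#' velocity.
#'
#' @param model a `tuning_model`.
#' @param target_angles_deg target directions in degrees.
#' @param n_reaches reaches per target.
#' @param target_distance center-to-target distance (workspace units).
#' @param speed prescribed movement speed (units/s).
#' @param hold_bins zero-speed bins appended at the endpoint of each reach.
#' @param seed integer seed.
#' @param noise if `FALSE`, counts are the noise-free expectations
#'   (useful for exact-recovery checks).
#' @return list with `counts` (units x bins), `states` (5 x bins state
#'   vectors: position, velocity, constant 1), and per-bin `target_id`,
#'   `reach_id` labels.
#' @export
passive_observation_set <- function(model, target_angles_deg = seq(0, 315, by = 45),
                                    n_reaches = 5L, target_distance = 10,
                                    speed = NULL, hold_bins = 2L, seed = NULL,
                                    noise = TRUE) {
  stopifnot(inherits(model, "tuning_model"))
  if (length(target_angles_deg) < 1L) stop("need at least one target", call. = FALSE)
  if (n_reaches < 1L) stop("need at least one reach per target", call. = FALSE)
  speed <- speed %||% model$max_speed
  dt <- model$bin_width
  n_move <- ceiling(target_distance / (speed * dt))
  bins_per_reach <- n_move + hold_bins
  n_bins <- length(target_angles_deg) * n_reaches * bins_per_reach
  counts <- matrix(0, model$n_units, n_bins)
  states <- matrix(0, 5L, n_bins)
  target_id <- integer(n_bins)
  reach_id <- integer(n_bins)
  with_seed(seed, {
    col <- 0L
    reach <- 0L
    for (k in seq_along(target_angles_deg)) {
      phi <- deg2rad(target_angles_deg[k])
      u <- c(cos(phi), sin(phi))
      for (r in seq_len(n_reaches)) {
        reach <- reach + 1L
        pos <- c(0, 0)
        for (b in seq_len(bins_per_reach)) {
          col <- col + 1L
          moving <- b <= n_move
          v <- if (moving) speed * u else c(0, 0)
          intent <- intent_state(v)
          rates <- expected_rates(model, intent)
          counts[, col] <- if (noise) sample_spikes(rates, dt) else rates * dt
          states[, col] <- c(pos, v, 1)
          target_id[col] <- k
          reach_id[col] <- reach
          if (moving) pos <- pos + dt * v
        }
      }
    }
  })
  list(counts = counts, states = states, target_id = target_id,
       reach_id = reach_id, bin_width = dt,
       target_angles_deg = target_angles_deg)
}
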