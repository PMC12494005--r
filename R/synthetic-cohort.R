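#' Configure a synthetic optomotor cohort
#'
#' Describes the trial structure and bout timing of a coherent-dot optomotor
#' experiment: each trial shows 0%-coherence dots for `baseline_duration`
#' seconds followed by directed motion at the scheduled coherence for
#' `stimulus_duration` seconds. Bouts are emitted as a Poisson renewal process
#' with a period-specific rate.
#'
#' @param n_fish Number of fish in the cohort (>= 1).
#' @param n_trials Trials per fish; must be even so that left/right stimuli can
#'   be balanced within successive pairs.
#' @param baseline_duration Baseline (0% coherence) period length, seconds.
#' @param stimulus_duration Stimulus period length, seconds.
#' @param coherence Stimulus coherence in `[0, 1]`; either a single value
#'   recycled to all trials or one value per trial.
#' @param baseline_bout_rate,stimulus_bout_rate Bout rates in bouts/min.
#' @param tracked_prob Probability that a bout is flagged as tracked.
#' @param seed Master seed; all cohort randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_fish = 64L,
                          n_trials = 30L,
                          baseline_duration = 150,
                          stimulus_duration = 30,
                          coherence = 1,
                          baseline_bout_rate = 62.9,
                          stimulus_bout_rate = 75.2,
                          tracked_prob = 1,
                          seed = 1L) {
  if (n_fish < 1) abort("`n_fish` must be >= 1.")
  if (n_trials < 1 || n_trials %% 2L != 0L) {
    abort("`n_trials` must be a positive even number (stimuli are balanced in pairs).")
  }
  if (baseline_duration <= 0 || stimulus_duration <= 0) {
    abort("Trial period durations must be positive.")
  }
  coherence <- rep_len(coherence, n_trials)
  if (any(coherence < 0 | coherence > 1)) abort("`coherence` values must lie in [0, 1].")
  if (baseline_bout_rate < 0 || stimulus_bout_rate < 0) abort("Bout rates must be >= 0.")
  stopifnot_prob(tracked_prob, "tracked_prob")
  structure(
    list(
      n_fish = as.integer(n_fish),
      n_trials = as.integer(n_trials),
      baseline_duration = baseline_duration,
      stimulus_duration = stimulus_duration,
      coherence = coherence,
      baseline_bout_rate = baseline_bout_rate,
      stimulus_bout_rate = stimulus_bout_rate,
      tracked_prob = tracked_prob,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Describe one fish's behavioral profile
#'
#' The attention chain is a two-state Markov process over trials with
#' `enter_rate` (disengaged -> engaged) and `exit_rate` (engaged ->
#' disengaged). Engaged stimulus-period turning follows the gated
#' drift-diffusion model in `ddm`; disengaged and baseline turning follow a
#' directional-persistence process in which the fish holds a latent side bias,
#' repeats it with probability `baseline_persistence`, and flips the bias with
#' probability `bias_switch_prob` per bout.
#'
#' @param enter_rate Per-trial probability of entering the engaged state.
#' @param exit_rate Per-trial probability of leaving the engaged state.
#' @param baseline_persistence Probability a (non-forward) turn follows the
#'   current side bias.
#' @param bias_switch_prob Per-bout probability the latent side bias flips.
#' @param forward_prob Probability a bout is a forward swim (turn angle 0).
#' @param turn_angle_sd Half-normal scale (degrees) for turn magnitudes.
#' @param wall_distraction_scale Logistic gain mapping a trial's mean radius to
#'   an extra probability of disengaging; 0 disables wall distraction.
#' @param rate_coef_boutrate,rate_coef_trial Log-odds coefficients modulating
#'   the attention rates by (centered) baseline bout rate and trial index;
#'   both default to 0 (a homogeneous chain).
#' @param ddm Engaged-state decision parameters, see [ddm_params()].
#' @return A `fish_profile` list.
#' @export
fish_profile <- function(enter_rate = 0.3,
                         exit_rate = 0.15,
                         baseline_persistence = 0.85,
                         bias_switch_prob = 0.015,
                         forward_prob = 0.3,
                         turn_angle_sd = 35,
                         wall_distraction_scale = 0,
                         rate_coef_boutrate = 0,
                         rate_coef_trial = 0,
                         ddm = ddm_params()) {
  stopifnot_prob(enter_rate, "enter_rate")
  stopifnot_prob(exit_rate, "exit_rate")
  stopifnot_prob(baseline_persistence, "baseline_persistence")
  stopifnot_prob(bias_switch_prob, "bias_switch_prob")
  stopifnot_prob(forward_prob, "forward_prob")
  if (turn_angle_sd <= 0) abort("`turn_angle_sd` must be positive.")
  structure(
    list(
      enter_rate = enter_rate,
      exit_rate = exit_rate,
      baseline_persistence = baseline_persistence,
      bias_switch_prob = bias_switch_prob,
      forward_prob = forward_prob,
      turn_angle_sd = turn_angle_sd,
      wall_distraction_scale = wall_distraction_scale,
      rate_coef_boutrate = rate_coef_boutrate,
      rate_coef_trial = rate_coef_trial,
      ddm = ddm
    ),
    class = "fish_profile"
  )
}

#' Generate a left/right balanced trial schedule
#'
#' Every successive pair of trials contains exactly one leftward and one
#' rightward stimulus, in random order. Each trial also receives an
#' independent fair-coin target direction used only to score the baseline
#' period.
#'
#' @param config A [cohort_config()] (or an even trial count).
#' @param seed Seed for the schedule draw; defaults to the config seed.
#' @return A tibble with columns `trial_index`, `stim_direction`, `coherence`,
#'   `baseline_target`.
#' @export
generate_trial_schedule <- function(config, seed = NULL) {
  if (is.numeric(config)) {
    config <- cohort_config(n_fish = 1L, n_trials = config)
  }
  n <- config$n_trials
  if (n %% 2L != 0L) abort("`n_trials` must be even.")
  seed <- seed %||% config$seed
  with_seed(seed, {
    n_pairs <- n %/% 2L
    first_left <- runif(n_pairs) < 0.5
    dirs <- character(n)
    dirs[seq(1, n, by = 2)] <- ifelse(first_left, "left", "right")
    dirs[seq(2, n, by = 2)] <- ifelse(first_left, "right", "left")
    tibble::tibble(
      trial_index = seq_len(n),
      stim_direction = dirs,
      coherence = config$coherence,
      baseline_target = ifelse(runif(n) < 0.5, "left", "right")
    )
  })
}

#' Simulate the engaged/disengaged attention chain
#'
#' A first-order two-state Markov chain over trials. The initial state is
#' drawn from the stationary distribution, so with homogeneous rates the
#' expected occupancy of the engaged state is `p / (p + q)` at every trial.
#' Optional covariates (baseline bout rate, trial index) shift the transition
#' rates on the log-odds scale; the default coefficients of zero leave the
#' chain homogeneous.
#'
#' @param profile A [fish_profile()].
#' @param n_trials Number of trials to simulate.
#' @param covariates Optional data frame with columns `baseline_bout_rate` and
#'   `trial_index` (one row per trial) used for rate modulation.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Character vector of `"engaged"` / `"disengaged"`, length `n_trials`.
#' @export
simulate_attention_chain <- function(profile, n_trials, covariates = NULL, seed = NULL) {
  run <- function() {
    p <- profile$enter_rate
    q <- profile$exit_rate
    modulated <- (profile$rate_coef_boutrate != 0 || profile$rate_coef_trial != 0) &&
      !is.null(covariates)
    if (modulated) {
      shift <- profile$rate_coef_boutrate *
        (covariates$baseline_bout_rate - mean(covariates$baseline_bout_rate)) +
        profile$rate_coef_trial * (covariates$trial_index - mean(covariates$trial_index))
      p_t <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + shift)
      q_t <- stats::plogis(stats::qlogis(pmin(pmax(q, 1e-12), 1 - 1e-12)) + shift)
    } else {
      p_t <- rep(p, n_trials)
      q_t <- rep(q, n_trials)
    }
    occ <- if (p + q > 0) p / (p + q) else 0.5
    states <- integer(n_trials) # 1 = engaged
    states[1] <- as.integer(runif(1) < occ)
    if (n_trials > 1) {
      u <- runif(n_trials - 1)
      for (t in 2:n_trials) {
        states[t] <- if (states[t - 1] == 1L) {
          as.integer(u[t - 1] >= q_t[t])
        } else {
          as.integer(u[t - 1] < p_t[t])
        }
      }
    }
    ifelse(states == 1L, "engaged", "disengaged")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Reflected 2-D random walk in the unit disk. Returns the radius at the START
# of each bout; `state` carries (x, y) across calls so position is continuous
# within a fish's session.
walk_radii <- function(state, n) {
  if (n == 0L) {
    return(list(radii = numeric(0), state = state))
  }
  len <- runif(n, 0.02, 0.08)
  ang <- runif(n, 0, 2 * pi)
  dx <- len * cos(ang)
  dy <- len * sin(ang)
  x <- state[1]
  y <- state[2]
  radii <- numeric(n)
  for (i in seq_len(n)) {
    radii[i] <- sqrt(x * x + y * y)
    x <- x + dx[i]
    y <- y + dy[i]
    r <- sqrt(x * x + y * y)
    if (r > 1) {
      s <- (2 - r) / r # radial fold back into the disk
      x <- x * s
      y <- y * s
    }
  }
  list(radii = pmin(radii, 1), state = c(x, y))
}

# Directional persistence turning: latent side bias (+1 right / -1 left)
# repeated with prob `persist`, flipping with prob `switch` after every bout;
# forward swims emit direction 0 without consuming the bias. Returns the
# directions and the updated bias.
persistence_directions <- function(n, bias, persist, switch, forward_prob) {
  if (n == 0L) {
    return(list(dir = integer(0), bias = bias))
  }
  forward <- runif(n) < forward_prob
  follow <- ifelse(runif(n) < persist, 1L, -1L)
  flips <- runif(n) < switch
  bias_seq <- bias * cumprod(c(1L, 1L - 2L * as.integer(flips[-n])))
  dir <- ifelse(forward, 0L, bias_seq * follow)
  list(dir = as.integer(dir), bias = as.integer(bias_seq[n] * (1L - 2L * as.integer(flips[n]))))
}

turn_angles_from_dirs <- function(dir, sd) {
  mag <- pmin(abs(rnorm(length(dir), 0, sd)), 179.99)
  ifelse(dir == 0L, 0, dir * mag)
}

#' Generate a synthetic bout-level cohort
#'
#' Composes the attention chain, the gated drift-diffusion decision process,
#' directional-persistence baseline turning, Poisson bout timing, and a
#' reflected random walk for dish position into a bout table with the layout
#' of a real tracking session. Engaged stimulus-period bouts read out the
#' drift-diffusion integrator; disengaged stimulus-period bouts (the gated
#' condition) and all baseline bouts follow the persistence process, so
#' disengaged trials score at chance irrespective of the stimulus.
#'
#' @param config A [cohort_config()].
#' @param profiles A single [fish_profile()] shared by all fish, or a list of
#'   `n_fish` profiles.
#' @param seed Master seed; defaults to the config seed. Per-fish RNG streams
#'   are split deterministically from it.
#' @return A list of class `omr_cohort` with elements `bouts` (tibble:
#'   `fish_id`, `trial_index`, `time_s`, `period`, `turn_angle_deg`, `radius`,
#'   `tracked`), `schedule`, `states` (true per-trial attention states, for
#'   validation), and `config`.
#' @export
generate_cohort <- function(config, profiles = fish_profile(), seed = NULL) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a `cohort_config`.")
  if (inherits(profiles, "fish_profile")) {
    profiles <- rep(list(profiles), config$n_fish)
  }
  if (length(profiles) != config$n_fish) {
    abort("`profiles` must supply one profile per fish.")
  }
  seed <- seed %||% config$seed
  schedule <- generate_trial_schedule(config, seed = seed)
  fish_seeds <- derive_seeds(seed, config$n_fish)
  fish_ids <- sprintf("f%03d", seq_len(config$n_fish))

  signed_coh <- ifelse(schedule$stim_direction == "right", 1, -1) * schedule$coherence
  covar <- tibble::tibble(
    baseline_bout_rate = rep(config$baseline_bout_rate, config$n_trials),
    trial_index = seq_len(config$n_trials)
  )

  per_fish <- purrr::map(seq_len(config$n_fish), function(f) {
    prof <- profiles[[f]]
    with_seed(fish_seeds[f], {
      states <- simulate_attention_chain(prof, config$n_trials, covariates = covar)
      theta0 <- runif(1, 0, 2 * pi)
      r0 <- sqrt(runif(1))
      pos <- c(r0 * cos(theta0), r0 * sin(theta0))
      bias <- if (runif(1) < 0.5) 1L else -1L
      trial_rows <- vector("list", config$n_trials)
      eff_states <- character(config$n_trials)
      for (t in seq_len(config$n_trials)) {
        nb <- rpois(1, config$baseline_bout_rate / 60 * config$baseline_duration)
        ns <- rpois(1, config$stimulus_bout_rate / 60 * config$stimulus_duration)
        tb <- sort(runif(nb, 0, config$baseline_duration))
        ts <- sort(runif(ns, 0, config$stimulus_duration))
        wb <- walk_radii(pos, nb)
        ws <- walk_radii(wb$state, ns)
        pos <- ws$state

        # Wall distraction: chance of losing engagement grows logistically
        # with the trial's mean (stimulus-period) radius.
        state_t <- states[t]
        if (state_t == "engaged" && prof$wall_distraction_scale > 0 && ns > 0) {
          p_wall <- stats::plogis(prof$wall_distraction_scale * (mean(ws$radii) - 0.75))
          if (runif(1) < p_wall) state_t <- "disengaged"
        }
        eff_states[t] <- state_t

        pb <- persistence_directions(
          nb, bias, prof$baseline_persistence, prof$bias_switch_prob, prof$forward_prob
        )
        bias <- pb$bias
        if (state_t == "engaged" && ns > 0) {
          dirs_s <- ddm_bout_directions(prof$ddm, signed_coh[t], ts)
        } else {
          ps <- persistence_directions(
            ns, bias, prof$baseline_persistence, prof$bias_switch_prob, prof$forward_prob
          )
          bias <- ps$bias
          dirs_s <- ps$dir
        }

        n_all <- nb + ns
        trial_rows[[t]] <- tibble::tibble(
          trial_index = t,
          time_s = c(tb, config$baseline_duration + ts),
          period = rep(c("baseline", "stimulus"), c(nb, ns)),
          turn_angle_deg = c(
            turn_angles_from_dirs(pb$dir, prof$turn_angle_sd),
            turn_angles_from_dirs(dirs_s, prof$turn_angle_sd)
          ),
          radius = c(wb$radii, ws$radii),
          tracked = if (config$tracked_prob >= 1) {
            rep(TRUE, n_all)
          } else {
            runif(n_all) < config$tracked_prob
          }
        )
      }
      list(
        bouts = dplyr::bind_rows(trial_rows),
        states = tibble::tibble(
          trial_index = seq_len(config$n_trials),
          state = eff_states
        )
      )
    })
  })

  bouts <- dplyr::bind_rows(
    purrr::map2(per_fish, fish_ids, ~ dplyr::mutate(.x$bouts, fish_id = .y))
  )
  bouts <- dplyr::select(
    bouts, "fish_id", "trial_index", "time_s", "period",
    "turn_angle_deg", "radius", "tracked"
  )
  states <- dplyr::bind_rows(
    purrr::map2(per_fish, fish_ids, ~ dplyr::mutate(.x$states, fish_id = .y))
  )
  states <- dplyr::select(states, "fish_id", "trial_index", "state")

  structure(
    list(bouts = bouts, schedule = schedule, states = states, config = config),
    class = "omr_cohort"
  )
}

#' @export
print.omr_cohort <- function(x, ...) {
  cat(sprintf(
    "<omr_cohort> %d fish x %d trials, %d bouts (%.0f s baseline + %.0f s stimulus)\n",
    x$config$n_fish, x$config$n_trials, nrow(x$bouts),
    x$config$baseline_duration, x$config$stimulus_duration
  ))
  invisible(x)
}
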