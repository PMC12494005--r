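#' Parameters of the gated leaky drift-diffusion decision model
#'
#' Evidence `x` evolves as a leaky integrator
#' `dx = (gate * drift_gain * coherence - leak * x) dt + noise_sd dW`.
#' When the attention gate is closed only the sensory drive term is zeroed;
#' leak and noise are unchanged, so gated trajectories are distributed exactly
#' like 0%-coherence trajectories.
#'
#' @param drift_gain Sensory drive per unit (signed) coherence, evidence/s.
#' @param leak Leak rate, 1/s (>= 0).
#' @param noise_sd Diffusion scale, evidence/sqrt(s) (> 0).
#' @param threshold Decision threshold, evidence units (> 0).
#' @param gate `"open"` or `"closed"`.
#' @return A `ddm_params` list.
#' @export
ddm_params <- function(drift_gain = 7, leak = 2, noise_sd = 1.5,
                       threshold = 0.45, gate = c("open", "closed")) {
  gate <- match.arg(gate)
  if (leak < 0) abort("`leak` must be >= 0.")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (threshold <= 0) abort("`threshold` must be > 0.")
  structure(
    list(
      drift_gain = drift_gain, leak = leak, noise_sd = noise_sd,
      threshold = threshold, gate = gate
    ),
    class = "ddm_params"
  )
}

#' Integrate a single evidence trajectory (Euler-Maruyama)
#'
#' @param params A [ddm_params()].
#' @param coherence Signed coherence in `[-1, 1]` (positive = rightward).
#' @param duration Integration time, seconds.
#' @param dt Time step, seconds (default 0.005).
#' @param x0 Initial evidence.
#' @return A tibble with columns `time` and `evidence` (including t = 0).
#' @export
integrate_evidence <- function(params, coherence, duration, dt = 0.005, x0 = 0) {
  if (dt <= 0 || duration < dt) abort("Need `dt` > 0 and `duration` >= `dt`.")
  n <- floor(duration / dt)
  gate <- as.numeric(params$gate == "open")
  drive <- gate * params$drift_gain * coherence
  noise <- params$noise_sd * sqrt(dt) * rnorm(n)
  x <- numeric(n + 1)
  x[1] <- x0
  for (i in seq_len(n)) {
    x[i + 1] <- x[i] + (drive - params$leak * x[i]) * dt + noise[i]
  }
  tibble::tibble(time = dt * (0:n), evidence = x)
}

#' Map evidence at bout time to a turn decision
#'
#' Rightward if evidence exceeds `+threshold`, leftward below `-threshold`,
#' forward otherwise.
#'
#' @param evidence Numeric vector of evidence values.
#' @param threshold Positive decision threshold.
#' @return Character vector in `{"left", "forward", "right"}`.
#' @export
decide_turn <- function(evidence, threshold) {
  if (threshold <= 0) abort("`threshold` must be > 0.")
  dplyr::case_when(
    evidence > threshold ~ "right",
    evidence < -threshold ~ "left",
    TRUE ~ "forward"
  )
}

# Exact Ornstein-Uhlenbeck transition over a gap `dt`: mean decays to
# drive/leak, variance to noise^2/(2*leak). Used for bout-triggered readout so
# no discretization error enters the generator.
ou_step <- function(x, dt, drive, leak, noise_sd) {
  if (leak > 0) {
    e <- exp(-leak * dt)
    mu <- x * e + (drive / leak) * (1 - e)
    v <- noise_sd^2 * (1 - e^2) / (2 * leak)
  } else {
    mu <- x + drive * dt
    v <- noise_sd^2 * dt
  }
  mu + sqrt(v) * rnorm(length(x))
}

# Directions (-1 left / 0 forward / +1 right) for bouts at `times` (seconds
# from stimulus onset). Evidence starts at 0 at stimulus onset; with
# reset_on_turn = TRUE it also resets to 0 after every executed turn
# (forward bouts never reset). The default keeps the integrator running all
# trial, so evidence sits near its equilibrium for every bout after the
# first -- the regime in which only the first bout shows a latency effect.
ddm_bout_directions <- function(params, coherence, times, reset_on_turn = FALSE) {
  n <- length(times)
  if (n == 0L) {
    return(integer(0))
  }
  gate <- as.numeric(params$gate == "open")
  drive <- gate * params$drift_gain * coherence
  x <- 0
  t_prev <- 0
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- ou_step(x, times[i] - t_prev, drive, params$leak, params$noise_sd)
    t_prev <- times[i]
    if (x > params$threshold) {
      out[i] <- 1L
      if (reset_on_turn) x <- 0
    } else if (x < -params$threshold) {
      out[i] <- -1L
      if (reset_on_turn) x <- 0
    } else {
      out[i] <- 0L
    }
  }
  out
}

#' Simulate stimulus-period bout decisions from the gated DDM
#'
#' Bout times form a Poisson renewal process; at each bout the evidence of the
#' (exactly-sampled) leaky integrator is read out with [decide_turn()]
#' semantics. Evidence resets at stimulus onset; by default it is NOT reset
#' after turns (it stays near its equilibrium, so only the first bout shows a
#' latency effect), but `reset_on_turn = TRUE` restores per-turn resetting.
#' `method = "euler"` uses the Euler-Maruyama discretization of
#' [integrate_evidence()] instead of the exact transition; the two agree as
#' `dt -> 0`.
#'
#' @param params A [ddm_params()].
#' @param coherence Signed coherence (positive = rightward stimulus).
#' @param n_trials Number of independent trials.
#' @param duration Stimulus duration, seconds.
#' @param bout_rate Bout rate, bouts/min.
#' @param method `"exact"` or `"euler"`.
#' @param dt Step size for `method = "euler"`.
#' @param reset_on_turn Reset the integrator to 0 after each executed turn.
#' @return A tibble with one row per bout: `trial`, `bout_index`, `time_s`,
#'   `direction` (-1/0/+1), `correct` (1, 0.5 for forward, 0; against the sign
#'   of `coherence`, or against rightward when coherence is 0).
#' @export
simulate_ddm_bouts <- function(params, coherence, n_trials, duration = 30,
                               bout_rate = 75.2, method = c("exact", "euler"),
                               dt = 0.005, reset_on_turn = FALSE) {
  method <- match.arg(method)
  counts <- rpois(n_trials, bout_rate / 60 * duration)
  times <- purrr::map(counts, ~ sort(runif(.x, 0, duration)))
  gate <- as.numeric(params$gate == "open")
  drive <- gate * params$drift_gain * coherence

  dirs <- if (method == "exact") {
    # Vectorized across trials, stepping bout-by-bout with the exact OU kernel.
    m <- max(counts, 0L)
    tm <- matrix(NA_real_, nrow = n_trials, ncol = max(m, 1L))
    for (i in seq_len(n_trials)) {
      if (counts[i] > 0) tm[i, seq_len(counts[i])] <- times[[i]]
    }
    x <- numeric(n_trials)
    t_prev <- numeric(n_trials)
    out <- matrix(NA_integer_, nrow = n_trials, ncol = max(m, 1L))
    for (j in seq_len(m)) {
      act <- which(!is.na(tm[, j]))
      if (length(act) == 0) break
      gap <- tm[act, j] - t_prev[act]
      x[act] <- ou_step(x[act], gap, drive, params$leak, params$noise_sd)
      t_prev[act] <- tm[act, j]
      d <- integer(length(act))
      d[x[act] > params$threshold] <- 1L
      d[x[act] < -params$threshold] <- -1L
      if (reset_on_turn) x[act][d != 0L] <- 0
      out[act, j] <- d
    }
    purrr::map(seq_len(n_trials), function(i) {
      if (counts[i] == 0) integer(0) else out[i, seq_len(counts[i])]
    })
  } else {
    purrr::map(seq_len(n_trials), function(i) {
      tt <- times[[i]]
      if (length(tt) == 0) {
        return(integer(0))
      }
      d <- integer(length(tt))
      x <- 0
      t_prev <- 0
      for (k in seq_along(tt)) {
        nstep <- max(1L, round((tt[k] - t_prev) / dt))
        for (s in seq_len(nstep)) {
          x <- x + (drive - params$leak * x) * dt + params$noise_sd * sqrt(dt) * rnorm(1)
        }
        t_prev <- tt[k]
        if (x > params$threshold) {
          d[k] <- 1L
          if (reset_on_turn) x <- 0
        } else if (x < -params$threshold) {
          d[k] <- -1L
          if (reset_on_turn) x <- 0
        }
      }
      d
    })
  }

  target <- if (coherence >= 0) 1L else -1L
  tibble::tibble(
    trial = rep(seq_len(n_trials), counts),
    bout_index = unlist(purrr::map(counts, seq_len), use.names = FALSE),
    time_s = unlist(times, use.names = FALSE),
    direction = unlist(dirs, use.names = FALSE)
  ) |>
    dplyr::mutate(
      correct = dplyr::case_when(
        .data$direction == 0L ~ 0.5,
        .data$direction == target ~ 1,
        TRUE ~ 0
      )
    )
}

#' Psychometric curve of the gated DDM
#'
#' Mean per-trial performance score at each coherence level, with the SEM over
#' trials. Trials without bouts are dropped.
#'
#' @param params A [ddm_params()].
#' @param coherences Unsigned coherence grid in `[0, 1]`.
#' @param n_trials Trials simulated per coherence.
#' @param duration,bout_rate,method,dt Passed to [simulate_ddm_bouts()].
#' @return A tibble with `coherence`, `mean_score`, `sem`, `n_trials`.
#' @export
psychometric_curve <- function(params, coherences = seq(0, 1, by = 0.25),
                               n_trials = 1000, duration = 30, bout_rate = 75.2,
                               method = "exact", dt = 0.005) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  purrr::map_dfr(coherences, function(coh) {
    bouts <- simulate_ddm_bouts(
      params, coh, n_trials,
      duration = duration, bout_rate = bout_rate, method = method, dt = dt
    )
    scores <- bouts |>
      dplyr::summarise(score = 2 * mean(.data$correct) - 1, .by = "trial")
    tibble::tibble(
      coherence = coh,
      mean_score = mean(scores$score),
      sem = sd(scores$score) / sqrt(nrow(scores)),
      n_trials = nrow(scores)
    )
  })
}
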