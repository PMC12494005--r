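#' Standard bout filters
#'
#' Removes (i) untracked bouts, (ii) bouts initiated at a radius greater than
#' 90% of the dish radius (forced wall turns), and (iii) baseline bouts in the
#' first 30 s of the baseline period, where turning can carry residual effects
#' of the previous stimulus. The filter preserves row order and is idempotent.
#'
#' @param bouts A bout table (see [generate_cohort()] / [read_bout_table()]).
#' @param wall_threshold Radius cutoff (default 0.9).
#' @param baseline_ignore Seconds of baseline ignored at trial start.
#' @param exclude_wall Set `FALSE` to keep near-wall bouts (used e.g. when
#'   checking rate fidelity of the generator).
#' @return The filtered bout table.
#' @export
apply_filters <- function(bouts, wall_threshold = 0.9, baseline_ignore = 30,
                          exclude_wall = TRUE) {
  out <- dplyr::filter(
    bouts,
    .data$tracked,
    !(.data$period == "baseline" & .data$time_s < baseline_ignore)
  )
  if (exclude_wall) {
    out <- dplyr::filter(out, .data$radius <= wall_threshold)
  }
  out
}

#' Per-trial performance score
#'
#' The fraction of bouts turned toward the target, rescaled to `[-1, 1]`.
#' Positive angles are rightward turns, negative leftward; an angle of exactly
#' 0 (forward swim) contributes 50% correctness.
#'
#' @param turn_angles Turn angles in degrees.
#' @param target_direction `"left"` or `"right"`.
#' @return Score in `[-1, 1]`, or `NA_real_` for an empty angle set (the trial
#'   is then excluded downstream).
#' @export
performance_score <- function(turn_angles, target_direction) {
  target_direction <- match.arg(target_direction, c("left", "right"))
  if (length(turn_angles) == 0) {
    return(NA_real_)
  }
  correct <- if (target_direction == "right") {
    ifelse(turn_angles > 0, 1, ifelse(turn_angles < 0, 0, 0.5))
  } else {
    ifelse(turn_angles < 0, 1, ifelse(turn_angles > 0, 0, 0.5))
  }
  2 * mean(correct) - 1
}

#' Bout rate with tracked-time exclusion
#'
#' Number of bouts divided by the tracked portion of the observation window,
#' expressed in bouts per minute.
#'
#' @param n_bouts Bout count in the window.
#' @param window_s Window length, seconds.
#' @param untracked_s Seconds of the window in which the fish was not tracked
#'   (excluded from the denominator).
#' @return Bouts/min, or `NA_real_` when no tracked time remains.
#' @export
bout_rate <- function(n_bouts, window_s, untracked_s = 0) {
  tracked <- window_s - untracked_s
  if (any(tracked <= 0)) {
    if (length(tracked) == 1) {
      return(NA_real_)
    }
  }
  out <- n_bouts / tracked * 60
  out[tracked <= 0] <- NA_real_
  out
}

#' Summarise a bout table into per-trial metrics
#'
#' Applies [apply_filters()] and computes, for every (fish, trial) pair
#' present in the table: the stimulus-period performance score against the
#' scheduled stimulus direction, the baseline score against the random
#' baseline target, bout counts and rates, the latency and correctness of the
#' first stimulus-period bout, and the mean bout radius.
#'
#' @param bouts A bout table.
#' @param schedule A trial schedule from [generate_trial_schedule()].
#' @param baseline_duration,stimulus_duration Trial period lengths, seconds.
#' @param baseline_ignore,wall_threshold,exclude_wall Passed to
#'   [apply_filters()].
#' @return A tibble with one row per (fish, trial): `fish_id`, `trial_index`,
#'   `score`, `baseline_score`, `n_bouts`, `n_baseline_bouts`,
#'   `baseline_bout_rate`, `stimulus_bout_rate`, `first_bout_latency`,
#'   `first_bout_correct`, `mean_radius`.
#' @export
trial_summaries <- function(bouts, schedule,
                            baseline_duration = 150, stimulus_duration = 30,
                            baseline_ignore = 30, wall_threshold = 0.9,
                            exclude_wall = TRUE) {
  fb <- apply_filters(bouts,
    wall_threshold = wall_threshold,
    baseline_ignore = baseline_ignore, exclude_wall = exclude_wall
  )
  sched <- dplyr::select(schedule, "trial_index", "stim_direction", "baseline_target")
  base_window <- baseline_duration - baseline_ignore

  grid <- tidyr::expand_grid(
    fish_id = unique(bouts$fish_id),
    trial_index = schedule$trial_index
  )

  per_trial <- fb |>
    dplyr::left_join(sched, by = "trial_index") |>
    dplyr::summarise(
      score = performance_score(
        .data$turn_angle_deg[.data$period == "stimulus"],
        .data$stim_direction[1]
      ),
      baseline_score = performance_score(
        .data$turn_angle_deg[.data$period == "baseline"],
        .data$baseline_target[1]
      ),
      n_bouts = sum(.data$period == "stimulus"),
      n_baseline_bouts = sum(.data$period == "baseline"),
      first_bout_latency = if (any(.data$period == "stimulus")) {
        min(.data$time_s[.data$period == "stimulus"]) - baseline_duration
      } else {
        NA_real_
      },
      first_bout_correct = {
        stim <- .data$period == "stimulus"
        if (any(stim)) {
          a <- .data$turn_angle_deg[stim][which.min(.data$time_s[stim])]
          tgt <- .data$stim_direction[1]
          if (a == 0) 0.5 else as.numeric((a > 0) == (tgt == "right"))
        } else {
          NA_real_
        }
      },
      mean_radius = mean(.data$radius),
      .by = c("fish_id", "trial_index")
    )

  grid |>
    dplyr::left_join(per_trial, by = c("fish_id", "trial_index")) |>
    dplyr::mutate(
      n_bouts = dplyr::coalesce(.data$n_bouts, 0L),
      n_baseline_bouts = dplyr::coalesce(.data$n_baseline_bouts, 0L),
      baseline_bout_rate = bout_rate(.data$n_baseline_bouts, base_window),
      stimulus_bout_rate = bout_rate(.data$n_bouts, stimulus_duration)
    ) |>
    dplyr::select(
      "fish_id", "trial_index", "score", "baseline_score", "n_bouts",
      "n_baseline_bouts", "baseline_bout_rate", "stimulus_bout_rate",
      "first_bout_latency", "first_bout_correct", "mean_radius"
    ) |>
    dplyr::arrange(.data$fish_id, .data$trial_index)
}

#' The 21-bin performance-score layout
#'
#' Bin centers at -1.0, -0.9, ..., +1.0 (width 0.1, end bins clipped to the
#' score domain). All score histograms and mixture fits use this layout.
#'
#' @return A list with `breaks` (22 values) and `centers` (21 values).
#' @export
score_bins <- function() {
  centers <- seq(-1, 1, by = 0.1)
  breaks <- c(-1, centers[-length(centers)] + 0.05)
  breaks <- c(breaks, 1)
  list(breaks = breaks, centers = centers)
}

#' Histogram of performance scores on the 21-bin layout
#'
#' @param scores Scores in `[-1, 1]`; `NA`s (empty trials) are dropped.
#' @return A tibble with `bin_center`, `count`, `probability` (summing to 1).
#' @export
score_histogram <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (any(scores < -1 - 1e-9 | scores > 1 + 1e-9)) {
    abort("Scores must lie in [-1, 1].")
  }
  b <- score_bins()
  idx <- findInterval(scores, b$breaks, rightmost.closed = TRUE, left.open = TRUE)
  idx[scores <= b$breaks[2] & idx < 1] <- 1L
  counts <- tabulate(idx, nbins = 21L)
  tibble::tibble(
    bin_center = b$centers,
    count = counts,
    probability = if (sum(counts) > 0) counts / sum(counts) else rep(0, 21)
  )
}

#' Histogram of turn angles
#'
#' Bin width of 5 degrees over `(-180, 180]` (72 bins), normalized to a
#' probability distribution.
#'
#' @param angles Turn angles in degrees.
#' @return A tibble with `bin_center`, `count`, `probability`.
#' @export
turn_angle_histogram <- function(angles) {
  if (any(angles <= -180 | angles > 180)) abort("Angles must lie in (-180, 180].")
  breaks <- seq(-180, 180, by = 5)
  idx <- findInterval(angles, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  counts <- tabulate(idx, nbins = 72L)
  tibble::tibble(
    bin_center = breaks[-length(breaks)] + 2.5,
    count = counts,
    probability = if (sum(counts) > 0) counts / sum(counts) else rep(0, 72)
  )
}

#' Lengths of same-direction turn streaks
#'
#' A streak is a maximal run of consecutive turns with the same sign; forward
#' swims (angle 0) are dropped before computing runs.
#'
#' @param angles Turn angles in degrees, in bout order.
#' @return Integer vector of streak lengths (partitioning the nonzero turns).
#' @export
streak_lengths <- function(angles) {
  s <- sign(angles[angles != 0])
  if (length(s) == 0) {
    return(integer(0))
  }
  rle(s)$lengths
}

#' Bin per-trial performance by radius or first-bout latency
#'
#' Reproduces the standard summaries: mean score per 0.1-wide mean-radius bin,
#' or mean first-bout correctness per 100-ms latency bin, with SEM = sample
#' SD / sqrt(n) within each bin.
#'
#' @param trials A tibble from [trial_summaries()].
#' @param by `"radius"` (bins `score` by `mean_radius`) or `"latency"` (bins
#'   `first_bout_correct` by `first_bout_latency`).
#' @param max_latency Latencies above this (seconds) are dropped in the
#'   latency analysis (few bouts, noisy bins).
#' @return A tibble with `bin`, `mean`, `sem`, `n`.
#' @export
binned_performance <- function(trials, by = c("radius", "latency"), max_latency = 2) {
  by <- match.arg(by)
  if (by == "radius") {
    dat <- trials |>
      dplyr::filter(!is.na(.data$score), !is.na(.data$mean_radius)) |>
      dplyr::mutate(
        bin = pmin(floor(.data$mean_radius / 0.1), 9) * 0.1 + 0.05,
        value = .data$score
      )
  } else {
    dat <- trials |>
      dplyr::filter(
        !is.na(.data$first_bout_correct), !is.na(.data$first_bout_latency),
        .data$first_bout_latency <= max_latency
      ) |>
      dplyr::mutate(
        bin = floor(.data$first_bout_latency / 0.1) * 0.1 + 0.05,
        value = .data$first_bout_correct
      )
  }
  dat |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .by = "bin"
    ) |>
    dplyr::arrange(.data$bin)
}
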