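test_that("trial schedules balance left/right within every pair and are seeded", {
  sched <- generate_trial_schedule(cohort_config(n_fish = 1, n_trials = 30), seed = 7)
  expect_equal(sum(sched$stim_direction == "left"), 15)
  expect_equal(sum(sched$stim_direction == "right"), 15)
  pairs <- matrix(sched$stim_direction, nrow = 2)
  expect_true(all(apply(pairs, 2, function(p) setequal(p, c("left", "right")))))

  for (s in 1:25) {
    two <- generate_trial_schedule(cohort_config(n_fish = 1, n_trials = 2), seed = s)
    expect_setequal(two$stim_direction, c("left", "right"))
  }

  expect_identical(
    generate_trial_schedule(cohort_config(n_fish = 1, n_trials = 30), seed = 3),
    generate_trial_schedule(cohort_config(n_fish = 1, n_trials = 30), seed = 3)
  )
  expect_error(cohort_config(n_trials = 31), "even")
})

test_that("attention chain has the stationary occupancy and geometric dwells", {
  prof <- fish_profile(enter_rate = 1, exit_rate = 0)
  expect_true(all(simulate_attention_chain(prof, 50, seed = 1) == "engaged"))

  # stationary occupancy p/(p+q): first-trial states are exact iid draws
  prof <- fish_profile(enter_rate = 0.3, exit_rate = 0.15)
  firsts <- vapply(
    1:3000,
    function(s) simulate_attention_chain(prof, 1, seed = s)[1] == "engaged",
    logical(1)
  )
  occ <- 0.3 / 0.45
  se <- sqrt(occ * (1 - occ) / 3000)
  expect_lt(abs(mean(firsts) - occ), 3 * se)

  # symmetric rates: engaged fraction tends to 1/2
  prof <- fish_profile(enter_rate = 0.5, exit_rate = 0.5)
  states <- simulate_attention_chain(prof, 20000, seed = 2)
  expect_lt(abs(mean(states == "engaged") - 0.5), 3 * sqrt(0.25 / 20000))

  # stay-probability 0.8 in both states: mean dwell length 1/(1 - 0.8) = 5
  prof <- fish_profile(enter_rate = 0.2, exit_rate = 0.2)
  states <- simulate_attention_chain(prof, 10000, seed = 3)
  dwells <- rle(states)$lengths
  expect_lt(abs(mean(dwells) - 5), 0.4)
})

test_that("generate_cohort is deterministic and honors its invariants", {
  cfg <- cohort_config(n_fish = 5, n_trials = 6, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$bouts, b$bouts)
  expect_identical(a$schedule, b$schedule)

  expect_equal(nrow(dplyr::distinct(a$bouts, fish_id, trial_index)), 5 * 6)
  expect_true(all(a$bouts$radius >= 0 & a$bouts$radius <= 1))
  expect_true(all(a$bouts$turn_angle_deg > -180 & a$bouts$turn_angle_deg <= 180))
  within_trial <- ifelse(
    a$bouts$period == "baseline",
    a$bouts$time_s <= cfg$baseline_duration,
    a$bouts$time_s <= cfg$baseline_duration + cfg$stimulus_duration
  )
  expect_true(all(a$bouts$time_s >= 0 & within_trial))

  # degenerate stimulus rate: no stimulus-period bouts at all
  cfg0 <- cohort_config(n_fish = 3, n_trials = 4, stimulus_bout_rate = 0, seed = 1)
  c0 <- generate_cohort(cfg0)
  expect_equal(sum(c0$bouts$period == "stimulus"), 0)

  expect_error(generate_cohort(cfg, profiles = list(fish_profile())), "per fish")
})

test_that("measured bout rates match the configured rates within 5%", {
  cfg <- cohort_config(n_fish = 40, seed = 21)
  coh <- generate_cohort(cfg)
  tr <- trial_summaries(coh$bouts, coh$schedule, exclude_wall = FALSE)
  expect_lt(abs(mean(tr$baseline_bout_rate) / cfg$baseline_bout_rate - 1), 0.05)
  expect_lt(abs(mean(tr$stimulus_bout_rate) / cfg$stimulus_bout_rate - 1), 0.05)
})

test_that("wall distraction lowers engagement for fish near the wall", {
  cfg <- cohort_config(n_fish = 30, n_trials = 30, seed = 5)
  plain <- generate_cohort(cfg, fish_profile(wall_distraction_scale = 0))
  distracted <- generate_cohort(cfg, fish_profile(wall_distraction_scale = 8))
  expect_lt(
    mean(distracted$states$state == "engaged"),
    mean(plain$states$state == "engaged")
  )
})
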