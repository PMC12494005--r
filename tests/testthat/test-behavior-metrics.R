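make_bouts <- function(...) {
  tibble::tibble(...)
}

test_that("filters drop wall bouts, early-baseline bouts and untracked bouts, idempotently", {
  bouts <- make_bouts(
    fish_id = "f001",
    trial_index = 1L,
    time_s = c(10, 31, 100, 100, 155, 160),
    period = c("baseline", "baseline", "baseline", "baseline", "stimulus", "stimulus"),
    turn_angle_deg = c(5, -5, 10, 20, 30, -30),
    radius = c(0.5, 0.5, 0.95, 0.9, 0.5, 0.5),
    tracked = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- apply_filters(bouts)
  # t = 10 baseline dropped; radius 0.95 dropped; radius 0.90 kept (threshold
  # is strict >); untracked stimulus bout dropped
  expect_equal(out$time_s, c(31, 100, 155))
  expect_identical(apply_filters(out), out)
  # early *stimulus* bouts are never dropped by the baseline rule
  stim <- make_bouts(
    fish_id = "f", trial_index = 1L, time_s = 5, period = "stimulus",
    turn_angle_deg = 1, radius = 0.1, tracked = TRUE
  )
  expect_equal(nrow(apply_filters(stim)), 1)
})

test_that("performance score matches its definition and the count-based oracle", {
  expect_equal(performance_score(c(10, 20, 5), "right"), 1)
  expect_equal(performance_score(0, "right"), 0)
  expect_equal(performance_score(0, "left"), 0)
  expect_equal(performance_score(c(10, -10), "right"), 0)
  expect_true(is.na(performance_score(numeric(0), "left")))

  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    angles <- round(runif(n, -179, 180), 1)
    angles[runif(n) < 0.2] <- 0
    target <- sample(c("left", "right"), 1)
    expect_equal(performance_score(angles, target), oracle_score(angles, target))
  }
})

test_that("bout rate divides counts by tracked time in minutes", {
  expect_equal(bout_rate(10, 10), 60)
  expect_equal(bout_rate(10, 20, untracked_s = 10), 60)
  expect_equal(bout_rate(0, 45), 0)
  expect_true(is.na(bout_rate(3, 10, untracked_s = 10)))
})

test_that("score histograms use the 21-bin layout and normalize", {
  b <- score_bins()
  expect_length(b$centers, 21)
  expect_equal(b$centers, seq(-1, 1, by = 0.1))

  h <- score_histogram(c(0))
  expect_equal(nrow(h), 21)
  expect_equal(h$probability[h$bin_center == 0], 1)

  set.seed(3)
  h2 <- score_histogram(runif(500, -1, 1))
  expect_equal(sum(h2$probability), 1, tolerance = 1e-12)
  expect_equal(sum(h2$count), 500)

  # boundary scores land in the end bins
  h3 <- score_histogram(c(-1, 1))
  expect_equal(h3$count[c(1, 21)], c(1L, 1L))
})

test_that("turn angle histograms have 72 five-degree bins", {
  set.seed(4)
  a <- runif(300, -179.9, 180)
  h <- turn_angle_histogram(a)
  expect_equal(nrow(h), 72)
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)
  expect_error(turn_angle_histogram(c(-180)), "180")
})

test_that("streaks partition the signed turns", {
  expect_equal(streak_lengths(c(5, 3, -2, -7, 1)), c(2, 2, 1))
  expect_equal(streak_lengths(c(0, 0)), integer(0))
  set.seed(5)
  for (i in 1:50) {
    a <- runif(30, -10, 10)
    a[runif(30) < 0.3] <- 0
    expect_equal(sum(streak_lengths(a)), sum(a != 0))
  }
})

test_that("binned performance reports SEM = sd / sqrt(n)", {
  trials <- tibble::tibble(
    fish_id = "f", trial_index = 1:6,
    score = c(0.2, 0.4, 0.6, -0.1, 0.0, 0.1),
    mean_radius = c(0.11, 0.15, 0.19, 0.51, 0.55, 0.59),
    first_bout_latency = NA_real_, first_bout_correct = NA_real_
  )
  out <- binned_performance(trials, by = "radius")
  expect_equal(out$mean, c(mean(c(0.2, 0.4, 0.6)), mean(c(-0.1, 0, 0.1))))
  expect_equal(out$sem, c(sd(c(0.2, 0.4, 0.6)) / sqrt(3), sd(c(-0.1, 0, 0.1)) / sqrt(3)))
})

test_that("baseline scores of a persistence-free cohort are symmetric about 0", {
  coh <- tiny_cohort(
    n_fish = 12, seed = 9,
    baseline_persistence = 0.5, bias_switch_prob = 0
  )
  tr <- trial_summaries(coh$bouts, coh$schedule)
  s <- tr$baseline_score[!is.na(tr$baseline_score)]
  n <- length(s)
  g1 <- mean((s - mean(s))^3) / sd(s)^3
  expect_lt(abs(g1), 3 * sqrt(6 / n))
  expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(n))
})
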