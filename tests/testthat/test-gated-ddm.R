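test_that("evidence integration has the right deterministic limits", {
  # noise -> 0, leak = 0: pure ramp x(t) = gain * coherence * t
  p <- ddm_params(drift_gain = 2, leak = 0, noise_sd = 1e-9)
  tr <- integrate_evidence(p, coherence = 0.5, duration = 1, dt = 0.001)
  expect_equal(tail(tr$evidence, 1), 2 * 0.5 * 1, tolerance = 1e-2)

  # leak > 0: relaxation to the fixed point gain * coherence / leak
  p <- ddm_params(drift_gain = 4, leak = 2, noise_sd = 1e-9)
  tr <- integrate_evidence(p, coherence = 1, duration = 6, dt = 0.001)
  expect_equal(tail(tr$evidence, 1), 4 / 2, tolerance = 1e-2)

  expect_error(integrate_evidence(p, 1, duration = 0.001, dt = 0.01), "duration")
})

test_that("a closed gate is equivalent to zero coherence", {
  open0 <- withr::with_seed(5, integrate_evidence(ddm_params(), 0, 2))
  closed <- withr::with_seed(
    5, integrate_evidence(ddm_params(gate = "closed"), 1, 2)
  )
  expect_identical(open0$evidence, closed$evidence)
})

test_that("decide_turn thresholds the evidence", {
  expect_equal(decide_turn(0, 1), "forward")
  expect_equal(decide_turn(2, 1), "right")
  expect_equal(decide_turn(-2, 1), "left")
  expect_equal(decide_turn(c(-3, 0.5, 3), 1), c("left", "forward", "right"))
  expect_error(decide_turn(0, 0), "threshold")
})

test_that("decisions are left/right symmetric at zero coherence", {
  set.seed(6)
  b <- simulate_ddm_bouts(ddm_params(), 0, 2000, duration = 10)
  n_turn <- sum(b$direction != 0)
  p_right <- sum(b$direction == 1) / n_turn
  expect_lt(abs(p_right - 0.5), 3 * sqrt(0.25 / n_turn))
})

test_that("Euler-Maruyama readout agrees with the exact transition kernel", {
  set.seed(7)
  exact <- simulate_ddm_bouts(ddm_params(), 1, 400, duration = 10, method = "exact")
  euler <- simulate_ddm_bouts(ddm_params(), 1, 400, duration = 10, method = "euler")
  ms <- function(b) {
    s <- dplyr::summarise(b, sc = 2 * mean(correct) - 1, .by = trial)
    c(mean(s$sc), sd(s$sc) / sqrt(nrow(s)))
  }
  a <- ms(exact)
  b2 <- ms(euler)
  expect_lt(abs(a[1] - b2[1]), 4 * sqrt(a[2]^2 + b2[2]^2))
})

test_that("psychometric curve is flat at zero when the gate is closed", {
  set.seed(8)
  pc <- psychometric_curve(
    ddm_params(gate = "closed"), c(0, 0.5, 1),
    n_trials = 400, duration = 10
  )
  expect_true(all(abs(pc$mean_score) < 4 * pc$sem))
})
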