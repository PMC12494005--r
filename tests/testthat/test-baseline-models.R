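test_that("coin flip model gives exact binomial score distributions", {
  d1 <- coinflip_score_distribution(1)
  expect_equal(d1$score, c(-1, 1))
  expect_equal(d1$probability, c(0.5, 0.5))

  d2 <- coinflip_score_distribution(2)
  expect_equal(d2$score, c(-1, 0, 1))
  expect_equal(d2$probability, c(0.25, 0.5, 0.25))

  d100 <- coinflip_score_distribution(100)
  expect_equal(dist_sd(d100), 0.1, tolerance = 1e-12)

  # averaging over mixed counts
  dm <- coinflip_score_distribution(c(1, 2))
  expect_equal(dm$probability[dm$score == 0], 0.25)
  expect_equal(sum(dm$probability), 1, tolerance = 1e-12)

  expect_error(coinflip_score_distribution(0), ">= 1")
})

test_that("persistence model reduces to the coin flip at persist = 0.5", {
  m <- persistence_model(persist_prob = 0.5, switch_prob = 0.1)
  expect_equal(
    persistence_score_distribution(m, c(4, 9))$probability,
    coinflip_score_distribution(c(4, 9))$probability,
    tolerance = 1e-12
  )
})

test_that("frozen persistence puts all mass at -1 and +1", {
  m <- persistence_model(persist_prob = 1, switch_prob = 0)
  d <- persistence_score_distribution(m, 12)
  expect_equal(d$probability[abs(d$score) == 1], c(0.5, 0.5))
  expect_equal(sum(d$probability[abs(d$score) < 1]), 0)
})

test_that("the exact persistence distribution matches joint brute-force enumeration", {
  for (case in list(c(0.8, 0.1, 5), c(0.7, 0.3, 4), c(0.9, 0.02, 6))) {
    m <- persistence_model(case[1], case[2])
    got <- persistence_score_distribution(m, case[3])
    want <- oracle_persistence(case[1], case[2], case[3])
    expect_equal(got$probability, want$probability, tolerance = 1e-12)
  }
})

test_that("simulation converges to enumeration and enumeration bounds are enforced", {
  m <- persistence_model(0.8, 0.05)
  exact <- persistence_score_distribution(m, 10)
  set.seed(31)
  sim <- persistence_score_distribution(m, 10, method = "simulate", n_sim = 1e5)
  expect_lt(tv_distance(exact, sim), 0.01)
  expect_error(persistence_score_distribution(m, 25), "<= 20")
})

test_that("distribution width grows with persistence and stays symmetric", {
  sds <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(p) {
    dist_sd(persistence_score_distribution(persistence_model(p, 0.05), 15))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))

  d <- persistence_score_distribution(persistence_model(0.8, 0.05), 9)
  expect_equal(d$probability, rev(d$probability), tolerance = 1e-12)
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)
})

test_that("score distributions bin onto the 21-bin layout without losing mass", {
  d <- coinflip_score_distribution(c(7, 12))
  binned <- bin_score_distribution(d)
  expect_equal(nrow(binned), 21)
  expect_equal(sum(binned$probability), 1, tolerance = 1e-12)
})
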