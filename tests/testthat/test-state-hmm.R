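two_state <- function() {
  gamma_hmm_params(
    pi = c(0.6, 0.4),
    A = matrix(c(0.85, 0.15, 0.2, 0.8), 2, byrow = TRUE),
    shape = c(6, 4), rate = c(100, 8)
  )
}

test_that("emission transform maps scores to clipped ceiling distances", {
  expect_equal(emission_transform(1), 1e-6)
  expect_equal(emission_transform(0), 0.5)
  expect_equal(emission_transform(-1), 1)
  s <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(emission_transform(s)) <= 0))
  expect_error(emission_transform(1.5), "\\[-1, 1\\]")
})

test_that("forward log-likelihood matches i.i.d. gamma for one state", {
  set.seed(20)
  d <- rgamma(40, shape = 3, rate = 10)
  p1 <- gamma_hmm_params(1, matrix(1, 1, 1), 3, 10)
  expect_equal(
    hmm_loglik(p1, d),
    sum(dgamma(d, shape = 3, rate = 10, log = TRUE)),
    tolerance = 1e-10
  )
})

test_that("forward log-likelihood matches brute-force path enumeration", {
  p <- two_state()
  set.seed(21)
  for (len in c(3, 5)) {
    d <- rgamma(len, shape = 3, rate = 10)
    expect_equal(hmm_loglik(p, d), oracle_hmm_loglik(p, d), tolerance = 1e-10)
  }
})

test_that("the likelihood is invariant to state relabeling", {
  p <- two_state()
  swapped <- gamma_hmm_params(
    p$pi[2:1], p$A[2:1, 2:1], p$shape[2:1], p$rate[2:1]
  )
  set.seed(22)
  d <- rgamma(25, shape = 4, rate = 9)
  expect_equal(hmm_loglik(p, d), hmm_loglik(swapped, d), tolerance = 1e-12)
})

test_that("posteriors normalize and the scaled pass agrees with the log-space forward", {
  p <- two_state()
  sim <- sample_hmm(p, 30, 8, seed = 23)
  seqs <- split(sim$d, sim$sequence)
  X <- do.call(rbind, seqs)
  fb <- omrfocus:::forward_backward_batch(p, X)
  expect_equal(max(abs(rowSums(matrix(fb$post, ncol = 2)) - 1)), 0, tolerance = 1e-10)
  expect_equal(fb$loglik, hmm_loglik(p, seqs), tolerance = 1e-8)
})

test_that("EM increases the likelihood monotonically and k=1 matches the MLE", {
  skip_if_not_installed("MASS")
  set.seed(24)
  d <- rgamma(600, shape = 2.5, rate = 7)
  fit <- fit_hmm(list(d), k = 1, n_starts = 2, seed = 1)
  expect_true(all(diff(fit$trace) > -1e-8 * abs(fit$trace[-1])))
  mle <- MASS::fitdistr(d, "gamma")
  expect_equal(fit$params$shape, unname(mle$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$params$rate, unname(mle$estimate["rate"]), tolerance = 1e-3)
})

test_that("EM recovers a well-separated two-state model and decodes it", {
  truth <- two_state()
  sim <- sample_hmm(truth, 30, 50, seed = 25)
  seqs <- split(sim$d, sim$sequence)
  fit <- fit_hmm(seqs, k = 2, seed = 26)
  expect_true(all(diff(fit$trace) > -1e-8 * abs(fit$trace[-1])))
  expect_lt(max(abs(fit$params$A - truth$A)), 0.05)

  pd <- posterior_decode(fit, seqs)
  truth_states <- unlist(split(sim$state, sim$sequence), use.names = FALSE)
  expect_gt(mean(pd$map_state == truth_states), 0.9)
  expect_equal(
    max(abs(pd$p_state_1 + pd$p_state_2 - 1)), 0,
    tolerance = 1e-10
  )
  # canonical order: state 1 has the higher mean score
  expect_gt(fit$state_means[1], fit$state_means[2])
})

test_that("dwell distributions follow the Markov-chain geometry", {
  p <- two_state()
  gen <- dwell_times(p, max_len = 50)
  s1 <- gen[gen$state == 1, ]
  expect_equal(s1$probability, 0.85^(s1$length - 1) * 0.15, tolerance = 1e-12)
  expect_equal(sum(s1$probability), 1, tolerance = 1e-3)

  # identity transitions: a single dwell spanning the sequence
  frozen <- gamma_hmm_params(
    c(0.5, 0.5), diag(2),
    shape = c(6, 4), rate = c(100, 8)
  )
  sim <- sample_hmm(frozen, 20, 4, seed = 27)
  pd <- posterior_decode(fit_hmm_stub(frozen), split(sim$d, sim$sequence))
  emp <- dwell_times(pd)
  expect_true(all(emp$length == 20))
})

test_that("cross-validation folds are seed-stable", {
  truth <- two_state()
  sim <- sample_hmm(truth, 15, 10, seed = 28)
  seqs <- split(sim$d, sim$sequence)
  cv1 <- cross_validate_states(seqs, k_range = 1:2, n_starts = 2, seed = 5)
  cv2 <- cross_validate_states(seqs, k_range = 1:2, n_starts = 2, seed = 5)
  expect_identical(cv1, cv2)
  expect_gt(cv1$mean_heldout_loglik[2], cv1$mean_heldout_loglik[1])
})

test_that("trials tibbles round through fitting and decoding", {
  truth <- two_state()
  sim <- sample_hmm(truth, 12, 6, seed = 29)
  trials <- tibble::tibble(
    fish_id = sprintf("f%02d", sim$sequence),
    trial_index = sim$trial_index,
    score = sim$score
  )
  fit <- fit_hmm(trials, k = 2, n_starts = 3, seed = 30)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$k, 2)
  pd <- posterior_decode(fit, trials)
  expect_equal(nrow(pd), nrow(trials))
})
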