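# Independent oracles used across the suite. These deliberately use brute
# force / closed forms, never the implementation paths they check.

# Count-based performance score: fraction of bouts toward the target (a zero
# angle counts one half), rescaled to [-1, 1].
oracle_score <- function(angles, target) {
  n_right <- sum(angles > 0)
  n_left <- sum(angles < 0)
  n_fwd <- sum(angles == 0)
  correct <- if (target == "right") n_right else n_left
  2 * ((correct + 0.5 * n_fwd) / length(angles)) - 1
}

# Exact score distribution of the two-level persistence chain by joint
# enumeration over all 2^n direction sequences x 2^n bias paths x 2 initial
# biases (feasible for n <= 6).
oracle_persistence <- function(persist, switch, n) {
  probs <- setNames(numeric(n + 1), as.character(0:n))
  combos <- expand.grid(rep(list(c(-1L, 1L)), 2 * n + 1))
  for (row in seq_len(nrow(combos))) {
    v <- as.integer(combos[row, ])
    bias0 <- v[1]
    dirs <- v[2:(n + 1)]
    flips <- v[(n + 2):(2 * n + 1)] # +1 = keep, -1 = flip, applied after emit
    p <- 0.5
    bias <- bias0
    for (b in seq_len(n)) {
      p <- p * if (dirs[b] == bias) persist else 1 - persist
      p <- p * if (flips[b] == 1L) 1 - switch else switch
      bias <- bias * flips[b]
    }
    k <- sum(dirs == 1L)
    probs[k + 1] <- probs[k + 1] + p
  }
  tibble::tibble(score = (2 * (0:n) - n) / n, probability = unname(probs))
}

# HMM likelihood by explicit summation over all k^T state paths.
oracle_hmm_loglik <- function(params, d) {
  k <- params$k
  tt <- length(d)
  paths <- expand.grid(rep(list(seq_len(k)), tt))
  total <- 0
  for (row in seq_len(nrow(paths))) {
    z <- as.integer(paths[row, ])
    p <- params$pi[z[1]]
    if (tt > 1) {
      for (t in 2:tt) p <- p * params$A[z[t - 1], z[t]]
    }
    p <- p * prod(dgamma(d, shape = params$shape[z], rate = params$rate[z]))
    total <- total + p
  }
  log(total)
}

# Total variation distance between two score distributions on a shared grid.
tv_distance <- function(d1, d2) {
  merged <- merge(d1, d2, by = "score", all = TRUE)
  merged[is.na(merged)] <- 0
  sum(abs(merged$probability.x - merged$probability.y)) / 2
}

dist_sd <- function(dist) {
  m <- sum(dist$score * dist$probability)
  sqrt(sum((dist$score - m)^2 * dist$probability))
}

# Wrap raw parameters so posterior_decode() can be driven without an EM fit.
fit_hmm_stub <- function(params) {
  structure(list(params = params), class = "omr_hmm")
}

# Small cohort shared by several metric tests.
tiny_cohort <- function(n_fish = 4, seed = 42, ...) {
  generate_cohort(cohort_config(n_fish = n_fish, seed = seed), fish_profile(...))
}
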