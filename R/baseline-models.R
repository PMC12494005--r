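#' Directional-persistence model of baseline turning
#'
#' A two-level chain: the fish holds a latent side bias, turns toward it with
#' probability `persist_prob` on each bout, and the bias itself flips to the
#' opposite side with probability `switch_prob` after each bout. With
#' `persist_prob = 0.5` the model reduces to a fair coin flip per bout.
#'
#' @param persist_prob Probability of turning toward the current bias.
#' @param switch_prob Per-bout probability the bias flips.
#' @return A `persistence_model` list.
#' @export
persistence_model <- function(persist_prob = 0.85, switch_prob = 0.02) {
  stopifnot_prob(persist_prob, "persist_prob")
  stopifnot_prob(switch_prob, "switch_prob")
  structure(
    list(persist_prob = persist_prob, switch_prob = switch_prob),
    class = "persistence_model"
  )
}

#' Coin-flip model of baseline performance scores
#'
#' Treats every bout as an independent fair coin flip. For a trial with `n`
#' bouts the achievable scores are `(2k - n) / n` with exact binomial
#' probabilities; the returned distribution is the average of these exact
#' distributions over all supplied bout counts.
#'
#' @param bout_counts Per-trial bout counts (all >= 1).
#' @return A tibble with `score` and `probability` (exact support; use
#'   [bin_score_distribution()] for the 21-bin layout).
#' @export
coinflip_score_distribution <- function(bout_counts) {
  if (length(bout_counts) == 0 || any(bout_counts < 1)) {
    abort("`bout_counts` must all be >= 1.")
  }
  bout_counts <- as.integer(bout_counts)
  tab <- table(bout_counts)
  ns <- as.integer(names(tab))
  wts <- as.numeric(tab) / length(bout_counts)
  purrr::map2_dfr(ns, wts, function(n, w) {
    k <- 0:n
    tibble::tibble(score = (2 * k - n) / n, probability = w * dbinom(k, n, 0.5))
  }) |>
    dplyr::summarise(probability = sum(.data$probability), .by = "score") |>
    dplyr::arrange(.data$score)
}

# Exact score distribution for one bout count under the persistence chain,
# by dynamic programming over (bias side, number of rightward turns). This
# sums the same terms as explicit enumeration of all 2^n direction sequences.
persistence_exact_one <- function(model, n) {
  p <- model$persist_prob
  s <- model$switch_prob
  # prob[bias + 1, k + 1]; bias index 1 = left-biased, 2 = right-biased
  prob <- matrix(0, nrow = 2, ncol = n + 1)
  prob[1, 1] <- 0.5
  prob[2, 1] <- 0.5
  for (b in seq_len(n)) {
    nxt <- matrix(0, nrow = 2, ncol = n + 1)
    for (bias in 1:2) {
      p_right <- if (bias == 2) p else 1 - p
      for (k in 0:(b - 1)) {
        m <- prob[bias, k + 1]
        if (m == 0) next
        stay <- if (bias == 1) c(1 - s, s) else c(s, 1 - s)
        # turn right
        nxt[1, k + 2] <- nxt[1, k + 2] + m * p_right * stay[1]
        nxt[2, k + 2] <- nxt[2, k + 2] + m * p_right * stay[2]
        # turn left
        nxt[1, k + 1] <- nxt[1, k + 1] + m * (1 - p_right) * stay[1]
        nxt[2, k + 1] <- nxt[2, k + 1] + m * (1 - p_right) * stay[2]
      }
    }
    prob <- nxt
  }
  k <- 0:n
  tibble::tibble(score = (2 * k - n) / n, probability = colSums(prob))
}

#' Score distribution under the directional-persistence model
#'
#' Either an exact distribution (summation over all direction sequences,
#' organized as a dynamic program; limited to `n <= 20` per the quoted
#' combinatorial bound) or a Monte Carlo estimate. Distributions for multiple
#' bout counts are averaged, as in [coinflip_score_distribution()].
#'
#' @param model A [persistence_model()].
#' @param bout_counts Per-trial bout counts (all >= 1).
#' @param method `"enumerate"` (exact, `n <= 20`) or `"simulate"`.
#' @param n_sim Simulated trials per distinct bout count.
#' @return A tibble with `score` and `probability`.
#' @export
persistence_score_distribution <- function(model, bout_counts,
                                           method = c("enumerate", "simulate"),
                                           n_sim = 1e5) {
  method <- match.arg(method)
  if (length(bout_counts) == 0 || any(bout_counts < 1)) {
    abort("`bout_counts` must all be >= 1.")
  }
  bout_counts <- as.integer(bout_counts)
  if (method == "enumerate" && any(bout_counts > 20)) {
    abort("Exact enumeration is limited to bout counts <= 20.")
  }
  tab <- table(bout_counts)
  ns <- as.integer(names(tab))
  wts <- as.numeric(tab) / length(bout_counts)
  dists <- purrr::map2_dfr(ns, wts, function(n, w) {
    d <- if (method == "enumerate") {
      persistence_exact_one(model, n)
    } else {
      persistence_simulate_one(model, n, n_sim)
    }
    dplyr::mutate(d, probability = .data$probability * w)
  })
  dists |>
    dplyr::summarise(probability = sum(.data$probability), .by = "score") |>
    dplyr::arrange(.data$score)
}

persistence_simulate_one <- function(model, n, n_sim) {
  p <- model$persist_prob
  s <- model$switch_prob
  bias <- ifelse(runif(n_sim) < 0.5, 1L, -1L)
  k <- numeric(n_sim)
  for (b in seq_len(n)) {
    follow <- runif(n_sim) < p
    dir <- ifelse(follow, bias, -bias)
    k <- k + (dir == 1L)
    flip <- runif(n_sim) < s
    bias <- ifelse(flip, -bias, bias)
  }
  tibble::tibble(score = (2 * (0:n) - n) / n, probability = tabulate(k + 1, n + 1) / n_sim)
}

#' Bin an exact score distribution to the 21-bin layout
#'
#' @param dist A tibble with `score` and `probability` columns.
#' @return A tibble with `bin_center` and `probability` (21 rows, summing to
#'   the total input mass).
#' @export
bin_score_distribution <- function(dist) {
  b <- score_bins()
  idx <- findInterval(dist$score, b$breaks, rightmost.closed = TRUE, left.open = TRUE)
  idx[dist$score <= b$breaks[2] & idx < 1] <- 1L
  probs <- vapply(
    seq_len(21),
    function(i) sum(dist$probability[idx == i]),
    numeric(1)
  )
  tibble::tibble(bin_center = b$centers, probability = probs)
}
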