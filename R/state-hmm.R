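#' Map performance scores to the positive emission scale
#'
#' Gamma emissions need positive support; scores are mapped to the ceiling
#' distance `d = (1 - score) / 2` (0 = perfect, 1 = fully against the
#' stimulus), clipped away from zero so perfect trials keep finite densities.
#'
#' @param score Scores in `[-1, 1]`.
#' @param floor Lower clip for `d` (default `1e-6`).
#' @return Emission values in `[floor, 1]`.
#' @export
emission_transform <- function(score, floor = 1e-6) {
  if (any(score < -1 - 1e-9 | score > 1 + 1e-9, na.rm = TRUE)) {
    abort("`score` must lie in [-1, 1].")
  }
  pmax((1 - score) / 2, floor)
}

#' Construct gamma-HMM parameters
#'
#' @param pi Initial state distribution (length k, sums to 1).
#' @param A k x k row-stochastic transition matrix.
#' @param shape,rate Per-state gamma emission parameters (length k, > 0).
#' @return A `gamma_hmm_params` list.
#' @export
gamma_hmm_params <- function(pi, A, shape, rate) {
  k <- length(pi)
  A <- as.matrix(A)
  if (!all(dim(A) == k) || length(shape) != k || length(rate) != k) {
    abort("Dimension mismatch among `pi`, `A`, `shape`, `rate`.")
  }
  if (abs(sum(pi) - 1) > 1e-10 || any(pi < 0)) abort("`pi` must be a probability vector.")
  if (any(abs(rowSums(A) - 1) > 1e-10) || any(A < 0)) {
    abort("Rows of `A` must sum to 1.")
  }
  if (any(shape <= 0) || any(rate <= 0)) abort("Emission shapes/rates must be > 0.")
  structure(
    list(k = k, pi = as.numeric(pi), A = A, shape = as.numeric(shape), rate = as.numeric(rate)),
    class = "gamma_hmm_params"
  )
}

# Coerce sequence inputs into a list of emission sequences on the d scale.
# A trials data frame (fish_id / trial_index / score) is transformed from the
# score scale; a numeric vector or list of vectors is taken to be on the
# positive emission scale already (use emission_transform() for scores).
as_emission_sequences <- function(x) {
  if (is.data.frame(x)) {
    x <- x |>
      dplyr::filter(!is.na(.data$score)) |>
      dplyr::arrange(.data$fish_id, .data$trial_index)
    seqs <- split(x$score, x$fish_id)
    return(purrr::map(seqs, emission_transform))
  }
  if (is.numeric(x)) x <- list(x)
  purrr::map(x, function(s) {
    if (any(s <= 0)) abort("Emission sequences must be positive (d scale).")
    s
  })
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

#' Log-likelihood of emission sequences under a gamma HMM
#'
#' Computed with the forward algorithm in log space.
#'
#' @param params A [gamma_hmm_params()].
#' @param x A single emission sequence (positive values on the d scale), a
#'   list of such sequences, or a trials tibble with `fish_id`, `trial_index`,
#'   `score` columns (scores are transformed internally).
#' @return Total log-likelihood across sequences.
#' @export
hmm_loglik <- function(params, x) {
  seqs <- as_emission_sequences(x)
  log_a <- log(params$A)
  log_pi <- log(params$pi)
  sum(purrr::map_dbl(seqs, function(d) {
    lb <- vapply(
      seq_len(params$k),
      function(j) dgamma(d, shape = params$shape[j], rate = params$rate[j], log = TRUE),
      numeric(length(d))
    )
    lb <- matrix(lb, nrow = length(d))
    la <- log_pi + lb[1, ]
    if (length(d) > 1) {
      for (t in 2:length(d)) {
        la <- apply(la + log_a, 2, logsumexp) + lb[t, ]
      }
    }
    logsumexp(la)
  }))
}

# Scaled forward-backward for a batch of equal-length sequences.
# X: n_seq x T matrix of emissions. Returns posteriors (n_seq x T x k as a
# list of n_seq x k matrices per t), expected transition counts, expected
# initial counts, and the total log-likelihood.
forward_backward_batch <- function(params, X) {
  n <- nrow(X)
  tt <- ncol(X)
  k <- params$k
  B <- array(0, dim = c(n, tt, k))
  for (j in seq_len(k)) {
    B[, , j] <- dgamma(X, shape = params$shape[j], rate = params$rate[j])
  }
  B[B < 1e-300] <- 1e-300
  alpha <- array(0, dim = c(n, tt, k))
  beta <- array(0, dim = c(n, tt, k))
  cs <- matrix(0, n, tt)

  a <- sweep(matrix(B[, 1, ], n, k), 2, params$pi, `*`)
  cs[, 1] <- rowSums(a)
  alpha[, 1, ] <- a / cs[, 1]
  if (tt > 1) {
    for (t in 2:tt) {
      a <- (matrix(alpha[, t - 1, ], n, k) %*% params$A) * matrix(B[, t, ], n, k)
      cs[, t] <- rowSums(a)
      alpha[, t, ] <- a / cs[, t]
    }
  }
  beta[, tt, ] <- 1
  if (tt > 1) {
    for (t in (tt - 1):1) {
      bb <- matrix(beta[, t + 1, ], n, k) * matrix(B[, t + 1, ], n, k)
      beta[, t, ] <- (bb %*% t(params$A)) / cs[, t + 1]
    }
  }
  post <- alpha * beta # already normalized per (seq, t)

  xi <- matrix(0, k, k)
  if (tt > 1) {
    for (t in 2:tt) {
      lhs <- matrix(alpha[, t - 1, ], n, k)
      rhs <- matrix(beta[, t, ], n, k) * matrix(B[, t, ], n, k) / cs[, t]
      xi <- xi + t(lhs) %*% rhs * params$A
    }
  }
  list(
    post = post,
    xi = xi,
    init = colSums(matrix(post[, 1, ], n, k)),
    loglik = sum(log(cs))
  )
}

# Random moment-matched initialization: group emissions by jittered quantile
# cuts and moment-match a gamma per group.
init_hmm_params <- function(d_all, k) {
  if (k == 1) {
    m <- mean(d_all)
    v <- max(var(d_all), 1e-8)
    return(gamma_hmm_params(1, matrix(1, 1, 1), m^2 / v, m / v))
  }
  qs <- sort(runif(k - 1, 0.15, 0.85))
  cuts <- quantile(d_all, qs)
  grp <- findInterval(d_all, cuts) + 1
  shape <- numeric(k)
  rate <- numeric(k)
  for (j in seq_len(k)) {
    xs <- d_all[grp == j]
    if (length(xs) < 2) xs <- sample(d_all, max(2, length(d_all) %/% k))
    m <- mean(xs)
    v <- max(var(xs), 1e-8)
    shape[j] <- max(m^2 / v, 1e-3)
    rate[j] <- max(m / v, 1e-3)
  }
  stay <- runif(1, 0.6, 0.95)
  A <- matrix((1 - stay) / (k - 1), k, k)
  diag(A) <- stay
  pi <- rep(1 / k, k)
  gamma_hmm_params(pi, A, shape, rate)
}

# Weighted gamma MLE via Newton iteration on the digamma equation.
gamma_weighted_mle <- function(x, w) {
  W <- sum(w)
  mx <- sum(w * x) / W
  mlx <- sum(w * log(x)) / W
  s <- max(log(mx) - mlx, 1e-10)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:100) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * (a + 1e-12)) {
      a <- a_new
      break
    }
    a <- a_new
  }
  a <- min(max(a, 1e-4), 1e6)
  list(shape = a, rate = a / mx)
}

# Sequences of unequal length are batched per length group; sufficient
# statistics are accumulated across groups.
em_single_run <- function(Xs, k, tol, max_iter) {
  x_all <- unlist(purrr::map(Xs, as.numeric), use.names = FALSE)
  params <- init_hmm_params(x_all, k)
  ll_trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  any_transitions <- any(purrr::map_int(Xs, ncol) > 1)
  for (iter in seq_len(max_iter)) {
    fbs <- purrr::map(Xs, ~ forward_backward_batch(params, .x))
    ll <- sum(purrr::map_dbl(fbs, "loglik"))
    ll_trace <- c(ll_trace, ll)
    if (ll < prev - 1e-8 * abs(prev)) {
      warn("EM log-likelihood decreased; stopping.")
      break
    }
    if (is.finite(prev) && abs(ll - prev) < tol * (abs(prev) + 1)) {
      converged <- TRUE
      break
    }
    prev <- ll
    init <- Reduce(`+`, purrr::map(fbs, "init"))
    xi <- Reduce(`+`, purrr::map(fbs, "xi"))
    pi_new <- init / sum(init)
    A_new <- if (any_transitions) xi / rowSums(xi) else params$A
    A_new[!is.finite(A_new)] <- 1 / k
    post_all <- do.call(rbind, purrr::map(fbs, function(fb) {
      matrix(fb$post, ncol = k) # (n * t) x k, same unrolling as as.numeric(X)
    }))
    shape <- numeric(k)
    rate <- numeric(k)
    for (j in seq_len(k)) {
      mle <- gamma_weighted_mle(x_all, post_all[, j] + 1e-12)
      shape[j] <- mle$shape
      rate[j] <- mle$rate
    }
    params <- gamma_hmm_params(pmax(pi_new, 1e-12) / sum(pmax(pi_new, 1e-12)), A_new, shape, rate)
  }
  list(params = params, loglik = ll_trace[length(ll_trace)], trace = ll_trace, converged = converged)
}

# Canonical state order: by mean performance score (descending), i.e. mean
# emission d ascending; state 1 is the engaged state.
canonicalize_hmm <- function(params) {
  ord <- order(params$shape / params$rate)
  gamma_hmm_params(
    params$pi[ord], params$A[ord, ord, drop = FALSE],
    params$shape[ord], params$rate[ord]
  )
}

#' Fit a gamma-emission HMM by expectation maximization
#'
#' Sequences are per-fish trial chains (transitions across fish are
#' meaningless and are never modeled). The E step uses scaled
#' forward-backward; the M step updates `pi` and `A` in closed form and the
#' gamma emissions by weighted maximum likelihood (Newton on the digamma
#' equation). The best of `n_starts` random moment-matched initializations is
#' returned, with states canonically ordered by mean performance (state 1 =
#' engaged).
#'
#' @param x Trials tibble (`fish_id`, `trial_index`, `score`), or a list of
#'   positive emission sequences (apply [emission_transform()] to scores).
#' @param k Number of hidden states (>= 1).
#' @param n_starts Random restarts (default 10).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Optional seed.
#' @return An object of class `omr_hmm`: `params` ([gamma_hmm_params()]),
#'   `loglik`, `trace` (per-iteration log-likelihood of the winning start),
#'   `converged`, `n_seq`, `n_obs`, `state_means` (mean score per state).
#' @export
fit_hmm <- function(x, k = 2, n_starts = 10, tol = 1e-7, max_iter = 200, seed = NULL) {
  if (k < 1) abort("`k` must be >= 1.")
  seqs <- as_emission_sequences(x)
  if (any(purrr::map_int(seqs, length) == 0)) {
    seqs <- seqs[purrr::map_int(seqs, length) > 0]
  }
  lens <- purrr::map_int(seqs, length)
  Xs <- purrr::map(split(seqs, lens), ~ do.call(rbind, .x))
  run <- function() {
    best <- NULL
    for (s in seq_len(n_starts)) {
      fit <- tryCatch(em_single_run(Xs, k, tol, max_iter), error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best
  }
  best <- if (is.null(seed)) run() else with_seed(seed, run())
  if (is.null(best)) abort("All EM starts failed.")
  params <- canonicalize_hmm(best$params)
  structure(
    list(
      params = params,
      loglik = best$loglik,
      trace = best$trace,
      converged = best$converged,
      n_seq = length(seqs),
      n_obs = sum(lens),
      state_means = 1 - 2 * params$shape / params$rate
    ),
    class = "omr_hmm"
  )
}

#' @export
print.omr_hmm <- function(x, ...) {
  cat(sprintf(
    "<omr_hmm> k = %d states, loglik = %.2f (%d sequences)%s\n",
    x$params$k, x$loglik, x$n_seq,
    if (!x$converged) " [not converged]" else ""
  ))
  for (j in seq_len(x$params$k)) {
    cat(sprintf(
      "  state %d: mean score %.2f (shape %.2f, rate %.2f), stay prob %.2f\n",
      j, x$state_means[j], x$params$shape[j], x$params$rate[j], x$params$A[j, j]
    ))
  }
  invisible(x)
}

#' @rdname fit_hmm
#' @param object,... For `tidy`/`glance`: an `omr_hmm` fit.
#' @export
tidy.omr_hmm <- function(x, ...) {
  k <- x$params$k
  tibble::tibble(
    state = seq_len(k),
    label = ifelse(seq_len(k) == 1, "engaged", ifelse(k == 2, "disengaged", paste0("state_", seq_len(k)))),
    shape = x$params$shape,
    rate = x$params$rate,
    mean_score = x$state_means,
    stay_prob = diag(x$params$A),
    initial_prob = x$params$pi
  )
}

#' @rdname fit_hmm
#' @export
glance.omr_hmm <- function(x, ...) {
  tibble::tibble(
    k = x$params$k,
    loglik = x$loglik,
    n_seq = x$n_seq,
    n_obs = x$n_obs,
    n_iter = length(x$trace),
    converged = x$converged
  )
}

viterbi_path <- function(params, d) {
  k <- params$k
  n <- length(d)
  lb <- vapply(
    seq_len(k),
    function(j) dgamma(d, shape = params$shape[j], rate = params$rate[j], log = TRUE),
    numeric(n)
  )
  lb <- matrix(lb, nrow = n)
  la <- log(params$A)
  v <- log(params$pi) + lb[1, ]
  back <- matrix(0L, n, k)
  if (n > 1) {
    for (t in 2:n) {
      m <- v + la # m[i, j] = v_i + log A_ij
      back[t, ] <- max.col(t(m), ties.method = "first")
      v <- m[cbind(back[t, ], seq_len(k))] + lb[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v)
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  path
}

#' Posterior state decoding
#'
#' Forward-backward posteriors per trial plus the maximum a posteriori
#' (Viterbi) state path. State 1 is the engaged state (highest mean
#' performance).
#'
#' @param fit An `omr_hmm` from [fit_hmm()].
#' @param x Trials tibble or sequences as in [fit_hmm()].
#' @return A tibble with `sequence` (fish id where available), `trial_index`,
#'   `map_state`, `p_engaged`, and one posterior column per state.
#' @export
posterior_decode <- function(fit, x) {
  seq_names <- if (is.data.frame(x)) {
    x2 <- dplyr::filter(x, !is.na(.data$score))
    as.character(sort(unique(x2$fish_id)))
  } else {
    NULL
  }
  seqs <- as_emission_sequences(x)
  params <- fit$params
  out <- purrr::imap_dfr(seqs, function(d, i) {
    X <- matrix(d, nrow = 1)
    fb <- forward_backward_batch(params, X)
    post <- matrix(fb$post[1, , ], ncol = params$k)
    path <- viterbi_path(params, d)
    res <- tibble::tibble(
      sequence = if (!is.null(seq_names)) as.character(i) else as.character(i),
      trial_index = seq_along(d),
      map_state = path,
      p_engaged = post[, 1]
    )
    for (j in seq_len(params$k)) {
      res[[paste0("p_state_", j)]] <- post[, j]
    }
    res
  })
  out
}

#' Dwell-time distributions
#'
#' Empirical dwell lengths from decoded state paths (maximal runs of a state),
#' or the generative geometric distribution implied by the transition matrix.
#'
#' @param x Either a `posterior_decode()` tibble (empirical dwells from the
#'   MAP path, computed within each sequence) or an `omr_hmm` / transition
#'   matrix (generative distribution).
#' @param max_len Longest dwell reported for the generative distribution.
#' @return For empirical input: tibble `state`, `length`, `n`, `probability`
#'   (normalized within state). For generative input: tibble `state`,
#'   `length`, `probability` with `P(L = l) = a^(l-1) (1 - a)` for stay
#'   probability `a`.
#' @export
dwell_times <- function(x, max_len = 30) {
  if (inherits(x, "omr_hmm")) x <- x$params$A
  if (inherits(x, "gamma_hmm_params")) x <- x$A
  if (is.matrix(x)) {
    k <- nrow(x)
    return(purrr::map_dfr(seq_len(k), function(j) {
      a <- x[j, j]
      tibble::tibble(
        state = j,
        length = seq_len(max_len),
        probability = a^(seq_len(max_len) - 1) * (1 - a)
      )
    }))
  }
  runs <- x |>
    dplyr::group_by(.data$sequence) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::reframe(
      state = rle(.data$map_state)$values,
      length = rle(.data$map_state)$lengths
    )
  runs |>
    dplyr::count(.data$state, .data$length, name = "n") |>
    dplyr::mutate(probability = .data$n / sum(.data$n), .by = "state") |>
    dplyr::arrange(.data$state, .data$length)
}

#' Sample sequences from a gamma HMM
#'
#' @param params A [gamma_hmm_params()].
#' @param n_trials Trials per sequence.
#' @param n_seq Number of sequences.
#' @param seed Optional seed.
#' @return A tibble with `sequence`, `trial_index`, `state`, `d` (emission),
#'   `score` (= 1 - 2 d).
#' @export
sample_hmm <- function(params, n_trials, n_seq = 1, seed = NULL) {
  run <- function() {
    purrr::map_dfr(seq_len(n_seq), function(s) {
      z <- integer(n_trials)
      z[1] <- sample.int(params$k, 1, prob = params$pi)
      if (n_trials > 1) {
        for (t in 2:n_trials) {
          z[t] <- sample.int(params$k, 1, prob = params$A[z[t - 1], ])
        }
      }
      d <- rgamma(n_trials, shape = params$shape[z], rate = params$rate[z])
      tibble::tibble(
        sequence = s, trial_index = seq_len(n_trials),
        state = z, d = d, score = 1 - 2 * d
      )
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Cross-validated choice of the number of hidden states
#'
#' Fish are split into `n_folds` folds; for each candidate `k` the HMM is fit
#' on the training fish and the forward log-likelihood is evaluated on the
#' held-out fish (whole chains). Reported per k as the mean held-out
#' log-likelihood per sequence.
#'
#' @param x Trials tibble or list of sequences (one chain per fish).
#' @param k_range Candidate state counts (default 1:10).
#' @param n_folds Number of folds (default 5); requires at least `n_folds`
#'   fish.
#' @param n_starts EM restarts per fit (reduced default for tractability).
#' @param seed Seed controlling the fold assignment and EM starts.
#' @param ... Passed to [fit_hmm()].
#' @return A tibble with `k`, `mean_heldout_loglik`, `total_heldout_loglik`,
#'   and `se` over folds.
#' @export
cross_validate_states <- function(x, k_range = 1:10, n_folds = 5, n_starts = 5,
                                  seed = 1, ...) {
  seqs <- as_emission_sequences(x)
  n <- length(seqs)
  if (n < n_folds) abort("Need at least `n_folds` sequences (fish).")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(n_folds), n))
    purrr::map_dfr(k_range, function(k) {
      per_fold <- purrr::map_dbl(seq_len(n_folds), function(f) {
        train <- seqs[fold != f]
        test <- seqs[fold == f]
        fit <- fit_hmm(train, k = k, n_starts = n_starts, ...)
        hmm_loglik(fit$params, test) / length(test)
      })
      tibble::tibble(
        k = k,
        mean_heldout_loglik = mean(per_fold),
        total_heldout_loglik = sum(per_fold * tabulate(fold, n_folds)),
        se = sd(per_fold) / sqrt(n_folds)
      )
    })
  })
}

#' Plot decoded engagement posteriors across trials
#'
#' @param decoded Output of [posterior_decode()].
#' @param max_sequences Cap on the number of fish shown.
#' @return A ggplot: per-trial engaged-state posterior, one panel per fish.
#' @export
plot_state_posteriors <- function(decoded, max_sequences = 16) {
  keep <- head(unique(decoded$sequence), max_sequences)
  dat <- dplyr::filter(decoded, .data$sequence %in% keep)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$trial_index, y = .data$p_engaged)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(
      ggplot2::aes(color = factor(.data$map_state)),
      size = 0.8
    ) +
    ggplot2::facet_wrap(~sequence) +
    ggplot2::labs(
      x = "trial", y = "P(engaged)", color = "MAP state"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
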