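#' Parameters of the truncated Gaussian-gamma performance mixture
#'
#' Stimulus-period score distributions are modeled as
#' `P = (1 - w) * TruncNormal(0, sigma) + w * TruncGamma(1 / kappa, theta)`:
#' a Gaussian centered at chance (score 0) for disengaged trials plus a gamma
#' component for engaged trials. The gamma is defined on the ceiling distance
#' `d = (1 - score) / 2`, with shape `1 / kappa` and rate `theta`, truncated
#' to `d` in `[0, 1]`; large `kappa` concentrates mass near perfect
#' performance (score +1). Both components are renormalized over the score
#' domain.
#'
#' @param w Weight of the gamma (engaged) component, in `[0, 1]`; "focus".
#' @param kappa Inverse shape of the gamma component (> 0); "competence".
#' @param sigma Gaussian SD, quoted on the axis chosen by `sigma_scale`
#'   (default 0.18 on the rescaled `[0, 1]` axis, i.e. 0.36 in score units).
#' @param theta Gamma rate parameter (fixed, default 15).
#' @param sigma_scale `"unit"` if `sigma` is quoted on the `[0, 1]` axis,
#'   `"score"` if on the `[-1, 1]` axis.
#' @return A `mixture_params` list (with the score-axis SD in `$sd_score`).
#' @export
mixture_params <- function(w, kappa, sigma = 0.18, theta = 15,
                           sigma_scale = c("unit", "score")) {
  sigma_scale <- match.arg(sigma_scale)
  stopifnot_prob(w, "w")
  if (kappa <= 0) abort("`kappa` must be > 0.")
  if (sigma <= 0 || theta <= 0) abort("`sigma` and `theta` must be > 0.")
  sd_score <- if (sigma_scale == "unit") 2 * sigma else sigma
  structure(
    list(
      w = w, kappa = kappa, sigma = sigma, theta = theta,
      sigma_scale = sigma_scale, sd_score = sd_score,
      z_gauss = pnorm(1, 0, sd_score) - pnorm(-1, 0, sd_score),
      z_gamma = pgamma(1, shape = 1 / kappa, rate = theta)
    ),
    class = "mixture_params"
  )
}

#' Mixture density over performance scores
#'
#' @param score Scores in `[-1, 1]`.
#' @param params A [mixture_params()].
#' @return Density values on the score axis (integrates to 1 over `[-1, 1]`).
#' @export
mixture_pdf <- function(score, params) {
  if (any(score < -1 | score > 1)) abort("`score` must lie in [-1, 1].")
  d <- (1 - score) / 2
  gauss <- dnorm(score, 0, params$sd_score) / params$z_gauss
  gam <- dgamma(d, shape = 1 / params$kappa, rate = params$theta) /
    params$z_gamma / 2
  (1 - params$w) * gauss + params$w * gam
}

# Exact bin probabilities on the 21-bin layout for each component.
gauss_bin_probs <- function(sd_score) {
  br <- score_bins()$breaks
  z <- pnorm(1, 0, sd_score) - pnorm(-1, 0, sd_score)
  diff(pnorm(br, 0, sd_score)) / z
}

gamma_bin_probs <- function(kappa, theta) {
  br <- score_bins()$breaks
  d <- (1 - br) / 2 # decreasing in score
  shape <- 1 / kappa
  z <- pgamma(1, shape = shape, rate = theta)
  p <- pgamma(d, shape = shape, rate = theta)
  (p[-length(p)] - p[-1]) / z
}

mixture_bin_probs <- function(params) {
  (1 - params$w) * gauss_bin_probs(params$sd_score) +
    params$w * gamma_bin_probs(params$kappa, params$theta)
}

#' MSE of the uniform null model
#'
#' The null assigns probability 1/21 to each score bin; its mean squared error
#' against an observed histogram contextualizes the mixture-fit MSE.
#'
#' @param hist A tibble from [score_histogram()] (or a 21-vector of bin
#'   probabilities).
#' @return The null MSE (mean over the 21 bins of `(p_i - 1/21)^2`).
#' @export
null_mse <- function(hist) {
  p <- hist_probs(hist)
  mean((p - 1 / 21)^2)
}

hist_probs <- function(x) {
  p <- if (is.data.frame(x)) x$probability else x
  if (length(p) != 21) abort("Expected a 21-bin score histogram.")
  p
}

# Gamma bin probabilities for many kappas at once (21 x K matrix).
gamma_bin_probs_multi <- function(kappas, theta) {
  br <- score_bins()$breaks
  d <- (1 - br) / 2
  K <- length(kappas)
  shapes <- 1 / kappas
  p <- matrix(
    pgamma(rep(d, K), shape = rep(shapes, each = length(d)), rate = theta),
    nrow = length(d)
  )
  z <- pgamma(1, shape = shapes, rate = theta)
  sweep(p[-length(d), , drop = FALSE] - p[-1, , drop = FALSE], 2, z, `/`)
}

# Least-squares fit of (w, kappa) to 21 bin probabilities. The model is linear
# in w, so w is profiled out in closed form for each kappa and the search is
# one-dimensional over log(kappa): the loss is evaluated at a fixed log grid
# plus `n_starts` random initial points (all vectorized), then polished with
# Brent around the best candidate.
fit_mixture_probs <- function(h, n_starts = 25, sigma = 0.18, theta = 15,
                              sigma_scale = "unit",
                              kappa_bounds = c(0.1, 100)) {
  sd_score <- if (sigma_scale == "unit") 2 * sigma else sigma
  g <- gauss_bin_probs(sd_score)
  hg <- h - g
  lb <- log(kappa_bounds[1])
  ub <- log(kappa_bounds[2])

  profile_w <- function(D) {
    ss <- colSums(D^2)
    w <- colSums(D * hg) / pmax(ss, 1e-300)
    pmin(pmax(w, 0), 1)
  }
  cand <- c(seq(lb, ub, length.out = 17), runif(n_starts, lb, ub))
  D <- gamma_bin_probs_multi(exp(cand), theta) - g
  ws <- profile_w(D)
  losses <- colMeans((hg - sweep(D, 2, ws, `*`))^2)
  i <- which.min(losses)

  obj <- function(lk) {
    D1 <- gamma_bin_probs_multi(exp(lk), theta) - g
    w <- profile_w(D1)
    mean((hg - w * D1)^2)
  }
  step <- (ub - lb) / 16
  opt <- optimize(obj, c(max(lb, cand[i] - step), min(ub, cand[i] + step)), tol = 1e-10)
  if (opt$objective <= losses[i]) {
    lk <- opt$minimum
    loss <- opt$objective
  } else {
    lk <- cand[i]
    loss <- losses[i]
  }
  D1 <- gamma_bin_probs_multi(exp(lk), theta) - g
  list(w = as.numeric(profile_w(D1)), kappa = exp(lk), loss = loss)
}

#' Fit the Gaussian-gamma mixture to a score distribution
#'
#' Least-squares fit of the model's exact bin probabilities to the empirical
#' 21-bin histogram, with `sigma` and `theta` held fixed and the best of
#' `n_starts` random initializations retained. `kappa` is bounded to
#' `[0.1, 100]` and `w` to `[0, 1]`.
#'
#' @param x Either a numeric vector of per-trial scores, or a 21-bin histogram
#'   (tibble from [score_histogram()]).
#' @param n_starts Number of random starts.
#' @param sigma,theta,sigma_scale Fixed shape parameters, see
#'   [mixture_params()].
#' @return An object of class `omr_mixture_fit` with elements `params`,
#'   `mse_fit`, `mse_null`, `mse_ratio_pct`, `loss`, `hist`, `n_scores`,
#'   `unreliable` (degenerate histogram flag), and (after [bootstrap_fit()])
#'   `se_w`, `se_kappa`.
#' @export
fit_mixture <- function(x, n_starts = 25, sigma = 0.18, theta = 15,
                        sigma_scale = "unit") {
  if (is.numeric(x)) {
    scores <- x[!is.na(x)]
    if (length(scores) == 0) abort("No non-missing scores supplied.")
    hist <- score_histogram(scores)
    n_scores <- length(scores)
  } else {
    hist <- x
    n_scores <- sum(hist$count %||% NA)
    scores <- NULL
  }
  h <- hist_probs(hist)
  if (abs(sum(h) - 1) > 1e-8) abort("Histogram probabilities must sum to 1.")
  unreliable <- sum(h > 0) < 2
  if (unreliable) {
    warn("Degenerate histogram (single occupied bin); fit flagged unreliable.")
  }
  fit <- fit_mixture_probs(h, n_starts, sigma, theta, sigma_scale)
  params <- mixture_params(fit$w, fit$kappa,
    sigma = sigma, theta = theta,
    sigma_scale = sigma_scale
  )
  mse_fit <- mean((mixture_bin_probs(params) - h)^2)
  mse_null <- null_mse(h)
  structure(
    list(
      params = params,
      mse_fit = mse_fit,
      mse_null = mse_null,
      mse_ratio_pct = if (mse_null > 0) 100 * mse_fit / mse_null else NA_real_,
      loss = fit$loss,
      hist = hist,
      scores = scores,
      n_scores = n_scores,
      n_starts = n_starts,
      unreliable = unreliable,
      se_w = NA_real_,
      se_kappa = NA_real_,
      n_boot = 0L
    ),
    class = "omr_mixture_fit"
  )
}

#' Bootstrap standard errors for the mixture parameters
#'
#' Resamples the per-trial scores with replacement `B` times, refits the
#' mixture on each resample, and reports the SD of the fitted parameters.
#'
#' @param scores Per-trial scores (>= 30 recommended), or an `omr_mixture_fit`
#'   built from raw scores.
#' @param B Number of bootstrap resamples (default 5000).
#' @param n_starts Random starts per resample fit (reduced for speed).
#' @param sigma,theta,sigma_scale Fixed shape parameters.
#' @return If given a fit: the fit with `se_w`, `se_kappa`, `n_boot` filled
#'   in. If given scores: a list with `se_w`, `se_kappa`, and the bootstrap
#'   draws `w`, `kappa`.
#' @export
bootstrap_fit <- function(scores, B = 5000, n_starts = 5,
                          sigma = 0.18, theta = 15, sigma_scale = "unit") {
  fit_obj <- NULL
  if (inherits(scores, "omr_mixture_fit")) {
    fit_obj <- scores
    scores <- fit_obj$scores
    if (is.null(scores)) abort("Fit does not carry raw scores; supply them directly.")
    sigma <- fit_obj$params$sigma
    theta <- fit_obj$params$theta
    sigma_scale <- fit_obj$params$sigma_scale
  }
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  draws <- purrr::map(seq_len(B), function(b) {
    res <- scores[sample.int(n, n, replace = TRUE)]
    fit_mixture_probs(score_histogram(res)$probability, n_starts, sigma, theta, sigma_scale)
  })
  ws <- purrr::map_dbl(draws, "w")
  ks <- purrr::map_dbl(draws, "kappa")
  se_w <- if (B > 1) sd(ws) else 0
  se_kappa <- if (B > 1) sd(ks) else 0
  if (!is.null(fit_obj)) {
    fit_obj$se_w <- se_w
    fit_obj$se_kappa <- se_kappa
    fit_obj$n_boot <- B
    return(fit_obj)
  }
  list(se_w = se_w, se_kappa = se_kappa, w = ws, kappa = ks)
}

#' Sample performance scores from the mixture
#'
#' @param n Number of scores.
#' @param params A [mixture_params()].
#' @return Numeric vector of scores in `[-1, 1]`.
#' @export
r_mixture <- function(n, params) {
  engaged <- runif(n) < params$w
  out <- numeric(n)
  n_e <- sum(engaged)
  if (n_e > 0) {
    u <- runif(n_e) * params$z_gamma
    d <- qgamma(u, shape = 1 / params$kappa, rate = params$theta)
    out[engaged] <- 1 - 2 * d
  }
  n_g <- n - n_e
  if (n_g > 0) {
    lo <- pnorm(-1, 0, params$sd_score)
    u <- lo + runif(n_g) * params$z_gauss
    out[!engaged] <- qnorm(u, 0, params$sd_score)
  }
  pmin(pmax(out, -1), 1)
}

#' @export
print.omr_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<omr_mixture_fit> w = %.3f, kappa = %.2f (sigma = %.2f, theta = %.1f)\n",
    x$params$w, x$params$kappa, x$params$sigma, x$params$theta
  ))
  cat(sprintf(
    "  MSE fit %.3g vs null %.3g (%.1f%%)%s\n",
    x$mse_fit, x$mse_null, x$mse_ratio_pct,
    if (x$n_boot > 0) {
      sprintf("; bootstrap SE(w) = %.3f, SE(kappa) = %.2f [B = %d]", x$se_w, x$se_kappa, x$n_boot)
    } else {
      ""
    }
  ))
  if (isTRUE(x$unreliable)) cat("  WARNING: degenerate histogram, fit unreliable\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_mixture
#' @param x,object An `omr_mixture_fit`.
#' @param ... Unused.
#' @export
tidy.omr_mixture_fit <- function(x, ...) {
  tibble::tibble(
    term = c("w", "kappa"),
    estimate = c(x$params$w, x$params$kappa),
    std.error = c(x$se_w, x$se_kappa)
  )
}

#' @rdname fit_mixture
#' @export
glance.omr_mixture_fit <- function(x, ...) {
  tibble::tibble(
    mse_fit = x$mse_fit,
    mse_null = x$mse_null,
    mse_ratio_pct = x$mse_ratio_pct,
    loss = x$loss,
    n_scores = x$n_scores,
    n_boot = x$n_boot,
    unreliable = x$unreliable
  )
}

#' Plot a mixture fit over its score histogram
#'
#' @param object An `omr_mixture_fit`.
#' @param ... Unused.
#' @return A ggplot: empirical bin probabilities (points) with the fitted
#'   mixture and its Gaussian / gamma components (lines).
#' @export
autoplot.omr_mixture_fit <- function(object, ...) {
  p <- object$params
  curves <- tibble::tibble(bin_center = score_bins()$centers) |>
    dplyr::mutate(
      gaussian = (1 - p$w) * gauss_bin_probs(p$sd_score),
      gamma = p$w * gamma_bin_probs(p$kappa, p$theta),
      mixture = .data$gaussian + .data$gamma
    ) |>
    tidyr::pivot_longer(-"bin_center", names_to = "component", values_to = "probability")
  ggplot2::ggplot(object$hist, ggplot2::aes(x = .data$bin_center, y = .data$probability)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(color = .data$component)
    ) +
    ggplot2::labs(
      x = "performance score", y = "probability",
      title = sprintf("w = %.2f, kappa = %.1f", p$w, p$kappa)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
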