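bout_table_cols <- c(
  "fish_id", "trial_index", "time_s", "period", "turn_angle_deg", "radius", "tracked"
)

validate_bout_table <- function(bouts) {
  missing <- setdiff(bout_table_cols, names(bouts))
  if (length(missing) > 0) {
    abort(sprintf("Bout table is missing columns: %s", paste(missing, collapse = ", ")))
  }
  check <- function(bad, column, rule) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      abort(sprintf(
        "Schema violation in column `%s` (%s) at rows: %s",
        column, rule, paste(head(rows, 5), collapse = ", ")
      ))
    }
  }
  check(bouts$radius < 0 | bouts$radius > 1, "radius", "must lie in [0, 1]")
  check(
    bouts$turn_angle_deg <= -180 | bouts$turn_angle_deg > 180,
    "turn_angle_deg", "must lie in (-180, 180]"
  )
  check(!bouts$period %in% c("baseline", "stimulus"), "period", "must be baseline/stimulus")
  check(bouts$time_s < 0, "time_s", "must be >= 0")
  check(is.na(bouts$tracked), "tracked", "must be logical")
  invisible(bouts)
}

#' Read / write bout tables and trial schedules
#'
#' Bout tables are CSV files with header
#' `fish_id,trial_index,time_s,period,turn_angle_deg,radius,tracked`;
#' schedules use `trial_index,stim_direction,coherence,baseline_target`.
#' Reading validates the schema (radius in `[0, 1]`, angles in
#' `(-180, 180]`, known period labels) and reports offending rows.
#'
#' @param path File path.
#' @return `read_bout_table()`: a validated tibble.
#' @export
read_bout_table <- function(path) {
  bouts <- readr::read_csv(
    path,
    col_types = readr::cols(
      fish_id = readr::col_character(),
      trial_index = readr::col_integer(),
      time_s = readr::col_double(),
      period = readr::col_character(),
      turn_angle_deg = readr::col_double(),
      radius = readr::col_double(),
      tracked = readr::col_logical()
    )
  )
  validate_bout_table(bouts)
  bouts
}

#' @rdname read_bout_table
#' @param bouts A bout table.
#' @export
write_bout_table <- function(bouts, path) {
  validate_bout_table(bouts)
  readr::write_csv(bouts[bout_table_cols], path)
  invisible(path)
}

#' @rdname read_bout_table
#' @export
read_trial_schedule <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      trial_index = readr::col_integer(),
      stim_direction = readr::col_character(),
      coherence = readr::col_double(),
      baseline_target = readr::col_character()
    )
  )
}

#' @rdname read_bout_table
#' @param schedule A trial schedule tibble.
#' @export
write_trial_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}

#' Serialize fitted results to JSON
#'
#' @param x An `omr_mixture_fit`, `omr_hmm`, or `omr_permutation`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path) {
  obj <- if (inherits(x, "omr_mixture_fit")) {
    list(
      type = "mixture_fit",
      params = list(
        w = x$params$w, kappa = x$params$kappa,
        sigma = x$params$sigma, theta = x$params$theta,
        sigma_scale = x$params$sigma_scale
      ),
      se = list(w = x$se_w, kappa = x$se_kappa, n_boot = x$n_boot),
      mse = list(fit = x$mse_fit, null = x$mse_null, ratio_pct = x$mse_ratio_pct),
      histogram = list(
        bin_center = x$hist$bin_center,
        probability = x$hist$probability
      ),
      unreliable = x$unreliable
    )
  } else if (inherits(x, "omr_hmm")) {
    list(
      type = "gamma_hmm",
      k = x$params$k,
      pi = x$params$pi,
      A = x$params$A,
      shape = x$params$shape,
      rate = x$params$rate,
      state_mean_score = x$state_means,
      loglik = x$loglik,
      converged = x$converged
    )
  } else if (inherits(x, "omr_permutation")) {
    list(
      type = "permutation_test",
      observed = as.list(tidy(x)),
      p = list(w = x$p_w, kappa = x$p_kappa),
      n_perm = x$n_perm,
      alternative = x$alternative
    )
  } else {
    abort("No JSON serialization for this object.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full simulate / score / fit pipeline
#'
#' Simulates a cohort, writes the bout table and schedule, computes trial
#' summaries, fits the performance mixture and the two-state gamma HMM on the
#' stimulus-period scores, runs a split-half permutation contrast (first half
#' of the fish vs second half; a null comparison on a homogeneous cohort), and
#' writes a run manifest referencing every artifact.
#'
#' @param config A [cohort_config()].
#' @param profiles Fish profiles as in [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param n_perm Permutations for the split-half contrast (reduced default for
#'   pipeline runs).
#' @param hmm_states Number of HMM states.
#' @param quiet Suppress per-stage log messages.
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, profiles = fish_profile(), out_dir,
                         n_perm = 200, hmm_states = 2, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  paths <- list(
    bouts = file.path(out_dir, "bouts.csv"),
    schedule = file.path(out_dir, "schedule.csv"),
    trials = file.path(out_dir, "trials.csv"),
    mixture = file.path(out_dir, "mixture.json"),
    hmm = file.path(out_dir, "hmm.json"),
    permutation = file.path(out_dir, "permutation.json"),
    config = file.path(out_dir, "config.yaml")
  )

  say("simulate: %d fish x %d trials", config$n_fish, config$n_trials)
  cohort <- generate_cohort(config, profiles)
  write_bout_table(cohort$bouts, paths$bouts)
  write_trial_schedule(cohort$schedule, paths$schedule)
  yaml::write_yaml(unclass(config), paths$config)

  trials <- trial_summaries(
    cohort$bouts, cohort$schedule,
    baseline_duration = config$baseline_duration,
    stimulus_duration = config$stimulus_duration
  )
  n_dropped <- sum(is.na(trials$score))
  say(
    "score: %d trials (%d with no surviving stimulus bouts dropped from distributions)",
    nrow(trials), n_dropped
  )
  readr::write_csv(trials, paths$trials)

  scores <- trials$score[!is.na(trials$score)]
  fit <- fit_mixture(scores)
  say("fit-mixture: w = %.3f, kappa = %.2f", fit$params$w, fit$params$kappa)
  write_results(fit, paths$mixture)

  hmm <- fit_hmm(trials, k = hmm_states)
  say("fit-hmm: k = %d, loglik = %.1f", hmm_states, hmm$loglik)
  write_results(hmm, paths$hmm)

  fish <- sort(unique(trials$fish_id))
  half <- fish[seq_len(length(fish) %/% 2)]
  keep <- dplyr::filter(trials, !is.na(.data$score))
  perm <- permutation_test(
    dplyr::filter(keep, .data$fish_id %in% half),
    dplyr::filter(keep, !.data$fish_id %in% half),
    n_perm = n_perm
  )
  say("permtest: p_w = %.3f, p_kappa = %.3f (split-half null)", perm$p_w, perm$p_kappa)
  write_results(perm, paths$permutation)

  manifest <- list(
    package_version = as.character(utils::packageVersion("omrfocus")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = unclass(config),
    n_trials_dropped = n_dropped,
    artifacts = paths
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  say("report: manifest.json written with %d artifacts", length(paths))
  invisible(manifest)
}
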