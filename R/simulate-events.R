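#' Build a pseudorandom event schedule
#'
#' Generates the event-related implicit emotion-recognition design: 50 face
#' stimuli (10 per condition: angry, fear, happy, neutral, sad), each
#' presented once per run, in a different pseudorandom order per run, with
#' inter-trial intervals jittered uniformly within `spec$iti_range_s`.
#'
#' @param spec A [cohort_spec()] (uses `n_runs`, `volumes_per_run`, `tr_s`,
#'   `event_duration_s`, `iti_range_s`).
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @param start_s Onset of the first event within each run (s).
#'
#' @return A tibble with columns `run`, `onset`, `duration`, `condition`,
#'   `stimulus_id`; onsets are strictly increasing within run.
#' @export
#' @examples
#' ev <- build_event_schedule(cohort_spec(n_subjects = 2), seed = 1)
#' dplyr::count(ev, condition)
build_event_schedule <- function(spec, seed = spec$rng_seed, start_s = 10) {
  stopifnot(inherits(spec, "cohort_spec"))
  conditions <- emotion_conditions()
  stimuli <- paste0(rep(conditions, each = 10), sprintf("%02d", 1:10))
  n_ev <- length(stimuli)
  run_len <- spec$volumes_per_run * spec$tr_s
  withr::local_seed(as.integer(seed))
  purrr::map_dfr(seq_len(spec$n_runs), function(r) {
    ord <- sample.int(n_ev)
    iti <- stats::runif(n_ev - 1, spec$iti_range_s[1], spec$iti_range_s[2])
    onsets <- start_s + c(0, cumsum(spec$event_duration_s + iti))
    # the run must accommodate the schedule plus the HRF support
    end_s <- onsets[n_ev] + spec$event_duration_s + hrf_support_s()
    if (end_s > run_len)
      stop(sprintf(
        "run too short for schedule: needs %.1f s, run is %.1f s",
        end_s, run_len))
    tibble::tibble(
      run = r,
      onset = onsets,
      duration = spec$event_duration_s,
      condition = sub("[0-9]+$", "", stimuli[ord]),
      stimulus_id = stimuli[ord]
    )
  })
}

#' Simulate behavioral responses
#'
#' Per-subject, per-condition sex-discrimination accuracy and response time
#' for the in-scanner implicit task. Accuracy is a binomial proportion over
#' the condition's trials around a per-condition mean; RT is log-normal
#' (strictly positive) around a per-condition median.
#'
#' @param phenotypes Phenotype tibble (only its row count and `subject_id`
#'   are used).
#' @param effect_spec List with elements `base_accuracy`, `base_rt_s`,
#'   `accuracy_offsets` and `rt_offsets_s` (named per-condition additive
#'   offsets; unnamed conditions get 0), `n_trials` (per condition),
#'   `rt_sdlog`.
#' @param seed Integer seed.
#'
#' @return A tibble with `subject_id`, `condition`, `accuracy` in \[0, 1\]
#'   and `rt_s` > 0.
#' @export
simulate_behavior <- function(phenotypes,
                              effect_spec = list(),
                              seed = 1L) {
  spec <- utils::modifyList(list(
    base_accuracy = 0.93, base_rt_s = 0.62,
    accuracy_offsets = c(angry = -0.05, fear = -0.05, sad = -0.05),
    rt_offsets_s = c(angry = 0.04, fear = 0.05, happy = 0.03, sad = 0.04),
    n_trials = 20, rt_sdlog = 0.12
  ), effect_spec)
  conditions <- emotion_conditions()
  acc_mean <- spec$base_accuracy +
    ifelse(conditions %in% names(spec$accuracy_offsets),
           spec$accuracy_offsets[conditions], 0)
  if (any(acc_mean < 0 | acc_mean > 1))
    stop("per-condition mean accuracy must lie in [0, 1]")
  rt_med <- spec$base_rt_s +
    ifelse(conditions %in% names(spec$rt_offsets_s),
           spec$rt_offsets_s[conditions], 0)
  if (any(rt_med <= 0)) stop("per-condition median RT must be positive")
  n <- nrow(phenotypes)
  withr::local_seed(as.integer(seed))
  tidyr::expand_grid(subject_id = phenotypes$subject_id,
                     condition = conditions) |>
    dplyr::mutate(
      accuracy = stats::rbinom(dplyr::n(), spec$n_trials,
                               rep(acc_mean, times = n)) / spec$n_trials,
      rt_s = stats::rlnorm(dplyr::n(), log(rep(rt_med, times = n)),
                           spec$rt_sdlog)
    )
}
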