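#' Configure a weighted up-down staircase
#'
#' The coherent-motion threshold test adjusts stimulus difficulty on a dB
#' attenuation scale relative to 100% coherence: every correct answer makes
#' the task harder by `down_step_db` (default 1 dB) and every wrong answer
#' makes it easier by `up_step_db` (default 3 dB). The track stops once the
#' step direction has reversed `stop_reversals` times (default 8). With the
#' 1-up/3-down weighting the track's equilibrium sits where
#' `p_correct = up / (up + down) = 0.75`, i.e. the staircase converges on
#' the observer's 75%-correct coherence.
#'
#' @param down_step_db dB added to the attenuation after a correct response
#'   (task gets harder). Must be > 0.
#' @param up_step_db dB removed after a wrong response (task gets easier).
#'   Must be > 0.
#' @param stop_reversals number of step-direction reversals at which the
#'   staircase terminates.
#' @param start_attenuation_db starting attenuation; 0 dB = 100% coherence.
#' @param max_trials safety cap on trial count (a pathological responder
#'   could otherwise wander forever).
#' @param min_attenuation_db,max_attenuation_db clamp bounds for the track.
#'   The default ceiling of 40 dB corresponds to 1% coherence.
#' @return an object of class `staircase_config`.
#' @examples
#' cfg <- staircase_config()
#' cfg$down_step_db
#' @seealso [run_staircase()], [estimate_threshold()]
#' @export
staircase_config <- function(down_step_db = 1, up_step_db = 3,
                             stop_reversals = 8, start_attenuation_db = 0,
                             max_trials = 500, min_attenuation_db = 0,
                             max_attenuation_db = 40) {
  if (down_step_db <= 0 || up_step_db <= 0)
    stop_domain("step sizes must be positive")
  if (stop_reversals < 1) stop_domain("stop_reversals must be >= 1")
  if (max_trials <= 0) stop_domain("max_trials must be positive")
  if (min_attenuation_db < 0 || max_attenuation_db <= min_attenuation_db)
    stop_domain("attenuation bounds must satisfy 0 <= min < max")
  if (start_attenuation_db < min_attenuation_db ||
      start_attenuation_db > max_attenuation_db)
    stop_domain("start_attenuation_db outside [min, max] bounds")
  structure(
    list(down_step_db = down_step_db, up_step_db = up_step_db,
         stop_reversals = as.integer(stop_reversals),
         start_attenuation_db = start_attenuation_db,
         max_trials = as.integer(max_trials),
         min_attenuation_db = min_attenuation_db,
         max_attenuation_db = max_attenuation_db),
    class = "staircase_config")
}

#' Convert dB attenuation to percent coherence (and back)
#'
#' Amplitude dB convention: `coherence = 100 * 10^(-attenuation/20)`, so
#' 0 dB is 100% coherence and every 20 dB divides coherence by 10.
#'
#' @param attenuation_db attenuation in dB, >= 0.
#' @param coherence_pct coherence in percent, in (0, 100].
#' @return percent coherence (resp. dB attenuation); vectorised.
#' @examples
#' attenuation_to_coherence(0)   # 100
#' attenuation_to_coherence(20)  # 10
#' coherence_to_attenuation(50)  # ~6.02 dB
#' @export
attenuation_to_coherence <- function(attenuation_db) {
  if (any(!is.finite(attenuation_db)) || any(attenuation_db < 0))
    stop_domain("attenuation_db must be finite and >= 0")
  100 * 10^(-attenuation_db / 20)
}

#' @rdname attenuation_to_coherence
#' @export
coherence_to_attenuation <- function(coherence_pct) {
  if (any(!is.finite(coherence_pct)) || any(coherence_pct <= 0) ||
      any(coherence_pct > 100))
    stop_domain("coherence_pct must be in (0, 100]")
  -20 * log10(coherence_pct / 100)
}

#' Initialise a staircase track
#'
#' @param config a [staircase_config()].
#' @return an object of class `staircase_state` holding the current
#'   attenuation, the per-trial history, the reversal log and the last step
#'   direction. Use [staircase_trial_log()] to view the history as a data
#'   frame.
#' @export
staircase_init <- function(config = staircase_config()) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(attenuation_db = config$start_attenuation_db,
         trial_attenuation = numeric(), trial_correct = logical(),
         trial_reversal = logical(),
         reversal_trial = integer(), reversal_attenuation = numeric(),
         last_step_direction = "none",
         terminated = FALSE, terminated_by = NA_character_),
    class = "staircase_state")
}

#' Trial and reversal logs of a staircase track
#'
#' @param state a `staircase_state`.
#' @return `staircase_trial_log()`: data frame with columns `trial`,
#'   `attenuation_db`, `coherence_pct`, `correct`, `reversal_flag`;
#'   `staircase_reversal_log()`: data frame with `trial`, `attenuation_db`.
#' @export
staircase_trial_log <- function(state) {
  stopifnot(inherits(state, c("staircase_state", "staircase_result")))
  if (inherits(state, "staircase_result")) return(state$trial_log)
  data.frame(trial = seq_along(state$trial_attenuation),
             attenuation_db = state$trial_attenuation,
             coherence_pct = attenuation_to_coherence(state$trial_attenuation),
             correct = state$trial_correct,
             reversal_flag = state$trial_reversal)
}

#' @rdname staircase_trial_log
#' @export
staircase_reversal_log <- function(state) {
  stopifnot(inherits(state, c("staircase_state", "staircase_result")))
  if (inherits(state, "staircase_result")) return(state$reversal_log)
  data.frame(trial = state$reversal_trial,
             attenuation_db = state$reversal_attenuation)
}

#' Advance a staircase by one response
#'
#' Applies the weighted up-down rule: correct adds `down_step_db` to the
#' attenuation (coherence decreases), wrong subtracts `up_step_db`
#' (coherence increases); the result is clamped to the configured bounds. A
#' reversal is logged when the applied step direction differs from the
#' previous one; the first response only sets the direction. A step clamped
#' at a bound still counts in its attempted direction for reversal
#' bookkeeping. The state terminates once `stop_reversals` reversals (or
#' `max_trials` trials) are reached.
#'
#' @param state a `staircase_state`.
#' @param correct logical, whether the response was correct.
#' @param config the [staircase_config()] in force.
#' @return the updated `staircase_state`.
#' @examples
#' st <- staircase_init()
#' st <- staircase_update(st, correct = TRUE)   # 0 -> 1 dB
#' st$attenuation_db
#' @export
staircase_update <- function(state, correct, config = staircase_config()) {
  stopifnot(inherits(state, "staircase_state"),
            inherits(config, "staircase_config"),
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  if (state$terminated)
    stop_domain("staircase already terminated; cannot update")

  at_before <- state$attenuation_db
  direction <- if (correct) "down" else "up"  # down = harder (less coherence)
  delta <- if (correct) config$down_step_db else -config$up_step_db
  at_after <- clamp(at_before + delta,
                    config$min_attenuation_db, config$max_attenuation_db)

  trial <- length(state$trial_attenuation) + 1L
  reversal <- state$last_step_direction != "none" &&
    direction != state$last_step_direction
  state$trial_attenuation[trial] <- at_before
  state$trial_correct[trial] <- correct
  state$trial_reversal[trial] <- reversal
  if (reversal) {
    i <- length(state$reversal_trial) + 1L
    state$reversal_trial[i] <- trial
    state$reversal_attenuation[i] <- at_before
  }
  state$last_step_direction <- direction
  state$attenuation_db <- at_after

  if (length(state$reversal_trial) >= config$stop_reversals) {
    state$terminated <- TRUE
    state$terminated_by <- "reversals"
  } else if (trial >= config$max_trials) {
    state$terminated <- TRUE
    state$terminated_by <- "max_trials"
  }
  state
}

#' Count step-direction reversals in a response sequence
#'
#' @param correct_seq logical vector of trial outcomes (TRUE = correct).
#' @return number of sign changes in the applied step directions.
#' @examples
#' count_reversals(c(TRUE, FALSE))        # 1
#' count_reversals(c(TRUE, TRUE, TRUE))   # 0
#' @export
count_reversals <- function(correct_seq) {
  stopifnot(is.logical(correct_seq))
  if (length(correct_seq) < 2L) return(0L)
  sum(correct_seq[-1L] != correct_seq[-length(correct_seq)])
}

#' Run a full staircase against a simulated observer
#'
#' @param observer an observer created by [psychometric_observer()] (or any
#'   object with a [respond()] method) mapping coherence to a correct/wrong
#'   response.
#' @param config a [staircase_config()].
#' @param seed optional integer; fixes the RNG so the whole trial log is
#'   reproducible. `NULL` uses (and advances) the current RNG stream.
#' @return an object of class `staircase_result` with elements
#'   `threshold_coherence_pct` (reversal-mean estimate, see
#'   [estimate_threshold()]), `trial_log`, `reversal_log`, `n_trials`,
#'   `n_reversals`, `terminated_by` and `seed`.
#' @examples
#' obs <- psychometric_observer(alpha75 = 30)
#' res <- run_staircase(obs, seed = 1)
#' res$n_reversals
#' @export
run_staircase <- function(observer, config = staircase_config(), seed = NULL) {
  stopifnot(inherits(config, "staircase_config"))
  with_seed(seed, {
    state <- staircase_init(config)
    while (!state$terminated) {
      coh <- attenuation_to_coherence(state$attenuation_db)
      state <- staircase_update(state, respond(observer, coh), config)
    }
    rev_log <- staircase_reversal_log(state)
    thr <- tryCatch(estimate_threshold_from_logs(rev_log),
                    error = function(e) NA_real_)
    structure(
      list(threshold_coherence_pct = thr,
           trial_log = staircase_trial_log(state), reversal_log = rev_log,
           n_trials = length(state$trial_attenuation),
           n_reversals = nrow(rev_log),
           terminated_by = state$terminated_by,
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
      class = "staircase_result")
  })
}

estimate_threshold_from_logs <- function(reversal_log, discard = NULL) {
  n <- nrow(reversal_log)
  if (is.null(discard)) discard <- floor(n / 2)
  if (n <= discard)
    stop_domain("need more than `discard` reversals to estimate a threshold")
  keep <- reversal_log$attenuation_db[(discard + 1L):n]
  attenuation_to_coherence(mean(keep))
}

#' Estimate the coherence threshold from a finished staircase
#'
#' The threshold is the mean reversal-point attenuation after discarding
#' the first `discard` reversals, converted to percent coherence.
#' Averaging happens on the dB scale the staircase steps on (not on the
#' coherence scale), and the default discards the first half of the
#' reversals: with the track started at 100% coherence the early reversals
#' still carry the approach to equilibrium, and keeping only the settled
#' (even-count) tail keeps the estimate within a few percent of the
#' observer's true 75% point (see the methods vignette for the
#' calibration). For the 1 dB / 3 dB weighted staircase the equilibrium is
#' the 75%-correct coherence.
#'
#' @param result a `staircase_result` from [run_staircase()].
#' @param discard number of initial reversals to drop; default half of the
#'   logged reversals.
#' @return threshold as percent coherence.
#' @export
estimate_threshold <- function(result, discard = NULL) {
  stopifnot(inherits(result, "staircase_result"))
  if (!is.null(discard)) discard <- as.integer(discard)
  estimate_threshold_from_logs(result$reversal_log, discard)
}

#' @export
print.staircase_result <- function(x, ...) {
  cat("Weighted up-down staircase run\n")
  cat(sprintf("  trials: %d, reversals: %d (terminated by %s)\n",
              x$n_trials, x$n_reversals, x$terminated_by))
  cat(sprintf("  threshold estimate: %.2f%% coherence\n",
              x$threshold_coherence_pct))
  invisible(x)
}

#' Write a staircase trial log / result summary to disk
#'
#' The trial log goes to CSV (`trial, attenuation_db, coherence_pct,
#' correct, reversal_flag`); the summary to JSON.
#'
#' @param result a `staircase_result`.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_staircase_result <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "staircase_result"))
  if (!is.null(csv_path))
    utils::write.csv(result$trial_log, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(threshold_coherence_pct = result$threshold_coherence_pct,
           n_trials = result$n_trials, n_reversals = result$n_reversals,
           terminated_by = result$terminated_by, seed = result$seed),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
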