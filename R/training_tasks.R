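#' Digit-counting task configuration and presentation schedule
#'
#' The digit-counting task has 10 progressive levels. Presentation time
#' falls from 560 ms at level 1 to 190 ms at level 10; the schedule is
#' linear between the printed endpoints (the interpolation is configurable
#' in principle, only the endpoints are fixed). Font size also decreases
#' with level but is carried as metadata only — nothing is rendered.
#'
#' @param n_levels number of levels (10).
#' @param presentation_ms_first,presentation_ms_last presentation time at
#'   the first and last level, ms.
#' @param max_mistakes cumulative wrong answers at which the session stops
#'   (4).
#' @param max_trials safety cap for a session.
#' @return a list of class `digit_task_config`.
#' @export
digit_task_config <- function(n_levels = 10, presentation_ms_first = 560,
                              presentation_ms_last = 190, max_mistakes = 4,
                              max_trials = 200) {
  if (n_levels < 2) stop_domain("need at least 2 levels")
  if (presentation_ms_last >= presentation_ms_first)
    stop_domain("presentation time must decrease with level")
  if (max_mistakes < 1 || max_trials < 1)
    stop_domain("max_mistakes and max_trials must be >= 1")
  structure(list(n_levels = as.integer(n_levels),
                 presentation_ms_first = presentation_ms_first,
                 presentation_ms_last = presentation_ms_last,
                 font_size_schedule = "decreasing (metadata only)",
                 max_mistakes = as.integer(max_mistakes),
                 max_trials = as.integer(max_trials)),
            class = "digit_task_config")
}

#' @rdname digit_task_config
#' @param level level in `1..n_levels`; vectorised.
#' @param config a `digit_task_config`.
#' @return `digit_schedule()`: presentation time in ms.
#' @examples
#' digit_schedule(1)   # 560
#' digit_schedule(10)  # 190
#' @export
digit_schedule <- function(level, config = digit_task_config()) {
  stopifnot(inherits(config, "digit_task_config"))
  if (any(level < 1) || any(level > config$n_levels) || any(level %% 1 != 0))
    stop_domain("level must be an integer in 1..", config$n_levels)
  span <- config$presentation_ms_first - config$presentation_ms_last
  config$presentation_ms_first - (level - 1) * span / (config$n_levels - 1)
}

#' Run one digit-counting session
#'
#' Level moves up one after each correct answer (capped at the top level)
#' and regresses one after each wrong answer (floored at level 1); the
#' session stops when `max_mistakes` cumulative mistakes are reached (or at
#' the `max_trials` safety cap).
#'
#' @param responder a function `function(level) -> logical` giving a
#'   correct/wrong answer for a trial at the given level; it may be
#'   stochastic (draws come from the current RNG stream).
#' @param config a [digit_task_config()].
#' @param seed optional RNG seed for reproducible stochastic responders.
#' @return list of class `task_session`: `log` (data frame with `trial`,
#'   `level`, `presentation_ms`, `correct`, `cumulative_mistakes`),
#'   `max_level_reached`, `n_mistakes`, `terminated_by`.
#' @examples
#' run_digit_session(function(level) FALSE)$n_mistakes  # 4, then stop
#' @export
run_digit_session <- function(responder, config = digit_task_config(),
                              seed = NULL) {
  stopifnot(is.function(responder), inherits(config, "digit_task_config"))
  with_seed(seed, {
    level <- 1L
    mistakes <- 0L
    lv <- integer(); ok <- logical(); cm <- integer()
    terminated_by <- "max_trials"
    for (trial in seq_len(config$max_trials)) {
      correct <- isTRUE(responder(level))
      if (!correct) mistakes <- mistakes + 1L
      lv[trial] <- level; ok[trial] <- correct; cm[trial] <- mistakes
      if (mistakes >= config$max_mistakes) {
        terminated_by <- "mistakes"
        break
      }
      level <- if (correct) min(level + 1L, config$n_levels)
               else max(level - 1L, 1L)
    }
    log <- data.frame(trial = seq_along(lv), level = lv,
                      presentation_ms = digit_schedule(lv, config),
                      correct = ok, cumulative_mistakes = cm)
    structure(list(task = "digit", log = log,
                   max_level_reached = max(lv), n_mistakes = mistakes,
                   terminated_by = terminated_by),
              class = "task_session")
  })
}

#' Dot-counting task configuration and level schedule
#'
#' Sequentially presented dots must be traced and counted. At level 1,
#' `level1_dots` dots (the task uses 7-9; the schedule anchors on the
#' configured count) are shown within `level1_duration_s` seconds, i.e. an
#' inter-dot interval of `level1_duration_s / level1_dots`. Each subsequent
#' level adds `dots_increment_per_level` dots and shortens the interval by
#' 25% (`interval_decay = 0.75`). A level is passed when at least
#' `advance_criterion` of its block of `trials_per_level` trials are
#' correct.
#'
#' @param level1_dots dots at level 1 (default 9, the top of the 7-9
#'   range, giving a 1 s interval).
#' @param level1_duration_s total presentation window at level 1, seconds.
#' @param advance_criterion proportion correct needed to advance (0.80).
#' @param interval_decay multiplicative interval change per level (0.75).
#' @param dots_increment_per_level dots added per level (default 2).
#' @param trials_per_level trials per block (default 10, making the 80%
#'   criterion an integer 8/10).
#' @param max_levels,max_blocks session caps.
#' @return a list of class `dot_task_config`.
#' @export
dot_task_config <- function(level1_dots = 9, level1_duration_s = 9,
                            advance_criterion = 0.80, interval_decay = 0.75,
                            dots_increment_per_level = 2,
                            trials_per_level = 10, max_levels = 10,
                            max_blocks = 30) {
  if (advance_criterion <= 0 || advance_criterion > 1)
    stop_domain("advance_criterion must be in (0, 1]")
  if (interval_decay <= 0 || interval_decay >= 1)
    stop_domain("interval_decay must be in (0, 1)")
  if (trials_per_level < 5)
    stop_domain("trials_per_level must be >= 5 for the criterion to bite")
  structure(list(level1_dots = as.integer(level1_dots),
                 level1_duration_s = level1_duration_s,
                 advance_criterion = advance_criterion,
                 interval_decay = interval_decay,
                 dots_increment_per_level = as.integer(dots_increment_per_level),
                 trials_per_level = as.integer(trials_per_level),
                 max_levels = as.integer(max_levels),
                 max_blocks = as.integer(max_blocks)),
            class = "dot_task_config")
}

#' @rdname dot_task_config
#' @param level level >= 1; vectorised.
#' @param config a `dot_task_config`.
#' @return `dot_schedule()`: data frame with `level`, `n_dots`,
#'   `interval_s` where `interval_s = (level1_duration_s / level1_dots) *
#'   interval_decay^(level - 1)`.
#' @examples
#' dot_schedule(1:4)$interval_s  # 1, 0.75, 0.5625, 0.421875
#' @export
dot_schedule <- function(level, config = dot_task_config()) {
  stopifnot(inherits(config, "dot_task_config"))
  if (any(level < 1) || any(level %% 1 != 0))
    stop_domain("level must be an integer >= 1")
  interval1 <- config$level1_duration_s / config$level1_dots
  data.frame(level = level,
             n_dots = config$level1_dots +
               (level - 1) * config$dots_increment_per_level,
             interval_s = interval1 * config$interval_decay^(level - 1))
}

#' Run one dot-counting session
#'
#' Trials come in blocks of `trials_per_level`; after each block the level
#' advances iff the proportion correct meets `advance_criterion`, otherwise
#' the level is repeated. Auditory feedback is recorded per trial (as a
#' flag; nothing is played). The session ends at `max_levels` or
#' `max_blocks`.
#'
#' @param responder function `function(level) -> logical`.
#' @param config a [dot_task_config()].
#' @param seed optional RNG seed.
#' @return list of class `task_session` with a per-trial `log` (columns
#'   `trial`, `block`, `level`, `n_dots`, `interval_s`, `correct`,
#'   `feedback`), `max_level_reached`, `terminated_by`.
#' @export
run_dot_session <- function(responder, config = dot_task_config(),
                            seed = NULL) {
  stopifnot(is.function(responder), inherits(config, "dot_task_config"))
  with_seed(seed, {
    level <- 1L
    rows <- vector("list", config$max_blocks)
    terminated_by <- "max_blocks"
    for (block in seq_len(config$max_blocks)) {
      sched <- dot_schedule(level, config)
      correct <- vapply(seq_len(config$trials_per_level),
                        function(i) isTRUE(responder(level)), logical(1))
      rows[[block]] <- data.frame(
        block = block, level = level, n_dots = sched$n_dots,
        interval_s = sched$interval_s, correct = correct, feedback = TRUE)
      if (mean(correct) >= config$advance_criterion) level <- level + 1L
      if (level > config$max_levels) {
        terminated_by <- "max_level"
        break
      }
    }
    log <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    log <- cbind(trial = seq_len(nrow(log)), log)
    rownames(log) <- NULL
    structure(list(task = "dot", log = log,
                   max_level_reached = max(log$level),
                   terminated_by = terminated_by),
              class = "task_session")
  })
}

#' Run the feedback (training) variant of the RDK staircase
#'
#' Identical staircase dynamics to [run_staircase()] plus a per-trial
#' feedback flag (a noise sounds on wrong choices); the session stops after
#' a cumulative total of `max_wrong` wrong choices (default 4), or at the
#' staircase's own safety cap.
#'
#' @param observer an observer object (see [psychometric_observer()]).
#' @param config a [staircase_config()]; its reversal stop is ignored in
#'   favour of the wrong-choice stop.
#' @param max_wrong cumulative wrong choices at which training stops.
#' @param seed optional RNG seed.
#' @return list of class `task_session`: per-trial `log` (staircase columns
#'   plus `feedback` and `cumulative_wrong`), `n_wrong`, `terminated_by`.
#' @export
run_rdk_training <- function(observer, config = staircase_config(),
                             max_wrong = 4, seed = NULL) {
  stopifnot(inherits(config, "staircase_config"))
  with_seed(seed, {
    # disable the reversal stop: training ends on accumulated mistakes
    cfg <- config
    cfg$stop_reversals <- cfg$max_trials + 1L
    state <- staircase_init(cfg)
    wrong <- 0L
    while (!state$terminated && wrong < max_wrong) {
      coh <- attenuation_to_coherence(state$attenuation_db)
      correct <- respond(observer, coh)
      if (!correct) wrong <- wrong + 1L
      state <- staircase_update(state, correct, cfg)
    }
    log <- staircase_trial_log(state)
    log$feedback <- !log$correct
    log$cumulative_wrong <- cumsum(!log$correct)
    structure(list(task = "rdk_training", log = log, n_wrong = wrong,
                   terminated_by = if (wrong >= max_wrong) "wrong_choices"
                                   else "max_trials"),
              class = "task_session")
  })
}

#' Build and score a saccade event log
#'
#' During saccadic assessment the child shifts gaze between two targets; a
#' saccade to the left followed by the next saccade to the right counts as
#' one cycle, and performance is the number of cycles per minute.
#'
#' @param timestamp_s non-decreasing event times in seconds, within
#'   `[0, duration_s]`.
#' @param direction character vector of `"left"` / `"right"`, same length.
#' @param duration_s session duration in seconds, > 0.
#' @return `saccade_log()`: a list of class `saccade_log`.
#' @examples
#' log <- saccade_log(c(1, 2, 10, 11), c("left", "right", "left", "right"), 60)
#' count_cycles(log)  # 2 cycles/min
#' @export
saccade_log <- function(timestamp_s, direction, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_domain("duration_s must be positive")
  stopifnot(length(timestamp_s) == length(direction))
  if (length(timestamp_s)) {
    if (is.unsorted(timestamp_s)) stop_domain("timestamps must be sorted")
    if (any(timestamp_s < 0) || any(timestamp_s > duration_s))
      stop_domain("timestamps must lie within [0, duration_s]")
    if (!all(direction %in% c("left", "right")))
      stop_domain("direction must be 'left' or 'right'")
  }
  structure(list(timestamp_s = as.numeric(timestamp_s),
                 direction = as.character(direction),
                 duration_s = duration_s),
            class = "saccade_log")
}

#' @rdname saccade_log
#' @param log a `saccade_log`.
#' @return `count_cycles()`: cycles per minute. Pairing is a strict
#'   left-then-right consumption scan: a pending left saccade is completed
#'   by the next right saccade; an unmatched trailing left is not a cycle.
#' @export
count_cycles <- function(log) {
  stopifnot(inherits(log, "saccade_log"))
  pending_left <- FALSE
  cycles <- 0L
  for (d in log$direction) {
    if (d == "left") {
      pending_left <- TRUE
    } else if (pending_left) {
      cycles <- cycles + 1L
      pending_left <- FALSE
    }
  }
  cycles / (log$duration_s / 60)
}
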