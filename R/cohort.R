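#' Configure a synthetic two-group longitudinal cohort
#'
#' Emulates the study design: two matched groups of boys aged 9-11
#' (default 13 experimental, 11 control), assessed at four sessions (pre,
#' after the 6th training session, after the 12th, and at a one-month
#' follow-up) on seven outcome measures. Each measure is described by a
#' per-group mean trajectory over the four sessions, a between-child SD
#' (a stable individual offset) and a within-child session noise SD; error
#' counts are drawn Poisson around the child-session rate.
#'
#' The default (`effects = "study"`) is a *scenario*, not data: baselines
#' are plausible values consistent with the inclusion screen, and the
#' experimental-group session shifts equal the printed within-group mean
#' differences (e.g. an RDK threshold drop of 14.154 points by mid-test).
#' `effects = "null"` keeps every trajectory flat at its baseline, for
#' type-I-error calibration.
#'
#' @param n_experimental,n_control group sizes.
#' @param effects `"study"` for the study-shaped effect scenario,
#'   `"null"` for flat trajectories.
#' @param rdk_mode `"parametric"` draws RDK thresholds directly from the
#'   latent trajectory; `"mechanistic"` actually runs the weighted up-down
#'   staircase against a simulated observer whose 75% point is the child's
#'   latent value (slower, but the threshold then comes out of the adaptive
#'   procedure itself).
#' @param measures optional named list overriding per-measure settings;
#'   each element is a list with `traj_experimental`, `traj_control`
#'   (length-4 numeric), `between_sd`, `within_sd`, `family`
#'   (`"normal"` or `"poisson"`).
#' @param age_mean,age_sd,age_range sampling distribution for ages
#'   (truncated normal).
#' @param sessions session labels, length 4.
#' @return a list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(effects = "null")
#' cfg$measures$rdk_threshold$traj_experimental
#' @export
cohort_config <- function(n_experimental = 13, n_control = 11,
                          effects = c("study", "null"),
                          rdk_mode = c("parametric", "mechanistic"),
                          measures = NULL,
                          age_mean = 9.76, age_sd = 0.59,
                          age_range = c(9, 11),
                          sessions = c("pre", "mid", "post", "followup")) {
  effects <- match.arg(effects)
  rdk_mode <- match.arg(rdk_mode)
  if (n_experimental < 2 || n_control < 2)
    stop_domain("each group needs at least 2 children")
  if (length(sessions) != 4)
    stop_domain("the design has exactly 4 assessment sessions")

  meas <- function(traj_exp, traj_ctl, between_sd, within_sd,
                   family = "normal") {
    list(traj_experimental = traj_exp, traj_control = traj_ctl,
         between_sd = between_sd, within_sd = within_sd, family = family)
  }
  # Experimental-group shifts follow the printed within-group mean
  # differences; control trajectories and all baselines/SDs are scenario
  # choices (see the methods vignette).
  defaults <- list(
    rdk_threshold = meas(
      traj_exp = 45 - c(0, 14.154, 18.385, 17.077),
      traj_ctl = c(45, 45, 45, 45), between_sd = 6, within_sd = 4),
    saccade_cycles = meas(
      traj_exp = 80 + c(0, 42.077, 58.231, 60.769),
      traj_ctl = c(80, 80, 80, 80), between_sd = 15, within_sd = 8),
    reading_accuracy = meas(
      traj_exp = 60 + c(0, 13.58, 20.07, 21.822),
      traj_ctl = 60 + c(0, 5, 8, 9), between_sd = 8, within_sd = 5),
    comprehension = meas(
      traj_exp = 50 + c(0, 5.774, 14.541, 17.252),
      traj_ctl = 50 + c(0, 5, 12, 15), between_sd = 10, within_sd = 6),
    visual_errors = meas(
      traj_exp = c(10, 9, 7.5, 7.5), traj_ctl = c(10, 10, 10, 10),
      between_sd = 2, within_sd = 0, family = "poisson"),
    phonological_errors = meas(
      traj_exp = c(6, 6.5, 8, 9), traj_ctl = c(6, 5.5, 5, 5),
      between_sd = 1.5, within_sd = 0, family = "poisson"),
    pragmatic_errors = meas(
      traj_exp = c(4, 4, 4, 4), traj_ctl = c(4, 4, 4, 4),
      between_sd = 1, within_sd = 0, family = "poisson"))
  if (effects == "null")
    defaults <- lapply(defaults, function(m) {
      m$traj_experimental <- rep(m$traj_experimental[1], 4)
      m$traj_control <- rep(m$traj_control[1], 4)
      m
    })
  if (!is.null(measures)) {
    for (nm in names(measures)) {
      if (is.null(defaults[[nm]]))
        defaults[[nm]] <- measures[[nm]]
      else
        defaults[[nm]][names(measures[[nm]])] <- measures[[nm]]
    }
  }
  for (nm in names(defaults)) {
    m <- defaults[[nm]]
    for (key in c("traj_experimental", "traj_control", "between_sd",
                  "within_sd", "family"))
      if (is.null(m[[key]]))
        stop_domain("measure '", nm, "' is missing key '", key, "'")
    if (length(m$traj_experimental) != 4 || length(m$traj_control) != 4)
      stop_domain("measure '", nm, "' trajectories must have length 4")
    if (m$between_sd < 0 || m$within_sd < 0)
      stop_domain("measure '", nm, "' SDs must be >= 0")
    if (!m$family %in% c("normal", "poisson"))
      stop_domain("measure '", nm, "' family must be 'normal' or 'poisson'")
  }
  structure(list(n_experimental = as.integer(n_experimental),
                 n_control = as.integer(n_control),
                 effects = effects, rdk_mode = rdk_mode,
                 measures = defaults, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, sessions = sessions),
            class = "cohort_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  tries <- 0
  while (any(bad) && tries < 50) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
    tries <- tries + 1
  }
  clamp(x, lo, hi)
}

#' Generate a synthetic longitudinal cohort
#'
#' Each child draws a stable individual offset per measure
#' (`Normal(0, between_sd)`); each session's value is the group trajectory
#' mean plus that offset plus `Normal(0, within_sd)` session noise.
#' Poisson-family measures use the resulting (floored at 0.05) value as the
#' Poisson rate. In `rdk_mode = "mechanistic"` the RDK threshold of each
#' child-session is obtained by running the full weighted up-down staircase
#' against a [psychometric_observer()] whose 75% point equals the
#' child-session latent value.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer seed; fixed seed gives a byte-identical
#'   table.
#' @return a long-format data frame of class `cohort_table` with columns
#'   `participant_id`, `group`, `age`, `session`, `measure`, `value`:
#'   exactly `n_children x 4 sessions x 7 measures` rows.
#' @examples
#' cohort <- generate_cohort(cohort_config(effects = "null"), seed = 1)
#' nrow(cohort)  # 24 * 4 * 7
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    ids <- c(sprintf("E%02d", seq_len(config$n_experimental)),
             sprintf("C%02d", seq_len(config$n_control)))
    groups <- rep(c("experimental", "control"),
                  c(config$n_experimental, config$n_control))
    n <- length(ids)
    ages <- round(rtruncnorm1(n, config$age_mean, config$age_sd,
                              config$age_range[1], config$age_range[2]), 2)
    k <- length(config$sessions)
    rows <- vector("list", length(config$measures))
    mi <- 0L
    for (nm in names(config$measures)) {
      m <- config$measures[[nm]]
      offset <- stats::rnorm(n, 0, m$between_sd)
      vals <- matrix(NA_real_, n, k)
      for (i in seq_len(n)) {
        traj <- if (groups[i] == "experimental") m$traj_experimental
                else m$traj_control
        latent <- traj + offset[i]
        if (nm == "rdk_threshold" && config$rdk_mode == "mechanistic") {
          a75 <- clamp(latent, 2, 90)
          vals[i, ] <- vapply(a75, function(a) {
            run_staircase(psychometric_observer(a))$threshold_coherence_pct
          }, numeric(1))
        } else if (m$family == "poisson") {
          rate <- pmax(latent + stats::rnorm(k, 0, m$within_sd), 0.05)
          vals[i, ] <- stats::rpois(k, rate)
        } else {
          x <- latent + stats::rnorm(k, 0, m$within_sd)
          if (nm == "rdk_threshold") x <- clamp(x, 1, 99)
          vals[i, ] <- x
        }
      }
      mi <- mi + 1L
      rows[[mi]] <- data.frame(
        participant_id = rep(ids, each = k),
        group = rep(groups, each = k),
        age = rep(ages, each = k),
        session = rep(config$sessions, n),
        measure = nm,
        value = as.vector(t(vals)))
    }
    out <- do.call(rbind, rows)
    out$session <- factor(out$session, levels = config$sessions)
    out$group <- factor(out$group, levels = c("experimental", "control"))
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "sessions") <- config$sessions
    out
  })
}

#' Apply the study's inclusion screen to a cohort
#'
#' A child is eligible when the baseline (first-session) reading accuracy
#' score is strictly below `apra_cutoff` AND the baseline RDK threshold is
#' strictly above `rdk_cutoff`. Both inequalities are strict, matching the
#' screen's wording ("below 71", "above 34").
#'
#' @param cohort a `cohort_table`.
#' @param apra_cutoff reading-score cut-off (default 71).
#' @param rdk_cutoff RDK threshold cut-off in percent coherence (default
#'   34).
#' @return the eligible subset (still a `cohort_table`), with attributes
#'   `n_kept`, `n_dropped` and `dropped_ids`.
#' @export
screen_inclusion <- function(cohort, apra_cutoff = 71, rdk_cutoff = 34) {
  stopifnot(inherits(cohort, "data.frame"))
  sessions <- levels(factor(cohort$session))
  baseline <- if (!is.null(attr(cohort, "sessions")))
    attr(cohort, "sessions")[1] else sessions[1]
  base <- cohort[cohort$session == baseline, ]
  ids <- unique(cohort$participant_id)
  apra <- base$value[match(paste(ids, "reading_accuracy"),
                           paste(base$participant_id, base$measure))]
  rdk <- base$value[match(paste(ids, "rdk_threshold"),
                          paste(base$participant_id, base$measure))]
  if (anyNA(apra) || anyNA(rdk))
    stop_domain("baseline reading_accuracy / rdk_threshold missing for ",
                "some participants")
  eligible <- ids[apra < apra_cutoff & rdk > rdk_cutoff]
  out <- cohort[cohort$participant_id %in% eligible, ]
  rownames(out) <- NULL
  class(out) <- class(cohort)
  attr(out, "sessions") <- attr(cohort, "sessions")
  attr(out, "n_kept") <- length(eligible)
  attr(out, "n_dropped") <- length(ids) - length(eligible)
  attr(out, "dropped_ids") <- setdiff(ids, eligible)
  out
}

#' Group-by-session summary of a cohort
#'
#' Means and standard errors per group x session x measure, the shape of
#' the study's figures (error bars = SEM).
#'
#' @param cohort a `cohort_table`.
#' @return data frame with `group`, `session`, `measure`, `n`, `mean`,
#'   `sd`, `sem`; `sem = sd / sqrt(n)`, reported as `NA` when `n = 1`.
#' @export
summarize_by_group_session <- function(cohort) {
  stopifnot(inherits(cohort, "data.frame"))
  agg <- stats::aggregate(
    value ~ group + session + measure, data = cohort,
    FUN = function(v) c(n = length(v), mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(group = agg$group, session = agg$session,
                    measure = agg$measure,
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"])
  out$sem <- ifelse(out$n > 1, out$sd / sqrt(out$n), NA_real_)
  out[order(out$measure, out$group, out$session), , drop = FALSE]
}
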