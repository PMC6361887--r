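#' Read and write cohort tables as long-format CSV
#'
#' The on-disk schema is the long format of [generate_cohort()]:
#' `participant_id, group, age, session, measure, value`. Reading
#' validates the file and refuses malformed rows with the offending row
#' index: unknown group/session/measure labels, non-numeric values,
#' RDK thresholds outside `(0, 100]`, or negative / non-integer error
#' counts.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @param sessions expected session labels, in design order.
#' @return `read_cohort_csv()`: a validated `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "data.frame"))
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path,
                            sessions = c("pre", "mid", "post", "followup")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "group", "age", "session", "measure", "value")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop_domain("cohort CSV is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  bad_row <- function(rows, why) {
    stop_domain("invalid cohort CSV: ", why, " at row ",
                paste(utils::head(rows, 5), collapse = ", "))
  }
  r <- which(!raw$group %in% c("experimental", "control"))
  if (length(r)) bad_row(r, "unknown group label")
  r <- which(!raw$session %in% sessions)
  if (length(r)) bad_row(r, "unknown session label")
  r <- which(!is.finite(raw$value))
  if (length(r)) bad_row(r, "non-numeric value")
  r <- which(raw$measure == "rdk_threshold" &
               (raw$value <= 0 | raw$value > 100))
  if (length(r)) bad_row(r, "rdk_threshold outside (0, 100]")
  counts <- grepl("_errors$", raw$measure)
  r <- which(counts & (raw$value < 0 | raw$value %% 1 != 0))
  if (length(r)) bad_row(r, "error count negative or non-integer")
  raw$session <- factor(raw$session, levels = sessions)
  raw$group <- factor(raw$group, levels = c("experimental", "control"))
  class(raw) <- c("cohort_table", "data.frame")
  attr(raw, "sessions") <- sessions
  raw
}

#' Serialise a cohort configuration to / from YAML
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @return `read_cohort_config()`: a validated `cohort_config` (unknown or
#'   missing keys raise an error naming the key).
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("n_experimental", "n_control", "effects", "rdk_mode",
                "measures"))
    if (is.null(raw[[key]]))
      stop_domain("cohort config is missing key '", key, "'")
  cohort_config(
    n_experimental = raw$n_experimental, n_control = raw$n_control,
    effects = raw$effects, rdk_mode = raw$rdk_mode,
    measures = lapply(raw$measures, function(m) {
      m$traj_experimental <- as.numeric(m$traj_experimental)
      m$traj_control <- as.numeric(m$traj_control)
      m
    }),
    age_mean = if (is.null(raw$age_mean)) 9.76 else raw$age_mean,
    age_sd = if (is.null(raw$age_sd)) 0.59 else raw$age_sd,
    age_range = if (is.null(raw$age_range)) c(9, 11)
                else as.numeric(raw$age_range),
    sessions = if (is.null(raw$sessions)) c("pre", "mid", "post", "followup")
               else as.character(raw$sessions))
}

analysis_report <- function(cohort, sphericity_alpha = 0.05) {
  measures <- unique(cohort$measure)
  sessions <- levels(cohort$session)
  report <- list()
  for (nm in measures) {
    dat <- cohort[cohort$measure == nm, ]
    fit <- mixed_anova(dat, dv = "value", sphericity_alpha = sphericity_alpha)
    pw <- pairwise_within(dat, dv = "value")
    between <- lapply(sessions, function(s) {
      sdat <- dat[dat$session == s, ]
      tt <- independent_t(sdat$value[sdat$group == "experimental"],
                          sdat$value[sdat$group == "control"])
      mw <- mann_whitney_u(sdat$value[sdat$group == "experimental"],
                           sdat$value[sdat$group == "control"])
      list(session = s, t = tt[c("statistic", "df", "p", "estimate")],
           mann_whitney = mw[c("statistic", "p", "exact")])
    })
    names(between) <- sessions
    report[[nm]] <- list(anova = fit$table, sphericity = fit$sphericity,
                         pairwise_within = pw, between_groups = between)
  }
  report
}

#' Replicate the study in silico, end to end
#'
#' Generates a synthetic cohort, applies the inclusion screen, summarises
#' the group x session means, runs the full mixed repeated-measures
#' analysis on every measure (ANOVA with sphericity handling, within-group
#' paired comparisons, between-group t and Mann-Whitney tests per session),
#' and writes all artifacts plus a run manifest to `out_dir`. All
#' randomness descends from `seed` via named [seed_stream()]s.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and just returns the results.
#' @param apra_cutoff,rdk_cutoff inclusion-screen cut-offs (see
#'   [screen_inclusion()]).
#' @param verbose log stage progress to standard error.
#' @return invisibly, a list with `cohort`, `eligible`, `summary`,
#'   `report`, `manifest`.
#' @examples
#' res <- run_full_pipeline(cohort_config(), seed = 1, out_dir = NULL)
#' res$report$rdk_threshold$anova
#' @export
run_full_pipeline <- function(config = cohort_config(), seed = 1,
                              out_dir = NULL, apra_cutoff = 71,
                              rdk_cutoff = 34, verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  log_stage <- function(...) if (verbose) message("[magnosim] ", ...)
  stages_done <- character()
  config_yaml <- yaml::as.yaml(unclass(config))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("magnosim")),
                   config_hash = fnv1a_hex(config_yaml),
                   master_seed = seed,
                   stage_seeds = list(cohort = seed_stream(seed, "cohort")),
                   started = format(Sys.time(), tz = "UTC"),
                   stages_completed = character(), outputs = character())
  write_all <- function(result) {
    if (is.null(out_dir)) return(character())
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(cohort = file.path(out_dir, "cohort.csv"),
               summary = file.path(out_dir, "summary.csv"),
               report = file.path(out_dir, "report.json"),
               config = file.path(out_dir, "config.yaml"),
               manifest = file.path(out_dir, "manifest.json"))
    if (!is.null(result$cohort)) write_cohort_csv(result$cohort, paths["cohort"])
    if (!is.null(result$summary))
      utils::write.csv(result$summary, paths["summary"], row.names = FALSE)
    if (!is.null(result$report))
      jsonlite::write_json(result$report, paths["report"],
                           auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(config_yaml, paths["config"])
    paths
  }

  result <- list()
  err <- tryCatch({
    log_stage("generating cohort (seed ",
              manifest$stage_seeds$cohort, ")")
    result$cohort <- generate_cohort(config,
                                     seed = manifest$stage_seeds$cohort)
    stages_done <- c(stages_done, "generate_cohort")

    log_stage("applying inclusion screen")
    result$eligible <- screen_inclusion(result$cohort, apra_cutoff,
                                        rdk_cutoff)
    manifest$screen <- list(n_kept = attr(result$eligible, "n_kept"),
                            n_dropped = attr(result$eligible, "n_dropped"))
    stages_done <- c(stages_done, "screen_inclusion")

    log_stage("summarising group x session means")
    result$summary <- summarize_by_group_session(result$eligible)
    stages_done <- c(stages_done, "summarize")

    log_stage("running mixed repeated-measures analysis")
    result$report <- analysis_report(result$eligible)
    stages_done <- c(stages_done, "analysis")
    NULL
  }, error = function(e) conditionMessage(e))

  manifest$stages_completed <- stages_done
  if (!is.null(err)) manifest$error <- err
  paths <- write_all(result)
  manifest$outputs <- unname(paths[names(paths) != "manifest"])
  manifest$finished <- format(Sys.time(), tz = "UTC")
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result$manifest <- manifest
  if (!is.null(err))
    warning("pipeline stopped early after [",
            paste(stages_done, collapse = ", "), "]: ", err, call. = FALSE)
  invisible(result)
}
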