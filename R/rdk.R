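#' Parameters for a two-panel random-dot kinematogram trial
#'
#' Two panels of moving dots are shown side by side; one panel (the signal
#' panel) contains a proportion of dots sharing a common left/right heading
#' among noise dots with uniform random headings, the other panel contains
#' only noise. Coordinates are normalised to `[0, 1)` per panel (origin
#' top-left, x rightward, y downward); dots wrap toroidally at the edges.
#'
#' @param n_dots_per_panel dots per panel (default 100).
#' @param n_frames frames per trial (default 20); displacements are defined
#'   between consecutive frames.
#' @param dot_step displacement magnitude per frame, panel units.
#' @param coherence percent of dots moving coherently, in `[0, 100]`.
#' @param signal_direction `"left"` or `"right"`.
#' @param signal_panel which panel carries the signal, `"left"` or
#'   `"right"`.
#' @return a list of class `rdk_params`.
#' @export
rdk_params <- function(n_dots_per_panel = 100, n_frames = 20,
                       dot_step = 0.02, coherence = 50,
                       signal_direction = c("left", "right"),
                       signal_panel = c("left", "right")) {
  signal_direction <- match.arg(signal_direction)
  signal_panel <- match.arg(signal_panel)
  if (n_dots_per_panel < 1) stop_domain("need at least one dot per panel")
  if (n_frames < 2) stop_domain("need at least two frames")
  if (coherence < 0 || coherence > 100)
    stop_domain("coherence must be in [0, 100]")
  if (dot_step <= 0) stop_domain("dot_step must be positive")
  structure(list(n_dots_per_panel = as.integer(n_dots_per_panel),
                 n_frames = as.integer(n_frames), dot_step = dot_step,
                 coherence = coherence, signal_direction = signal_direction,
                 signal_panel = signal_panel),
            class = c("rdk_params", "list"))
}

# headings matrix [n_dots, n_steps] for one panel; signal dots are re-drawn
# at random every frame step so no single dot can be tracked.
panel_headings <- function(n_dots, n_steps, n_signal, signal_angle) {
  theta <- matrix(stats::runif(n_dots * n_steps, 0, 2 * pi), n_dots, n_steps)
  signal_sets <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    idx <- if (n_signal > 0) sample.int(n_dots, n_signal) else integer()
    theta[idx, s] <- signal_angle
    signal_sets[[s]] <- sort(idx)
  }
  list(theta = theta, signal_sets = signal_sets)
}

#' Generate one two-panel RDK trial
#'
#' The signal panel carries exactly `round(coherence/100 * n_dots)` signal
#' dots per frame step (half-up rounding), re-drawn at random each step;
#' all other dots take independent uniform headings. Positions start
#' uniform and wrap toroidally.
#'
#' @param params an [rdk_params()] list.
#' @param seed optional RNG seed for a reproducible trial.
#' @return an object of class `rdk_trial`: per-panel dot positions
#'   (`x`, `y`: `n_dots x n_frames` matrices), per-step headings
#'   (`theta`: `n_dots x (n_frames - 1)`), and per-step signal index sets.
#' @examples
#' tr <- generate_rdk_trial(rdk_params(n_dots_per_panel = 10, coherence = 50),
#'                          seed = 1)
#' lengths(tr$panels$left$signal_sets)  # 5 signal dots per step
#' @export
generate_rdk_trial <- function(params, seed = NULL) {
  stopifnot(inherits(params, "rdk_params"))
  with_seed(seed, {
    n <- params$n_dots_per_panel
    n_steps <- params$n_frames - 1L
    n_signal <- as.integer(round_half_up(params$coherence / 100 * n))
    angle <- if (params$signal_direction == "right") 0 else pi

    build_panel <- function(has_signal) {
      h <- panel_headings(n, n_steps, if (has_signal) n_signal else 0L, angle)
      x <- matrix(NA_real_, n, params$n_frames)
      y <- matrix(NA_real_, n, params$n_frames)
      x[, 1] <- stats::runif(n)
      y[, 1] <- stats::runif(n)
      for (s in seq_len(n_steps)) {
        x[, s + 1] <- (x[, s] + params$dot_step * cos(h$theta[, s])) %% 1
        y[, s + 1] <- (y[, s] + params$dot_step * sin(h$theta[, s])) %% 1
      }
      list(x = x, y = y, theta = h$theta, signal_sets = h$signal_sets)
    }
    panels <- list(left = build_panel(params$signal_panel == "left"),
                   right = build_panel(params$signal_panel == "right"))
    structure(list(params = params, panels = panels), class = "rdk_trial")
  })
}

#' Mean resultant length of a panel's dot motion
#'
#' Pools the displacement unit vectors of every dot over every frame step
#' and returns the modulus of their mean: 1 for perfectly coherent motion,
#' tending to 0 (at rate ~ n^(-1/2)) for pure noise.
#'
#' @param trial an `rdk_trial`.
#' @param panel `"left"` or `"right"`.
#' @param noise_sd optional angular noise (radians) added to each heading
#'   before pooling (used by the mechanistic observer).
#' @return statistic in `[0, 1]`.
#' @examples
#' tr <- generate_rdk_trial(rdk_params(coherence = 100, signal_panel = "left"),
#'                          seed = 1)
#' panel_coherence_statistic(tr, "left")  # 1
#' @export
panel_coherence_statistic <- function(trial, panel = c("left", "right"),
                                      noise_sd = 0) {
  stopifnot(inherits(trial, "rdk_trial"))
  panel <- match.arg(panel)
  theta <- trial$panels[[panel]]$theta
  if (noise_sd > 0)
    theta <- theta + stats::rnorm(length(theta), 0, noise_sd)
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Decide which panel contains the coherent motion
#'
#' The mechanistic observer's decision rule: perturb every perceived dot
#' heading with `Normal(0, direction_noise_sd)` angular noise, compute the
#' mean resultant length per panel, and choose the larger; an exact tie is
#' broken by a fair coin.
#'
#' @param trial an `rdk_trial`.
#' @param observer a [mechanistic_observer()].
#' @return `"left"` or `"right"`.
#' @export
decide_panel <- function(trial, observer) {
  stopifnot(inherits(trial, "rdk_trial"),
            inherits(observer, "mechanistic_observer"))
  sd <- observer$direction_noise_sd
  s_left <- panel_coherence_statistic(trial, "left", noise_sd = sd)
  s_right <- panel_coherence_statistic(trial, "right", noise_sd = sd)
  if (s_left > s_right) "left"
  else if (s_right > s_left) "right"
  else if (stats::runif(1) < 0.5) "left" else "right"
}

#' Flatten an RDK trial to a long data frame
#'
#' One row per (frame step, panel, dot): positions before the step, the
#' displacement applied, and whether the dot was a signal dot on that step.
#' Suitable for CSV dumps and plotting; no rendering is done.
#'
#' @param trial an `rdk_trial`.
#' @return data frame with columns `frame`, `panel`, `dot_id`, `x`, `y`,
#'   `dx`, `dy`, `is_signal`.
#' @export
rdk_trial_to_df <- function(trial) {
  stopifnot(inherits(trial, "rdk_trial"))
  step <- trial$params$dot_step
  out <- lapply(c("left", "right"), function(side) {
    p <- trial$panels[[side]]
    n_steps <- ncol(p$theta)
    n <- nrow(p$theta)
    do.call(rbind, lapply(seq_len(n_steps), function(s) {
      data.frame(frame = s, panel = side, dot_id = seq_len(n),
                 x = p$x[, s], y = p$y[, s],
                 dx = step * cos(p$theta[, s]),
                 dy = step * sin(p$theta[, s]),
                 is_signal = seq_len(n) %in% p$signal_sets[[s]])
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
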