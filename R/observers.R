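#' Simulated observers for the two-panel coherent-motion task
#'
#' `psychometric_observer()` builds a closed-form observer: a Weibull
#' psychometric function under two-alternative forced choice,
#' \deqn{p(c) = 0.5 + (0.5 - \lambda)\,(1 - e^{-(c/\tilde\alpha)^\beta}),}
#' with the scale \eqn{\tilde\alpha} solved analytically so that
#' `p(alpha75) = 0.75` exactly. `mechanistic_observer()` builds an observer
#' with no assumed psychometric function: it perturbs every perceived dot
#' heading by Gaussian angular noise and picks the panel with the larger
#' mean resultant length (see [decide_panel()]); its 75% point *emerges*
#' from the stimulus and can be measured with [calibrate_alpha75()].
#'
#' @param alpha75 coherence (percent, in (0, 100]) at which the observer is
#'   75% correct.
#' @param slope Weibull steepness (dimensionless, > 0). Default 2, a
#'   typical value for child coherence psychometrics.
#' @param lapse lapse probability in `[0, 0.06]`; caps performance at
#'   `1 - lapse` even for a fully coherent stimulus. Default 0.02.
#' @param direction_noise_sd angular noise, radians, added to each
#'   perceived dot displacement by the mechanistic observer.
#' @return an object of class `psychometric_observer` /
#'   `mechanistic_observer` (both inherit `rdk_observer`).
#' @examples
#' obs <- psychometric_observer(alpha75 = 30)
#' p_correct(obs, 30)  # 0.75 by construction
#' @export
psychometric_observer <- function(alpha75, slope = 2, lapse = 0.02) {
  if (!is.numeric(alpha75) || alpha75 <= 0 || alpha75 > 100)
    stop_domain("alpha75 must be in (0, 100]")
  if (slope <= 0) stop_domain("slope must be > 0")
  if (lapse < 0 || lapse > 0.06) stop_domain("lapse must be in [0, 0.06]")
  # Solve p(alpha75) = 0.75: 0.25 = (0.5 - lapse) * (1 - exp(-(a75/scale)^b))
  q <- 1 - 0.25 / (0.5 - lapse)
  scale <- alpha75 / (-log(q))^(1 / slope)
  structure(list(alpha75 = alpha75, slope = slope, lapse = lapse,
                 guess = 0.5, scale = scale),
            class = c("psychometric_observer", "rdk_observer"))
}

#' @rdname psychometric_observer
#' @export
mechanistic_observer <- function(direction_noise_sd) {
  if (!is.numeric(direction_noise_sd) || direction_noise_sd < 0)
    stop_domain("direction_noise_sd must be >= 0")
  structure(list(direction_noise_sd = direction_noise_sd,
                 integration = "resultant-vector"),
            class = c("mechanistic_observer", "rdk_observer"))
}

#' Probability of a correct response at a given coherence
#'
#' @param observer a [psychometric_observer()].
#' @param coherence_pct coherence in percent, in `[0, 100]`; vectorised.
#' @return probability of a correct 2AFC response; 0.5 at zero coherence,
#'   at most `1 - lapse`.
#' @export
p_correct <- function(observer, coherence_pct) {
  UseMethod("p_correct")
}

#' @export
p_correct.psychometric_observer <- function(observer, coherence_pct) {
  if (any(!is.finite(coherence_pct)) || any(coherence_pct < 0) ||
      any(coherence_pct > 100))
    stop_domain("coherence_pct must be in [0, 100]")
  0.5 + (0.5 - observer$lapse) *
    (1 - exp(-(coherence_pct / observer$scale)^observer$slope))
}

#' Draw a correct/wrong response from an observer
#'
#' For a psychometric observer this is a Bernoulli draw with probability
#' [p_correct()]. For a mechanistic observer a full two-panel RDK trial is
#' generated at the given coherence (parameters in
#' `observer$rdk_params`, defaulting to [rdk_params()]) and judged with
#' [decide_panel()].
#'
#' @param observer an observer object.
#' @param coherence_pct stimulus coherence in percent.
#' @param ... passed on to methods.
#' @return logical: was the response correct?
#' @export
respond <- function(observer, coherence_pct, ...) {
  UseMethod("respond")
}

#' @export
respond.psychometric_observer <- function(observer, coherence_pct, ...) {
  stats::runif(1) < p_correct(observer, coherence_pct)
}

#' @export
respond.mechanistic_observer <- function(observer, coherence_pct, ...) {
  params <- observer$rdk_params
  if (is.null(params)) params <- rdk_params()
  params$coherence <- coherence_pct
  params$signal_panel <- if (stats::runif(1) < 0.5) "left" else "right"
  params$signal_direction <- if (stats::runif(1) < 0.5) "left" else "right"
  trial <- generate_rdk_trial(params)
  decide_panel(trial, observer) == params$signal_panel
}

#' Measure a mechanistic observer's 75%-correct coherence
#'
#' Monte-Carlo bisection: the observer's percent correct is estimated at
#' candidate coherences (each probe runs `trials_per_probe` full
#' generate-and-decide RDK trials) and the coherence where it crosses 0.75
#' is bracketed to `tol_pct`. If the observer is already above 75% correct
#' at the lowest representable coherence (e.g. a noiseless observer), that
#' lower bound is returned. If it never reaches 75% by 100% coherence the
#' search does not bracket and an error is raised.
#'
#' @param observer a [mechanistic_observer()].
#' @param params an [rdk_params()] list describing the stimulus.
#' @param trials_per_probe Monte-Carlo trials per probed coherence
#'   (default 2000).
#' @param tol_pct bisection stopping width in percent coherence.
#' @param seed optional RNG seed.
#' @return estimated `alpha75` in percent coherence.
#' @export
calibrate_alpha75 <- function(observer, params = rdk_params(),
                              trials_per_probe = 2000, tol_pct = 1,
                              seed = NULL) {
  stopifnot(inherits(observer, "mechanistic_observer"))
  with_seed(seed, {
    probe <- function(coh) {
      hits <- vapply(seq_len(trials_per_probe), function(i) {
        p <- params
        p$coherence <- coh
        p$signal_panel <- if (stats::runif(1) < 0.5) "left" else "right"
        p$signal_direction <- if (stats::runif(1) < 0.5) "left" else "right"
        decide_panel(generate_rdk_trial(p), observer) == p$signal_panel
      }, logical(1))
      mean(hits)
    }
    # smallest coherence that still yields one signal dot
    lo <- 100 * 0.5 / params$n_dots_per_panel
    hi <- 100
    if (probe(lo) >= 0.75) return(lo)
    if (probe(hi) < 0.75)
      stop_domain("calibration failed: observer never reaches 75% correct")
    while (hi - lo > tol_pct) {
      mid <- (lo + hi) / 2
      if (probe(mid) < 0.75) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

#' Serialise / deserialise an observer specification
#'
#' Observers travel in configs as plain lists:
#' `{kind: psychometric|mechanistic, alpha75, slope, lapse,
#' direction_noise_sd}`.
#'
#' @param spec a named list (e.g. parsed from YAML/JSON).
#' @param observer an observer object.
#' @return `observer_from_spec()`: an observer; `observer_to_spec()`: a
#'   plain named list.
#' @export
observer_from_spec <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  switch(spec$kind,
    psychometric = psychometric_observer(
      alpha75 = spec$alpha75,
      slope = if (is.null(spec$slope)) 2 else spec$slope,
      lapse = if (is.null(spec$lapse)) 0.02 else spec$lapse),
    mechanistic = mechanistic_observer(spec$direction_noise_sd),
    stop_domain("unknown observer kind: ", spec$kind))
}

#' @rdname observer_from_spec
#' @export
observer_to_spec <- function(observer) {
  if (inherits(observer, "psychometric_observer"))
    list(kind = "psychometric", alpha75 = observer$alpha75,
         slope = observer$slope, lapse = observer$lapse)
  else if (inherits(observer, "mechanistic_observer"))
    list(kind = "mechanistic",
         direction_noise_sd = observer$direction_noise_sd)
  else stop_domain("not an observer object")
}

#' @export
print.rdk_observer <- function(x, ...) {
  if (inherits(x, "psychometric_observer"))
    cat(sprintf(
      "2AFC Weibull observer: alpha75 = %.2f%%, slope = %.2f, lapse = %.3f\n",
      x$alpha75, x$slope, x$lapse))
  else
    cat(sprintf(
      "Mechanistic RDK observer: direction noise sd = %.3f rad (%s)\n",
      x$direction_noise_sd, x$integration))
  invisible(x)
}
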