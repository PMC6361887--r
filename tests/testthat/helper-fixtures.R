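# Shared fixtures: deterministic responders and small stimulus settings.

# responder that answers according to a fixed TRUE/FALSE pattern, recycling
make_pattern_responder <- function(pattern) {
  i <- 0L
  function(level) {
    i <<- i + 1L
    pattern[((i - 1L) %% length(pattern)) + 1L]
  }
}

# deterministic threshold observer: correct iff coherence > cut
make_cut_observer <- function(cut) {
  structure(list(cut = cut), class = c("cut_observer", "rdk_observer"))
}
respond.cut_observer <- function(observer, coherence_pct, ...) {
  coherence_pct > observer$cut
}
# register the S3 method for the test session
registerS3method("respond", "cut_observer", respond.cut_observer,
                 envir = asNamespace("magnosim"))

# small, fast RDK stimulus for mechanistic-observer tests
small_rdk <- function(coherence = 50, ...) {
  rdk_params(n_dots_per_panel = 20, n_frames = 4, coherence = coherence, ...)
}

# brute-force split-plot decomposition used as the independent oracle:
# everything from explicit group-mean projections, no shared code with
# mixed_anova()
brute_force_split_plot <- function(d) {
  y <- d$value
  gm <- mean(y)
  subj <- unique(d$participant_id)
  k <- length(unique(d$session))
  subj_mean <- sapply(subj, function(s) mean(y[d$participant_id == s]))
  subj_grp <- sapply(subj, function(s) d$group[d$participant_id == s][1])
  grps <- unique(d$group)
  n_g <- sapply(grps, function(g) sum(subj_grp == g))
  grp_mean <- sapply(grps, function(g) mean(y[d$group == g]))
  sess <- unique(d$session)
  sess_mean <- sapply(sess, function(s) mean(y[d$session == s]))
  ss_bs <- k * sum((subj_mean - gm)^2)
  ss_g <- k * sum(n_g * (grp_mean - gm)^2)
  ss_subj <- ss_bs - ss_g
  ss_s <- length(subj) * sum((sess_mean - gm)^2)
  ss_cells <- 0
  for (g in grps) for (s in sess) {
    cell <- y[d$group == g & d$session == s]
    ss_cells <- ss_cells + length(cell) * (mean(cell) - gm)^2
  }
  ss_gs <- ss_cells - ss_g - ss_s
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_bs - ss_s - ss_gs
  df <- list(g = length(grps) - 1, subj = length(subj) - length(grps),
             s = k - 1, gs = (length(grps) - 1) * (k - 1),
             err = (k - 1) * (length(subj) - length(grps)))
  list(F_group = (ss_g / df$g) / (ss_subj / df$subj),
       F_session = (ss_s / df$s) / (ss_err / df$err),
       F_inter = (ss_gs / df$gs) / (ss_err / df$err),
       ss = c(ss_g, ss_subj, ss_s, ss_gs, ss_err), ss_total = ss_tot)
}

# long-format toy dataset for the mixed ANOVA, fixed numbers
toy_split_plot <- function() {
  # 2 groups x 3 subjects x 2 sessions, hand-enterable values
  data.frame(
    participant_id = rep(c("a", "b", "c", "d", "e", "f"), each = 2),
    group = rep(c("g1", "g2"), each = 6),
    session = rep(c("s1", "s2"), 6),
    value = c(3, 5, 4, 7, 2, 6, 8, 9, 7, 11, 9, 12))
}
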