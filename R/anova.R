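#' Mixed-design (split-plot) repeated-measures ANOVA
#'
#' Classical decomposition for a design with one between-subjects factor
#' (group) and one within-subjects factor (session), balanced across
#' sessions (every subject measured at every session; group sizes may
#' differ). The between-subjects stratum splits into the group effect and
#' subjects-within-group; the within-subjects stratum into session, the
#' group x session interaction, and session x subjects-within-group error:
#' \deqn{F_{group} = MS_{group}/MS_{subj(group)},\qquad
#'       F_{session}, F_{g \times s} = MS/MS_{s \times subj(group)}.}
#' Partial eta squared for each effect is
#' \eqn{SS_{effect}/(SS_{effect}+SS_{error})} with the effect's own error
#' term. Sphericity of the within-subject covariance is tested with
#' [mauchly_test()]; Greenhouse-Geisser corrected degrees of freedom
#' (uncorrected df times [gg_epsilon()]) and the corresponding p-values are
#' reported alongside the uncorrected ones, and the `p_reported` column
#' follows the stated policy: the corrected p when Mauchly rejects at
#' `sphericity_alpha`, the uncorrected p otherwise.
#'
#' @param data long-format data frame.
#' @param dv name of the numeric response column.
#' @param id,within,between names of the subject, within-factor and
#'   between-factor columns.
#' @param sphericity_alpha Mauchly significance level driving the
#'   correction policy (default 0.05).
#' @return an object of class `mixed_anova`: `table` (one row per effect
#'   with `SS`, `df`, `MS`, `F`, `p`, `partial_eta_sq`, `df1_gg`, `df2_gg`,
#'   `p_gg`, `p_reported`), `sphericity` (`mauchly_W`, `mauchly_chisq`,
#'   `mauchly_df`, `mauchly_p`, `gg_epsilon`, `corrected`), and the design
#'   sizes.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' rdk <- cohort[cohort$measure == "rdk_threshold", ]
#' fit <- mixed_anova(rdk, dv = "value")
#' fit$table
#' @export
mixed_anova <- function(data, dv = "value", id = "participant_id",
                        within = "session", between = "group",
                        sphericity_alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c(dv, id, within, between) %in% names(data)))
  y <- data[[dv]]
  if (anyNA(y)) stop_domain("missing responses are not supported")
  subj <- factor(data[[id]])
  sess <- factor(data[[within]])
  grp <- factor(data[[between]])
  k <- nlevels(sess)
  g <- nlevels(grp)
  N <- nlevels(subj)
  if (g < 2) stop_domain("need at least 2 groups")
  if (k < 2) stop_domain("need at least 2 within-subject levels")

  # every subject must have exactly one observation per session
  tab <- table(subj, sess)
  if (any(tab != 1))
    stop_domain("unbalanced design: every subject needs exactly one ",
                "observation per within level (no imputation is done)")
  subj_group <- tapply(as.character(grp), subj, function(v) v[1])
  n_per_group <- table(factor(subj_group, levels = levels(grp)))
  if (any(n_per_group < 2)) stop_domain("need >= 2 subjects per group")

  gm <- mean(y)
  ss_total <- sum((y - gm)^2)

  subj_means <- tapply(y, subj, mean)
  ss_between_subj <- k * sum((subj_means - gm)^2)
  grp_means <- tapply(y, grp, mean)
  ss_group <- k * sum(n_per_group * (grp_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group

  sess_means <- tapply(y, sess, mean)
  ss_session <- N * sum((sess_means - gm)^2)
  cell_means <- tapply(y, list(grp, sess), mean)
  ss_cells <- sum(as.vector(n_per_group) * (cell_means - gm)^2)
  ss_inter <- ss_cells - ss_group - ss_session
  ss_error_within <- ss_total - ss_between_subj - ss_session - ss_inter

  df_group <- g - 1
  df_subj <- N - g
  df_session <- k - 1
  df_inter <- (g - 1) * (k - 1)
  df_error <- (k - 1) * (N - g)

  # wide response matrix for the sphericity block
  wide <- matrix(NA_real_, N, k,
                 dimnames = list(levels(subj), levels(sess)))
  wide[cbind(as.integer(subj), as.integer(sess))] <- y
  wide_groups <- factor(subj_group, levels = levels(grp))
  sph <- tryCatch({
    mt <- mauchly_test(wide, groups = wide_groups)
    eps <- gg_epsilon(wide, groups = wide_groups)
    list(mauchly_W = mt$W, mauchly_chisq = mt$chi_sq, mauchly_df = mt$df,
         mauchly_p = mt$p, gg_epsilon = eps)
  }, error = function(e) list(mauchly_W = NA_real_,
                              mauchly_chisq = NA_real_, mauchly_df = NA_real_,
                              mauchly_p = NA_real_, gg_epsilon = NA_real_))
  correct_df <- isTRUE(sph$mauchly_p < sphericity_alpha)
  sph$corrected <- correct_df

  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    if (!is.finite(ms_err) || ms_err <= .Machine$double.eps * abs(gm + 1))
      return(NA_real_)
    ms_eff / ms_err
  }
  effects <- data.frame(
    effect = c("group", "subjects_within_group", "session",
               "group_x_session", "session_x_subjects_within_group"),
    SS = c(ss_group, ss_subj_within, ss_session, ss_inter, ss_error_within),
    df = c(df_group, df_subj, df_session, df_inter, df_error))
  effects$MS <- effects$SS / effects$df
  effects$F <- NA_real_
  effects$F[1] <- f_of(ss_group, df_group, ss_subj_within, df_subj)
  effects$F[3] <- f_of(ss_session, df_session, ss_error_within, df_error)
  effects$F[4] <- f_of(ss_inter, df_inter, ss_error_within, df_error)
  err_df <- c(df_subj, NA, df_error, df_error, NA)
  err_ss <- c(ss_subj_within, NA, ss_error_within, ss_error_within, NA)
  effects$df2 <- err_df
  effects$p <- ifelse(is.na(effects$F), NA,
                      stats::pf(effects$F, effects$df, err_df,
                                lower.tail = FALSE))
  effects$partial_eta_sq <- ifelse(
    is.na(effects$F) | (effects$SS + err_ss) == 0, NA,
    effects$SS / (effects$SS + err_ss))

  eps <- sph$gg_epsilon
  effects$df1_gg <- effects$df
  effects$df2_gg <- err_df
  effects$p_gg <- effects$p
  if (is.finite(eps)) {
    for (i in c(3L, 4L)) {  # within-subject effects only
      effects$df1_gg[i] <- effects$df[i] * eps
      effects$df2_gg[i] <- err_df[i] * eps
      if (!is.na(effects$F[i]))
        effects$p_gg[i] <- stats::pf(effects$F[i], effects$df1_gg[i],
                                     effects$df2_gg[i], lower.tail = FALSE)
    }
  }
  effects$p_reported <- if (correct_df) effects$p_gg else effects$p
  rownames(effects) <- NULL

  structure(list(table = effects, sphericity = sph,
                 ss_total = ss_total, n_subjects = N, n_groups = g,
                 n_within = k, dv = dv),
            class = "mixed_anova")
}

# Pooled within-group covariance of the k repeated measures, then projected
# onto an orthonormal contrast basis. Shared by Mauchly and GG epsilon.
contrast_covariance <- function(wide, groups = NULL) {
  stopifnot(is.matrix(wide), ncol(wide) >= 2)
  if (anyNA(wide)) stop_domain("missing cells in the response matrix")
  k <- ncol(wide)
  if (is.null(groups)) groups <- factor(rep("all", nrow(wide)))
  groups <- factor(groups)
  g <- nlevels(groups)
  n_err <- nrow(wide) - g
  if (n_err < k - 1)
    stop_domain("need more than k-1 error degrees of freedom (n - groups)")
  centred <- wide
  for (lev in levels(groups)) {
    sel <- groups == lev
    centred[sel, ] <- sweep(wide[sel, , drop = FALSE], 2,
                            colMeans(wide[sel, , drop = FALSE]))
  }
  S <- crossprod(centred) / n_err
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")  # orthonormal contrasts
  list(S_c = t(C) %*% S %*% C, n_err = n_err, k = k)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of the orthonormal within-subject contrasts
#' is proportional to the identity:
#' \eqn{W = \det(S_c) / (\mathrm{tr}(S_c)/(k-1))^{k-1}}, with the usual
#' chi-square approximation
#' \eqn{\chi^2 = -(n' - (2p^2+p+2)/(6p)) \log W} on
#' \eqn{p(p+1)/2 - 1} df, where \eqn{p = k-1} and \eqn{n'} is the error df
#' of the pooled covariance. With `k = 2` there is a single contrast and
#' sphericity holds trivially (`W = 1, p = 1`).
#'
#' @param wide `n x k` response matrix, one row per subject, one column per
#'   within-subject level.
#' @param groups optional between-group factor (length `n`); the covariance
#'   is pooled within groups.
#' @return list with `W`, `chi_sq`, `df`, `p`.
#' @export
mauchly_test <- function(wide, groups = NULL) {
  cc <- contrast_covariance(wide, groups)
  p <- cc$k - 1
  if (p == 1)
    return(list(W = 1, chi_sq = 0, df = 0, p = 1))
  detS <- det(cc$S_c)
  trS <- sum(diag(cc$S_c))
  if (trS <= 0 || detS < 0)
    stop_domain("degenerate contrast covariance")
  W <- detS / (trS / p)^p
  if (W <= 0) stop_domain("singular contrast covariance")
  mult <- cc$n_err - (2 * p^2 + p + 2) / (6 * p)
  chi_sq <- -mult * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, chi_sq = chi_sq, df = df,
       p = stats::pchisq(chi_sq, df, lower.tail = FALSE))
}

#' Greenhouse-Geisser epsilon
#'
#' Box's correction factor computed from the orthonormal-contrast
#' covariance \eqn{S_c}:
#' \eqn{\hat\epsilon = \mathrm{tr}(S_c)^2 / ((k-1)\,\mathrm{tr}(S_c^2))},
#' bounded in `[1/(k-1), 1]`. Corrected within-subject dfs are the
#' uncorrected dfs multiplied by \eqn{\hat\epsilon}.
#'
#' @inheritParams mauchly_test
#' @return epsilon estimate.
#' @export
gg_epsilon <- function(wide, groups = NULL) {
  cc <- contrast_covariance(wide, groups)
  trS <- sum(diag(cc$S_c))
  if (trS <= 0) stop_domain("degenerate contrast covariance")
  trS^2 / ((cc$k - 1) * sum(cc$S_c^2))
}

#' Partial eta squared from an F statistic
#'
#' The algebraic identity
#' \eqn{\eta^2_p = F\,df_1 / (F\,df_1 + df_2)}, which recovers the effect
#' size from a printed F and its degrees of freedom (corrected dfs work
#' unchanged since both df carry the same epsilon factor... the identity is
#' exact for whatever df pair accompanied the F).
#'
#' @param f F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom (possibly
#'   fractional after a sphericity correction).
#' @return partial eta squared in `[0, 1]`; vectorised.
#' @examples
#' partial_eta_sq_from_f(6.20, 1, 22)        # ~0.22
#' partial_eta_sq_from_f(111.11, 1.73, 38.21) # ~0.83
#' @export
partial_eta_sq_from_f <- function(f, df1, df2) {
  if (any(f < 0, na.rm = TRUE) || any(df1 <= 0) || any(df2 <= 0))
    stop_domain("need f >= 0 and positive dfs")
  f * df1 / (f * df1 + df2)
}

#' Paired comparisons between sessions within each group
#'
#' Paired t-tests for the requested session pairs, run separately within
#' each group. The reported `mean_diff` follows the first-minus-second
#' convention: `mean(session_a) - mean(session_b)`, so a drop from `pre` to
#' `mid` appears as a positive difference for `pair = c("pre", "mid")`.
#' Unadjusted and Bonferroni-adjusted p-values (across the pairs within a
#' group) are both reported.
#'
#' @param data long-format data frame (see [mixed_anova()]).
#' @param dv,id,within,between column names.
#' @param pairs list of length-2 character vectors of session labels;
#'   default: baseline against each later session.
#' @return data frame with one row per group x pair: `group`, `session_a`,
#'   `session_b`, `n`, `mean_diff`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
pairwise_within <- function(data, dv = "value", id = "participant_id",
                            within = "session", between = "group",
                            pairs = NULL) {
  stopifnot(is.data.frame(data),
            all(c(dv, id, within, between) %in% names(data)))
  sess_levels <- levels(factor(data[[within]]))
  if (is.null(pairs))
    pairs <- lapply(sess_levels[-1], function(s) c(sess_levels[1], s))
  rows <- list()
  for (grp in levels(factor(data[[between]]))) {
    gdat <- data[data[[between]] == grp, ]
    for (pr in pairs) {
      a <- gdat[gdat[[within]] == pr[1], ]
      b <- gdat[gdat[[within]] == pr[2], ]
      ids <- intersect(a[[id]], b[[id]])
      if (length(ids) < 2)
        stop_domain("need >= 2 paired observations for ", pr[1], " vs ",
                    pr[2], " in group ", grp)
      xa <- a[[dv]][match(ids, a[[id]])]
      xb <- b[[dv]][match(ids, b[[id]])]
      d <- xa - xb
      if (stats::sd(d) == 0) {
        t_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
        p <- if (mean(d) == 0) 1 else 0
      } else {
        tt <- stats::t.test(xa, xb, paired = TRUE)
        t_stat <- unname(tt$statistic)
        p <- tt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = grp, session_a = pr[1], session_b = pr[2],
        n = length(ids), mean_diff = mean(d), t = t_stat,
        df = length(ids) - 1, p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- NA_real_
  for (grp in unique(out$group)) {
    sel <- out$group == grp
    out$p_bonferroni[sel] <- stats::p.adjust(out$p[sel], "bonferroni")
  }
  rownames(out) <- NULL
  out
}

#' Independent-samples t-test (pooled variance)
#'
#' Student's two-sample t with pooled variance, so that two groups of 13
#' and 11 children give `df = 22`. If the pooled variance is zero with
#' unequal means the degenerate `t = +/-Inf, p = 0` edge is reported
#' explicitly.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list of class `magnosim_test`: `statistic`, `df`, `p`,
#'   `estimate` (mean(x) - mean(y)), `method`.
#' @export
independent_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_domain("each group needs n >= 2")
  est <- mean(x) - mean(y)
  df <- length(x) + length(y) - 2
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stat <- if (est == 0) 0 else Inf * sign(est)
    p <- if (est == 0) 1 else 0
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(statistic = stat, df = df, p = p, estimate = est,
                 method = "independent_t"),
            class = "magnosim_test")
}

#' Mann-Whitney U test
#'
#' Wilcoxon rank-sum reported on the U scale
#' (`U = rank-sum of x - nx(nx+1)/2`). For small samples
#' (`nx * ny <= 400`) without ties the p-value is exact (full enumeration
#' of the rank distribution); otherwise the normal approximation with
#' continuity and tie correction is used.
#'
#' @param x,y numeric vectors, non-empty.
#' @return list of class `magnosim_test`: `statistic` (U), `p`,
#'   `estimate` (median(x) - median(y)), `exact` flag, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop_domain("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 estimate = stats::median(x) - stats::median(y),
                 exact = use_exact, method = "mann_whitney_u"),
            class = "magnosim_test")
}

#' @export
print.magnosim_test <- function(x, ...) {
  if (x$method == "independent_t")
    cat(sprintf("t(%d) = %.3f, p = %.4g, mean difference = %.3f\n",
                x$df, x$statistic, x$p, x$estimate))
  else
    cat(sprintf("U = %.1f, p = %.4g (%s)\n", x$statistic, x$p,
                if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' @export
print.mixed_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA on '%s' (%d subjects, %d x %d design)\n",
              x$dv, x$n_subjects, x$n_groups, x$n_within))
  sph <- x$sphericity
  cat(sprintf("Mauchly W = %.3f, p = %.4g; GG epsilon = %.3f (%s)\n",
              sph$mauchly_W, sph$mauchly_p, sph$gg_epsilon,
              if (isTRUE(sph$corrected)) "correction applied"
              else "no correction applied"))
  tab <- x$table
  for (i in which(!is.na(tab$F))) {
    use_gg <- isTRUE(sph$corrected)
    cat(sprintf("  %s: F[%.2f, %.2f] = %.2f, p = %.4g, eta2p = %.2f\n",
                tab$effect[i],
                if (use_gg) tab$df1_gg[i] else tab$df[i],
                if (use_gg) tab$df2_gg[i] else tab$df2[i],
                tab$F[i], tab$p_reported[i], tab$partial_eta_sq[i]))
  }
  invisible(x)
}
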