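test_that("mixed ANOVA matches brute-force projection arithmetic on a toy set", {
  d <- toy_split_plot()
  fit <- mixed_anova(d)
  oracle <- brute_force_split_plot(d)
  expect_equal(fit$table$F[1], oracle$F_group, tolerance = 1e-12)
  expect_equal(fit$table$F[3], oracle$F_session, tolerance = 1e-12)
  expect_equal(fit$table$F[4], oracle$F_inter, tolerance = 1e-12)
  expect_equal(fit$table$SS, oracle$ss, tolerance = 1e-12)
})

test_that("mixed ANOVA agrees with stats::aov on realistic cohorts", {
  cohort <- generate_cohort(cohort_config(), seed = 5)
  for (nm in c("rdk_threshold", "comprehension", "visual_errors")) {
    d <- cohort[cohort$measure == nm, ]
    fit <- mixed_anova(d)
    d$participant_id <- factor(d$participant_id)
    av <- summary(stats::aov(
      value ~ group * session + Error(participant_id / session), data = d))
    between <- av[["Error: participant_id"]][[1]]
    within <- av[["Error: participant_id:session"]][[1]]
    expect_equal(fit$table$F[1], between["group", "F value"],
                 tolerance = 1e-8)
    expect_equal(fit$table$F[3], within["session", "F value"],
                 tolerance = 1e-8)
    expect_equal(fit$table$F[4], within["group:session", "F value"],
                 tolerance = 1e-8)
    expect_equal(fit$table$SS[5], within["Residuals", "Sum Sq"],
                 tolerance = 1e-8)
  }
})

test_that("sums of squares always add up to the total", {
  set.seed(41)
  for (i in 1:20) {
    n_e <- sample(3:8, 1); n_c <- sample(3:8, 1); k <- sample(2:5, 1)
    d <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_e + n_c)),
                     session = paste0("s", seq_len(k)))
    d$group <- ifelse(as.integer(factor(d$participant_id)) <= n_e,
                      "experimental", "control")
    d$value <- rnorm(nrow(d), sd = sample(c(0.5, 2, 10), 1))
    fit <- mixed_anova(d)
    expect_equal(sum(fit$table$SS), fit$ss_total, tolerance = 1e-10)
  }
})

test_that("partial eta squared obeys its F/df identity on every row", {
  cohort <- generate_cohort(cohort_config(), seed = 6)
  d <- cohort[cohort$measure == "saccade_cycles", ]
  fit <- mixed_anova(d)
  tab <- fit$table
  for (i in which(!is.na(tab$F)))
    expect_equal(tab$partial_eta_sq[i],
                 tab$F[i] * tab$df[i] / (tab$F[i] * tab$df[i] + tab$df2[i]),
                 tolerance = 1e-12)
})

test_that("a constant response yields zero SS and undefined F", {
  d <- toy_split_plot()
  d$value <- 7
  fit <- mixed_anova(d)
  expect_equal(fit$table$SS, rep(0, 5), tolerance = 1e-20)
  expect_true(all(is.na(fit$table$F[c(1, 3, 4)])))
  expect_true(all(is.na(fit$table$partial_eta_sq[c(1, 3, 4)])))
})

test_that("incomplete designs are refused, not imputed", {
  d <- toy_split_plot()
  expect_error(mixed_anova(d[-1, ]), "unbalanced")
  d2 <- toy_split_plot()
  d2$value[2] <- NA
  expect_error(mixed_anova(d2), "missing")
})

test_that("with two sessions the split-plot F reduces to squared t statistics", {
  set.seed(42)
  for (i in 1:5) {
    d <- toy_split_plot()
    d$value <- rnorm(12)
    fit <- mixed_anova(d)
    wide <- reshape(d, idvar = c("participant_id", "group"),
                    timevar = "session", direction = "wide")
    diffs <- wide$value.s1 - wide$value.s2
    g <- wide$group
    # session F = squared t on the difference scores, with the group means
    # partialed out of the variance (the split-plot's error term)
    d_centred <- diffs - ave(diffs, g)
    s2_pooled <- sum(d_centred^2) / (length(diffs) - 2)
    t_session <- mean(diffs) * sqrt(length(diffs)) / sqrt(s2_pooled)
    expect_equal(fit$table$F[3], t_session^2, tolerance = 1e-8)
    # interaction F = squared pooled independent t between the groups'
    # difference scores
    t_inter <- independent_t(diffs[g == "g1"], diffs[g == "g2"])$statistic
    expect_equal(fit$table$F[4], t_inter^2, tolerance = 1e-8)
  }
})

test_that("Mauchly's W is 1 for two sessions and below 1 otherwise", {
  m2 <- mauchly_test(matrix(rnorm(40), 20, 2))
  expect_equal(m2$W, 1)
  expect_equal(m2$p, 1)
  # one contrast carrying most variance drives W down
  set.seed(43)
  b <- rnorm(40, sd = 4)
  wide <- cbind(b, -b, rnorm(40, sd = 0.3), rnorm(40, sd = 0.3))
  m4 <- mauchly_test(wide)
  expect_lt(m4$W, 1)
  expect_lt(m4$p, 0.01)
})

test_that("Mauchly's test holds its size under compound symmetry", {
  set.seed(44)
  n <- 200
  rejections <- replicate(200, {
    subj_eff <- rnorm(n, sd = 1)      # shared across sessions: spherical
    wide <- sapply(1:3, function(s) subj_eff + rnorm(n))
    mauchly_test(wide)$p < 0.05
  })
  # 200 replicates: 2.3 binomial sds around the nominal 5%
  expect_lt(abs(mean(rejections) - 0.05), 0.035)
})

test_that("GG epsilon spans its theoretical bounds", {
  # exactly spherical contrast covariance: epsilon = 1
  # construct data whose sample covariance is the identity
  set.seed(45)
  x <- matrix(rnorm(80 * 4), 80, 4)
  x_sph <- x %*% solve(chol(cov(x)))  # whitened: sample covariance = identity
  expect_equal(gg_epsilon(x_sph), 1, tolerance = 1e-8)
  # one dominant contrast: epsilon near the 1/(k-1) floor (1/3 for k = 4)
  b <- rnorm(60, sd = 5)
  wide <- cbind(b, -b, rnorm(60, sd = 1e-3), rnorm(60, sd = 1e-3))
  expect_equal(gg_epsilon(wide), 1 / 3, tolerance = 0.01)
  # never outside [1/(k-1), 1]
  for (i in 1:10) {
    w <- matrix(rnorm(15 * 4), 15, 4) %*% matrix(rnorm(16), 4, 4)
    e <- gg_epsilon(w)
    expect_gte(e, 1 / 3 - 1e-12)
    expect_lte(e, 1 + 1e-12)
  }
})

test_that("GG epsilon matches Box's raw-covariance formula", {
  # independent implementation straight from the raw k x k covariance
  box_eps <- function(S) {
    k <- ncol(S)
    sbar <- mean(S)
    dbar <- mean(diag(S))
    row_means <- rowMeans(S)
    num <- k^2 * (dbar - sbar)^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
    num / den
  }
  set.seed(46)
  wide <- matrix(rnorm(30 * 4), 30, 4) %*% matrix(rnorm(16), 4, 4)
  wide_c <- scale(wide, center = TRUE, scale = FALSE)
  S <- crossprod(wide_c) / (nrow(wide) - 1)
  expect_equal(gg_epsilon(wide), box_eps(S), tolerance = 1e-10)
})

test_that("corrected dfs scale by epsilon and drive the reported p", {
  # build a cohort with a strongly non-spherical within-subject covariance
  set.seed(47)
  n <- 24
  drift <- rnorm(n, sd = 6)
  wide <- cbind(rnorm(n), rnorm(n) + drift, rnorm(n) + 2 * drift,
                rnorm(n) + 3 * drift)
  d <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:n), each = 4),
    group = rep(rep(c("experimental", "control"), c(13, 11)), each = 4),
    session = rep(paste0("s", 1:4), n),
    value = as.vector(t(wide)))
  fit <- mixed_anova(d)
  eps <- fit$sphericity$gg_epsilon
  expect_lt(fit$sphericity$mauchly_p, 0.05)
  expect_true(fit$sphericity$corrected)
  expect_equal(fit$table$df1_gg[3], 3 * eps)
  expect_equal(fit$table$df2_gg[3], 3 * 22 * eps)
  expect_equal(fit$table$p_reported[3], fit$table$p_gg[3])
  expect_equal(fit$table$p_gg[3],
               pf(fit$table$F[3], 3 * eps, 66 * eps, lower.tail = FALSE))
})

test_that("paired session comparisons recover forced shifts and closed forms", {
  d <- toy_split_plot()
  # identical sessions: zero difference, p = 1
  d0 <- d; d0$value <- rep(c(4, 4), 6)
  pw0 <- pairwise_within(d0)
  expect_equal(pw0$mean_diff, rep(0, 2))
  expect_equal(pw0$p, rep(1, 2))
  # adding +5 to session 2 with no noise: difference exactly -5
  d5 <- d0; d5$value[d5$session == "s2"] <- d5$value[d5$session == "s2"] + 5
  pw5 <- pairwise_within(d5)
  expect_equal(pw5$mean_diff, rep(-5, 2))
  expect_equal(pw5$p, rep(0, 2))
  # random paired data: t equals mean(d) / (sd(d)/sqrt(n))
  set.seed(48)
  d$value <- rnorm(12)
  pw <- pairwise_within(d)
  for (g in c("g1", "g2")) {
    a <- d$value[d$group == g & d$session == "s1"]
    b <- d$value[d$group == g & d$session == "s2"]
    dd <- a - b
    t_oracle <- mean(dd) / (sd(dd) / sqrt(length(dd)))
    expect_equal(pw$t[pw$group == g], t_oracle, tolerance = 1e-12)
    expect_equal(pw$mean_diff[pw$group == g], mean(dd))
  }
  expect_true(all(pw$p_bonferroni >= pw$p))
})

test_that("the independent t is pooled-variance with additive dfs", {
  x <- rnorm(13, mean = 1); y <- rnorm(11)
  tt <- independent_t(x, y)
  expect_equal(tt$df, 22)   # 13 + 11 - 2, the design's df
  # closed-form pooled t recomputed independently
  sp2 <- ((13 - 1) * var(x) + (11 - 1) * var(y)) / 22
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 13 + 1 / 11))
  expect_equal(tt$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-abs(t_oracle), 22), tolerance = 1e-12)
  # identical groups
  same <- independent_t(c(2, 2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # degenerate zero-variance, unequal means: explicit p = 0 edge
  degen <- independent_t(c(3, 3), c(1, 1))
  expect_equal(degen$p, 0)
  expect_true(is.infinite(degen$statistic))
  expect_error(independent_t(1, c(1, 2)), "n >= 2")
})

test_that("Mann-Whitney U matches enumeration over all rank assignments", {
  # maximal separation and full tie
  expect_equal(mann_whitney_u(c(10, 11, 12), c(1, 2))$statistic, 6)  # nA*nB
  expect_equal(mann_whitney_u(5, 5)$statistic, 0.5)                  # nA*nB/2
  # exact p by brute-force enumeration (no ties, small n)
  set.seed(49)
  for (i in 1:5) {
    x <- sample(seq(1, 100, by = 3), 4)
    y <- sample(seq(2, 101, by = 3), 3)
    res <- mann_whitney_u(x, y)
    expect_true(res$exact)
    ranks <- rank(c(x, y))
    u_obs <- sum(ranks[1:4]) - 4 * 5 / 2
    combos <- combn(7, 4)
    u_all <- apply(combos, 2, function(idx) sum(rank(c(x, y))[idx]) - 10)
    # two-sided doubling rule on the exact U distribution
    p_lo <- mean(u_all <= u_obs); p_hi <- mean(u_all >= u_obs)
    p_oracle <- min(1, 2 * min(p_lo, p_hi))
    expect_equal(res$statistic, u_obs)
    expect_equal(res$p, p_oracle, tolerance = 1e-12)
  }
  # ties force the corrected normal approximation
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 4))
  expect_false(tied$exact)
})
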