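# long-format helper: one row per subject x within level
long_table <- function(values, groups) {
  k <- ncol(values)
  n <- nrow(values)
  data.frame(
    subject = rep(sprintf("s%02d", 1:n), each = k),
    group = rep(groups, each = k),
    cond = rep(paste0("w", 1:k), n),
    dv = as.vector(t(values))
  )
}

test_that("mixed ANOVA reproduces a hand-computed toy table", {
  # 2 groups x 2 conditions x 3 subjects; all sums of squares done by hand:
  # GM = 12; SS_group = 27; SS_subj(group) = 10; SS_cond = 48;
  # SS_inter = 3; SS_error_within = 4
  # F_group = 27 / (10/4) = 10.8; F_cond = 48 / 1 = 48; F_inter = 3
  vals <- rbind(c(10, 14), c(12, 16), c(11, 18),
                c(9, 11), c(8, 12), c(10, 13))
  d <- long_table(vals, rep(c("g1", "g2"), each = 3))
  res <- mixed_anova(d, dv = "dv", within = "cond", subject = "subject",
                     between = "group")
  expect_equal(res$ss, c(27, 48, 3), tolerance = 1e-12)
  expect_equal(res$f, c(10.8, 48, 3), tolerance = 1e-12)
  expect_equal(res$df1, c(1, 1, 1))
  expect_equal(res$df2, c(4, 4, 4))
  expect_equal(res$eta_p_sq, c(27 / 37, 48 / 52, 3 / 7), tolerance = 1e-12)
})

test_that("mixed ANOVA agrees with the aov() error-strata oracle", {
  set.seed(77)
  for (rep in 1:3) {
    n <- c(8, 6)[1 + rep %% 2]
    vals <- matrix(stats::rnorm(2 * n * 3), 2 * n, 3) +
      outer(rep(c(0, 0.5), each = n), c(0, 0.3, 0.6), `+`)
    d <- long_table(vals, rep(c("a", "b"), each = n))
    res <- mixed_anova(d, dv = "dv", within = "cond", subject = "subject",
                       between = "group")
    ref <- summary(stats::aov(dv ~ group * cond + Error(subject),
                              data = d))
    btw <- ref[["Error: subject"]][[1]]
    wth <- ref[["Error: Within"]][[1]]
    expect_equal(res$f, c(btw["group", "F value"],
                          wth["cond", "F value"],
                          wth["group:cond", "F value"]),
                 tolerance = 1e-10)
    expect_equal(res$p, c(btw["group", "Pr(>F)"],
                          wth["cond", "Pr(>F)"],
                          wth["group:cond", "Pr(>F)"]),
                 tolerance = 1e-10)
  }
})

test_that("sums of squares decompose additively", {
  set.seed(12)
  vals <- matrix(stats::rnorm(30), 10, 3)
  d <- long_table(vals, rep(c("a", "b"), each = 5))
  res <- mixed_anova(d, dv = "dv", within = "cond", subject = "subject",
                     between = "group")
  ss_total <- sum((d$dv - mean(d$dv))^2)
  m_i <- tapply(d$dv, d$subject, mean)
  gm <- mean(d$dv)
  grp <- tapply(as.character(d$group), d$subject, `[`, 1)
  m_g <- tapply(m_i, grp, mean)
  ss_subj_err <- 3 * sum((m_i - m_g[grp])^2)
  ss_err_within <- ss_total - 3 * sum((m_i - gm)^2) - res$ss[2] - res$ss[3]
  expect_equal(sum(res$ss) + ss_subj_err + ss_err_within, ss_total,
               tolerance = 1e-9)
})

test_that("paired t-squared equals the within F for two levels", {
  set.seed(9)
  vals <- matrix(stats::rnorm(24), 12, 2) + outer(rep(0, 12), c(0, 0.4), `+`)
  d <- long_table(vals, rep("only", 12))
  res <- mixed_anova(d, dv = "dv", within = "cond", subject = "subject")
  tt <- paired_t(vals[, 1], vals[, 2])
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("constant response gives all-zero F", {
  vals <- matrix(5, 6, 3)
  d <- long_table(vals, rep(c("a", "b"), each = 3))
  res <- mixed_anova(d, dv = "dv", within = "cond", subject = "subject",
                     between = "group")
  expect_true(all(res$f == 0))
  expect_true(all(res$p == 1))
})

test_that("mixed ANOVA validates its input", {
  vals <- matrix(stats::rnorm(12), 6, 2)
  d <- long_table(vals, rep(c("a", "b"), each = 3))
  expect_error(mixed_anova(d[-1, ], dv = "dv", within = "cond",
                           subject = "subject", between = "group"),
               "exactly one observation")
  d1 <- long_table(matrix(stats::rnorm(4), 2, 2), c("a", "b"))
  expect_error(mixed_anova(d1, dv = "dv", within = "cond",
                           subject = "subject", between = "group"),
               "at least 2 subjects")
})

test_that("Mauchly test matches an independent reference implementation", {
  # reference values computed with pingouin.sphericity on this table
  Y <- matrix(c(0.52, 0.31, 0.44,
                0.40, 0.25, 0.60,
                0.61, 0.28, 0.50,
                0.45, 0.48, 0.41,
                0.55, 0.30, 0.58,
                0.38, 0.42, 0.35,
                0.50, 0.27, 0.47,
                0.47, 0.35, 0.52), ncol = 3, byrow = TRUE)
  m <- volatilearn:::mauchly_sphericity(Y)
  expect_equal(m$W, 0.767872708902448, tolerance = 1e-10)
  expect_equal(m$chisq, 1.5847878191283613, tolerance = 1e-10)
  expect_equal(m$df, 2)
  expect_equal(m$p, 0.45275963129673613, tolerance = 1e-10)
  # two within levels: sphericity trivially holds
  m2 <- volatilearn:::mauchly_sphericity(Y[, 1:2])
  expect_equal(m2$p, 1)
})

test_that("repeated contrasts reduce to paired t-tests for one group", {
  set.seed(21)
  Y <- matrix(stats::rnorm(36), 12, 3) +
    outer(rep(0, 12), c(0, 0.1, 0.8), `+`)
  rc <- volatilearn:::repeated_contrasts(Y)
  t1 <- paired_t(Y[, 2], Y[, 1])
  t2 <- paired_t(Y[, 3], Y[, 2])
  expect_equal(rc$f, c(unname(t1$statistic)^2, unname(t2$statistic)^2),
               tolerance = 1e-10)
  expect_equal(rc$p, c(t1$p.value, t2$p.value), tolerance = 1e-10)
})

test_that("Welch correction engages automatically on unequal variances", {
  set.seed(4)
  x <- stats::rnorm(20, sd = 1)
  y <- stats::rnorm(25, sd = 4)
  auto <- two_sample_t(x, y)
  expect_equal(auto$parameter, stats::t.test(x, y)$parameter) # fractional df
  z <- stats::rnorm(25, sd = 1.05)
  pooled <- two_sample_t(x, z)
  expect_equal(unname(pooled$parameter), 43) # integer pooled df
})

test_that("planted and null simulations hit nominal rates", {
  # direct Gaussian simulation of per-subject condition tables
  set.seed(2024)
  n_sim <- 300
  p_group_null <- numeric(n_sim)
  p_cond_planted <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    n <- 10
    subj_eff <- stats::rnorm(2 * n, 0, 0.5)
    vals <- cbind(subj_eff + stats::rnorm(2 * n, 0, 0.3),
                  subj_eff + 0.4 + stats::rnorm(2 * n, 0, 0.3))
    d <- long_table(vals, rep(c("a", "b"), each = n))
    res <- mixed_anova(d, dv = "dv", within = "cond", subject = "subject",
                       between = "group")
    p_group_null[i] <- res$p[1]
    p_cond_planted[i] <- res$p[2]
  }
  # null group effect: type-I rate within the 95% binomial band around .05
  rate <- mean(p_group_null < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / n_sim)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
  # planted condition effect (d ~ 1.3 on the diff scale): high power
  expect_gt(mean(p_cond_planted < 0.05), 0.95)
})

test_that("analysis report assembles the full pipeline summary", {
  set.seed(8)
  n <- 6
  rates <- data.frame(
    subject = rep(sprintf("s%02d", 1:(2 * n)), each = 2),
    group = rep(c("g1", "g2"), each = 2 * n),
    condition = rep(c("stable", "volatile"), 2 * n),
    log_alpha = stats::rnorm(4 * n, rep(c(-2, -1.3), 2 * n), 0.3)
  )
  rep <- analysis_report(rates)
  expect_s3_class(rep$learning_rate_anova, "data.frame")
  expect_named(rep$group_delta_ci, "g1_vs_g2")
  expect_length(rep$group_delta_ci$g1_vs_g2$ci, 2)
  expect_lt(rep$learning_rate_anova$p[2], 0.01) # condition effect planted
})
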