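#' Mixed-design ANOVA
#'
#' Classical univariate mixed ANOVA with one within-subject factor and
#' optionally one between-subject factor, computed from the textbook
#' sums-of-squares decomposition: between-subject variation splits into
#' the group effect and subject-within-group error; within-subject
#' variation splits into the within factor, its interaction with group,
#' and the within error. Partial eta-squared is reported per effect. With
#' unequal group sizes the weighted-means (Type I) decomposition is used;
#' for the balanced designs produced by this package it coincides with the
#' Type III decomposition reported by standard software.
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param within name of the within-subject factor column.
#' @param between name of the between-subject factor column, or NULL for a
#'   purely repeated-measures one-way ANOVA.
#' @param subject name of the subject-identifier column.
#' @return data frame with one row per effect: \code{effect}, \code{ss},
#'   \code{df1}, \code{df2}, \code{f}, \code{p}, \code{eta_p_sq}.
#' @export
mixed_anova <- function(data, dv, within, subject, between = NULL) {
  y <- data[[dv]]
  w <- factor(data[[within]])
  s <- factor(data[[subject]])
  k <- nlevels(w)
  if (k < 2) stop("within factor needs at least 2 levels", call. = FALSE)
  tab <- table(s, w)
  if (any(tab != 1)) {
    stop("each subject must contribute exactly one observation per within level",
         call. = FALSE)
  }
  n_subj <- nlevels(s)
  gm <- mean(y)
  m_i <- tapply(y, s, mean)
  m_j <- tapply(y, w, mean)
  ss_total <- sum((y - gm)^2)
  ss_between_subj <- k * sum((m_i - gm)^2)
  ss_within_subj <- ss_total - ss_between_subj
  ss_within <- n_subj * sum((m_j - gm)^2)

  if (!is.null(between)) {
    g <- factor(data[[between]])
    subj_group <- tapply(as.character(g), s, function(x) x[1])
    ng <- table(factor(subj_group, levels = levels(g)))
    if (any(ng < 2)) stop("need at least 2 subjects per group", call. = FALSE)
    m_g <- tapply(m_i, factor(subj_group, levels = levels(g)), mean)
    ss_group <- k * sum(as.numeric(ng) * (m_g - gm)^2)
    ss_subj_err <- ss_between_subj - ss_group
    m_gj <- tapply(y, list(g, w), mean)
    dev_gj <- sweep(sweep(m_gj, 1, m_g), 2, m_j) + gm
    ss_inter <- sum(as.numeric(ng) * dev_gj^2)
    ss_err_within <- ss_within_subj - ss_within - ss_inter
    glev <- nlevels(g)
    df <- list(group = c(glev - 1, n_subj - glev),
               within = c(k - 1, (n_subj - glev) * (k - 1)),
               inter = c((glev - 1) * (k - 1), (n_subj - glev) * (k - 1)))
    ms_subj_err <- ss_subj_err / df$group[2]
    ms_err_within <- ss_err_within / df$within[2]
    eff <- data.frame(
      effect = c(between, within, paste(between, within, sep = ":")),
      ss = c(ss_group, ss_within, ss_inter),
      df1 = c(df$group[1], df$within[1], df$inter[1]),
      df2 = c(df$group[2], df$within[2], df$inter[2]),
      stringsAsFactors = FALSE
    )
    err_ss <- c(ss_subj_err, ss_err_within, ss_err_within)
    ms_err <- c(ms_subj_err, ms_err_within, ms_err_within)
    eff$f <- (eff$ss / eff$df1) / ms_err
    eff$p <- stats::pf(eff$f, eff$df1, eff$df2, lower.tail = FALSE)
    eff$eta_p_sq <- eff$ss / (eff$ss + err_ss)
  } else {
    ss_err_within <- ss_within_subj - ss_within
    df1 <- k - 1
    df2 <- (n_subj - 1) * (k - 1)
    f <- (ss_within / df1) / (ss_err_within / df2)
    eff <- data.frame(
      effect = within, ss = ss_within, df1 = df1, df2 = df2, f = f,
      p = stats::pf(f, df1, df2, lower.tail = FALSE),
      eta_p_sq = ss_within / (ss_within + ss_err_within),
      stringsAsFactors = FALSE
    )
  }
  # degenerate inputs (constant dv) produce 0/0; report F = 0, p = 1
  zero <- !is.finite(eff$f)
  eff$f[zero] <- 0
  eff$p[zero] <- 1
  eff$eta_p_sq[!is.finite(eff$eta_p_sq)] <- 0
  eff
}

# Mauchly's test of sphericity on a wide matrix of repeated measures
# (rows = subjects, cols = within levels), pooling covariance within
# groups. Returns W, the chi-squared approximation and its df.
mauchly_sphericity <- function(Y, group = NULL) {
  k <- ncol(Y)
  n <- nrow(Y)
  if (k < 3) {
    return(list(W = 1, chisq = 0, df = 0, p = 1))
  }
  if (is.null(group)) group <- rep(1, n)
  group <- factor(group)
  E <- Y
  for (g in levels(group)) {
    idx <- group == g
    E[idx, ] <- sweep(Y[idx, , drop = FALSE], 2,
                      colMeans(Y[idx, , drop = FALSE]))
  }
  df_err <- n - nlevels(group)
  S <- crossprod(E) / df_err
  C <- contrast_orthonormal(k)
  T <- C %*% S %*% t(C)
  d <- k - 1
  W <- det(T) / (sum(diag(T)) / d)^d
  f_corr <- 1 - (2 * d^2 + d + 2) / (6 * d * df_err)
  chisq <- -df_err * f_corr * log(W)
  df <- d * (d + 1) / 2 - 1
  list(W = W, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

# orthonormal contrast basis spanning the within-subject space
contrast_orthonormal <- function(k) {
  C <- stats::contr.helmert(k)
  C <- t(C) / sqrt(colSums(C^2))
  C
}

# SPSS-style repeated contrasts (level 1 vs 2, 2 vs 3, ...) on a wide
# repeated-measures matrix, testing each successive difference against its
# within-group error, with group differences removed (unweighted means).
repeated_contrasts <- function(Y, group = NULL) {
  k <- ncol(Y)
  n <- nrow(Y)
  if (is.null(group)) group <- rep(1, n)
  group <- factor(group)
  glev <- nlevels(group)
  rows <- list()
  for (j in seq_len(k - 1)) {
    d <- Y[, j + 1] - Y[, j]
    m_g <- tapply(d, group, mean)
    n_g <- table(group)
    resid <- d - m_g[group]
    df2 <- n - glev
    mse <- sum(resid^2) / df2
    est <- mean(m_g) # unweighted mean over groups
    se2 <- mse * sum(1 / n_g) / glev^2
    f <- est^2 / se2
    ss_eff <- est^2 / (sum(1 / n_g) / glev^2)
    rows[[j]] <- data.frame(
      contrast = sprintf("level%d_vs_level%d", j, j + 1),
      estimate = est, f = f, df1 = 1, df2 = df2,
      p = stats::pf(f, 1, df2, lower.tail = FALSE),
      eta_p_sq = ss_eff / (ss_eff + sum(resid^2)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample t-test with automatic Welch correction
#'
#' Uses the pooled-variance test when the sample variances are similar and
#' switches to the Welch (unequal-variance) test when the variance ratio
#' exceeds a threshold, mirroring common applied practice of reporting
#' fractional degrees of freedom only when needed.
#'
#' @param x,y numeric samples.
#' @param var_equal force pooled (TRUE) or Welch (FALSE); NULL = automatic.
#' @param var_ratio_threshold variance ratio above which Welch is used.
#' @return \code{htest} object from \code{\link[stats]{t.test}}.
#' @export
two_sample_t <- function(x, y, var_equal = NULL, var_ratio_threshold = 2) {
  if (is.null(var_equal)) {
    vr <- max(stats::var(x), stats::var(y)) /
      min(stats::var(x), stats::var(y))
    var_equal <- vr <= var_ratio_threshold
  }
  stats::t.test(x, y, var.equal = var_equal)
}

#' Paired t-test with mean-difference confidence interval
#'
#' @param x,y paired numeric samples.
#' @param conf_level confidence level.
#' @return \code{htest} object.
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors.
#' @return \code{htest} object from \code{\link[stats]{cor.test}}.
#' @export
pearson_cor <- function(x, y) {
  stats::cor.test(x, y, method = "pearson")
}

#' Full group-level analysis report
#'
#' Runs the standard pipeline outputs -- the condition-by-group mixed
#' ANOVA on log learning rates, the volatile-minus-stable contrast CI per
#' group pair, and the interval-by-group reversal-slope ANOVA -- and
#' assembles them into one JSON-serializable list.
#'
#' @param rates data frame with columns \code{subject}, \code{group},
#'   \code{condition}, \code{log_alpha}.
#' @param slopes long slope table as from \code{\link{cohort_slopes}} with
#'   a \code{group} column.
#' @return list with components \code{learning_rate_anova},
#'   \code{group_delta_ci}, \code{reversal}.
#' @export
analysis_report <- function(rates, slopes = NULL) {
  out <- list()
  out$learning_rate_anova <- mixed_anova(
    rates, dv = "log_alpha", within = "condition", subject = "subject",
    between = if (length(unique(rates$group)) > 1) "group" else NULL
  )
  wide <- stats::reshape(
    rates[, c("subject", "group", "condition", "log_alpha")],
    direction = "wide", idvar = c("subject", "group"),
    timevar = "condition", v.names = "log_alpha"
  )
  delta <- wide$log_alpha.volatile - wide$log_alpha.stable
  groups <- unique(wide$group)
  ci <- list()
  if (length(groups) >= 2) {
    for (pr in utils::combn(groups, 2, simplify = FALSE)) {
      tt <- two_sample_t(delta[wide$group == pr[1]],
                         delta[wide$group == pr[2]])
      ci[[paste(pr, collapse = "_vs_")]] <- list(
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, ci = as.numeric(tt$conf.int)
      )
    }
  }
  out$group_delta_ci <- ci
  if (!is.null(slopes)) out$reversal <- interval_anova(slopes)
  out
}
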