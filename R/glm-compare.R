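#' Build the per-subject strategy design matrix
#'
#' Four candidate strategies are encoded as regressors for a logistic
#' model of the subject's trial-by-trial choices:
#' \describe{
#'   \item{\code{ideal}}{the ideal observer as a choice model: optimal
#'     behaviour computes the expected value of each option (estimated
#'     reward probability times displayed magnitude), so the default
#'     regressor is the observer's decision variable -- the expected-value
#'     difference between the options on a unit scale,
#'     \eqn{m_A/100 + E[r_A] - 1} (subject-independent given the
#'     schedule). Set \code{ideal_regressor = "e_r"} to use the bare
#'     probability estimate \eqn{E[r_A] - 0.5} instead.}
#'   \item{\code{alternation}}{the choice an alternator would make given
#'     the subject's own previous choice.}
#'   \item{\code{wsls}}{the choice a win-stay lose-shift strategy would
#'     make given the subject's previous choice and its outcome.}
#'   \item{\code{value}}{the displayed reward magnitude of option A,
#'     z-scored.}
#' }
#' Binary strategy predictions are coded +0.5 (predicts A) / -0.5
#' (predicts B) so all regressors are centered with respect to the
#' constant; t-statistics are invariant to these affine codings. The first
#' trial has no previous choice, so the alternation and WSLS predictions
#' are undefined and the trial is dropped.
#'
#' @param trials a played \code{vl_schedule} or its trials data frame with
#'   choices recorded.
#' @param trajectory a \code{vl_trajectory} from \code{\link{run_observer}}
#'   on the same schedule.
#' @param ideal_regressor coding of the ideal-observer regressor:
#'   \code{"ev_diff"} (default; the observer's expected-value decision
#'   variable) or \code{"e_r"} (the bare probability estimate).
#' @return a data frame of class \code{vl_design} with columns
#'   \code{trial}, \code{response} (1 = chose A), \code{ideal},
#'   \code{alternation}, \code{wsls}, \code{value}.
#' @export
build_design <- function(trials, trajectory,
                         ideal_regressor = c("ev_diff", "e_r")) {
  ideal_regressor <- match.arg(ideal_regressor)
  df <- if (inherits(trials, "vl_schedule")) trials$trials else trials
  if (nrow(df) != nrow(trajectory)) {
    stop("trials (", nrow(df), ") and trajectory (", nrow(trajectory),
         ") lengths differ", call. = FALSE)
  }
  if (anyNA(df$choice)) {
    stop("all trials must have recorded choices", call. = FALSE)
  }
  n <- nrow(df)
  prev_choice <- c(NA, df$choice[-n])
  prev_rewarded <- c(NA, df$rewarded[-n])
  alt_pred <- ifelse(prev_choice == "A", "B", "A")
  won_prev <- prev_choice == prev_rewarded
  wsls_pred <- ifelse(won_prev, prev_choice,
                      ifelse(prev_choice == "A", "B", "A"))
  code_pm <- function(pred) ifelse(pred == "A", 0.5, -0.5)
  x_ideal <- if (ideal_regressor == "ev_diff") {
    ev_diff_unit(trajectory$e_r, df$mag_a, df$mag_b)
  } else {
    trajectory$e_r - 0.5
  }
  out <- data.frame(
    trial = df$trial,
    response = as.integer(df$choice == "A"),
    ideal = x_ideal,
    alternation = code_pm(alt_pred),
    wsls = code_pm(wsls_pred),
    value = as.numeric(scale(df$mag_a))
  )
  out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vl_design", "data.frame")
  out
}

# Ridge-penalized logistic regression by Newton iterations. The penalty
# (never applied to the intercept) exists to keep perfectly separated
# fits -- guaranteed for deterministic strategy agents -- finite; at the
# default lambda it leaves t-statistics of non-degenerate fits essentially
# unchanged (shift well below 1% for |beta| < 10).
ridge_logistic <- function(X, y, lambda = 0.01, max_iter = 200,
                           tol = 1e-10) {
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1))
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- logistic(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # dampen oversized Newton steps (separation makes early steps huge)
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- logistic(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X * w, X) + diag(pen, p)
  se <- sqrt(diag(solve(H)))
  list(coef = beta, se = se, converged = converged,
       loglik = sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12))))
}

#' Fit the four-strategy logistic choice model
#'
#' Fits one simultaneous logistic GLM of the subject's choices on a
#' constant plus all four strategy regressors, with a weak ridge penalty
#' so that perfect separation (deterministic subjects) yields finite,
#' well-defined estimates. A strategy "fits" the subject when its
#' regressor's two-sided p-value is below 0.05; the best-fitting strategy
#' is the one with the largest t-statistic.
#'
#' @param design a \code{vl_design} from \code{\link{build_design}}.
#' @param lambda ridge penalty on the non-intercept coefficients.
#' @return object of class \code{vl_model_fit}: list with
#'   \code{coefficients} (data frame: term, estimate, se, t, p,
#'   significant), \code{best_model}, \code{converged}, \code{n},
#'   \code{dropped} (rank-deficient columns removed, if any).
#' @export
fit_choice_glm <- function(design, lambda = 0.01) {
  if (nrow(design) < 20) {
    stop("need at least 20 choice trials to fit the choice GLM",
         call. = FALSE)
  }
  terms <- c("ideal", "alternation", "wsls", "value")
  X <- cbind(`(Intercept)` = 1, as.matrix(design[, terms]))
  y <- design$response
  dropped <- character(0)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warning("rank-deficient design; dropping column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  fit <- ridge_logistic(X, y, lambda = lambda)
  df_resid <- nrow(X) - ncol(X)
  tval <- fit$coef / fit$se
  pval <- 2 * stats::pt(-abs(tval), df = df_resid)
  coefs <- data.frame(
    term = colnames(X), estimate = fit$coef, se = fit$se, t = tval,
    p = pval, significant = pval < 0.05, stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  model_rows <- coefs$term %in% terms
  best <- coefs$term[model_rows][which.max(coefs$t[model_rows])]
  structure(
    list(coefficients = coefs, best_model = best,
         converged = fit$converged, n = nrow(X), loglik = fit$loglik,
         dropped = dropped),
    class = "vl_model_fit"
  )
}

#' @export
print.vl_model_fit <- function(x, ...) {
  cat(sprintf("<vl_model_fit> n=%d, best model: %s\n", x$n, x$best_model))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Group-level summary of strategy fits
#'
#' For each group and candidate strategy: the mean t-statistic with its
#' standard error, and the proportion of subjects the strategy fits
#' significantly (p < .05). Differences in those proportions between
#' pairs of groups are tested with Pearson chi-squared tests (no
#' continuity correction). Because "best-fitting model" can be read per
#' group (argmax of the mean t) or per subject (majority of per-subject
#' argmaxes), both summaries are returned.
#'
#' @param fits list of \code{vl_model_fit}, one per subject.
#' @param groups character vector of group labels, one per fit.
#' @return list with \code{mean_t}, \code{prop_fit} (group x strategy
#'   matrices), \code{se_t}, \code{best_by_group}, \code{best_by_subject}
#'   (per-group tables of subject-level best models), and
#'   \code{prop_tests} (data frame of pairwise chi-squared tests per
#'   strategy).
#' @export
summarize_group <- function(fits, groups) {
  if (length(fits) == 0 || length(fits) != length(groups)) {
    stop("fits and groups must be non-empty and the same length",
         call. = FALSE)
  }
  terms <- c("ideal", "alternation", "wsls", "value")
  tmat <- t(vapply(fits, function(f) {
    co <- f$coefficients
    stats::setNames(co$t[match(terms, co$term)], terms)
  }, numeric(4)))
  sigmat <- t(vapply(fits, function(f) {
    co <- f$coefficients
    stats::setNames(co$significant[match(terms, co$term)], terms)
  }, logical(4)))
  glab <- unique(groups)
  agg <- function(m, fun) {
    out <- t(vapply(glab, function(g) apply(m[groups == g, , drop = FALSE],
                                            2, fun), numeric(4)))
    rownames(out) <- glab
    out
  }
  mean_t <- agg(tmat, mean)
  se_t <- agg(tmat, function(x) stats::sd(x) / sqrt(length(x)))
  prop_fit <- agg(sigmat, mean)
  best_subj <- vapply(fits, function(f) f$best_model, character(1))
  best_by_subject <- lapply(stats::setNames(glab, glab), function(g) {
    table(factor(best_subj[groups == g], levels = terms))
  })
  best_by_group <- apply(mean_t, 1, function(x) terms[which.max(x)])

  prop_tests <- NULL
  if (length(glab) >= 2) {
    pairs <- utils::combn(glab, 2, simplify = FALSE)
    rows <- list()
    for (m in terms) {
      for (pr in pairs) {
        n1 <- sum(groups == pr[1]); n2 <- sum(groups == pr[2])
        k1 <- sum(sigmat[groups == pr[1], m])
        k2 <- sum(sigmat[groups == pr[2], m])
        tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
        test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          model = m, group1 = pr[1], group2 = pr[2],
          chisq = unname(test$statistic), df = unname(test$parameter),
          p = test$p.value, stringsAsFactors = FALSE
        )
      }
    }
    prop_tests <- do.call(rbind, rows)
  }
  list(mean_t = mean_t, se_t = se_t, prop_fit = prop_fit,
       best_by_group = best_by_group, best_by_subject = best_by_subject,
       prop_tests = prop_tests)
}
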