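#' Estimation window for a task variant and condition
#'
#' The learning rate is estimated inside fixed windows that skip the early
#' trials of each phase. For the short variant the windows are the 61
#' trials from trial 20 to trial 80 (stable) and the 61 trials from trial
#' 90 to trial 150 (volatile). For the long variant they are the last 81
#' trials of each phase, whose absolute positions depend on whether the
#' stable phase came first.
#'
#' @param variant "short" or "long".
#' @param condition "stable" or "volatile".
#' @param stable_first for the long variant, whether the stable phase was
#'   presented first.
#' @return list of class \code{vl_window} with \code{condition},
#'   \code{start}, \code{end} (1-based, inclusive).
#' @export
estimation_window <- function(variant = c("short", "long"),
                              condition = c("stable", "volatile"),
                              stable_first = TRUE) {
  variant <- match.arg(variant)
  condition <- match.arg(condition)
  w <- if (variant == "short") {
    if (condition == "stable") c(20L, 80L) else c(90L, 150L)
  } else {
    # phases: stable 120 trials, volatile 170 trials; window = last 81
    if (isTRUE(stable_first)) {
      if (condition == "stable") c(40L, 120L) else c(210L, 290L)
    } else {
      if (condition == "volatile") c(90L, 170L) else c(210L, 290L)
    }
  }
  structure(list(condition = condition, start = w[1], end = w[2]),
            class = "vl_window")
}

#' Negative log-likelihood of a delta-rule learner's choices
#'
#' The model has a "predictor" -- the Rescorla-Wagner update
#' \eqn{\hat r \leftarrow \hat r + \alpha (y - \hat r)} run over \emph{all}
#' trials from trial 1 (trials before the window still shape the learner's
#' state) -- and a "selector" that chooses option A with probability
#' \eqn{\mathrm{logit}^{-1}(\beta d_t)}, where \eqn{d_t} is the
#' expected-value difference on the unit scale. Only trials inside the
#' window contribute likelihood terms. Choice probabilities are floored at
#' 1e-10 inside the log to keep the objective bounded.
#'
#' @param alpha learning rate in (0, 1).
#' @param beta selector inverse temperature, >= 0.
#' @param trials played \code{vl_schedule} or trials data frame with
#'   choices.
#' @param window a \code{vl_window} (or list with start/end).
#' @return the summed negative log-likelihood over window trials.
#' @export
choice_likelihood <- function(alpha, beta, trials, window) {
  df <- if (inherits(trials, "vl_schedule")) trials$trials else trials
  if (window$start < 1 || window$end > nrow(df)) {
    stop("window [", window$start, ", ", window$end,
         "] outside the 1..", nrow(df), " trial range", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  y <- as.integer(df$rewarded == "A")
  r_hat <- rw_trace(y, alpha)
  idx <- window$start:window$end
  if (anyNA(df$choice[idx])) {
    stop("window contains trials without choices", call. = FALSE)
  }
  d <- ev_diff_unit(r_hat[idx], df$mag_a[idx], df$mag_b[idx])
  p_a <- logistic(beta * d)
  p_choice <- ifelse(df$choice[idx] == "A", p_a, 1 - p_a)
  -sum(log(pmax(p_choice, 1e-10)))
}

# NLL and its analytic gradient in one pass. The predictor-trace
# sensitivity dr_hat/dalpha follows the same first-order recursion as the
# trace itself, so both are computed with recursive filters.
nll_and_grad <- function(par, y, mag_a, c_a, idx) {
  alpha <- par[1]; beta <- par[2]
  n <- length(y)
  r_full <- stats::filter(alpha * y, filter = 1 - alpha,
                          method = "recursive", init = 0.5)
  r_hat <- c(0.5, as.numeric(r_full)[-n])
  err <- y - r_hat
  g_full <- stats::filter(err, filter = 1 - alpha, method = "recursive",
                          init = 0)
  g <- c(0, as.numeric(g_full)[-n]) # dr_hat/dalpha
  d <- mag_a[idx] / 100 + r_hat[idx] - 1
  p_a <- logistic(beta * d)
  p_choice <- ifelse(c_a, p_a, 1 - p_a)
  nll <- -sum(log(pmax(p_choice, 1e-10)))
  resid <- p_a - c_a
  list(value = nll,
       grad = c(sum(resid * beta * g[idx]), sum(resid * d)))
}

# fixed multi-start grid: results are deterministic given the data
.alpha_starts <- c(0.02, 0.1, 0.3, 0.6, 0.9)
.beta_starts <- c(0.5, 2, 5, 15, 40)

#' Fit the delta-rule learning rate in a window
#'
#' Maximum-likelihood estimation of \eqn{(\alpha, \beta)} by bounded
#' quasi-Newton optimization (L-BFGS-B) from a fixed 5 x 5 grid of start
#' points, keeping the best converged optimum. \eqn{\beta} is a nuisance
#' parameter fitted jointly: the predictor has a single free parameter
#' (the learning rate), but a proper likelihood needs the selector's
#' temperature too.
#'
#' @inheritParams choice_likelihood
#' @param alpha_bounds,beta_bounds optimizer box constraints.
#' @return object of class \code{vl_fit_result}: list with
#'   \code{alpha_hat}, \code{beta_hat}, \code{log_alpha} (natural log),
#'   \code{nll}, \code{window}, \code{converged}.
#' @export
fit_learning_rate <- function(trials, window,
                              alpha_bounds = c(0.001, 0.999),
                              beta_bounds = c(0, 50)) {
  df <- if (inherits(trials, "vl_schedule")) trials$trials else trials
  idx <- window$start:window$end
  if (sum(!is.na(df$choice[idx])) < 30) {
    stop("window must contain at least 30 choice trials", call. = FALSE)
  }
  y <- as.integer(df$rewarded == "A")
  c_a <- df$choice[idx] == "A"
  obj <- function(par) nll_and_grad(par, y, df$mag_a, c_a, idx)$value
  grd <- function(par) nll_and_grad(par, y, df$mag_a, c_a, idx)$grad
  best <- NULL
  any_conv <- FALSE
  for (a0 in .alpha_starts) {
    for (b0 in .beta_starts) {
      res <- tryCatch(
        stats::optim(c(a0, b0), obj, gr = grd, method = "L-BFGS-B",
                     lower = c(alpha_bounds[1], beta_bounds[1]),
                     upper = c(alpha_bounds[2], beta_bounds[2])),
        error = function(e) NULL
      )
      if (is.null(res)) next
      conv <- res$convergence == 0
      any_conv <- any_conv || conv
      if (is.null(best) || res$value < best$value - 1e-12) {
        best <- res
        best$converged <- conv
      }
    }
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  structure(
    list(alpha_hat = best$par[1], beta_hat = best$par[2],
         log_alpha = log(best$par[1]), nll = best$value,
         window = window, converged = isTRUE(best$converged) && any_conv),
    class = "vl_fit_result"
  )
}

#' Fit both condition windows for one subject
#'
#' @param trials played \code{vl_schedule} with choices.
#' @param variant "short" or "long".
#' @param stable_first long-variant phase order.
#' @return named list with elements \code{stable} and \code{volatile},
#'   each a \code{vl_fit_result}.
#' @export
fit_subject <- function(trials, variant = "short", stable_first = TRUE) {
  list(
    stable = fit_learning_rate(
      trials, estimation_window(variant, "stable", stable_first)),
    volatile = fit_learning_rate(
      trials, estimation_window(variant, "volatile", stable_first))
  )
}

#' Volatile-minus-stable contrast of log learning rates
#'
#' Computes the per-subject difference
#' \eqn{\Delta = \log\hat\alpha_{volatile} - \log\hat\alpha_{stable}} and
#' its group mean with a t-based 95% confidence interval. Subjects whose
#' fits did not converge in both windows are excluded (with a message).
#'
#' @param fits list over subjects; each element a list with
#'   \code{stable} and \code{volatile} \code{vl_fit_result}s (as returned
#'   by \code{\link{fit_subject}}).
#' @param conf_level confidence level for the group-mean interval.
#' @return list with \code{delta} (per-subject vector), \code{mean},
#'   \code{ci} (length-2), \code{n}, \code{excluded}.
#' @export
condition_contrast <- function(fits, conf_level = 0.95) {
  ok <- vapply(fits, function(f) {
    isTRUE(f$stable$converged) && isTRUE(f$volatile$converged)
  }, logical(1))
  if (any(!ok)) {
    message(sum(!ok), " subject(s) excluded for non-convergence")
  }
  delta <- vapply(fits[ok], function(f) {
    f$volatile$log_alpha - f$stable$log_alpha
  }, numeric(1))
  n <- length(delta)
  if (n < 2) stop("need at least 2 converged subjects", call. = FALSE)
  m <- mean(delta)
  se <- stats::sd(delta) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  list(delta = delta, mean = m, ci = c(m - tq * se, m + tq * se),
       n = n, excluded = names(fits)[!ok])
}
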