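#' Initialize the ideal observer's posterior grid
#'
#' The ideal observer is a Bayesian agent that tracks three latent
#' quantities from the sequence of rewarded options alone: the reward
#' probability \eqn{r} of option A, the (log) volatility \eqn{v} governing
#' how fast \eqn{r} drifts between trials, and a drift parameter \eqn{k}
#' governing how fast the volatility itself changes. Inference is exact
#' discretized Bayes on a three-dimensional grid: \eqn{r} evolves through a
#' beta-family transition kernel with mean \eqn{r_t} and concentration
#' \eqn{\exp(-v)} (larger \eqn{v} = more diffusion = more volatile), \eqn{v}
#' follows a Gaussian random walk with standard deviation \eqn{\exp(k)},
#' and \eqn{k} is static within a run and marginalized over.
#'
#' Grid resolutions and prior ranges are numerical choices, not task facts;
#' defaults were fixed once so that doubling every resolution changes the
#' posterior-mean trajectory by less than 0.01 in sup-norm on a 160-trial
#' schedule.
#'
#' @param grid_sizes integer triple: number of grid points for
#'   \eqn{(r, v, k)}; each must be at least 2.
#' @param r_range range of reward-probability support, inside (0, 1).
#' @param v_range range of log-volatility; the beta transition kernel has
#'   concentration \code{exp(-v)}.
#' @param k_range range of the volatility-drift parameter; the random walk
#'   on \eqn{v} has standard deviation \code{exp(k)}.
#' @return object of class \code{vl_posterior}: grids, a joint weight array
#'   (uniform at initialization) and cached transition operators.
#' @export
init_posterior <- function(grid_sizes = c(30L, 15L, 15L),
                           r_range = c(0.01, 0.99),
                           v_range = c(-7, -0.7),
                           k_range = c(-4, 0.5)) {
  grid_sizes <- as.integer(grid_sizes)
  if (length(grid_sizes) != 3 || any(grid_sizes < 2)) {
    stop("grid_sizes must be three integers, each >= 2", call. = FALSE)
  }
  r_grid <- seq(r_range[1], r_range[2], length.out = grid_sizes[1])
  v_grid <- seq(v_range[1], v_range[2], length.out = grid_sizes[2])
  k_grid <- seq(k_range[1], k_range[2], length.out = grid_sizes[3])

  # Transition kernels are integrated over destination grid cells (CDF
  # differences) rather than evaluated pointwise: at low volatility the
  # beta kernel is narrower than the grid spacing and pointwise densities
  # alias badly, while cell masses stay exact.
  r_edges <- c(0, (r_grid[-1] + r_grid[-length(r_grid)]) / 2, 1)
  v_edges <- c(-Inf, (v_grid[-1] + v_grid[-length(v_grid)]) / 2, Inf)

  # r-transition: one column-stochastic nr x nr matrix per v level.
  trans_r <- lapply(v_grid, function(v) {
    conc <- exp(-v)
    vapply(r_grid, function(ri) {
      diff(stats::pbeta(r_edges, shape1 = ri * conc,
                        shape2 = (1 - ri) * conc))
    }, numeric(length(r_grid)))
    # m[j, i] = P(r' in cell j | r = r_i, v); columns sum to 1
  })
  # v-transition: one column-stochastic nv x nv matrix per k level.
  trans_v <- lapply(k_grid, function(k) {
    sdv <- exp(k)
    vapply(v_grid, function(vi) {
      diff(stats::pnorm(v_edges, mean = vi, sd = sdv))
    }, numeric(length(v_grid)))
  })

  w <- array(1 / prod(grid_sizes), dim = grid_sizes)
  structure(
    list(r_grid = r_grid, v_grid = v_grid, k_grid = k_grid, weights = w,
         trans_r = trans_r, trans_v = trans_v),
    class = "vl_posterior"
  )
}

#' Posterior means of the ideal observer
#'
#' @param post a \code{vl_posterior}.
#' @return named numeric vector with components \code{e_r} (posterior mean
#'   reward probability for option A), \code{e_v} and \code{e_k}.
#' @export
posterior_means <- function(post) {
  stopifnot(inherits(post, "vl_posterior"))
  w <- post$weights
  c(e_r = sum(post$r_grid * apply(w, 1, sum)),
    e_v = sum(post$v_grid * apply(w, 2, sum)),
    e_k = sum(post$k_grid * apply(w, 3, sum)))
}

#' One filtering step of the ideal observer
#'
#' Propagates the joint belief through one trial's worth of latent dynamics
#' (\eqn{v} diffuses under its \eqn{k}-controlled random walk, then \eqn{r}
#' diffuses under its \eqn{v}-controlled beta kernel), multiplies in the
#' Bernoulli likelihood \eqn{r^y (1-r)^{1-y}} of the observed outcome, and
#' renormalizes.
#'
#' @param post a \code{vl_posterior}.
#' @param outcome 0/1 indicator that option A was rewarded on this trial.
#' @return the updated, normalized \code{vl_posterior}.
#' @export
update_posterior <- function(post, outcome) {
  stopifnot(inherits(post, "vl_posterior"))
  if (!(length(outcome) == 1 && outcome %in% c(0, 1))) {
    stop("outcome must be a single 0/1 indicator", call. = FALSE)
  }
  w <- post$weights
  d <- dim(w)
  nr <- d[1]; nv <- d[2]; nk <- d[3]
  # v-diffusion, separately per static k
  for (ik in seq_len(nk)) {
    w[, , ik] <- w[, , ik] %*% t(post$trans_v[[ik]])
  }
  # r-diffusion, conditional on the post-diffusion v
  for (iv in seq_len(nv)) {
    w[, iv, ] <- post$trans_r[[iv]] %*% w[, iv, , drop = TRUE]
  }
  lik <- if (outcome == 1) post$r_grid else 1 - post$r_grid
  w <- w * lik
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    stop(sprintf(
      "posterior mass underflow (total = %g) on grid %d x %d x %d",
      total, nr, nv, nk), call. = FALSE)
  }
  post$weights <- w / total
  post
}

#' Run the ideal observer over a schedule
#'
#' Applies \code{\link{update_posterior}} sequentially over the rewarded
#' outcomes of a schedule. Only the outcome sequence is used: the observer
#' never sees choices or reward magnitudes, since the magnitudes are
#' random and carry no information about the reward probability.
#'
#' Each trajectory row is the observer's \emph{prediction} for that trial,
#' i.e. the posterior mean given the outcomes of all preceding trials: the
#' quantity available when the decision on that trial is made, and hence
#' the quantity used as a choice regressor downstream.
#'
#' @param schedule a \code{vl_schedule} or a trials data frame with a
#'   \code{rewarded} column.
#' @param grid_sizes,r_range,v_range,k_range passed to
#'   \code{\link{init_posterior}}.
#' @param keep_posterior logical; also return the final posterior object.
#' @return object of class \code{vl_trajectory}: data frame with columns
#'   \code{trial}, \code{e_r}, \code{e_v} (attribute \code{posterior} holds
#'   the final posterior when requested).
#' @export
run_observer <- function(schedule, grid_sizes = c(30L, 15L, 15L),
                         r_range = c(0.01, 0.99), v_range = c(-7, -0.7),
                         k_range = c(-4, 0.5), keep_posterior = FALSE) {
  trials <- if (inherits(schedule, "vl_schedule")) schedule$trials else schedule
  if (is.null(trials$rewarded) || nrow(trials) == 0) {
    stop("schedule must contain at least one trial with a rewarded option",
         call. = FALSE)
  }
  y <- as.integer(trials$rewarded == "A")
  post <- init_posterior(grid_sizes, r_range, v_range, k_range)
  n <- length(y)
  e_r <- numeric(n)
  e_v <- numeric(n)
  for (t in seq_len(n)) {
    m <- posterior_means(post)
    e_r[t] <- m[["e_r"]]
    e_v[t] <- m[["e_v"]]
    post <- update_posterior(post, y[t])
  }
  out <- data.frame(trial = trials$trial %||% seq_len(n), e_r = e_r, e_v = e_v)
  class(out) <- c("vl_trajectory", "data.frame")
  if (keep_posterior) attr(out, "posterior") <- post
  out
}

#' Expected value of an option
#'
#' The expected value of choosing an option is its reward probability
#' multiplied by the number of points displayed on its flag.
#'
#' @param prob reward probability in [0, 1].
#' @param magnitude reward magnitude in points (0-100).
#' @return \code{prob * magnitude}, in points.
#' @export
#' @examples
#' expected_value(0.5, 27)  # 13.5
expected_value <- function(prob, magnitude) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    stop("prob must lie in [0, 1]", call. = FALSE)
  }
  if (any(magnitude < 0 | magnitude > 100, na.rm = TRUE)) {
    stop("magnitude must lie in [0, 100]", call. = FALSE)
  }
  prob * magnitude
}

# Normalized expected-value difference between options A and B, given the
# estimated probability that A is rewarded. Exactly one option is rewarded
# per trial, so P(B rewarded) = 1 - p. Dividing by the 100-point total puts
# the difference on a unit scale so selector temperatures are comparable
# across magnitude scales: d = mag_a/100 + p - 1, in [-1, 1].
ev_diff_unit <- function(p, mag_a, mag_b) {
  (expected_value(p, mag_a) - expected_value(1 - p, mag_b)) / 100
}
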