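#' Specify a synthetic choice-generating agent
#'
#' Agents turn a reward schedule into a choice sequence and are the
#' package's synthetic-data engine: every downstream analysis can be
#' exercised and validated on agents with known parameters.
#'
#' Available strategies:
#' \describe{
#'   \item{\code{delta_rule}}{Rescorla-Wagner learner. A "predictor" tracks
#'     the probability that option A is rewarded via
#'     \eqn{\hat r \leftarrow \hat r + \alpha (y - \hat r)} where \eqn{y}
#'     indicates that A was rewarded; a "selector" chooses A with
#'     probability \eqn{\mathrm{logit}^{-1}(\beta d)} where \eqn{d} is the
#'     expected-value difference between the options on a unit (0-1) scale,
#'     mixed with a lapse rate \eqn{\epsilon}. \code{alpha} may be a single
#'     value or a named vector \code{c(stable = , volatile = )} to let the
#'     learning rate change with the condition.}
#'   \item{\code{wsls}}{win-stay lose-shift: repeats the previous choice if
#'     it was rewarded, otherwise switches. First choice random.}
#'   \item{\code{alternator}}{switches option on every trial. First choice
#'     random.}
#'   \item{\code{value_follower}}{always picks the option with the larger
#'     displayed magnitude (random on 50/50 ties).}
#'   \item{\code{random}}{fair coin on every trial.}
#' }
#'
#' @param kind strategy name (see Details).
#' @param alpha learning rate in (0, 1]; scalar or
#'   \code{c(stable = , volatile = )} (delta_rule only).
#' @param beta selector inverse temperature, >= 0; on the unit
#'   expected-value scale, \code{beta = 0} is random choice and
#'   \code{beta = 1000} is effectively deterministic.
#' @param epsilon lapse probability in [0, 0.5): with probability
#'   \code{epsilon} the agent ignores its policy and flips a fair coin.
#' @param seed integer seed for the agent's private RNG stream.
#' @return an object of class \code{vl_agent_spec}.
#' @export
agent_spec <- function(kind = c("delta_rule", "wsls", "alternator",
                                "value_follower", "random"),
                       alpha = 0.3, beta = 5, epsilon = 0, seed = 1L) {
  kind <- match.arg(kind)
  alpha <- unlist(alpha)
  if (any(alpha <= 0 | alpha > 1)) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (length(alpha) == 2 && !all(c("stable", "volatile") %in% names(alpha))) {
    stop("condition-specific alpha must be named c(stable=, volatile=)",
         call. = FALSE)
  }
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (epsilon < 0 || epsilon >= 0.5) {
    stop("epsilon must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(kind = kind, alpha = alpha, beta = beta, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "vl_agent_spec")
}

# Rescorla-Wagner predictor trace: r_hat[t] is the estimate *before* seeing
# trial t's outcome (r_hat[1] = 0.5). Updates depend only on the outcome
# sequence, never on choices, so the trace is a first-order recursive
# filter and can be computed in one vectorized pass. alpha may vary per
# trial (condition-dependent learning rates).
rw_trace <- function(y, alpha) {
  n <- length(y)
  if (length(alpha) == 1) {
    r <- stats::filter(alpha * y, filter = 1 - alpha, method = "recursive",
                       init = 0.5)
    c(0.5, as.numeric(r)[-n])
  } else {
    r <- numeric(n)
    r[1] <- 0.5
    for (t in seq_len(n - 1)) {
      r[t + 1] <- r[t] + alpha[t] * (y[t] - r[t])
    }
    r
  }
}

# Expand a (possibly condition-named) alpha to one value per trial.
alpha_per_trial <- function(alpha, condition) {
  if (length(alpha) == 1) return(rep(unname(alpha), length(condition)))
  unname(alpha[condition])
}

#' Simulate an agent's choices on a schedule
#'
#' @param spec a \code{vl_agent_spec}.
#' @param schedule a \code{vl_schedule}.
#' @return the schedule with its \code{choice} column filled; the attribute
#'   \code{r_hat} carries the delta-rule predictor trace when applicable.
#' @export
simulate_agent <- function(spec, schedule) {
  stopifnot(inherits(spec, "vl_agent_spec"), inherits(schedule, "vl_schedule"))
  trials <- schedule$trials
  n <- nrow(trials)
  y <- as.integer(trials$rewarded == "A")
  with_seed(spec$seed, {
    choice <- switch(spec$kind,
      delta_rule = {
        alpha_t <- alpha_per_trial(spec$alpha, trials$condition)
        r_hat <- rw_trace(y, if (length(spec$alpha) == 1) spec$alpha else alpha_t)
        d <- ev_diff_unit(r_hat, trials$mag_a, trials$mag_b)
        p_a <- (1 - spec$epsilon) * logistic(spec$beta * d) + spec$epsilon / 2
        ch <- ifelse(stats::runif(n) < p_a, "A", "B")
        attr(ch, "r_hat") <- r_hat
        ch
      },
      wsls = {
        ch <- character(n)
        ch[1] <- sample(c("A", "B"), 1)
        for (t in seq_len(n - 1)) {
          won <- ch[t] == trials$rewarded[t]
          ch[t + 1] <- if (won) ch[t] else setdiff(c("A", "B"), ch[t])
        }
        ch
      },
      alternator = {
        first <- sample(c("A", "B"), 1)
        rep(if (first == "A") c("A", "B") else c("B", "A"),
            length.out = n)
      },
      value_follower = {
        ch <- ifelse(trials$mag_a > trials$mag_b, "A",
                     ifelse(trials$mag_a < trials$mag_b, "B", NA))
        ties <- is.na(ch)
        ch[ties] <- sample(c("A", "B"), sum(ties), replace = TRUE)
        ch
      },
      random = sample(c("A", "B"), n, replace = TRUE)
    )
    r_hat <- attr(choice, "r_hat")
    out <- set_choices(schedule, as.character(choice))
    if (!is.null(r_hat)) attr(out, "r_hat") <- r_hat
    out
  })
}

#' Specify a synthetic cohort
#'
#' A cohort is a set of groups of agents, each agent playing its own
#' schedule realization. Ground-truth parameters are always recorded next
#' to the simulated logs so parameter-recovery analyses are possible.
#'
#' @param groups list of group descriptions; each is a list with
#'   \code{label}, \code{n} (subjects), and agent parameters:
#'   \code{kind} (default \code{"delta_rule"}), \code{alpha_stable},
#'   \code{alpha_volatile} (each a scalar or a \code{function(n)} drawing n
#'   values), \code{beta} (scalar or \code{function(n)}), \code{epsilon}.
#' @param schedule_config a \code{vl_schedule_config}; each subject gets a
#'   fresh schedule with a subject-specific seed derived from \code{seed}.
#' @param seed master integer seed.
#' @param share_schedule logical; if TRUE all subjects play the identical
#'   schedule realization (useful for calibration studies where the design
#'   must be held fixed).
#' @return object of class \code{vl_cohort_spec}.
#' @export
cohort_spec <- function(groups, schedule_config, seed = 1L,
                        share_schedule = FALSE) {
  stopifnot(inherits(schedule_config, "vl_schedule_config"))
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n) || g$n < 1) {
      stop("each group needs a label and n >= 1", call. = FALSE)
    }
  }
  structure(list(groups = groups, schedule_config = schedule_config,
                 seed = as.integer(seed),
                 share_schedule = isTRUE(share_schedule)),
            class = "vl_cohort_spec")
}

draw_param <- function(x, n, default) {
  if (is.null(x)) rep(default, length.out = n)
  else if (is.function(x)) x(n)
  else rep(x, length.out = n)
}

#' Simulate a cohort of agents
#'
#' @param spec a \code{vl_cohort_spec}.
#' @return object of class \code{vl_cohort}: a list with \code{subjects}
#'   (named list of played \code{vl_schedule}s) and \code{truth} (data
#'   frame of per-subject generating parameters: subject, group, kind,
#'   alpha_stable, alpha_volatile, beta, epsilon, schedule_seed).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "vl_cohort_spec"))
  subjects <- list()
  truth <- list()
  sid <- 0L
  # subject-level seeds drawn reproducibly from the master seed
  n_total <- sum(vapply(spec$groups, function(g) as.integer(g$n), integer(1)))
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max / 2, 2 * n_total + 1))
  shared_seed <- seeds[length(seeds)]
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    kind <- g$kind %||% "delta_rule"
    a_s <- with_seed(spec$seed + 101L * gi,
                     draw_param(g$alpha_stable, g$n, 0.2))
    a_v <- with_seed(spec$seed + 211L * gi,
                     draw_param(g$alpha_volatile, g$n, unname(a_s)))
    b <- with_seed(spec$seed + 307L * gi, draw_param(g$beta, g$n, 5))
    eps <- g$epsilon %||% 0
    for (i in seq_len(g$n)) {
      sid <- sid + 1L
      cfg <- spec$schedule_config
      cfg$seed <- if (spec$share_schedule) shared_seed else seeds[2 * sid - 1]
      sched <- build_schedule(cfg)
      aspec <- agent_spec(
        kind = kind,
        alpha = if (kind == "delta_rule")
          c(stable = a_s[i], volatile = a_v[i]) else 0.3,
        beta = b[i], epsilon = eps, seed = seeds[2 * sid]
      )
      id <- sprintf("s%03d", sid)
      subjects[[id]] <- simulate_agent(aspec, sched)
      truth[[id]] <- data.frame(
        subject = id, group = g$label, kind = kind,
        alpha_stable = a_s[i], alpha_volatile = a_v[i],
        beta = b[i], epsilon = eps, schedule_seed = cfg$seed,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(subjects = subjects,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 spec = spec),
            class = "vl_cohort")
}

#' Write a cohort to a directory of CSV logs
#'
#' Writes one trial log per subject plus \code{truth.csv} with the
#' generating parameters.
#'
#' @param cohort a \code{vl_cohort}.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vl_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    write_trials(cohort$subjects[[id]], file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
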