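#' Trailing running average of a choice sequence
#'
#' Mean of the \code{window_len} trials ending at each position; defined
#' from position \code{window_len} onwards (earlier positions are NA).
#' With the default 4-trial window and 0/1 choices the values lie in
#' {0, .25, .5, .75, 1}.
#'
#' @param choices numeric 0/1 vector (1 = chose option A).
#' @param window_len window length in trials.
#' @return numeric vector the same length as \code{choices}, NA before the
#'   window is full.
#' @export
running_average <- function(choices, window_len = 4) {
  if (length(choices) < window_len) {
    stop("sequence shorter than the running-average window", call. = FALSE)
  }
  cs <- cumsum(choices)
  out <- rep(NA_real_, length(choices))
  idx <- window_len:length(choices)
  out[idx] <- (cs[idx] - c(0, cs)[idx - window_len + 1]) / window_len
  out
}

# OLS slope of y against 1..length(y)
ols_slope <- function(y) {
  x <- seq_along(y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Post-reversal adaptation slopes
#'
#' For each volatile-phase reversal of the short task (reward ratio flips
#' at trials 101, 121 and 141), fits an ordinary least-squares regression
#' line to the first ten running-average values after the switch (trials
#' s..s+9) and returns the raw slope, its absolute value, and the
#' square-root of the absolute value (the transform used to normalize
#' slopes before ANOVA). A positive raw slope means the subject moved
#' towards option A over the interval.
#'
#' @param trials played \code{vl_schedule} or trials data frame with
#'   choices (short variant).
#' @param switches trial indices at which the intervals start.
#' @param window_len running-average window.
#' @return data frame of class \code{vl_slopes}: one row per interval with
#'   columns \code{interval} ("101-110", ...), \code{slope},
#'   \code{abs_slope}, \code{sqrt_abs_slope}.
#' @export
post_switch_slopes <- function(trials, switches = c(101L, 121L, 141L),
                               window_len = 4) {
  df <- if (inherits(trials, "vl_schedule")) trials$trials else trials
  if (anyNA(df$choice)) {
    stop("all trials must have recorded choices", call. = FALSE)
  }
  ch <- as.integer(df$choice == "A")
  ra <- running_average(ch, window_len)
  rows <- lapply(switches, function(s) {
    idx <- s:(s + 9L)
    if (max(idx) > length(ra) || anyNA(ra[idx])) {
      return(data.frame(interval = sprintf("%d-%d", s, s + 9L),
                        slope = NA_real_, abs_slope = NA_real_,
                        sqrt_abs_slope = NA_real_))
    }
    sl <- ols_slope(ra[idx])
    data.frame(interval = sprintf("%d-%d", s, s + 9L), slope = sl,
               abs_slope = abs(sl), sqrt_abs_slope = sqrt(abs(sl)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vl_slopes", "data.frame")
  out
}

#' Cohort-level slope table
#'
#' @param cohort a \code{vl_cohort}.
#' @return long data frame with columns \code{subject}, \code{group},
#'   \code{interval}, \code{slope}, \code{abs_slope},
#'   \code{sqrt_abs_slope}.
#' @export
cohort_slopes <- function(cohort) {
  stopifnot(inherits(cohort, "vl_cohort"))
  rows <- lapply(names(cohort$subjects), function(id) {
    sl <- post_switch_slopes(cohort$subjects[[id]])
    sl$subject <- id
    sl$group <- cohort$truth$group[cohort$truth$subject == id]
    sl
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed ANOVA on post-reversal slopes
#'
#' Mixed-design ANOVA on the square-root-transformed absolute slopes with
#' trial interval as the within-subject factor and group as the
#' between-subject factor, plus Mauchly's sphericity test and repeated
#' contrasts (interval 1 vs 2, interval 2 vs 3). Subjects missing any
#' interval are dropped listwise with a warning.
#'
#' @param slopes long data frame as from \code{\link{cohort_slopes}}.
#' @return list with \code{anova} (the \code{\link{mixed_anova}} table),
#'   \code{mauchly} (W, chisq, df, p), and \code{contrasts} (data frame of
#'   the two repeated contrasts).
#' @export
interval_anova <- function(slopes) {
  need <- c("subject", "group", "interval", "sqrt_abs_slope")
  stopifnot(all(need %in% names(slopes)))
  wide <- stats::reshape(
    slopes[, need], direction = "wide", idvar = c("subject", "group"),
    timevar = "interval", v.names = "sqrt_abs_slope"
  )
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) dropped for missing intervals")
    wide <- wide[complete, , drop = FALSE]
  }
  long <- slopes[slopes$subject %in% wide$subject, need]
  res <- mixed_anova(long, dv = "sqrt_abs_slope", within = "interval",
                     between = "group", subject = "subject")
  ycols <- grep("^sqrt_abs_slope\\.", names(wide), value = TRUE)
  Y <- as.matrix(wide[, ycols])
  mau <- mauchly_sphericity(Y, wide$group)
  contr <- repeated_contrasts(Y, wide$group)
  list(anova = res, mauchly = mau, contrasts = contr)
}
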