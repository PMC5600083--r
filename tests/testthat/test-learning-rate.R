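test_that("estimation windows match the task design", {
  ws <- estimation_window("short", "stable")
  wv <- estimation_window("short", "volatile")
  expect_equal(c(ws$start, ws$end), c(20, 80))
  expect_equal(c(wv$start, wv$end), c(90, 150))
  expect_equal(ws$end - ws$start + 1, 61)
  expect_equal(wv$end - wv$start + 1, 61)
  # long variant: last 81 trials of each phase, both phase orders
  for (sf in c(TRUE, FALSE)) {
    ls <- estimation_window("long", "stable", stable_first = sf)
    lv <- estimation_window("long", "volatile", stable_first = sf)
    expect_equal(ls$end - ls$start + 1, 81)
    expect_equal(lv$end - lv$start + 1, 81)
  }
  expect_equal(unlist(estimation_window("long", "volatile")[c("start", "end")],
                      use.names = FALSE), c(210, 290))
  expect_equal(unlist(estimation_window("long", "volatile",
                                        stable_first = FALSE)[c("start", "end")],
                      use.names = FALSE), c(90, 170))
})

test_that("coin-flip selector gives exactly (window length) * log 2", {
  a <- played_schedule(3)
  w <- estimation_window("short", "stable")
  for (alpha in c(0.1, 0.5, 0.9)) {
    expect_equal(choice_likelihood(alpha, 0, a, w), 61 * log(2),
                 tolerance = 1e-12)
  }
})

test_that("likelihood matches a hand-worked five-trial sequence", {
  # alpha = .4, beta = .1; delta-rule trace written out by hand:
  # r1 = .5
  # r2 = .5 + .4(1 - .5)   = .7      (trial 1 rewarded A)
  # r3 = .7 + .4(0 - .7)   = .42     (trial 2 rewarded B)
  # r4 = .42 + .4(1 - .42) = .652
  # r5 = .652 + .4(1-.652) = .7912
  df <- toy_trials(rewarded = c("A", "B", "A", "A", "B"),
                   mag_a = c(60, 30, 80, 50, 10),
                   choice = c("A", "A", "B", "A", "B"))
  r_hand <- c(0.5, 0.7, 0.42, 0.652, 0.7912)
  d_hand <- c(60, 30, 80, 50, 10) / 100 + r_hand - 1
  p_a <- 1 / (1 + exp(-0.1 * d_hand))
  p_choice <- c(p_a[1], p_a[2], 1 - p_a[3], p_a[4], 1 - p_a[5])
  expect_equal(
    choice_likelihood(0.4, 0.1, df, list(start = 1, end = 5)),
    -sum(log(p_choice)),
    tolerance = 1e-12
  )
})

test_that("burn-in trials shape the predictor but not the likelihood", {
  a <- played_schedule(4, alpha = 0.3, beta = 8)
  w <- list(condition = "stable", start = 40, end = 80)
  full <- choice_likelihood(0.3, 8, a, w)
  # deleting pre-window *choices* must not matter
  cut <- a
  cut$trials$choice[1:39] <- NA
  expect_equal(choice_likelihood(0.3, 8, cut, w), full)
  # but changing pre-window *outcomes* must (they drive the trace)
  flip <- a
  flip$trials$rewarded[1:39] <- ifelse(a$trials$rewarded[1:39] == "A", "B", "A")
  expect_false(isTRUE(all.equal(choice_likelihood(0.3, 8, flip, w), full)))
})

test_that("likelihood rejects invalid inputs", {
  a <- played_schedule(3)
  expect_error(choice_likelihood(0.3, 5, a, list(start = 100, end = 200)),
               "outside")
  expect_error(choice_likelihood(1.5, 5, a, estimation_window("short", "stable")),
               "alpha")
  unplayed <- short_schedule(3)
  expect_error(
    choice_likelihood(0.3, 5, unplayed, estimation_window("short", "stable")),
    "without choices")
})

test_that("near-deterministic matched data attains near-zero loss", {
  s <- short_schedule(31)
  a <- simulate_agent(agent_spec("delta_rule", alpha = 0.999, beta = 1000,
                                 seed = 7), s)
  w <- estimation_window("short", "stable")
  nll <- choice_likelihood(0.999, 50, a, w)
  expect_lt(nll, 0.15 * 61 * log(2))
})

test_that("fitting is deterministic and recovers the optimum", {
  a <- played_schedule(11, alpha = 0.25, beta = 8)
  w <- estimation_window("short", "stable")
  f1 <- fit_learning_rate(a, w)
  f2 <- fit_learning_rate(a, w)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  expect_equal(f1$log_alpha, log(f1$alpha_hat))
  # the optimum beats the truth and nearby perturbations
  truth <- choice_likelihood(0.25, 8, a, w)
  expect_lte(f1$nll, truth + 1e-9)
  for (da in c(-0.05, 0.05)) {
    expect_lte(f1$nll,
               choice_likelihood(f1$alpha_hat + da, f1$beta_hat, a, w) + 1e-6)
  }
})

test_that("window must contain enough recorded choices", {
  s <- short_schedule(3) # no choices at all
  expect_error(fit_learning_rate(s, estimation_window("short", "stable")),
               "at least 30")
})

test_that("minimized loss sits within likelihood-ratio range of the truth", {
  # E[NLL(truth) - NLL(fit)] ~ chi2_2 / 2 = 1 for a 2-parameter fit
  w <- estimation_window("short", "stable")
  gaps <- vapply(1:15, function(i) {
    s <- short_schedule(500 + i)
    a <- simulate_agent(agent_spec("delta_rule", alpha = 0.3, beta = 5,
                                   seed = 600 + i), s)
    choice_likelihood(0.3, 5, a, w) - fit_learning_rate(a, w)$nll
  }, numeric(1))
  expect_true(all(gaps >= 0))
  expect_lt(mean(gaps), 2.5)
})

test_that("median recovered alpha increases with the true alpha", {
  w <- estimation_window("short", "stable")
  med <- vapply(c(0.1, 0.3, 0.6), function(al) {
    stats::median(vapply(1:8, function(i) {
      s <- short_schedule(700 + i)
      a <- simulate_agent(agent_spec("delta_rule", alpha = al, beta = 5,
                                     seed = 800 + i * 7), s)
      fit_learning_rate(a, w)$alpha_hat
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("log learning-rate recovery bias stays within the frozen bound", {
  # regression test over the recovery harness: 50 subjects per true alpha,
  # 61-trial stable window, beta = 5
  w <- estimation_window("short", "stable")
  for (al in c(0.1, 0.2, 0.4)) {
    la <- vapply(1:50, function(i) {
      s <- short_schedule(9000 + i)
      a <- simulate_agent(agent_spec("delta_rule", alpha = al, beta = 5,
                                     seed = 400 + i), s)
      fit_learning_rate(a, w)$log_alpha
    }, numeric(1))
    expect_lt(abs(mean(la) - log(al)), 0.3)
    if (al == 0.1) {
      # median recovered alpha within [.05, .2] for a true alpha of .1
      expect_gt(exp(stats::median(la)), 0.05)
      expect_lt(exp(stats::median(la)), 0.2)
    }
  }
})

test_that("condition contrast aggregates per-subject differences", {
  mk <- function(ls, lv, conv = TRUE) {
    list(stable = structure(list(alpha_hat = exp(ls), log_alpha = ls,
                                 converged = conv), class = "vl_fit_result"),
         volatile = structure(list(alpha_hat = exp(lv), log_alpha = lv,
                                   converged = TRUE), class = "vl_fit_result"))
  }
  fits <- list(a = mk(-2, -2), b = mk(-2, -1), c = mk(-1.5, -0.5))
  cc <- condition_contrast(fits)
  expect_equal(unname(cc$delta), c(0, 1, 1))
  expect_equal(cc$mean, 2 / 3)
  expect_equal(cc$n, 3)
  expect_lt(cc$ci[1], cc$mean)
  expect_gt(cc$ci[2], cc$mean)
  # non-converged subjects are excluded with a message
  fits$d <- mk(-9, 9, conv = FALSE)
  expect_message(cc2 <- condition_contrast(fits), "excluded")
  expect_equal(cc2$n, 3)
  expect_equal(cc2$excluded, "d")
  expect_error(suppressMessages(condition_contrast(list(a = mk(0, 0)))),
               "at least 2")
})
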