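test_that("staircase rules fire exactly as specified", {
  st <- staircase_state(start = 4)
  st$consecutive_correct <- 1L
  st2 <- staircase_update(st, TRUE)
  expect_equal(st2$set_size, 5L)
  expect_equal(st2$consecutive_correct, 0L)

  st <- staircase_state(start = 4)
  st3 <- staircase_update(st, FALSE)
  expect_equal(st3$set_size, 3L)

  # always-correct observer: +1 every 2 trials until the upper bound
  st <- staircase_state(start = 3, bounds = c(2, 12))
  sizes <- integer(24)
  for (i in 1:24) {
    sizes[i] <- st$set_size
    st <- staircase_update(st, TRUE)
  }
  expect_equal(sizes, pmin(3 + (0:23) %/% 2, 12))
  # lower bound clipping
  st <- staircase_state(start = 2, bounds = c(2, 12))
  expect_equal(staircase_update(st, FALSE)$set_size, 2L)
})

test_that("the staircase trace is a pure function of the response sequence", {
  withr::with_seed(17, responses <- runif(80) < 0.7)
  replay <- function() {
    st <- staircase_state()
    out <- integer(length(responses))
    for (i in seq_along(responses)) {
      out[i] <- st$set_size
      st <- staircase_update(st, responses[i])
    }
    out
  }
  expect_identical(replay(), replay())
  # and run_practice's internal fast loop reproduces staircase_update:
  # replay the practice set sizes from its own recorded responses
  ob <- observer_model()
  pr <- run_practice(ob, seed = 33)
  drat <- pr[pr$task == "DRAT", ]
  st <- staircase_state()
  for (i in seq_len(nrow(drat))) {
    expect_equal(drat$set_size[i], st$set_size)
    st <- staircase_update(st, drat$correct[i])
  }
})

test_that("practice sessions have the right shape and are reproducible", {
  ob <- observer_model()
  pr <- run_practice(ob, seed = 5)
  expect_equal(nrow(pr), 8 * 35)
  expect_equal(sum(pr$task == "DRAT"), 6 * 35)
  expect_equal(sum(pr$task == "DRMT"), 2 * 35)
  expect_true(all(pr$set_size >= 2 & pr$set_size <= 12))
  expect_identical(pr, run_practice(ob, seed = 5))
  expect_false(identical(pr$correct, run_practice(ob, seed = 6)$correct))
})

test_that("the staircase settles near the 70.7% convergence point", {
  # Levitt 2-down-1-up: equilibrium where p(correct)^2 = 0.5; the late-trial
  # empirical accuracy should straddle ~0.707 (modest n, generous band)
  accs <- vapply(1:40, function(i) {
    ob <- observer_model(lapse = 0)
    pr <- run_practice(ob, seed = 1000 + i)
    drat <- pr[pr$task == "DRAT" & pr$block >= 4, ]
    mean(drat$correct)
  }, numeric(1))
  expect_true(median(accs) > 0.65 && median(accs) < 0.76)
})

test_that("sigmoid fitting recovers generating parameters and rejects bad input", {
  ob <- observer_model(threshold_s0 = 6, slope_k = 1.2, lapse = 0.02,
                       task_shift = c(DRAT = 0, DRMT = 0))
  trials <- withr::with_seed(9, {
    s <- rep(2:10, length.out = 2000)
    data.frame(set_size = s,
               correct = runif(2000) < predicted_accuracy(ob, s))
  })
  fit <- fit_sigmoid(trials)
  expect_true(fit$converged)
  expect_lt(abs(fit$s0 - 6), 0.3)
  expect_lt(abs(fit$k - 1.2), 0.4)
  # degenerate data paths
  expect_error(fit_sigmoid(data.frame(set_size = rep(5, 50),
                                      correct = rep(c(TRUE, FALSE), 25))),
               "distinct set sizes")
  expect_error(fit_sigmoid(data.frame(set_size = 2:11,
                                      correct = rep(TRUE, 10))),
               "poor behavioral performance")
})

test_that("step-like data drive the fit to the step location with a steep slope", {
  trials <- data.frame(
    set_size = rep(2:9, each = 40),
    correct = rep(rep(c(TRUE, FALSE), c(4, 4)), each = 40)
  )
  fit <- fit_sigmoid(trials)
  # grid-search oracle over (s0, log k)
  nll <- function(s0, k) {
    p <- pmin(pmax(0.5 + 0.48 / (1 + exp(k * (trials$set_size - s0))),
                   1e-9), 1 - 1e-9)
    -sum(ifelse(trials$correct, log(p), log(1 - p)))
  }
  grid <- expand.grid(s0 = seq(3, 8, by = 0.05), k = exp(seq(log(0.3), log(30),
                                                             length.out = 80)))
  grid$nll <- mapply(nll, grid$s0, grid$k)
  best <- grid[which.min(grid$nll), ]
  # with separable step data s0 is identified only up to the inter-step
  # interval: the fitted likelihood must match the grid optimum and the
  # location must sit in the same interval
  expect_lt(abs(fit$s0 - best$s0), 0.5)
  expect_lte(-fit$loglik, best$nll + 1e-3)
  # the step sits between 5 and 6 and the slope is steep
  expect_true(fit$s0 > 5 && fit$s0 < 6)
  expect_gt(fit$k, 3)
})

test_that("difficulty levels follow the threshold rule on the fitted curve", {
  fake_fit <- function(tbl) {
    list(converged = TRUE,
         predicted = function(s) unname(tbl[as.character(s)]))
  }
  tbl <- setNames(c(0.95, 0.93, 0.91, 0.90, 0.84, 0.78, 0.70, 0.65, 0.6, 0.55, 0.5),
                  2:12)
  lv <- difficulty_levels(fake_fit(tbl))
  expect_equal(lv$easy, 6) # largest set size still >= 0.82
  expect_equal(lv$medium, 7)
  expect_equal(lv$hard, 8)
  # flat high curve: Hard would exceed the range
  flat <- setNames(rep(0.95, 11), 2:12)
  expect_error(difficulty_levels(fake_fit(flat)), "range exhausted")
  # nothing meets threshold
  low <- setNames(rep(0.7, 11), 2:12)
  expect_error(difficulty_levels(fake_fit(low)), "no level meets threshold")
  # monotone in the threshold: raising it never increases easy
  easies <- vapply(c(0.7, 0.8, 0.9), function(th) {
    difficulty_levels(fake_fit(tbl), threshold = th)$easy
  }, integer(1))
  expect_true(all(diff(easies) <= 0))
})

test_that("true-curve difficulty levels match the fit rule applied to the observer", {
  ob <- observer_model(threshold_s0 = 6.5, slope_k = 1.2)
  lv <- true_difficulty_levels(ob)
  expect_equal(lv$medium, lv$easy + 1L)
  expect_equal(lv$hard, lv$easy + 2L)
  expect_gte(predicted_accuracy(ob, lv$easy), 0.82)
  expect_lt(predicted_accuracy(ob, lv$easy + 1), 0.82)
})
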