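#' Initialize a 2-down-1-up staircase
#'
#' @param start Starting set size.
#' @param bounds Length-2 integer vector `(min_set, max_set)`.
#' @return An object of class `staircase_state`.
#' @export
staircase_state <- function(start = 4L, bounds = c(2L, 12L)) {
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop_input("bounds must be (min_set, max_set) with min < max")
  }
  if (start < bounds[1] || start > bounds[2]) {
    stop_input("start must lie within bounds")
  }
  structure(
    list(
      set_size = as.integer(start),
      consecutive_correct = 0L,
      bounds = as.integer(bounds),
      history = data.frame(set_size = integer(), correct = logical())
    ),
    class = "staircase_state"
  )
}

#' One 2-down-1-up staircase update
#'
#' Difficulty is the set size: after two consecutive correct responses the
#' set size increases by one (and the counter resets); after any error it
#' decreases by one. Both moves are clipped at the bounds. The procedure
#' converges near the 70.7%-correct point of the psychometric function.
#'
#' @param state A [staircase_state()].
#' @param correct Logical, was the response correct.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  state$history <- rbind(
    state$history,
    data.frame(set_size = state$set_size, correct = correct)
  )
  if (correct) {
    if (state$consecutive_correct == 1L) {
      state$set_size <- min(state$set_size + 1L, state$bounds[2])
      state$consecutive_correct <- 0L
    } else {
      state$consecutive_correct <- 1L
    }
  } else {
    state$set_size <- max(state$set_size - 1L, state$bounds[1])
    state$consecutive_correct <- 0L
  }
  state
}

#' Run the practice session (staircased blocks of both tasks)
#'
#' Six blocks of the alphabetization task followed by two blocks of the
#' maintenance task, 35 trials each, with the set size driven by the
#' 2-down-1-up staircase (one staircase per task, continuing across that
#' task's blocks). Fully reproducible from the seed.
#'
#' @param observer An [observer_model()].
#' @param n_drat_blocks,n_drmt_blocks Block counts (default 6 and 2).
#' @param trials_per_block Trials per block (default 35).
#' @param seed Integer RNG seed.
#' @param start,bounds Staircase start and bounds.
#' @return Data frame with columns `block`, `trial`, `task`, `set_size`,
#'   `correct`, `rt_ms`.
#' @export
run_practice <- function(observer, n_drat_blocks = 6L, n_drmt_blocks = 2L,
                         trials_per_block = 35L, seed = 1L,
                         start = 4L, bounds = c(2L, 12L)) {
  stopifnot(inherits(observer, "observer_model"))
  tasks <- c(rep("DRAT", n_drat_blocks), rep("DRMT", n_drmt_blocks))
  n_total <- length(tasks) * trials_per_block
  with_seed_(seed, {
    block <- integer(n_total); trial <- integer(n_total)
    task_col <- character(n_total); set_size <- integer(n_total)
    correct <- logical(n_total); rt_ms <- numeric(n_total)
    i <- 0L
    for (task in unique(tasks)) {
      ## light-weight staircase loop (same rule as staircase_update, kept
      ## in scalars for speed; equivalence is covered by a replay test)
      s <- as.integer(start); cc <- 0L
      for (b in which(tasks == task)) {
        for (tr in seq_len(trials_per_block)) {
          p <- predicted_accuracy(observer, s, task = task)
          corr <- stats::runif(1) < p
          rt <- rtruncnorm_lower(1, unname(observer$rt_mean_ms[task]),
                                 unname(observer$rt_sd_ms[task]), 200)
          i <- i + 1L
          block[i] <- b; trial[i] <- tr; task_col[i] <- task
          set_size[i] <- s; correct[i] <- corr; rt_ms[i] <- rt
          if (corr) {
            if (cc == 1L) { s <- min(s + 1L, bounds[2]); cc <- 0L }
            else cc <- 1L
          } else {
            s <- max(s - 1L, bounds[1]); cc <- 0L
          }
        }
      }
    }
    data.frame(block = block, trial = trial, task = task_col,
               set_size = set_size, correct = correct, rt_ms = rt_ms)
  })
}

#' Fit the sigmoid psychometric function to staircase trials
#'
#' Maximum-likelihood fit of the binomial logistic
#' `acc(s) = gamma + (1 - gamma - lapse) / (1 + exp(k (s - s0)))` with the
#' guessing rate fixed at 0.5 (binary response) and the lapse fixed by
#' default. Multi-start Nelder-Mead over `(s0, log k)`.
#'
#' @param trials Data frame with columns `set_size` and `correct` (the
#'   caller restricts to alphabetization-task trials).
#' @param gamma Fixed guessing rate.
#' @param lapse Fixed lapse rate.
#' @return An object of class `psychometric_fit` with `s0`, `k`, `gamma`,
#'   `lapse`, `loglik`, `converged`, and a `predicted(s)` function.
#' @export
fit_sigmoid <- function(trials, gamma = 0.5, lapse = 0.02) {
  trials <- as.data.frame(trials)
  if (!all(c("set_size", "correct") %in% names(trials))) {
    stop_input("trials needs columns set_size and correct")
  }
  if (length(unique(trials$set_size)) < 2L) {
    stop_input("need at least 2 distinct set sizes")
  }
  if (all(trials$correct) || !any(trials$correct)) {
    stop_input("poor behavioral performance: responses are all-correct or all-error")
  }
  agg <- stats::aggregate(correct ~ set_size, trials,
                          function(x) c(k = sum(x), n = length(x)))
  s <- agg$set_size
  k_succ <- agg$correct[, "k"]
  n_tr <- agg$correct[, "n"]
  span <- 1 - gamma - lapse
  nll <- function(par) {
    s0 <- par[1]
    k <- exp(par[2])
    p <- gamma + span / (1 + exp(k * (s - s0)))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(k_succ * log(p) + (n_tr - k_succ) * log(1 - p))
  }
  starts <- expand.grid(
    s0 = stats::quantile(trials$set_size, c(0.25, 0.5, 0.75), names = FALSE),
    logk = log(c(0.5, 1.2, 3))
  )
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(as.numeric(starts[i, ]), nll, method = "Nelder-Mead",
                 control = list(maxit = 500))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  s0_hat <- best$par[1]
  k_hat <- exp(best$par[2])
  converged <- best$convergence == 0 && is.finite(best$value)
  ## a fit pinned to the edge of the sampled range signals poor performance
  if (!converged) {
    stop_input("poor behavioral performance: sigmoid fit did not converge")
  }
  predicted <- function(set_size) {
    clip01(gamma + span / (1 + exp(k_hat * (set_size - s0_hat))))
  }
  structure(
    list(s0 = s0_hat, k = k_hat, gamma = gamma, lapse = lapse,
         loglik = -best$value, converged = converged, predicted = predicted),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> s0 = %.2f, k = %.2f (gamma %.2f, lapse %.2f), loglik %.1f\n",
              x$s0, x$k, x$gamma, x$lapse, x$loglik))
  invisible(x)
}

#' Derive the Easy/Medium/Hard set sizes from a psychometric fit
#'
#' Easy is the largest integer set size in range whose predicted accuracy
#' still meets the threshold; Medium and Hard are the next two set sizes
#' down the (decreasing) fitted curve, i.e. `easy + 1` and `easy + 2`.
#' Note the natural-language rule "smallest set size above threshold" is
#' degenerate on a decreasing curve (the smallest set size trivially
#' passes); the implemented reading is the one consistent with Medium and
#' Hard lying lower on the curve.
#'
#' @param fit A [psychometric_fit()] (or any list with a `predicted`
#'   function).
#' @param threshold Accuracy threshold, default 0.82.
#' @param set_range Integer candidate set sizes, default `2:12`.
#' @return An object of class `difficulty_levels` with integer `easy`,
#'   `medium`, `hard`, and the `threshold`.
#' @export
difficulty_levels <- function(fit, threshold = 0.82, set_range = 2:12) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    stop_input("difficulty levels require a converged fit")
  }
  pred <- fit$predicted(set_range)
  ok <- set_range[pred >= threshold]
  if (length(ok) == 0L) stop_input("no level meets threshold")
  easy <- max(ok)
  if (easy + 2L > max(set_range)) stop_input("range exhausted")
  structure(
    list(easy = as.integer(easy), medium = as.integer(easy + 1L),
         hard = as.integer(easy + 2L), threshold = threshold),
    class = "difficulty_levels"
  )
}

#' @export
print.difficulty_levels <- function(x, ...) {
  cat(sprintf("<difficulty_levels> easy %d / medium %d / hard %d (threshold %.2f)\n",
              x$easy, x$medium, x$hard, x$threshold))
  invisible(x)
}

#' Difficulty levels straight from an observer's true psychometric curve
#'
#' Convenience for simulation studies: skips the practice session and fit
#' and applies the threshold rule to the observer's own (noise-free) curve
#' for the alphabetization task.
#'
#' @param observer An [observer_model()].
#' @inheritParams difficulty_levels
#' @return A [difficulty_levels()] object.
#' @export
true_difficulty_levels <- function(observer, threshold = 0.82,
                                   set_range = 2:12) {
  fit <- list(
    converged = TRUE,
    predicted = function(s) predicted_accuracy(observer, s, task = "DRAT")
  )
  difficulty_levels(fit, threshold, set_range)
}
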