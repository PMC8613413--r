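## 20-consonant letter pool (no vowels, no Y): avoids chunkable words.
LETTER_POOL <- c("B", "C", "D", "F", "G", "H", "J", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Z")

#' Randomize a subject into one of the four counterbalancing groups
#'
#' The four groups form the 2 x 2 of target order (which target on the
#' first TMS visit) and stimulation order (active or sham during the first
#' half of the first TMS visit). Within a visit one target is stimulated
#' and both stimulation types occur, one per half; the second visit
#' reverses the stimulation order, so each group's four visit-halves cover
#' {active, sham} x {DLPFC, LPC} exactly once.
#'
#' @param subject_id Character id (hashed into the draw so the assignment
#'   is a pure function of `(subject_id, seed)`).
#' @param seed Integer RNG seed.
#' @return An object of class `randomization_group` with `group_id`,
#'   `target_order` (visits 3 and 4), and `stim_order` (per visit, first
#'   and second half).
#' @export
assign_group <- function(subject_id, seed = 1L) {
  h <- sum(utf8ToInt(as.character(subject_id)) *
             seq_along(utf8ToInt(as.character(subject_id))))
  g <- with_seed_((as.integer(seed) + h) %% (.Machine$integer.max - 1L),
                  sample.int(4L, 1L))
  target_order <- if (g <= 2L) c("DLPFC", "LPC") else c("LPC", "DLPFC")
  first_stim <- if (g %% 2L == 1L) c("active", "sham") else c("sham", "active")
  structure(
    list(
      group_id = g,
      target_order = stats::setNames(target_order, c("visit3", "visit4")),
      stim_order = list(visit3 = first_stim, visit4 = rev(first_stim))
    ),
    class = "randomization_group"
  )
}

## One probe for a letter array: valid probes use the task's ordering rule
## (alphabetical rank for DRAT, original position for DRMT); invalid probes
## use a uniformly drawn wrong position.
make_probe <- function(letters_arr, task, valid) {
  letter <- letters_arr[sample.int(length(letters_arr), 1L)]
  true_pos <- if (task == "DRAT") {
    match(letter, sort(letters_arr))
  } else {
    match(letter, letters_arr)
  }
  pos <- if (valid) {
    true_pos
  } else {
    wrong <- setdiff(seq_along(letters_arr), true_pos)
    wrong[sample.int(length(wrong), 1L)]
  }
  list(letter = letter, position = pos)
}

#' Build the two-visit factorial trial schedule
#'
#' Two visits of 12 blocks x 30 trials (720 trials). Tasks alternate block
#' by block; the rTMS train (25 pulses at 5 Hz) precedes the letter array
#' on every other trial starting with the first; each visit stimulates one
#' target with active rTMS in one half (blocks 1-6 or 7-12) and sham in the
#' other, per the randomization group. Cohort 1 runs everything at the Hard
#' set size; Cohort 2 intermixes Easy and Hard, balanced 15/15 within each
#' block in randomized order. Probe validity is balanced 15/15 per block.
#'
#' @param group A [assign_group()] result.
#' @param cohort 1 or 2.
#' @param levels A [difficulty_levels()] object.
#' @param seed Integer RNG seed.
#' @param letters Generate letter arrays and probes (default `TRUE`; turn
#'   off in large simulation studies where only the factor structure and
#'   set sizes matter).
#' @return Data frame of trial specifications, 720 rows.
#' @export
build_schedule <- function(group, cohort, levels, seed = 1L, letters = TRUE) {
  stopifnot(inherits(group, "randomization_group"),
            cohort %in% c(1L, 2L),
            inherits(levels, "difficulty_levels"))
  if (levels$hard > length(LETTER_POOL)) {
    stop_input("hard set size exceeds the letter pool")
  }
  n_blocks <- 12L
  n_trials <- 30L
  with_seed_(seed, {
    out <- vector("list", 2L * n_blocks)
    for (v in 1:2) {
      visit_name <- c("visit3", "visit4")[v]
      target <- group$target_order[[visit_name]]
      stim_halves <- group$stim_order[[visit_name]]
      first_task <- c("DRAT", "DRMT")[v] # starting task alternates by visit
      for (b in seq_len(n_blocks)) {
        task <- if ((b %% 2L) == 1L) first_task else setdiff(c("DRAT", "DRMT"), first_task)
        stimulation <- if (b <= 6L) stim_halves[1] else stim_halves[2]
        difficulty <- if (cohort == 1L) {
          rep("hard", n_trials)
        } else {
          sample(rep(c("easy", "hard"), each = n_trials / 2L))
        }
        validity <- sample(rep(c("valid", "invalid"), each = n_trials / 2L))
        set_size <- ifelse(difficulty == "easy", levels$easy, levels$hard)
        pulse <- (seq_len(n_trials) %% 2L) == 1L
        df <- data.frame(
          visit = v + 2L, block = b, trial = seq_len(n_trials),
          task = task, target = target, stimulation = stimulation,
          difficulty = difficulty, validity = validity,
          set_size = as.integer(set_size), pulse = pulse,
          letters = NA_character_, probe_letter = NA_character_,
          probe_position = NA_integer_,
          stringsAsFactors = FALSE
        )
        if (letters) {
          for (tr in seq_len(n_trials)) {
            arr <- sample(LETTER_POOL, df$set_size[tr])
            pr <- make_probe(arr, task, df$validity[tr] == "valid")
            df$letters[tr] <- paste(arr, collapse = "")
            df$probe_letter[tr] <- pr$letter
            df$probe_position[tr] <- pr$position
          }
        }
        out[[(v - 1L) * n_blocks + b]] <- df
      }
    }
    sched <- do.call(rbind, out)
    rownames(sched) <- NULL
    sched
  })
}

#' Factorial condition cell counts of a schedule
#'
#' @param schedule A [build_schedule()] data frame.
#' @param factors Factor columns defining the cells; the default crosses
#'   stimulation, target, task, and pulse, plus difficulty whenever the
#'   schedule contains more than one difficulty level.
#' @return Data frame of cell counts (one row per condition).
#' @export
count_conditions <- function(schedule,
                             factors = NULL) {
  if (is.null(factors)) {
    factors <- c("stimulation", "target", "task", "pulse")
    if (length(unique(schedule$difficulty)) > 1L) {
      factors <- c(factors, "difficulty")
    }
  }
  if (!all(factors %in% names(schedule))) stop_input("unknown factor column")
  counts <- as.data.frame(table(schedule[factors]), stringsAsFactors = FALSE)
  names(counts)[ncol(counts)] <- "n"
  counts
}

#' Simulate one subject's full TMS sessions against an observer
#'
#' Vectorized Bernoulli responses from the observer's psychometric curve.
#' The rTMS effect applies only on trials that actually received a train
#' (`pulse` true) under active stimulation. A configurable no-response
#' rate marks trials unanswered.
#'
#' @param schedule A [build_schedule()] data frame.
#' @param observer An [observer_model()].
#' @param seed Integer RNG seed.
#' @param no_response_rate Probability a trial goes unanswered.
#' @return The schedule with `answered`, `correct`, and `rt_ms` columns
#'   (class `trial_table`).
#' @export
simulate_session <- function(schedule, observer, seed = 1L,
                             no_response_rate = 0.02) {
  stopifnot(inherits(observer, "observer_model"))
  if (no_response_rate < 0 || no_response_rate >= 1) {
    stop_input("no_response_rate must be in [0, 1)")
  }
  n <- nrow(schedule)
  with_seed_(seed, {
    stim_ctx <- ifelse(schedule$pulse, schedule$stimulation, "none")
    tgt_ctx <- ifelse(schedule$pulse, schedule$target, "none")
    p <- predicted_accuracy(observer, schedule$set_size, schedule$task,
                            tgt_ctx, stim_ctx)
    correct <- stats::runif(n) < p
    answered <- stats::runif(n) >= no_response_rate
    rt <- rtruncnorm_lower(n, unname(observer$rt_mean_ms[schedule$task]),
                           unname(observer$rt_sd_ms[schedule$task]), 200)
    out <- schedule
    out$answered <- answered
    out$correct <- ifelse(answered, correct, NA)
    out$rt_ms <- ifelse(answered, rt, NA_real_)
    class(out) <- c("trial_table", class(out))
    out
  })
}
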