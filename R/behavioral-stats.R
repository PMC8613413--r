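#' Per-subject condition accuracies from a trial table
#'
#' Drops trials without a TMS train (`pulse` false) and unanswered trials,
#' then averages correctness per subject and condition cell. Cells a
#' subject never saw are reported as `NA` and flagged.
#'
#' @param table Trial table (rows of subject, task, target, stimulation,
#'   ... with `pulse`, `answered`, `correct`).
#' @param by Factor columns defining the condition cells.
#' @param complete When `TRUE` (default), the output covers the full
#'   subject-by-cell grid with `NA` accuracy (and a warning) for cells a
#'   subject never saw; set `FALSE` for designs where subjects legitimately
#'   differ in their factor levels (e.g. cohorts with different difficulty
#'   sets).
#' @return Data frame with one row per subject x cell and an `accuracy`
#'   column; attribute `incomplete_subjects` lists subjects with empty
#'   cells.
#' @export
prepare_accuracy <- function(table,
                             by = c("task", "target", "stimulation"),
                             complete = TRUE) {
  table <- as.data.frame(table)
  need <- c("subject", by, "pulse", "answered", "correct")
  if (!all(need %in% names(table))) {
    stop_input("trial table is missing columns: %s",
               paste(setdiff(need, names(table)), collapse = ", "))
  }
  kept <- table[table$pulse & table$answered, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no pulsed, answered trials left after filtering")
    out <- data.frame()
    attr(out, "incomplete_subjects") <- character()
    return(out)
  }
  agg <- stats::aggregate(kept$correct,
                          by = c(list(subject = kept$subject), kept[by]),
                          FUN = mean)
  names(agg)[ncol(agg)] <- "accuracy"
  if (!complete) {
    out <- agg[do.call(order, agg[c("subject", by)]), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "incomplete_subjects") <- character()
    return(out)
  }
  full <- expand.grid(
    c(list(subject = unique(table$subject)),
      lapply(table[by], function(col) sort(unique(col)))),
    stringsAsFactors = FALSE
  )
  out <- merge(full, agg, all.x = TRUE, sort = TRUE)
  incomplete <- unique(out$subject[is.na(out$accuracy)])
  if (length(incomplete)) {
    warning(sprintf("subject(s) with empty design cells: %s",
                    paste(incomplete, collapse = ", ")))
  }
  attr(out, "incomplete_subjects") <- incomplete
  out
}

#' Test the Valid/Invalid factor and collapse over it
#'
#' Paired t test of per-subject accuracy on valid versus invalid probes;
#' the two validity levels are then averaged per subject (unweighted)
#' regardless of the outcome, with a warning when the test is significant.
#'
#' @param cells Data frame from [prepare_accuracy()] with a `validity`
#'   column among the cell factors.
#' @return List with `t`, `df`, `p`, and `collapsed` (the cells averaged
#'   over validity).
#' @export
validity_collapse <- function(cells) {
  if (!"validity" %in% names(cells)) stop_input("cells must carry a validity factor")
  if (!all(c("valid", "invalid") %in% cells$validity)) {
    stop_input("both validity levels must be present")
  }
  per_subj <- stats::aggregate(accuracy ~ subject + validity, cells, mean)
  wide <- stats::reshape(per_subj, idvar = "subject", timevar = "validity",
                         direction = "wide")
  if (nrow(wide) < 2L) stop_input("paired t test undefined for a single subject")
  d <- wide$accuracy.valid - wide$accuracy.invalid
  n <- length(d)
  if (stats::sd(d) == 0) {
    ## degenerate but well-defined: no difference anywhere
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pval <- if (tstat == 0) 1 else 0
  } else {
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  tt <- list(statistic = tstat, parameter = n - 1, p.value = pval)
  if (tt$p.value < 0.05) {
    warning(sprintf("validity effect is significant (p = %.3g); collapsing anyway",
                    tt$p.value))
  }
  other <- setdiff(names(cells), c("validity", "accuracy"))
  collapsed <- stats::aggregate(
    cells$accuracy, by = cells[other], FUN = mean
  )
  names(collapsed)[ncol(collapsed)] <- "accuracy"
  list(
    t = unname(tt$statistic), df = unname(tt$parameter), p = unname(tt$p.value),
    collapsed = collapsed
  )
}

## Balanced fully-crossed sums of squares via inclusion-exclusion over
## precomputed marginal-mean arrays. `idx` is a named list of integer level
## codes per variable, `mu` a cache of tapply mean arrays keyed by the
## sorted subset name, `grand` the grand mean, `n_total` the row count.
ss_engine <- function(y, idx) {
  n_total <- length(y)
  grand <- mean(y)
  n_levels <- vapply(idx, max, integer(1))
  mu <- new.env(parent = emptyenv())
  subset_key <- function(u) paste(sort(u), collapse = "|")
  mean_array <- function(u) {
    key <- subset_key(u)
    if (!is.null(mu[[key]])) return(mu[[key]])
    arr <- tapply(y, idx[sort(u)], mean)
    mu[[key]] <- arr
    arr
  }
  ss_for_term <- function(term) {
    term <- sort(term)
    cells <- as.matrix(expand.grid(lapply(n_levels[term], seq_len)))
    colnames(cells) <- term
    eff <- rep(grand * (-1)^length(term), nrow(cells))
    for (k in seq_along(term)) {
      for (u in utils::combn(term, k, simplify = FALSE)) {
        sgn <- (-1)^(length(term) - length(u))
        arr <- mean_array(u)
        vals <- if (length(u) == 1L) {
          arr[cells[, u]]
        } else {
          arr[cells[, sort(u), drop = FALSE]]
        }
        eff <- eff + sgn * vals
      }
    }
    reps <- n_total / nrow(cells)
    reps * sum(eff^2)
  }
  ss_for_term
}

#' Repeated-measures ANOVA for a fully-crossed within-subject design
#'
#' Standard balanced within-subject sums-of-squares decomposition: every
#' effect (main effects and all interactions of the within factors) is
#' tested against its own interaction with subjects. Reports F, degrees of
#' freedom, p, and both eta-squared flavors — classical
#' (`SS_effect / SS_total`) and partial
#' (`SS_effect / (SS_effect + SS_error)`).
#'
#' @param cells Long data frame with a `subject` column, the factor
#'   columns, and the response; one observation per subject x cell (cells
#'   are averaged first if replicated).
#' @param factors Character vector of within-subject factor columns.
#' @param dv Response column name, default `"accuracy"`.
#' @return An `rm_anova` object: data frame of effects plus `ss_total` and
#'   `ss_check` (decomposition-conservation residual) attributes.
#' @export
rm_anova <- function(cells, factors, dv = "accuracy") {
  cells <- as.data.frame(cells)
  need <- c("subject", factors, dv)
  if (!all(need %in% names(cells))) stop_input("missing columns for rm_anova")
  if (any(is.na(cells[[dv]]))) {
    drop_subj <- unique(cells$subject[is.na(cells[[dv]])])
    warning(sprintf("dropping subject(s) with missing cells: %s",
                    paste(drop_subj, collapse = ", ")))
    cells <- cells[!(cells$subject %in% drop_subj), , drop = FALSE]
  }
  ## average any replicates so the design has one observation per cell
  agg <- stats::aggregate(cells[[dv]],
                          by = c(list(subject = cells$subject), cells[factors]),
                          FUN = mean)
  names(agg)[ncol(agg)] <- dv
  n_subj <- length(unique(agg$subject))
  if (n_subj < 3L) stop_input("need at least 3 subjects")
  n_levels <- vapply(factors, function(f) length(unique(agg[[f]])), integer(1))
  if (nrow(agg) != n_subj * prod(n_levels)) {
    stop_input("design is not fully crossed and balanced")
  }
  grand <- mean(agg[[dv]])
  ss_total <- sum((agg[[dv]] - grand)^2)
  idx <- lapply(c(list(subject = agg$subject), agg[factors]), function(v) {
    as.integer(factor(v))
  })
  ss_of <- ss_engine(agg[[dv]], idx)
  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(effects, function(term) {
    ss_e <- ss_of(term)
    ss_err <- ss_of(c("subject", term))
    df_e <- prod(n_levels[term] - 1L)
    df_err <- df_e * (n_subj - 1L)
    ms_e <- ss_e / df_e
    ms_err <- ss_err / df_err
    f <- if (ms_err > 0) ms_e / ms_err else ifelse(ms_e > 0, Inf, 0)
    data.frame(
      effect = paste(term, collapse = ":"),
      df1 = df_e, df2 = df_err,
      ss = ss_e, ss_error = ss_err,
      F = f,
      p = stats::pf(f, df_e, df_err, lower.tail = FALSE),
      eta2_classical = ss_e / ss_total,
      eta2_partial = ss_e / (ss_e + ss_err),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  ss_subject <- ss_of("subject")
  ss_accounted <- ss_subject + sum(tab$ss) + sum(tab$ss_error)
  structure(tab,
            ss_total = ss_total,
            ss_subject = ss_subject,
            ss_check = ss_total - ss_accounted,
            n_subjects = n_subj,
            class = c("rm_anova", "data.frame"))
}

#' Bonferroni-corrected paired post-hoc contrasts
#'
#' Each contrast compares two condition cells within subjects by a paired t
#' test; p values are multiplied by the family size and capped at 1.
#'
#' @param cells Long data frame from [prepare_accuracy()].
#' @param contrasts List of contrasts, each a list with elements `a` and
#'   `b`: named character vectors of factor = level filters.
#' @param dv Response column.
#' @param m Family size for the correction (default the number of
#'   contrasts).
#' @return Data frame with one row per contrast: t, df, raw and adjusted p.
#' @export
posthoc_bonferroni <- function(cells, contrasts, dv = "accuracy",
                               m = length(contrasts)) {
  if (length(contrasts) == 0L) stop_input("empty contrast family")
  cell_mean <- function(filt) {
    sel <- rep(TRUE, nrow(cells))
    for (f in names(filt)) sel <- sel & cells[[f]] == filt[[f]]
    sub <- cells[sel, , drop = FALSE]
    if (nrow(sub) == 0L) stop_input("contrast references an empty cell")
    out <- stats::aggregate(sub[[dv]], by = list(subject = sub$subject), FUN = mean)
    stats::setNames(out$x, out$subject)
  }
  rows <- lapply(seq_along(contrasts), function(i) {
    ctr <- contrasts[[i]]
    a <- cell_mean(ctr$a)
    b <- cell_mean(ctr$b)
    subj <- intersect(names(a), names(b))
    tt <- stats::t.test(a[subj], b[subj], paired = TRUE)
    data.frame(
      contrast = names(contrasts)[i] %||% paste0("contrast_", i),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value,
      p_bonferroni = min(1, m * tt$p.value),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-subject rTMS effect as percent change from sham
#'
#' The combined performance measure: accuracy averaged across the two
#' tasks, restricted to Hard trials (when a difficulty column is present),
#' then `100 * (active - sham) / sham` per subject, reported separately
#' per stimulation target.
#'
#' @param cells Long data frame with subject, task, target, stimulation
#'   (and optionally difficulty) cell accuracies.
#' @param dv Response column.
#' @return Data frame with columns `subject`, `target`, `acc_active`,
#'   `acc_sham`, `effect_pct`.
#' @export
rtms_effect <- function(cells, dv = "accuracy") {
  cells <- as.data.frame(cells)
  if ("difficulty" %in% names(cells)) {
    cells <- cells[cells$difficulty == "hard", , drop = FALSE]
  }
  need <- c("subject", "task", "target", "stimulation", dv)
  if (!all(need %in% names(cells))) stop_input("missing columns for rtms_effect")
  ## average across tasks first, then form the active/sham ratio
  comb <- stats::aggregate(
    cells[[dv]],
    by = list(subject = cells$subject, target = cells$target,
              stimulation = cells$stimulation),
    FUN = mean
  )
  wide <- stats::reshape(comb, idvar = c("subject", "target"),
                         timevar = "stimulation", direction = "wide")
  names(wide) <- sub("^x\\.", "acc_", names(wide))
  if (!all(c("acc_active", "acc_sham") %in% names(wide))) {
    stop_input("both active and sham cells must be present")
  }
  if (any(wide$acc_sham <= 0, na.rm = TRUE)) stop_input("sham accuracy is zero")
  wide$effect_pct <- 100 * (wide$acc_active - wide$acc_sham) / wide$acc_sham
  wide[order(wide$subject, wide$target), , drop = FALSE]
}

#' Paired Cohen's d for the rTMS effect per task and target
#'
#' `d = mean(active - sham) / sd(active - sham)` across subjects (sample
#' standard deviation), one d per (task, target) condition.
#'
#' @param cells Long data frame of subject x task x target x stimulation
#'   accuracies.
#' @param dv Response column.
#' @return Data frame with columns `task`, `target`, `n`, `d`.
#' @export
cohens_d_paired <- function(cells, dv = "accuracy") {
  comb <- stats::aggregate(
    cells[[dv]],
    by = list(subject = cells$subject, task = cells$task,
              target = cells$target, stimulation = cells$stimulation),
    FUN = mean
  )
  wide <- stats::reshape(comb, idvar = c("subject", "task", "target"),
                         timevar = "stimulation", direction = "wide")
  rows <- by(wide, list(wide$task, wide$target), function(g) {
    diffs <- g$x.active - g$x.sham
    sdd <- stats::sd(diffs)
    if (!is.finite(sdd) || sdd == 0) {
      stop_input("zero variance of paired differences")
    }
    data.frame(task = g$task[1], target = g$target[1],
               n = nrow(g), d = mean(diffs) / sdd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, as.list(rows))
  rownames(out) <- NULL
  out[order(out$task, out$target), , drop = FALSE]
}

#' Correlate the rTMS effect with dosing and targeting covariates
#'
#' Pearson correlation (with two-sided p) between the per-subject rTMS
#' effect and each covariate, computed separately per stimulation target.
#'
#' @param effects Data frame from [rtms_effect()] (`subject`, `target`,
#'   `effect_pct`).
#' @param covariates Data frame with `subject`, `target`, and one column
#'   per covariate (e.g. amplitude %MSO, amplitude %rMT, z score at the
#'   target, modal controllability).
#' @return Data frame with columns `target`, `covariate`, `n`, `r`, `p`.
#' @export
correlate_covariates <- function(effects, covariates) {
  cov_cols <- setdiff(names(covariates), c("subject", "target"))
  if (length(cov_cols) == 0L) stop_input("no covariate columns")
  merged <- merge(effects[c("subject", "target", "effect_pct")], covariates,
                  by = c("subject", "target"))
  rows <- list()
  for (tgt in sort(unique(merged$target))) {
    sub <- merged[merged$target == tgt, , drop = FALSE]
    for (cv in cov_cols) {
      x <- sub[[cv]]
      y <- sub$effect_pct
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4L) stop_input("need at least 4 paired observations")
      if (stats::sd(x[ok]) == 0) stop_input("constant covariate: %s", cv)
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        target = tgt, covariate = cv, n = sum(ok),
        r = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Summarize the blinding ratings
#'
#' Ratings are integers in [-10, 10] (negative = perceived disruption,
#' positive = perceived enhancement). Returns the per-visit histogram and
#' flags subjects whose rating differed between their active and sham
#' halves within a visit.
#'
#' @param ratings Data frame with columns `subject`, `visit`,
#'   `stimulation` (`"active"`/`"sham"`), `rating`.
#' @return List with `histogram` (counts per rating per visit) and
#'   `flagged` (per-subject active/sham rating deltas where nonzero).
#' @export
blinding_summary <- function(ratings) {
  need <- c("subject", "visit", "stimulation", "rating")
  if (!all(need %in% names(ratings))) stop_input("malformed ratings table")
  if (any(ratings$rating < -10 | ratings$rating > 10)) {
    stop_input("ratings must lie in [-10, 10]")
  }
  histogram <- as.data.frame(table(rating = ratings$rating,
                                   visit = ratings$visit),
                             stringsAsFactors = FALSE)
  names(histogram)[3] <- "n"
  histogram$rating <- as.integer(histogram$rating)
  wide <- stats::reshape(
    stats::aggregate(rating ~ subject + visit + stimulation, ratings, mean),
    idvar = c("subject", "visit"), timevar = "stimulation",
    direction = "wide"
  )
  wide$delta <- wide$rating.active - wide$rating.sham
  flagged <- wide[!is.na(wide$delta) & wide$delta != 0,
                  c("subject", "visit", "rating.active", "rating.sham", "delta")]
  rownames(flagged) <- NULL
  list(histogram = histogram, flagged = flagged)
}
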