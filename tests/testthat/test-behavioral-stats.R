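make_trials <- function(rows) {
  defaults <- list(subject = "s1", task = "DRAT", target = "DLPFC",
                   stimulation = "active", pulse = TRUE, answered = TRUE,
                   correct = TRUE)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(defaults, r))
  }))
}

test_that("accuracy preparation filters unpulsed and unanswered trials", {
  tt <- make_trials(c(
    rep(list(list()), 7),
    rep(list(list(correct = FALSE)), 3)
  ))
  cells <- prepare_accuracy(tt)
  expect_equal(cells$accuracy, 0.7)
  # a hand-built mixed table matches hand computation
  tt2 <- make_trials(list(
    list(correct = TRUE), list(correct = FALSE),
    list(correct = TRUE, answered = FALSE),  # dropped
    list(correct = TRUE, pulse = FALSE),     # dropped
    list(stimulation = "sham", correct = FALSE),
    list(stimulation = "sham", correct = TRUE),
    list(stimulation = "sham", correct = TRUE)
  ))
  cells2 <- prepare_accuracy(tt2)
  expect_equal(cells2$accuracy[cells2$stimulation == "active"], 0.5)
  expect_equal(cells2$accuracy[cells2$stimulation == "sham"], 2 / 3)
  # all pulse = FALSE: warning and empty result
  tt3 <- make_trials(list(list(pulse = FALSE)))
  expect_warning(out <- prepare_accuracy(tt3), "no pulsed")
  expect_equal(nrow(out), 0)
  # a subject missing a whole cell is flagged
  tt4 <- rbind(tt2, within(tt2, subject <- "s2")[1:2, ])
  expect_warning(cells4 <- prepare_accuracy(tt4), "empty design cells")
  expect_equal(attr(cells4, "incomplete_subjects"), "s2")
})

test_that("validity collapse reports the paired t and averages the levels", {
  cells <- expand.grid(subject = sprintf("s%d", 1:20),
                       validity = c("valid", "invalid"),
                       stringsAsFactors = FALSE)
  cells$accuracy <- 0.8
  res <- validity_collapse(cells)
  expect_equal(res$t, 0) # identical valid/invalid accuracies
  expect_equal(res$collapsed$accuracy, rep(0.8, 20))

  withr::with_seed(4, {
    cells$accuracy <- 0.8 + ifelse(cells$validity == "invalid", 0.1, 0) +
      rnorm(nrow(cells), sd = 0.01)
  })
  expect_warning(res2 <- validity_collapse(cells), "significant")
  expect_gt(abs(res2$t), 10)
  # paired-t closed form oracle
  wide <- reshape(cells, idvar = "subject", timevar = "validity",
                  direction = "wide")
  d <- wide$accuracy.valid - wide$accuracy.invalid
  expect_equal(res2$t, mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  expect_error(validity_collapse(cells[cells$subject == "s1", ]),
               "single subject")
})

test_that("rm_anova: null case, F = t^2 identity, and SS conservation", {
  # all condition means equal per subject: every F is ~0
  cells <- make_cells(n_subj = 8, noise = 0)
  cells$accuracy <- rep(seq(0.6, 0.95, length.out = 8), 8) # subject offsets only
  tab <- rm_anova(cells, factors = c("task", "target", "stimulation"))
  expect_true(all(tab$ss < 1e-20))

  # one two-level factor: F equals the squared paired t
  cells2 <- make_cells(n_subj = 12, seed = 5, task_shift = 0.05)
  pertask <- aggregate(accuracy ~ subject + task, cells2, mean)
  wide <- reshape(pertask, idvar = "subject", timevar = "task",
                  direction = "wide")
  tt <- t.test(wide$accuracy.DRAT, wide$accuracy.DRMT, paired = TRUE)
  tab2 <- rm_anova(cells2, factors = "task")
  expect_equal(tab2$F[tab2$effect == "task"], unname(tt$statistic)^2,
               tolerance = 1e-8)
  expect_equal(tab2$p[tab2$effect == "task"], tt$p.value, tolerance = 1e-8)

  # decomposition conservation on the full factorial
  tab3 <- rm_anova(cells2, factors = c("task", "target", "stimulation"))
  expect_lt(abs(attr(tab3, "ss_check")), 1e-8)
  expect_true(all(tab3$eta2_partial >= 0 & tab3$eta2_partial <= 1))
  expect_true(all(tab3$eta2_classical >= 0 & tab3$eta2_classical <= 1))
  expect_error(rm_anova(cells2[cells2$subject %in% c("s01", "s02"), ],
                        factors = "task"), "3 subjects")
})

test_that("rm_anova reproduces stats::aov on a random balanced design", {
  cells <- make_cells(n_subj = 9, seed = 31, task_shift = 0.04,
                      stim_shift = 0.02, noise = 0.06)
  tab <- rm_anova(cells, factors = c("task", "target", "stimulation"))
  aovfit <- summary(aov(
    accuracy ~ task * target * stimulation +
      Error(subject / (task * target * stimulation)),
    data = transform(cells, subject = factor(subject), task = factor(task),
                     target = factor(target),
                     stimulation = factor(stimulation))
  ))
  for (stratum in names(aovfit)) {
    s <- aovfit[[stratum]][[1]]
    eff <- trimws(rownames(s))
    for (i in seq_along(eff)) {
      if (eff[i] %in% tab$effect) {
        expect_equal(tab$F[tab$effect == eff[i]], s[i, "F value"],
                     tolerance = 1e-8)
        expect_equal(tab$p[tab$effect == eff[i]], s[i, "Pr(>F)"],
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("subjects with missing cells are dropped listwise with a warning", {
  cells <- make_cells(n_subj = 6, seed = 2)
  cells$accuracy[1] <- NA
  expect_warning(tab <- rm_anova(cells, factors = c("task", "target")),
                 "dropping subject")
  expect_equal(attr(tab, "n_subjects"), 5)
})

test_that("Bonferroni post-hocs multiply and cap the raw p", {
  cells <- make_cells(n_subj = 10, seed = 8, task_shift = 0.08)
  fam <- list(
    task_at_active = list(a = c(task = "DRAT", stimulation = "active"),
                          b = c(task = "DRMT", stimulation = "active")),
    stim_at_drat = list(a = c(task = "DRAT", stimulation = "active"),
                        b = c(task = "DRAT", stimulation = "sham"))
  )
  res <- posthoc_bonferroni(cells, fam)
  expect_equal(res$p_bonferroni, pmin(1, 2 * res$p_raw))
  # m = 1 leaves p unchanged
  res1 <- posthoc_bonferroni(cells, fam[1])
  expect_equal(res1$p_bonferroni, res1$p_raw)
  # manual oracle for one contrast
  a <- aggregate(accuracy ~ subject, cells[cells$task == "DRAT" &
                                             cells$stimulation == "active", ],
                 mean)
  b <- aggregate(accuracy ~ subject, cells[cells$task == "DRMT" &
                                             cells$stimulation == "active", ],
                 mean)
  tt <- t.test(a$accuracy, b$accuracy, paired = TRUE)
  expect_equal(res$t[1], unname(tt$statistic), tolerance = 1e-12)
  # capping
  expect_equal(min(1, 4 * 0.3), 1)
  expect_error(posthoc_bonferroni(cells, list()), "empty")
})

test_that("the rTMS percent-change effect does the arithmetic and the cohort merge", {
  cells <- expand.grid(subject = "s1", task = c("DRAT", "DRMT"),
                       target = "DLPFC", stimulation = c("active", "sham"),
                       stringsAsFactors = FALSE)
  cells$accuracy <- ifelse(cells$stimulation == "active", 0.84, 0.80)
  eff <- rtms_effect(cells)
  expect_equal(eff$effect_pct, 5)
  # active == sham: zero effect
  cells$accuracy <- 0.8
  expect_equal(rtms_effect(cells)$effect_pct, 0)
  # cohort merge bookkeeping: 15 hard-only + 14 easy/hard subjects give one
  # 29-row vector per target
  c1 <- do.call(rbind, lapply(1:15, function(i) {
    g <- make_cells(n_subj = 1, seed = i)
    g$subject <- sprintf("c1-%02d", i)
    g$difficulty <- "hard"
    g
  }))
  c2 <- do.call(rbind, lapply(1:14, function(i) {
    g <- rbind(transform(make_cells(n_subj = 1, seed = 100 + i),
                         difficulty = "easy"),
               transform(make_cells(n_subj = 1, seed = 200 + i),
                         difficulty = "hard"))
    g$subject <- sprintf("c2-%02d", i)
    g
  }))
  eff_all <- rtms_effect(rbind(c1, c2))
  expect_equal(nrow(eff_all), 29 * 2) # two targets per subject
  expect_equal(sum(eff_all$target == "DLPFC"), 29)
  # sham accuracy of zero is rejected
  bad <- cells
  bad$accuracy <- ifelse(bad$stimulation == "sham", 0, 0.5)
  expect_error(rtms_effect(bad), "sham accuracy")
})

test_that("paired Cohen's d matches its construction and flips with sign", {
  cells <- make_cells(n_subj = 25, seed = 12, stim_shift = 0.05, noise = 0.05)
  d <- cohens_d_paired(cells)
  expect_equal(nrow(d), 4)
  # construction: shift of +1 noise-SD of the paired difference
  wide_sd <- sqrt(2) * 0.05 # var of difference of two iid noise draws
  expect_true(all(abs(d$d - 0.05 / wide_sd) < 0.45))
  # antisymmetry
  flipped <- cells
  flipped$stimulation <- ifelse(cells$stimulation == "active", "sham", "active")
  d2 <- cohens_d_paired(flipped)
  expect_equal(d$d, -d2$d, tolerance = 1e-12)
  # zero variance errors
  const <- make_cells(n_subj = 5, noise = 0)
  expect_error(cohens_d_paired(const), "zero variance")
})

test_that("covariate correlations reproduce the textbook formula", {
  eff <- data.frame(subject = sprintf("s%d", 1:5), target = "DLPFC",
                    effect_pct = c(2, -1, 4, 0, 3))
  cov <- data.frame(subject = sprintf("s%d", 1:5), target = "DLPFC",
                    amplitude = c(40, 55, 35, 50, 42))
  res <- correlate_covariates(eff, cov)
  r_hand <- sum((eff$effect_pct - mean(eff$effect_pct)) *
                  (cov$amplitude - mean(cov$amplitude))) /
    sqrt(sum((eff$effect_pct - mean(eff$effect_pct))^2) *
           sum((cov$amplitude - mean(cov$amplitude))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  # perfect correlation
  cov2 <- data.frame(subject = eff$subject, target = "DLPFC",
                     same = eff$effect_pct)
  expect_equal(correlate_covariates(eff, cov2)$r, 1)
  # constant covariate errors
  cov3 <- data.frame(subject = eff$subject, target = "DLPFC", flat = 1)
  expect_error(correlate_covariates(eff, cov3), "constant covariate")
  expect_error(correlate_covariates(eff[1:3, ], cov[1:3, ]), "at least 4")
})

test_that("the null distribution of r at n = 29 has the right 5% band", {
  # |r| >= 0.367 is the two-sided 5% point for n = 29
  withr::with_seed(77, {
    rs <- vapply(1:3000, function(i) cor(rnorm(29), rnorm(29)), numeric(1))
  })
  expect_lt(abs(mean(rs)), 0.01)
  expect_true(abs(mean(abs(rs) >= 0.367) - 0.05) < 0.015)
})

test_that("blinding summaries histogram ratings and flag active/sham deltas", {
  ratings <- expand.grid(subject = sprintf("s%d", 1:5), visit = c(3, 4),
                         stimulation = c("active", "sham"),
                         stringsAsFactors = FALSE)
  ratings$rating <- 0
  res <- blinding_summary(ratings)
  expect_equal(nrow(res$flagged), 0)
  expect_true(all(res$histogram$rating == 0))
  # one subject moves from -5 (sham) to -2 (active) on a visit
  ratings$rating[ratings$subject == "s1" & ratings$visit == 3 &
                   ratings$stimulation == "sham"] <- -5
  ratings$rating[ratings$subject == "s1" & ratings$visit == 3 &
                   ratings$stimulation == "active"] <- -2
  res2 <- blinding_summary(ratings)
  expect_equal(nrow(res2$flagged), 1)
  expect_equal(res2$flagged$delta, 3)
  ratings$rating[1] <- 11
  expect_error(blinding_summary(ratings), "-10, 10")
})
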