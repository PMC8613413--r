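#' Pipeline configuration
#'
#' Collects every tunable of the targeting, dosing, calibration, and
#' scheduling stages. Defaults are the study's operating values: reference
#' exposure 56 V/m, activation threshold z > 1.96, 25% activation gate,
#' 82% accuracy threshold, 25-pulse 5 Hz trains, 130 %rMT safety
#' guideline.
#'
#' @param e_ref Reference E100 exposure in V/m.
#' @param z_thresh Activation z threshold.
#' @param activation_gate Minimum activated-voxel fraction.
#' @param accuracy_threshold Psychometric threshold for the Easy level.
#' @param staircase_start,staircase_bounds Staircase start and bounds.
#' @param pulses_per_train,train_rate_hz rTMS train description (carried
#'   as metadata; the schedule realizes it as the per-trial pulse flag).
#' @param safety_limit_pct_rmt Safety guideline limit in %rMT.
#' @param test_drive Calibration test drive in %MSO.
#' @param effect_size Activation effect size (DRAT-vs-DRMT beta difference
#'   in noise-SD units) used by the synthetic activation stage.
#' @param no_response_rate Probability a simulated trial goes unanswered.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(e_ref = 56, z_thresh = 1.96,
                            activation_gate = 0.25,
                            accuracy_threshold = 0.82,
                            staircase_start = 4L,
                            staircase_bounds = c(2L, 12L),
                            pulses_per_train = 25L, train_rate_hz = 5,
                            safety_limit_pct_rmt = 130,
                            test_drive = 50, effect_size = 5,
                            no_response_rate = 0.02) {
  cfg <- list(
    e_ref = e_ref, z_thresh = z_thresh, activation_gate = activation_gate,
    accuracy_threshold = accuracy_threshold,
    staircase_start = staircase_start, staircase_bounds = staircase_bounds,
    pulses_per_train = pulses_per_train, train_rate_hz = train_rate_hz,
    safety_limit_pct_rmt = safety_limit_pct_rmt,
    test_drive = test_drive, effect_size = effect_size,
    no_response_rate = no_response_rate
  )
  stopifnot(e_ref > 0, z_thresh > 0, activation_gate >= 0,
            accuracy_threshold > 0, accuracy_threshold < 1,
            pulses_per_train > 0, train_rate_hz > 0)
  structure(cfg, class = "pipeline_config")
}

## Default functional-run block design: six alternating task blocks of six
## trials (~16.5 s at 2 s TR), repeated to fill the run.
default_block_design <- function(tr_s = 2, n_volumes = 150L,
                                 block_s = 24, rest_s = 6) {
  onsets <- seq(rest_s, tr_s * n_volumes - block_s, by = block_s + rest_s)
  cond <- rep(c("DRAT", "DRMT"), length.out = length(onsets))
  block_design(tr_s, n_volumes,
               data.frame(condition = cond, onset_s = onsets,
                          duration_s = block_s))
}

#' Run one subject through targeting, dosing, and task calibration
#'
#' Activation GLM on synthetic BOLD, modal controllability, the
#' gate-then-max-phi target decision for both regions, stimulation plans,
#' and the staircase practice with sigmoid difficulty fitting.
#'
#' @param bundle A [generate_subject()] bundle.
#' @param config A [pipeline_config()].
#' @param design Optional [block_design()] override.
#' @return List with per-stage artifacts for the subject.
#' @export
run_subject_stages <- function(bundle, config = pipeline_config(),
                               design = default_block_design()) {
  conn <- bundle$connectome
  rois <- bundle$roi_set
  profile <- modal_controllability(conn)

  ## activation: the true DRAT-preferring regions are a random half of the
  ## candidates, seeded per subject
  candidates <- c(rois$frontal_labels, rois$parietal_labels)
  active <- with_seed_(bundle$activation_seed, {
    c(sample(rois$frontal_labels, ceiling(length(rois$frontal_labels) / 2)),
      sample(rois$parietal_labels, ceiling(length(rois$parietal_labels) / 2)))
  })
  bold <- generate_activation(rois$rois, active, config$effect_size, design,
                              seed = bundle$activation_seed)
  zm <- fit_glm_contrast(bold, build_design_matrix(design))
  fractions_all <- roi_activation_fraction(zm, rois$rois, config$z_thresh)

  decisions <- list()
  plans <- list()
  for (region in c("frontal", "parietal")) {
    cand <- candidate_controllability(profile, conn, region)
    phis <- stats::setNames(cand$phi, cand$label)
    label_ids <- vapply(names(phis), function(nm) {
      as.integer(names(which(rois$rois$label_names == nm)))
    }, integer(1))
    fractions <- stats::setNames(fractions_all[as.character(label_ids)],
                                 names(phis))
    dec <- select_target(fractions, phis, gate = config$activation_gate,
                         region = region)
    decisions[[region]] <- dec
    plans[[region]] <- plan_stimulation(
      bundle, dec, e_ref = config$e_ref, test_drive = config$test_drive,
      safety_limit_pct_rmt = config$safety_limit_pct_rmt
    )
  }

  practice <- run_practice(bundle$observer, seed = bundle$practice_seed,
                           start = config$staircase_start,
                           bounds = config$staircase_bounds)
  fit <- fit_sigmoid(practice[practice$task == "DRAT", ])
  levels <- difficulty_levels(fit, config$accuracy_threshold,
                              config$staircase_bounds[1]:config$staircase_bounds[2])

  ## covariates for the exploratory correlations
  covariates <- do.call(rbind, lapply(names(plans), function(region) {
    plan <- plans[[region]]
    dec <- decisions[[region]]
    label_id <- as.integer(names(which(rois$rois$label_names == dec$chosen_label)))
    zvals <- zm$values[rois$rois$labels == label_id]
    data.frame(
      subject = bundle$subject_id,
      target = c(frontal = "DLPFC", parietal = "LPC")[region],
      amplitude_pct_mso = plan$amplitude_pct_mso,
      amplitude_pct_rmt = plan$amplitude_pct_rmt_exact,
      z_at_target = mean(zvals, na.rm = TRUE),
      modal_controllability = dec$phi,
      stringsAsFactors = FALSE
    )
  }))

  list(
    subject_id = bundle$subject_id,
    cohort = bundle$cohort,
    controllability = profile,
    zmap = zm,
    fractions = fractions_all,
    decisions = decisions,
    plans = plans,
    fit = fit,
    levels = levels,
    covariates = covariates
  )
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, runs every subject through targeting,
#' dosing, and task calibration, simulates both TMS visits, and performs
#' the planned and exploratory behavioral analyses. Every artifact carries
#' the config, the seed, and a content hash; reruns with the same inputs
#' are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param n_subjects Cohort size (ignored when `cohort` is supplied).
#' @param seed Master seed.
#' @param cohort Optional pre-built list of [generate_subject()] bundles.
#' @param effect_map Injected rTMS effect for the synthetic observers.
#' @return An object of class `study_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), n_subjects = 8L,
                         seed = 1L, cohort = NULL, effect_map = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(n_subjects, seed = seed, effect_map = effect_map)
  }
  stage_results <- lapply(cohort, function(bundle) {
    tryCatch(
      run_subject_stages(bundle, config),
      error = function(e) {
        stop_input("stage failure for %s: %s", bundle$subject_id,
                   conditionMessage(e))
      }
    )
  })
  trial_tables <- lapply(seq_along(cohort), function(i) {
    bundle <- cohort[[i]]
    group <- assign_group(bundle$subject_id, seed = bundle$rng_seed)
    sched <- build_schedule(group, bundle$cohort, stage_results[[i]]$levels,
                            seed = bundle$session_seed)
    tt <- simulate_session(sched, bundle$observer, seed = bundle$session_seed,
                           no_response_rate = config$no_response_rate)
    tt$subject <- bundle$subject_id
    tt$cohort <- bundle$cohort
    tt
  })
  trials <- do.call(rbind, trial_tables)

  cells_validity <- prepare_accuracy(
    trials, by = c("task", "target", "stimulation", "difficulty", "validity"),
    complete = FALSE # cohorts legitimately differ in their difficulty levels
  )
  collapse <- validity_collapse(cells_validity)
  cells <- collapse$collapsed
  anova_tab <- rm_anova(cells[cells$difficulty == "hard", , drop = FALSE],
                        factors = c("task", "target", "stimulation"))
  effects <- rtms_effect(cells)
  dvals <- cohens_d_paired(cells[cells$difficulty == "hard", , drop = FALSE])
  covariates <- do.call(rbind, lapply(stage_results, `[[`, "covariates"))
  correlations <- correlate_covariates(effects, covariates)

  core <- list(
    trials = trials,
    validity_t = collapse[c("t", "df", "p")],
    anova = as.data.frame(anova_tab),
    rtms_effects = effects,
    cohens_d = dvals,
    correlations = correlations,
    stim_plans = do.call(rbind, lapply(stage_results, function(sr) {
      do.call(rbind, lapply(sr$plans, function(p) {
        data.frame(subject = p$subject_id, region = p$region,
                   label = p$target_label,
                   amplitude_pct_mso = p$amplitude_pct_mso,
                   amplitude_pct_rmt = p$amplitude_pct_rmt,
                   achieved_e100 = p$achieved_e100,
                   flags = paste(p$safety_flags, collapse = "; "),
                   stringsAsFactors = FALSE)
      }))
    })),
    difficulty = do.call(rbind, lapply(stage_results, function(sr) {
      data.frame(subject = sr$subject_id, easy = sr$levels$easy,
                 medium = sr$levels$medium, hard = sr$levels$hard)
    }))
  )
  structure(
    list(
      provenance = list(
        seed = seed,
        config = unclass(config),
        n_subjects = length(cohort),
        hash = content_hash(core)
      ),
      results = core,
      stages = stage_results
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d subjects, seed %s, hash %s\n",
    x$provenance$n_subjects, x$provenance$seed, x$provenance$hash
  ))
  sig <- x$results$anova[x$results$anova$p < 0.05, "effect"]
  cat(sprintf("  significant rANOVA effects (p < 0.05): %s\n",
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}
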