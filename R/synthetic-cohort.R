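#' Generate a synthetic streamline-count connectome
#'
#' Draws an Erdos-Renyi edge support at the requested density, puts
#' positive Poisson streamline counts on the selected edges, symmetrizes,
#' zeroes the diagonal, and flags disjoint candidate frontal and parietal
#' node sets. Identical seeds give byte-identical matrices.
#'
#' @param n_nodes Number of atlas regions (>= 2).
#' @param density Edge probability in (0, 1].
#' @param candidate_frontal,candidate_parietal Number of candidate regions
#'   to flag in each area (both >= 1).
#' @param seed Integer RNG seed.
#' @param mean_streamlines Mean streamline count on present edges.
#' @return A [connectome()].
#' @export
generate_connectome <- function(n_nodes, density = 0.1,
                                candidate_frontal = 9L,
                                candidate_parietal = 8L,
                                seed = 1L, mean_streamlines = 50) {
  if (n_nodes < 2L) stop_input("need at least 2 nodes")
  if (candidate_frontal < 1L || candidate_parietal < 1L) {
    stop_input("candidate sets must be non-empty")
  }
  if (n_nodes < candidate_frontal + candidate_parietal + 1L) {
    stop_input("n_nodes too small for the requested candidate sets")
  }
  if (density <= 0 || density > 1) stop_input("density must be in (0, 1]")
  with_seed_(seed, {
    w <- matrix(0, n_nodes, n_nodes)
    ut <- upper.tri(w)
    n_edges <- sum(ut)
    present <- stats::runif(n_edges) < density
    counts <- integer(n_edges)
    ## 1 + Poisson keeps every present edge strictly positive
    counts[present] <- 1L + stats::rpois(sum(present), mean_streamlines - 1)
    w[ut] <- counts
    w <- w + t(w)
    picks <- sample.int(n_nodes, candidate_frontal + candidate_parietal)
    frontal <- sort(picks[seq_len(candidate_frontal)])
    parietal <- sort(picks[candidate_frontal + seq_len(candidate_parietal)])
    labels <- sprintf("node_%03d", seq_len(n_nodes))
    labels[frontal] <- sprintf("L_MFG_%02d", seq_along(frontal))
    labels[parietal] <- sprintf("L_LPC_%02d", seq_along(parietal))
    connectome(w, labels, frontal, parietal)
  })
}

## Triangulated UV sphere with exact radial outward normals.
sphere_mesh <- function(radius, n_lat = 24L, n_lon = 48L) {
  theta <- seq(0, pi, length.out = n_lat + 1L)[-c(1L, n_lat + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  grid <- expand.grid(phi = phi, theta = theta)
  ring <- cbind(
    sin(grid$theta) * cos(grid$phi),
    sin(grid$theta) * sin(grid$phi),
    cos(grid$theta)
  )
  vertices <- rbind(c(0, 0, 1), ring, c(0, 0, -1)) * radius
  normals <- unit_rows(vertices)
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  for (j in seq_len(n_lon)) { # polar caps
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
    faces[[length(faces) + 1L]] <-
      c(nrow(vertices), idx(n_lat - 1L, j + 1L), idx(n_lat - 1L, j))
  }
  for (i in seq_len(n_lat - 2L)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, d)
      faces[[length(faces) + 1L]] <- c(a, d, cc)
    }
  }
  list(vertices = vertices, faces = do.call(rbind, faces), normals = normals)
}

#' Generate concentric-sphere head anatomy
#'
#' A deliberately simple head stand-in: scalp and cortex are concentric
#' spheres with analytically known outward normals, sulcal wall points carry
#' inward-pointing normals that are near-tangential to the cortex surface
#' (|dot with the radial direction| <= 0.5 by construction), and a small
#' rigid MNI-to-native affine is attached.
#'
#' @param scalp_radius_mm,cortex_radius_mm Sphere radii (scalp > cortex > 0).
#' @param n_sulci Number of sulcal wall points.
#' @param seed Integer RNG seed.
#' @return An object of class `anatomy_meshes`.
#' @export
generate_anatomy <- function(scalp_radius_mm = 95, cortex_radius_mm = 80,
                             n_sulci = 20L, seed = 1L) {
  if (scalp_radius_mm <= cortex_radius_mm || cortex_radius_mm <= 0) {
    stop_input("need scalp_radius_mm > cortex_radius_mm > 0")
  }
  if (n_sulci < 1L) stop_input("need at least one sulcal point")
  with_seed_(seed, {
    scalp <- sphere_mesh(scalp_radius_mm)
    cortex <- sphere_mesh(cortex_radius_mm)
    ## sulcal points: random cortex locations, inward normals built from a
    ## tangent direction plus a bounded radial component
    u <- matrix(stats::rnorm(n_sulci * 3), ncol = 3)
    pos_dir <- unit_rows(u)
    pos <- pos_dir * cortex_radius_mm
    tang <- matrix(stats::rnorm(n_sulci * 3), ncol = 3)
    tang <- tang - rowSums(tang * pos_dir) * pos_dir
    tang <- unit_rows(tang)
    radial_mix <- stats::runif(n_sulci, -0.4, 0.4)
    normals <- unit_rows(tang + radial_mix * pos_dir)
    ## small rigid MNI -> native transform
    ang <- stats::runif(3, -0.05, 0.05)
    rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                c(-sin(ang[2]), 0, cos(ang[2])))
    rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    aff <- diag(4)
    aff[1:3, 1:3] <- rx %*% ry %*% rz
    aff[1:3, 4] <- stats::runif(3, -3, 3)
    structure(
      list(
        scalp_mesh = scalp,
        cortex_mesh = cortex,
        sulcal_points = list(positions = pos, normals = normals),
        mni_to_native_affine = aff
      ),
      class = "anatomy_meshes"
    )
  })
}

#' Place cubic candidate ROI volumes on the synthetic cortex
#'
#' Builds an ROI label grid with `n_frontal` candidate regions on an
#' anterior-superior cap and `n_parietal` on a posterior cap of the cortex
#' sphere. The frontal cap sits at a larger radius (shallower below the
#' scalp) than the parietal cap, mirroring the shorter frontal
#' scalp-to-cortex distance. Each region is a cube of `cube^3` voxels.
#'
#' @param n_frontal,n_parietal Number of candidate regions per area.
#' @param vox_mm Isotropic voxel size in mm.
#' @param cube Region edge length in voxels (default 6, i.e. 216 voxels).
#' @param frontal_radius_mm,parietal_radius_mm Radii of the ROI-center caps.
#' @param labels Optional character vector of region names
#'   (`n_frontal + n_parietal` entries, frontal first).
#' @return A list with the [roi_volume()] (`rois`), the frontal and parietal
#'   label ids, and the ROI center coordinates in mm.
#' @export
make_candidate_rois <- function(n_frontal = 9L, n_parietal = 8L, vox_mm = 3,
                                cube = 5L, frontal_radius_mm = 70,
                                parietal_radius_mm = 66, labels = NULL) {
  half_fov <- 96
  n_vox <- as.integer(2 * half_fov / vox_mm)
  affine <- diag(c(vox_mm, vox_mm, vox_mm, 1))
  affine[1:3, 4] <- -half_fov + vox_mm / 2
  arr <- array(0L, dim = rep(n_vox, 3))
  cap_points <- function(n, center_dir, spread, radius) {
    ## deterministic spiral of n directions around center_dir
    k <- seq_len(n)
    ang <- 2.399963 * k                      # golden angle
    r <- spread * sqrt(k / n)
    ez <- center_dir / sqrt(sum(center_dir^2))
    ex <- c(ez[2], -ez[1], 0)
    if (sum(ex^2) < 1e-9) ex <- c(1, 0, 0)
    ex <- ex / sqrt(sum(ex^2))
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
            ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    dirs <- t(vapply(seq_len(n), function(i) {
      d <- cos(r[i]) * ez + sin(r[i]) * (cos(ang[i]) * ex + sin(ang[i]) * ey)
      d / sqrt(sum(d^2))
    }, numeric(3)))
    dirs * radius
  }
  frontal_c <- cap_points(n_frontal, c(0.4, 0.75, 0.6), 0.55, frontal_radius_mm)
  parietal_c <- cap_points(n_parietal, c(0.35, -0.75, 0.6), 0.5, parietal_radius_mm)
  centers <- rbind(frontal_c, parietal_c)
  axes <- seq(0, n_vox - 1L) * vox_mm - half_fov + vox_mm / 2
  reach <- (cube - 1L) %/% 2L
  for (l in seq_len(nrow(centers))) {
    ## cube of exactly cube^3 voxels centered at the nearest grid voxel
    sel <- lapply(1:3, function(ax) {
      i0 <- which.min(abs(axes - centers[l, ax]))
      i0 <- min(max(i0, 1L + reach), n_vox - (cube - 1L - reach))
      (i0 - reach):(i0 + (cube - 1L - reach))
    })
    arr[sel[[1]], sel[[2]], sel[[3]]] <- l
  }
  if (is.null(labels)) {
    labels <- c(sprintf("L_MFG_%02d", seq_len(n_frontal)),
                sprintf("L_LPC_%02d", seq_len(n_parietal)))
  }
  rois <- roi_volume(arr, affine,
                     stats::setNames(labels, seq_len(nrow(centers))))
  list(
    rois = rois,
    frontal_labels = seq_len(n_frontal),
    parietal_labels = n_frontal + seq_len(n_parietal),
    centers_mm = centers
  )
}

#' Generate block-design BOLD data with known task effects
#'
#' Voxel time series are the design-matrix signal plus white Gaussian
#' noise. In the listed active regions the DRAT beta exceeds the DRMT beta
#' by `effect_size * noise_sd`; everywhere else the two betas are equal.
#'
#' @param roi_set A [roi_volume()].
#' @param active_labels Labels whose voxels carry the task effect.
#' @param effect_size DRAT-minus-DRMT beta difference in noise-SD units.
#' @param design A [block_design()].
#' @param noise_sd Noise standard deviation (> 0).
#' @param seed Integer RNG seed.
#' @param baseline_beta Shared task response amplitude for both conditions.
#' @return An object of class `block_bold`: time-by-voxel `data`, voxel
#'   linear indices into the ROI grid, the design, and the ROI volume.
#' @export
generate_activation <- function(roi_set, active_labels, effect_size, design,
                                noise_sd = 1, seed = 1L, baseline_beta = 1) {
  stopifnot(inherits(roi_set, "roi_volume"), inherits(design, "block_design"))
  if (noise_sd <= 0) stop_input("noise_sd must be positive")
  present <- unique(roi_set$labels[roi_set$labels > 0])
  if (!all(active_labels %in% present)) {
    stop_input("active_labels must be labels of roi_set")
  }
  voxels <- which(roi_set$labels > 0)
  x <- build_design_matrix(design)
  lab <- roi_set$labels[voxels]
  beta_drat <- baseline_beta +
    ifelse(lab %in% active_labels, effect_size * noise_sd, 0)
  beta_drmt <- rep(baseline_beta, length(voxels))
  signal <- x[, "DRAT"] %o% beta_drat + x[, "DRMT"] %o% beta_drmt
  noise <- with_seed_(seed, matrix(
    stats::rnorm(length(signal), sd = noise_sd),
    nrow = nrow(signal)
  ))
  structure(
    list(data = signal + noise, voxels = voxels, design = design,
         roi = roi_set),
    class = "block_bold"
  )
}

#' Bernoulli observer with a logistic set-size psychometric function
#'
#' Accuracy follows `gamma + (1 - gamma - lapse) * logistic(-k (s - s0))`,
#' i.e. it decays from near-perfect at small set sizes towards the guessing
#' rate, plus an additive per-task bonus (the maintenance task is easier
#' than alphabetization) and an additive per-(target, task, stimulation)
#' rTMS effect. Probabilities are clipped to [0, 1].
#'
#' @param threshold_s0 Set size at the accuracy midpoint.
#' @param slope_k Logistic slope per set-size unit (> 0).
#' @param guess_gamma Chance level in [0, 1); 0.5 for the binary
#'   Valid/Invalid response.
#' @param lapse Lapse rate in [0, 0.1].
#' @param effect_map Data frame with columns `target`, `task`,
#'   `stimulation`, `shift` giving additive accuracy shifts on the
#'   probability scale, or `NULL` for no stimulation effects.
#' @param task_shift Named numeric, additive accuracy bonus per task.
#' @param rt_mean_ms,rt_sd_ms Named numeric (per task), reaction-time
#'   truncated-normal parameters in milliseconds.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(threshold_s0 = 6.5, slope_k = 1.2,
                           guess_gamma = 0.5, lapse = 0.02,
                           effect_map = NULL,
                           task_shift = c(DRAT = 0, DRMT = 0.18),
                           rt_mean_ms = c(DRAT = 1850, DRMT = 1650),
                           rt_sd_ms = c(DRAT = 330, DRMT = 250)) {
  if (guess_gamma < 0 || guess_gamma >= 1) stop_input("guess_gamma must be in [0, 1)")
  if (lapse < 0 || lapse > 0.1) stop_input("lapse must be in [0, 0.1]")
  if (slope_k <= 0) stop_input("slope_k must be positive")
  if (!is.null(effect_map)) {
    effect_map <- as.data.frame(effect_map)
    need <- c("target", "task", "stimulation", "shift")
    if (!all(need %in% names(effect_map))) {
      stop_input("effect_map needs columns target, task, stimulation, shift")
    }
  }
  structure(
    list(threshold_s0 = threshold_s0, slope_k = slope_k,
         guess_gamma = guess_gamma, lapse = lapse, effect_map = effect_map,
         task_shift = task_shift, rt_mean_ms = rt_mean_ms,
         rt_sd_ms = rt_sd_ms),
    class = "observer_model"
  )
}

## Vectorized effect_map lookup; returns 0 where no entry matches.
effect_shift <- function(observer, target, task, stimulation) {
  n <- max(length(target), length(task), length(stimulation))
  target <- rep_len(target, n); task <- rep_len(task, n)
  stimulation <- rep_len(stimulation, n)
  out <- numeric(n)
  em <- observer$effect_map
  if (is.null(em) || nrow(em) == 0L) return(out)
  key <- paste(target, task, stimulation, sep = "|")
  ekey <- paste(em$target, em$task, em$stimulation, sep = "|")
  hit <- match(key, ekey)
  out[!is.na(hit)] <- em$shift[hit[!is.na(hit)]]
  out
}

#' Predicted response accuracy of an observer
#'
#' @param observer An [observer_model()].
#' @param set_size Integer set size(s) (>= 1).
#' @param task `"DRAT"` or `"DRMT"`.
#' @param target,stimulation Stimulation context (`"none"` for no rTMS).
#' @return Probability of a correct response, clipped to [0, 1].
#' @export
predicted_accuracy <- function(observer, set_size, task = "DRAT",
                               target = "none", stimulation = "none") {
  if (any(set_size < 1)) stop_input("set_size must be >= 1")
  g <- observer$guess_gamma
  p <- g + (1 - g - observer$lapse) /
    (1 + exp(observer$slope_k * (set_size - observer$threshold_s0)))
  p <- p + unname(observer$task_shift[task])
  p <- p + effect_shift(observer, target, task, stimulation)
  clip01(p)
}

#' Simulate a single trial response
#'
#' Draws a Bernoulli correctness from [predicted_accuracy()] and a reaction
#' time from a normal truncated below at 200 ms.
#'
#' @inheritParams predicted_accuracy
#' @return A list with `correct` (logical) and `rt_ms`.
#' @export
simulate_response <- function(observer, set_size, task = "DRAT",
                              target = "none", stimulation = "none") {
  p <- predicted_accuracy(observer, set_size, task, target, stimulation)
  correct <- stats::runif(length(p)) < p
  rt <- rtruncnorm_lower(length(p),
                         unname(observer$rt_mean_ms[task]),
                         unname(observer$rt_sd_ms[task]), 200)
  list(correct = correct, rt_ms = rt)
}

#' Analytic coil electric-field model, exactly linear in drive
#'
#' Field magnitude at position `x` for a coil pose and drive `d` (%MSO) is
#' `amp * d * exp(-||x - center|| / lambda_decay)`: strictly decreasing
#' with distance from the coil center and exactly proportional to the
#' drive, which is the physical assumption that makes dose calibration a
#' single rescaling.
#'
#' @param amp Field scale in V/m per %MSO at the coil center.
#' @param lambda_decay Exponential decay length in mm.
#' @param reference_drive Drive (%MSO) at which snapshots are exported.
#' @return An object of class `field_model` with a `magnitude(x, pose,
#'   drive)` function (`x` is an `n x 3` matrix of mm positions).
#' @export
field_model <- function(amp = 6, lambda_decay = 20, reference_drive = 50) {
  if (amp <= 0 || lambda_decay <= 0 || reference_drive <= 0) {
    stop_input("field model parameters must be positive")
  }
  magnitude <- function(x, pose, drive) {
    x <- matrix(x, ncol = 3)
    d <- sqrt(rowSums((x - matrix(pose$center_mm, nrow(x), 3, byrow = TRUE))^2))
    amp * drive * exp(-d / lambda_decay)
  }
  structure(
    list(magnitude = magnitude, amp = amp, lambda_decay = lambda_decay,
         reference_drive = reference_drive),
    class = "field_model"
  )
}

#' Generate one synthetic participant
#'
#' Bundles anatomy, connectome, candidate ROI volume, field model, motor
#' threshold, hair thickness, and a Bernoulli observer, all reproducible
#' from `(subject_id, seed)`.
#'
#' @param subject_id Character id.
#' @param cohort 1 (Hard only) or 2 (Easy and Hard).
#' @param seed Integer RNG seed.
#' @param n_nodes Connectome size (default 120 keeps per-subject work
#'   light; the candidate sets are the study's 9 frontal + 8 parietal).
#' @param effect_map Passed to [observer_model()].
#' @param observer_s0_mean,observer_s0_sd Population distribution of the
#'   psychometric midpoint.
#' @return An object of class `subject_bundle`.
#' @export
generate_subject <- function(subject_id, cohort = 1L, seed = 1L,
                             n_nodes = 120L, effect_map = NULL,
                             observer_s0_mean = 6.5, observer_s0_sd = 0.5) {
  stopifnot(cohort %in% c(1L, 2L))
  seeds <- derive_seeds(seed, 6L)
  anatomy <- generate_anatomy(seed = seeds[1])
  conn <- generate_connectome(n_nodes, density = 0.15, seed = seeds[2])
  roi_set <- make_candidate_rois(
    labels = c(conn$node_labels[conn$candidate_frontal],
               conn$node_labels[conn$candidate_parietal])
  )
  scalars <- with_seed_(seeds[3], {
    list(
      rmt = round(min(max(stats::rnorm(1, 53.5, 13.7), 30), 85)),
      hair = round(stats::runif(1, 0, 4), 2),
      s0 = min(max(stats::rnorm(1, observer_s0_mean, observer_s0_sd), 5.0), 8.0),
      k = min(max(stats::rnorm(1, 1.2, 0.15), 0.8), 1.8)
    )
  })
  observer <- observer_model(
    threshold_s0 = scalars$s0, slope_k = scalars$k, effect_map = effect_map
  )
  structure(
    list(
      subject_id = as.character(subject_id),
      cohort = as.integer(cohort),
      anatomy = anatomy,
      connectome = conn,
      roi_set = roi_set,
      field_model = field_model(),
      rmt_pct_mso = scalars$rmt,
      hair_mm = scalars$hair,
      observer = observer,
      rng_seed = as.integer(seed),
      activation_seed = seeds[4],
      practice_seed = seeds[5],
      session_seed = seeds[6]
    ),
    class = "subject_bundle"
  )
}

#' @export
print.subject_bundle <- function(x, ...) {
  cat(sprintf(
    "<subject_bundle> %s (cohort %d): rMT %g %%MSO, hair %.2f mm, s0 %.2f\n",
    x$subject_id, x$cohort, x$rmt_pct_mso, x$hair_mm,
    x$observer$threshold_s0
  ))
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' @param n_subjects Number of participants.
#' @param seed Master RNG seed; per-subject seeds are derived from it.
#' @param cohorts Optional integer vector of cohort assignments (recycled);
#'   default splits roughly half and half like the study (15 + 14).
#' @param effect_map Passed to every observer (the injected rTMS effect).
#' @param ... Further arguments for [generate_subject()].
#' @return List of [generate_subject()] bundles.
#' @export
generate_cohort <- function(n_subjects, seed = 1L, cohorts = NULL,
                            effect_map = NULL, ...) {
  if (n_subjects < 1L) stop_input("need at least one subject")
  if (is.null(cohorts)) {
    cohorts <- rep(1:2, c(ceiling(n_subjects / 2), floor(n_subjects / 2)))
  }
  cohorts <- rep_len(as.integer(cohorts), n_subjects)
  seeds <- derive_seeds(seed, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    generate_subject(sprintf("sub-%03d", i), cohort = cohorts[i],
                     seed = seeds[i], effect_map = effect_map, ...)
  })
}
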