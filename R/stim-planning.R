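#' Project a brain target to the scalp and offset for hair
#'
#' Nearest-neighbor projection: the scalp point is the mesh vertex closest
#' to the target (ties broken by lowest vertex index), the coil sits
#' `hair_mm` further out along that vertex's outward normal.
#'
#' @param target_mm Length-3 target coordinate in native mm.
#' @param scalp Scalp mesh (list with `vertices` and `normals`).
#' @param hair_mm Compressed hair thickness in mm (>= 0).
#' @return List with `scalp_point`, `coil_center`, `normal`.
#' @export
project_to_scalp <- function(target_mm, scalp, hair_mm = 0) {
  if (is.null(scalp$vertices) || nrow(scalp$vertices) == 0L) {
    stop_input("empty scalp mesh")
  }
  if (hair_mm < 0) stop_input("hair_mm must be >= 0")
  d2 <- rowSums((scalp$vertices -
                   matrix(target_mm, nrow(scalp$vertices), 3, byrow = TRUE))^2)
  i <- which.min(d2) # which.min returns the first (lowest-index) minimum
  scalp_point <- scalp$vertices[i, ]
  normal <- scalp$normals[i, ]
  list(
    scalp_point = scalp_point,
    coil_center = scalp_point + hair_mm * normal,
    normal = normal
  )
}

#' Orient the coil from the nearest sulcal wall normal
#'
#' The induced E-field's second phase should point along the inward normal
#' of the sulcal wall closest to the brain target. That normal is projected
#' onto the tangent plane perpendicular to the coil (scalp) normal; the
#' normalized projection is the second-phase direction, and the twist angle
#' is measured against a reference tangent axis (the projection of +y onto
#' the tangent plane, falling back to +x when degenerate).
#'
#' @param coil_center Length-3 coil center in mm.
#' @param normal Outward unit scalp normal at the coil.
#' @param sulcal_points List with `positions` (n x 3) and `normals` (n x 3,
#'   inward unit vectors).
#' @param target_mm Brain target used to pick the nearest sulcal point.
#' @return An object of class `coil_pose`.
#' @export
orient_coil <- function(coil_center, normal, sulcal_points, target_mm) {
  pos <- sulcal_points$positions
  if (is.null(pos) || nrow(pos) == 0L) stop_input("need at least one sulcal point")
  d2 <- rowSums((pos - matrix(target_mm, nrow(pos), 3, byrow = TRUE))^2)
  w <- sulcal_points$normals[which.min(d2), ]
  proj <- w - sum(w * normal) * normal
  np <- sqrt(sum(proj^2))
  if (np < 1e-6) stop_input("degenerate orientation: sulcal normal parallel to coil normal")
  second_phase <- proj / np
  ref <- c(0, 1, 0) - sum(c(0, 1, 0) * normal) * normal
  ref_axis <- "anterior(+y)"
  if (sqrt(sum(ref^2)) < 1e-6) {
    ref <- c(1, 0, 0) - sum(c(1, 0, 0) * normal) * normal
    ref_axis <- "right(+x)"
  }
  ref <- ref / sqrt(sum(ref^2))
  twist <- signed_angle_deg(ref, second_phase, normal)
  structure(
    list(center_mm = coil_center, normal = normal,
         second_phase_dir = second_phase, twist_deg = twist,
         reference_axis = ref_axis),
    class = "coil_pose"
  )
}

#' The E100 field-exposure metric
#'
#' The 100th largest E-field magnitude across the ROI voxels — a robust
#' measure of the field actually delivered to the region. For ROIs with
#' fewer than 100 voxels the smallest magnitude is returned and the result
#' carries a `"fewer than 100 voxels"` flag (a conservative fallback that
#' never overestimates the dose).
#'
#' @param field_mags Numeric vector of per-voxel field magnitudes (V/m).
#' @return The E100 value, with attribute `flag` when the fallback fired.
#' @export
compute_e100 <- function(field_mags) {
  if (length(field_mags) == 0L) stop_input("empty ROI")
  s <- sort(field_mags, decreasing = TRUE)
  if (length(s) < 100L) {
    out <- s[length(s)]
    attr(out, "flag") <- "fewer than 100 voxels: smallest magnitude used"
    warning("ROI has fewer than 100 voxels; returning the smallest magnitude")
    return(out)
  }
  s[100L]
}

#' Calibrate the stimulator amplitude to the reference exposure
#'
#' Evaluates the field at a test drive, computes E100 over the ROI voxels,
#' and rescales the drive so the recomputed E100 equals `e_ref` (exact
#' because the field is linear in drive). Amplitudes above 100 %MSO are
#' capped with a `"device limit"` flag.
#'
#' @param field_model A [field_model()].
#' @param pose A [orient_coil()] pose (only `center_mm` is used by the
#'   default field).
#' @param roi_mm `n x 3` matrix of ROI voxel coordinates in mm.
#' @param e_ref Reference exposure in V/m (default 56).
#' @param test_drive Test drive in %MSO (> 0).
#' @return List with `amplitude_pct_mso`, `achieved_e100`, `e_ref`,
#'   `test_drive`, `e100_at_test`, `safety_flags`.
#' @export
calibrate_amplitude <- function(field_model, pose, roi_mm, e_ref = 56,
                                test_drive = 50) {
  if (test_drive <= 0) stop_input("test_drive must be positive")
  mags <- field_model$magnitude(roi_mm, pose, test_drive)
  e100_test <- compute_e100(mags)
  flags <- character()
  if (!is.null(attr(e100_test, "flag"))) flags <- attr(e100_test, "flag")
  e100_test <- as.numeric(e100_test)
  if (e100_test <= 0) stop_input("target unreachable: zero field in ROI")
  amp <- test_drive * e_ref / e100_test
  if (amp > 100) {
    amp <- 100
    flags <- c(flags, "device limit: amplitude capped at 100 %MSO")
  }
  achieved <- as.numeric(compute_e100(field_model$magnitude(roi_mm, pose, amp)))
  list(
    amplitude_pct_mso = amp,
    achieved_e100 = achieved,
    e_ref = e_ref,
    test_drive = test_drive,
    e100_at_test = e100_test,
    safety_flags = flags
  )
}

#' Express an amplitude as a percentage of the resting motor threshold
#'
#' `100 * amplitude / rMT`, rounded to the nearest integer for table
#' reporting with full precision retained, plus a safety flag when the
#' value exceeds the guideline limit.
#'
#' @param amplitude_pct_mso Stimulation amplitude in %MSO.
#' @param rmt_pct_mso Resting motor threshold in %MSO (> 0).
#' @param safety_limit_pct_rmt Guideline limit, default 130 %rMT.
#' @return List with `pct_rmt` (rounded), `pct_rmt_exact`, `safety_flags`.
#' @export
percent_rmt <- function(amplitude_pct_mso, rmt_pct_mso,
                        safety_limit_pct_rmt = 130) {
  if (rmt_pct_mso <= 0) stop_input("rMT must be positive")
  exact <- 100 * amplitude_pct_mso / rmt_pct_mso
  flags <- if (exact > safety_limit_pct_rmt) {
    sprintf("above safety guideline: %.1f %%rMT > %g", exact,
            safety_limit_pct_rmt)
  } else character()
  list(pct_rmt = round(exact), pct_rmt_exact = exact, safety_flags = flags)
}

#' Full stimulation plan for one subject and region
#'
#' Chains [roi_center_native()], [project_to_scalp()], [orient_coil()],
#' [calibrate_amplitude()], and [percent_rmt()] into a stimulation plan.
#'
#' @param bundle A [generate_subject()] bundle.
#' @param decision A [select_target()] decision for that subject.
#' @param e_ref Reference exposure (V/m).
#' @param test_drive Calibration test drive (%MSO).
#' @param safety_limit_pct_rmt Guideline limit for the %rMT flag.
#' @return An object of class `stim_plan`.
#' @export
plan_stimulation <- function(bundle, decision, e_ref = 56, test_drive = 50,
                             safety_limit_pct_rmt = 130) {
  rois <- bundle$roi_set$rois
  label_id <- as.integer(names(which(rois$label_names == decision$chosen_label)))
  target <- roi_center_native(rois, label_id,
                              bundle$anatomy$mni_to_native_affine)
  proj <- project_to_scalp(target, bundle$anatomy$scalp_mesh, bundle$hair_mm)
  pose <- orient_coil(proj$coil_center, proj$normal,
                      bundle$anatomy$sulcal_points, target)
  roi_mm <- roi_voxel_mm(rois, label_id)
  cal <- calibrate_amplitude(bundle$field_model, pose, roi_mm,
                             e_ref = e_ref, test_drive = test_drive)
  rmt <- percent_rmt(cal$amplitude_pct_mso, bundle$rmt_pct_mso,
                     safety_limit_pct_rmt)
  structure(
    list(
      subject_id = bundle$subject_id,
      region = decision$region,
      target_label = decision$chosen_label,
      target_mm = target,
      pose = pose,
      amplitude_pct_mso = cal$amplitude_pct_mso,
      amplitude_pct_rmt = rmt$pct_rmt,
      amplitude_pct_rmt_exact = rmt$pct_rmt_exact,
      achieved_e100 = cal$achieved_e100,
      e_ref = e_ref,
      safety_flags = c(cal$safety_flags, rmt$safety_flags)
    ),
    class = "stim_plan"
  )
}

#' @export
print.stim_plan <- function(x, ...) {
  cat(sprintf(
    "<stim_plan> %s %s: %.1f %%MSO (%d %%rMT), E100 %.2f V/m (ref %g)%s\n",
    x$subject_id, x$target_label, x$amplitude_pct_mso, x$amplitude_pct_rmt,
    x$achieved_e100, x$e_ref,
    if (length(x$safety_flags)) paste0(" [", paste(x$safety_flags, collapse = "; "), "]")
    else ""
  ))
  invisible(x)
}

#' Audit the published stimulation-amplitude table
#'
#' Recomputes the column means and sample standard deviations of the
#' packaged 29-participant amplitude table and checks each row's printed
#' %rMT against `round(100 * %MSO / rMT)` with a +/-1 rounding slack.
#'
#' @param table Data frame with columns `cohort`, `rmt_pct_mso`,
#'   `dlpfc_pct_mso`, `dlpfc_pct_rmt`, `lpc_pct_mso`, `lpc_pct_rmt`;
#'   defaults to the packaged table ([amplitude_table()]).
#' @return List with `means`, `sds` (sample, n-1), `consistency` (per-row
#'   data frame), and `discrepancies` (rows deviating by more than 1).
#' @export
audit_amplitude_table <- function(table = amplitude_table()) {
  num_cols <- c("rmt_pct_mso", "dlpfc_pct_mso", "dlpfc_pct_rmt",
                "lpc_pct_mso", "lpc_pct_rmt")
  if (!all(num_cols %in% names(table))) stop_input("malformed amplitude table")
  if (nrow(table) != 29L) stop_input("expected 29 rows, got %d", nrow(table))
  x <- table[num_cols]
  if (any(!vapply(x, is.numeric, logical(1)))) stop_input("non-numeric column")
  means <- colMeans(x)
  sds <- vapply(x, stats::sd, numeric(1))
  consistency <- data.frame(
    row = seq_len(nrow(table)),
    dlpfc_expected = round(100 * x$dlpfc_pct_mso / x$rmt_pct_mso),
    dlpfc_printed = x$dlpfc_pct_rmt,
    lpc_expected = round(100 * x$lpc_pct_mso / x$rmt_pct_mso),
    lpc_printed = x$lpc_pct_rmt
  )
  consistency$dlpfc_ok <-
    abs(consistency$dlpfc_expected - consistency$dlpfc_printed) <= 1
  consistency$lpc_ok <-
    abs(consistency$lpc_expected - consistency$lpc_printed) <= 1
  list(
    means = means,
    sds = sds,
    consistency = consistency,
    discrepancies = consistency[!(consistency$dlpfc_ok & consistency$lpc_ok), ]
  )
}

#' The packaged published stimulation-amplitude table
#'
#' Resting motor threshold and calibrated rTMS amplitudes at the two
#' targets for the 29 study completers, as printed in the source study
#' (one row per participant, sorted by rMT within cohort).
#'
#' @return Data frame with 29 rows.
#' @export
amplitude_table <- function() {
  path <- system.file("extdata", "stimulation_amplitudes.tsv",
                      package = "stimpipe", mustWork = TRUE)
  utils::read.delim(path)
}
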