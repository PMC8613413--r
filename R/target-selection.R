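#' Select the stimulation target: activation gate, then maximal
#' controllability
#'
#' Two conditions in sequence: a candidate region passes only if at least a
#' `gate` fraction of its voxels is significantly activated; among the
#' passing regions, the one with the highest modal controllability is
#' chosen. Ties are broken by ascending label so the decision is
#' deterministic. An empty passing set is an explicit error, never a silent
#' fallback.
#'
#' @param fractions Named numeric vector: activated-voxel fraction per
#'   candidate label.
#' @param phis Named numeric vector: modal controllability per candidate
#'   label (same label set as `fractions`).
#' @param gate Activation gate, default 0.25 (the rule is `>= gate`).
#' @param exclude Optional labels excluded a priori (e.g. for coil
#'   placement reasons); recorded with reasons in the decision.
#' @param region Optional region tag carried into the decision.
#' @return An object of class `target_decision`.
#' @export
select_target <- function(fractions, phis, gate = 0.25, exclude = character(),
                          region = NA_character_) {
  labs <- sort(names(fractions))
  if (!setequal(labs, names(phis))) {
    stop_input("fractions and phis must share the candidate label set")
  }
  labs <- setdiff(labs, exclude)
  if (length(labs) == 0L) stop_input("no eligible target: all candidates excluded")
  f <- fractions[labs]
  p <- phis[labs]
  passing <- labs[f >= gate]
  rejected <- data.frame(
    label = c(setdiff(sort(names(fractions)), labs), labs[f < gate]),
    reason = c(rep("excluded a priori", length(setdiff(sort(names(fractions)), labs))),
               sprintf("activation fraction %.3f < gate %.3f",
                       f[f < gate], gate)),
    stringsAsFactors = FALSE
  )
  if (length(passing) == 0L) stop_input("no eligible target: empty passing set")
  ord <- order(-p[passing], passing)
  chosen <- passing[ord[1]]
  structure(
    list(
      region = region,
      chosen_label = chosen,
      activation_fraction = unname(f[chosen]),
      phi = unname(p[chosen]),
      passing_labels = sort(passing),
      rejected_labels = rejected,
      gate = gate
    ),
    class = "target_decision"
  )
}

#' @export
print.target_decision <- function(x, ...) {
  cat(sprintf(
    "<target_decision>%s %s (activation %.2f >= %.2f, phi %.4f; %d passing, %d rejected)\n",
    if (is.na(x$region)) "" else paste0(" [", x$region, "]"),
    x$chosen_label, x$activation_fraction, x$gate, x$phi,
    length(x$passing_labels), nrow(x$rejected_labels)
  ))
  invisible(x)
}

#' Native-space center of an ROI
#'
#' The mass centroid of the label's voxels in mm (through the ROI affine).
#' If the centroid falls outside the label mask (e.g. a C-shaped region),
#' it is snapped to the nearest in-mask voxel center before mapping
#' through the MNI-to-native affine: a stimulation target must lie in
#' tissue.
#'
#' @param rois A [roi_volume()].
#' @param label Label id.
#' @param affine_mni_to_native 4x4 affine mapping ROI-space mm to native mm.
#' @return Length-3 numeric mm coordinate in native space.
#' @export
roi_center_native <- function(rois, label, affine_mni_to_native = diag(4)) {
  if (abs(det(affine_mni_to_native)) < 1e-12) stop_input("affine must be invertible")
  mm <- roi_voxel_mm(rois, label)
  center <- colMeans(mm)
  ## in-mask check: does the voxel containing the centroid carry the label?
  ijk <- round(solve(rois$affine, c(center, 1))[1:3]) + 1L
  inside <- all(ijk >= 1L) && all(ijk <= dim(rois$labels)) &&
    rois$labels[ijk[1], ijk[2], ijk[3]] == label
  if (!inside) {
    d2 <- rowSums((mm - matrix(center, nrow(mm), 3, byrow = TRUE))^2)
    center <- mm[which.min(d2), ]
  }
  drop(affine_mni_to_native %*% c(center, 1))[1:3]
}
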