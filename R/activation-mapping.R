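#' Block design for the two working-memory tasks
#'
#' Describes when the alphabetization (DRAT) and maintenance (DRMT) blocks
#' occur inside one functional run.
#'
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of acquired volumes.
#' @param blocks Data frame with columns `condition` (`"DRAT"` or `"DRMT"`),
#'   `onset_s`, and `duration_s`.
#' @return An object of class `block_design`.
#' @export
block_design <- function(tr_s, n_volumes, blocks) {
  if (!is.numeric(tr_s) || tr_s <= 0) stop_input("tr_s must be positive")
  if (n_volumes < 1L) stop_input("need at least one volume")
  blocks <- as.data.frame(blocks)
  need <- c("condition", "onset_s", "duration_s")
  if (!all(need %in% names(blocks))) {
    stop_input("blocks needs columns condition, onset_s, duration_s")
  }
  if (nrow(blocks) == 0L) stop_input("empty design")
  if (!all(blocks$condition %in% c("DRAT", "DRMT"))) {
    stop_input("conditions must be DRAT or DRMT")
  }
  if (any(blocks$onset_s < 0) || any(blocks$duration_s <= 0)) {
    stop_input("onsets must be nonnegative and durations positive")
  }
  if (any(blocks$onset_s + blocks$duration_s > tr_s * n_volumes + 1e-9)) {
    stop_input("blocks extend past the end of the run")
  }
  for (cond in unique(blocks$condition)) {
    b <- blocks[blocks$condition == cond, , drop = FALSE]
    b <- b[order(b$onset_s), , drop = FALSE]
    if (nrow(b) > 1L &&
        any(b$onset_s[-1] < (b$onset_s + b$duration_s)[-nrow(b)] - 1e-9)) {
      stop_input("overlapping %s blocks", cond)
    }
  }
  structure(
    list(tr_s = tr_s, n_volumes = as.integer(n_volumes), blocks = blocks),
    class = "block_design"
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma-density form: a positive response peaking around
#' 5-6 s minus an undershoot around 16 s scaled by the peak/undershoot
#' ratio. Evaluated at `t` seconds after stimulus onset; zero for `t < 0`
#' and beyond `length_s`.
#'
#' @param t Numeric vector of times in seconds.
#' @param peak_shape,undershoot_shape Gamma shape parameters (rate 1).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Support length of the kernel in seconds.
#' @return HRF values at `t`.
#' @export
double_gamma_hrf <- function(t, peak_shape = 6, undershoot_shape = 16,
                             ratio = 6, length_s = 32) {
  h <- stats::dgamma(t, shape = peak_shape, rate = 1) -
    stats::dgamma(t, shape = undershoot_shape, rate = 1) / ratio
  h[t < 0 | t > length_s] <- 0
  h
}

#' Build the GLM design matrix for a block design
#'
#' Each condition's boxcar is convolved with the double-gamma HRF on a fine
#' time grid and sampled at the volume acquisition times. Columns are the
#' DRAT regressor, the DRMT regressor, and an intercept.
#'
#' @param design A [block_design()].
#' @param oversample Fine-grid oversampling factor relative to the TR.
#' @param hrf_args Optional list of overrides passed to [double_gamma_hrf()].
#' @return `n_volumes x 3` numeric matrix with columns `DRAT`, `DRMT`,
#'   `intercept`.
#' @export
build_design_matrix <- function(design, oversample = 16L, hrf_args = list()) {
  stopifnot(inherits(design, "block_design"))
  dt <- design$tr_s / oversample
  total_s <- design$tr_s * design$n_volumes
  fine_t <- seq(0, total_s, by = dt)
  hrf <- do.call(double_gamma_hrf, c(list(t = fine_t[fine_t <= 40]), hrf_args))
  cols <- lapply(c("DRAT", "DRMT"), function(cond) {
    box <- numeric(length(fine_t))
    b <- design$blocks[design$blocks$condition == cond, , drop = FALSE]
    for (i in seq_len(nrow(b))) {
      box[fine_t >= b$onset_s[i] & fine_t < b$onset_s[i] + b$duration_s[i]] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(fine_t)] * dt
    vol_t <- (seq_len(design$n_volumes) - 1L) * design$tr_s
    conv[round(vol_t / dt) + 1L]
  })
  x <- cbind(DRAT = cols[[1]], DRMT = cols[[2]], intercept = 1)
  rownames(x) <- NULL
  x
}

#' Voxelwise z-map
#'
#' @param values Numeric vector or array of z scores (NA outside the mask).
#' @param affine 4x4 voxel-to-mm affine.
#' @param mask Logical vector/array of in-brain voxels, same shape.
#' @param flags Optional character vector of quality flags.
#' @return An object of class `zmap`.
#' @export
zmap <- function(values, affine = diag(4), mask = NULL, flags = character()) {
  if (is.null(mask)) mask <- !is.na(values)
  if (any(!is.finite(values[mask]) & !is.infinite(values[mask]))) {
    stop_input("z values inside the mask must not be NaN/NA")
  }
  if (abs(det(affine)) < 1e-12) stop_input("affine must be invertible")
  structure(list(values = values, affine = affine, mask = mask, flags = flags),
            class = "zmap")
}

#' ROI label volume
#'
#' Per-voxel integer labels (0 = background) on a regular grid, with a 4x4
#' voxel-to-mm affine (0-based voxel indices, NIfTI convention) and a
#' label-to-name map.
#'
#' @param labels Integer array of labels.
#' @param affine 4x4 voxel-to-mm affine.
#' @param label_names Named character vector mapping label id (as name) to
#'   region name.
#' @return An object of class `roi_volume`.
#' @export
roi_volume <- function(labels, affine = diag(4), label_names = NULL) {
  if (any(labels < 0)) stop_input("labels must be nonnegative integers")
  if (abs(det(affine)) < 1e-12) stop_input("affine must be invertible")
  present <- sort(unique(labels[labels > 0]))
  if (is.null(label_names)) {
    label_names <- stats::setNames(sprintf("roi_%d", present), present)
  }
  structure(
    list(labels = labels, affine = affine, label_names = label_names),
    class = "roi_volume"
  )
}

## mm coordinates of the voxels carrying `label` (0-based ijk -> affine).
roi_voxel_mm <- function(rois, label) {
  idx <- which(rois$labels == label, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)
  if (nrow(idx) == 0L) stop_input("label %s has no voxels", label)
  ijk1 <- cbind(idx - 1L, 1)
  mm <- ijk1 %*% t(rois$affine)
  mm[, 1:3, drop = FALSE]
}

#' Fit the voxelwise GLM and form the task-contrast z-map
#'
#' Ordinary least squares per voxel; the contrast t statistic is mapped to a
#' z score through the t CDF and the standard normal quantile. Voxels with
#' zero residual variance but a nonzero contrast get a signed infinite
#' sentinel and are flagged.
#'
#' @param bold A `block_bold` object from [generate_activation()], or a
#'   plain `n_volumes x n_voxels` matrix.
#' @param x Design matrix from [build_design_matrix()].
#' @param contrast Numeric contrast vector, default `DRAT - DRMT`.
#' @return A [zmap()] whose `values` are laid out on the ROI grid when the
#'   input carries one, otherwise a plain vector.
#' @export
fit_glm_contrast <- function(bold, x, contrast = c(1, -1, 0)) {
  y <- if (inherits(bold, "block_bold")) bold$data else as.matrix(bold)
  if (nrow(y) != nrow(x)) stop_input("time series length must match design rows")
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop_input("design matrix is rank deficient")
  n <- nrow(x)
  dof <- n - qx$rank
  xtx_inv <- chol2inv(qr.R(qx))
  beta <- qr.coef(qx, y)
  res <- y - x %*% beta
  ss_res <- colSums(res^2)
  ## zero residual variance up to float noise relative to the data scale
  degenerate <- ss_res <= 1e-20 * pmax(colSums(y^2), 1)
  sigma2 <- ss_res / dof
  cvar <- drop(t(contrast) %*% xtx_inv %*% contrast)
  cb <- drop(t(contrast) %*% beta)
  se <- sqrt(sigma2 * cvar)
  tstat <- cb / se
  tstat[degenerate] <- sign(cb[degenerate]) * Inf
  ## t -> z through the CDF; work in the small tail on the log scale so
  ## extreme statistics keep their magnitude instead of collapsing to +/-Inf
  log_tail <- stats::pt(-abs(tstat), df = dof, log.p = TRUE)
  z <- -sign(tstat) * stats::qnorm(log_tail, log.p = TRUE)
  z[degenerate] <- sign(cb[degenerate]) * Inf
  flags <- if (any(degenerate)) {
    sprintf("zero-variance voxel(s): %s", paste(which(degenerate), collapse = ","))
  } else character()
  if (inherits(bold, "block_bold") && !is.null(bold$voxels)) {
    vals <- array(NA_real_, dim = dim(bold$roi$labels))
    vals[bold$voxels] <- z
    mask <- array(FALSE, dim = dim(bold$roi$labels))
    mask[bold$voxels] <- TRUE
    zmap(vals, affine = bold$roi$affine, mask = mask, flags = flags)
  } else {
    zmap(z, mask = rep(TRUE, length(z)), flags = flags)
  }
}

#' Per-ROI fraction of significantly activated voxels
#'
#' A voxel counts as activated when its z score is strictly greater than
#' `z_thresh` (one-sided). Labels with zero voxels are dropped with a
#' warning.
#'
#' @param z A [zmap()] on the same grid as `rois`.
#' @param rois A [roi_volume()].
#' @param z_thresh Threshold, default 1.96.
#' @return Named numeric vector: fraction of supra-threshold voxels per
#'   label.
#' @export
roi_activation_fraction <- function(z, rois, z_thresh = 1.96) {
  if (z_thresh <= 0) stop_input("z_thresh must be positive")
  if (length(z$values) != length(rois$labels)) {
    stop_input("z-map and ROI volume must share the same grid")
  }
  labs <- sort(unique(rois$labels[rois$labels > 0]))
  out <- vapply(labs, function(l) {
    v <- z$values[rois$labels == l]
    mean(!is.na(v) & v > z_thresh)
  }, numeric(1))
  names(out) <- as.character(labs)
  empty <- setdiff(as.integer(names(rois$label_names)), labs)
  if (length(empty)) {
    warning(sprintf("label(s) with zero voxels excluded: %s",
                    paste(empty, collapse = ",")))
  }
  out
}
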