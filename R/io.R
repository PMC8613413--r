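#' Read and write connectomes
#'
#' Streamline-count matrices are exchanged as MatrixMarket (`.mtx`) or CSV.
#' Candidate index sets travel in a sidecar JSON with the same basename.
#'
#' @param c A [connectome()].
#' @param path Output path (`.mtx` or `.csv`).
#' @return `write_connectome` returns `path` invisibly; `read_connectome`
#'   returns a [connectome()].
#' @export
write_connectome <- function(c, path) {
  validate_connectome(c)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(c$weights, sparse = TRUE), path)
  } else {
    utils::write.csv(as.data.frame(c$weights), path, row.names = FALSE)
  }
  sidecar <- sub("\\.(mtx|csv)$", ".json", path)
  jsonlite::write_json(
    list(node_labels = c$node_labels,
         candidate_frontal = c$candidate_frontal,
         candidate_parietal = c$candidate_parietal),
    sidecar, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  w <- if (grepl("\\.mtx$", path)) {
    as.matrix(Matrix::readMM(path))
  } else {
    as.matrix(utils::read.csv(path))
  }
  dimnames(w) <- NULL
  sidecar <- sub("\\.(mtx|csv)$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  connectome(w, meta$node_labels, meta$candidate_frontal,
             meta$candidate_parietal)
}

#' Write a z-map or ROI volume as NIfTI
#'
#' @param x A [zmap()] or [roi_volume()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  if (inherits(x, "zmap")) {
    vals <- x$values
    vals[!x$mask] <- 0
    img <- RNifti::asNifti(vals)
  } else if (inherits(x, "roi_volume")) {
    img <- RNifti::asNifti(array(as.numeric(x$labels), dim = dim(x$labels)))
  } else {
    stop_input("expected a zmap or roi_volume")
  }
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume back as a z-map or ROI volume
#'
#' @param path NIfTI file path.
#' @param as `"zmap"` or `"roi_volume"`.
#' @return The requested object.
#' @export
read_volume_nifti <- function(path, as = c("zmap", "roi_volume")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  arr <- array(as.vector(img), dim = dim(img))
  if (as == "zmap") {
    zmap(arr, affine = unclass(aff))
  } else {
    roi_volume(array(as.integer(round(arr)), dim = dim(arr)),
               affine = unclass(aff))
  }
}

#' Write a triangulated mesh as ASCII PLY
#'
#' @param mesh List with `vertices` (n x 3), `faces` (m x 3, 1-based), and
#'   optionally `normals` (n x 3).
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  has_n <- !is.null(mesh$normals)
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    if (has_n) c("property float nx", "property float ny", "property float nz"),
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vert_block <- if (has_n) cbind(v, mesh$normals) else v
  vert_lines <- apply(vert_block, 1, paste, collapse = " ")
  face_lines <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(header, vert_lines, face_lines), path)
  invisible(path)
}

#' Read and write trial tables as TSV
#'
#' @param trials A trial table data frame.
#' @param path TSV path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the data
#'   frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a whole synthetic subject to a directory
#'
#' Writes the connectome (MatrixMarket), the ROI label volume (NIfTI), the
#' scalp and cortex meshes (PLY), and a JSON manifest of the scalar fields.
#'
#' @param bundle A [generate_subject()] bundle.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_connectome(bundle$connectome, file.path(dir, "connectome.mtx"))
  write_volume_nifti(bundle$roi_set$rois, file.path(dir, "rois.nii.gz"))
  write_ply(bundle$anatomy$scalp_mesh, file.path(dir, "scalp.ply"))
  write_ply(bundle$anatomy$cortex_mesh, file.path(dir, "cortex.ply"))
  jsonlite::write_json(
    list(
      subject_id = bundle$subject_id,
      cohort = bundle$cohort,
      rmt_pct_mso = bundle$rmt_pct_mso,
      hair_mm = bundle$hair_mm,
      rng_seed = bundle$rng_seed,
      observer = bundle$observer[c("threshold_s0", "slope_k", "guess_gamma",
                                   "lapse")],
      mni_to_native_affine = bundle$anatomy$mni_to_native_affine,
      sulcal_points = bundle$anatomy$sulcal_points
    ),
    file.path(dir, "subject.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
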