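#' Structural connectome object
#'
#' A connectome is an `n x n` symmetric, nonnegative matrix of streamline
#' counts between atlas regions, with a zero diagonal, together with node
#' labels and the index sets of the candidate frontal and parietal
#' stimulation regions.
#'
#' @param weights Symmetric nonnegative numeric matrix with zero diagonal.
#' @param node_labels Character vector of region labels, one per node.
#' @param candidate_frontal,candidate_parietal Integer vectors of node
#'   indices flagging candidate stimulation regions. Must be disjoint.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, node_labels = NULL,
                       candidate_frontal = integer(),
                       candidate_parietal = integer()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(node_labels)) {
    node_labels <- sprintf("node_%03d", seq_len(n))
  }
  obj <- structure(
    list(
      weights = weights,
      node_labels = as.character(node_labels),
      candidate_frontal = as.integer(candidate_frontal),
      candidate_parietal = as.integer(candidate_parietal)
    ),
    class = "connectome"
  )
  validate_connectome(obj)
  obj
}

validate_connectome <- function(x) {
  w <- x$weights
  n <- nrow(w)
  if (n < 2L || ncol(w) != n) stop_input("connectome must be square with n >= 2")
  if (any(!is.finite(w))) stop_input("connectome weights must be finite")
  if (any(w < 0)) stop_input("connectome weights must be nonnegative")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12))) {
    stop_input("connectome weights must be symmetric")
  }
  if (any(diag(w) != 0)) stop_input("connectome diagonal must be zero")
  if (length(x$node_labels) != n) stop_input("need one label per node")
  if (length(intersect(x$candidate_frontal, x$candidate_parietal)) > 0L) {
    stop_input("candidate index sets must be disjoint")
  }
  idx <- c(x$candidate_frontal, x$candidate_parietal)
  if (length(idx) && (any(idx < 1L) || any(idx > n))) {
    stop_input("candidate indices out of range")
  }
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> %d nodes, %d edges, %d frontal / %d parietal candidates\n",
    nrow(x$weights), sum(x$weights[upper.tri(x$weights)] > 0),
    length(x$candidate_frontal), length(x$candidate_parietal)
  ))
  invisible(x)
}

#' Modal controllability of every connectome node
#'
#' Normalizes the weight matrix to `A = W / (1 + lambda_max(W))` so that all
#' eigenvalues lie strictly inside the unit circle, eigendecomposes the
#' symmetric `A` into orthonormal eigenvectors `V` and eigenvalues `lambda`,
#' and scores each node by `phi_i = sum_j w(lambda_j) * V[i, j]^2`. The
#' default weighting `w(lambda) = 1 - lambda^2` emphasizes a node's coupling
#' to fast-decaying (hard-to-reach) modes of the linear network dynamics; the
#' alternative `(1 - lambda)^2` weighting is available but off by default.
#'
#' @param c A [connectome()].
#' @param weighting `"one_minus_lambda_sq"` (default) or
#'   `"one_minus_lambda_sq_alt"` for the `(1 - lambda)^2` variant.
#' @return An object of class `controllability_profile` with fields `phi`
#'   (named per-node values), `lambda_max`, `normalized_spectrum`, and
#'   `weighting`.
#' @export
modal_controllability <- function(c, weighting = c("one_minus_lambda_sq",
                                                   "one_minus_lambda_sq_alt")) {
  weighting <- match.arg(weighting)
  validate_connectome(c)
  w <- c$weights
  lambda_max <- max(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
  a <- w / (1 + lambda_max)
  es <- eigen(a, symmetric = TRUE)
  lam <- es$values
  v <- es$vectors
  wts <- if (weighting == "one_minus_lambda_sq") 1 - lam^2 else (1 - lam)^2
  phi <- as.vector((v^2) %*% wts)
  names(phi) <- c$node_labels
  structure(
    list(
      phi = phi,
      lambda_max = lambda_max,
      normalized_spectrum = lam,
      weighting = weighting
    ),
    class = "controllability_profile"
  )
}

#' @export
print.controllability_profile <- function(x, ...) {
  cat(sprintf(
    "<controllability_profile> %d nodes, phi in [%.4f, %.4f], lambda_max = %.3f\n",
    length(x$phi), min(x$phi), max(x$phi), x$lambda_max
  ))
  invisible(x)
}

#' Controllability of the candidate regions of one hemisphere area
#'
#' Extracts the modal controllability values of the candidate frontal or
#' parietal regions, ordered by descending phi with ties broken by ascending
#' label so the ordering is deterministic.
#'
#' @param profile A `controllability_profile` from [modal_controllability()].
#' @param c The [connectome()] the profile was computed on.
#' @param region `"frontal"` or `"parietal"`.
#' @return A data frame with columns `label` and `phi`, one row per
#'   candidate, in selection order.
#' @export
candidate_controllability <- function(profile, c, region = c("frontal", "parietal")) {
  region <- match.arg(region)
  idx <- switch(region,
    frontal = c$candidate_frontal,
    parietal = c$candidate_parietal
  )
  if (length(idx) == 0L) stop_input("empty %s candidate set", region)
  out <- data.frame(
    label = c$node_labels[idx],
    phi = unname(profile$phi[idx]),
    stringsAsFactors = FALSE
  )
  out[order(-out$phi, out$label), , drop = FALSE]
}
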