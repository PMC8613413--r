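#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate an expression under a temporary RNG seed
#'
#' When `seed` is `NULL` the expression runs under the ambient RNG stream.
#' @noRd
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

## Derive `n` child seeds from one master seed. Kept below 2^30 so callers
## can add small offsets without integer overflow.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(2^30, n))
}

## Stable content hash of plain data (used for pipeline provenance).
## Serializes with version 3 and a fixed byte order, then md5s the file.
content_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

## Unit-normalize the rows of a matrix (or a single vector).
unit_rows <- function(m) {
  if (is.null(dim(m))) return(m / sqrt(sum(m^2)))
  m / sqrt(rowSums(m^2))
}

## Signed angle (degrees, in (-180, 180]) from `a` to `b` around axis `axis`.
signed_angle_deg <- function(a, b, axis) {
  crossp <- c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
  ang <- atan2(sum(crossp * axis), sum(a * b)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## Draws from a normal truncated below at `lower`.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}
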