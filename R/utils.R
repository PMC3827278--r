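#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a labeled distance matrix
#'
#' Checks that `m` is a square numeric matrix with matching, unique row and
#' column names, zero diagonal and symmetry within `tol`.
#'
#' @param m numeric matrix.
#' @param tol symmetry tolerance.
#' @return `m`, invisibly, with symmetric averaging applied.
#' @noRd
check_distance_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m)) stop("distance matrix must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("distance matrix must have dimnames")
  if (!identical(rownames(m), colnames(m))) stop("row and column labels differ")
  if (anyDuplicated(rownames(m))) stop("duplicate labels in distance matrix")
  if (any(!is.finite(m))) stop("distance matrix contains non-finite entries")
  asym <- max(abs(m - t(m)))
  if (asym > tol) stop(sprintf("matrix asymmetric beyond tolerance (max |m - t(m)| = %.3g)", asym))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  invisible(m)
}

#' Shift a distance matrix to be nonnegative
#'
#' \eqn{F_{ST}} estimates can be slightly negative for undifferentiated pairs.
#' Before tree building, if any off-diagonal entry is negative the whole
#' off-diagonal is shifted up by the (absolute) minimum so the smallest entry
#' becomes zero; the diagonal stays zero. A message reports the shift.
#'
#' @param m labeled symmetric matrix.
#' @return shifted matrix with a `"shift"` attribute (0 when untouched).
#' @export
shift_nonnegative <- function(m) {
  m <- check_distance_matrix(m, tol = 1e-8)
  off <- m[upper.tri(m) | lower.tri(m)]
  shift <- 0
  if (length(off) && min(off) < 0) {
    shift <- -min(off)
    m[upper.tri(m) | lower.tri(m)] <- m[upper.tri(m) | lower.tri(m)] + shift
    message(sprintf("negative distances shifted up by %.6g before tree building", shift))
  }
  attr(m, "shift") <- shift
  m
}

#' Derive a sequence of stage seeds from a master seed
#'
#' All pipeline stages draw their own seed from the master seed through this
#' single scheme, so any stage can be re-run in isolation. Seeds stay within
#' the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param n number of stage seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Rank-transform a vector to [0, 1]
#' @noRd
unit_rank <- function(x) {
  r <- rank(x, ties.method = "average")
  if (length(x) <= 1) return(rep(0.5, length(x)))
  (r - 1) / (length(x) - 1)
}
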