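#' Binary substructure fingerprint
#'
#' A fingerprint is the unit of all similarity arithmetic in the package: a
#' fixed-length binary descriptor stored sparsely as the sorted set of its
#' set-bit positions (1-based). Fingerprints of chemical structures are
#' produced by [fingerprint_molecules()]; synthetic fingerprints come from
#' [simulate_library()].
#'
#' @param bits integer vector of set-bit positions, each in `1..nbits`.
#'   Duplicates are collapsed.
#' @param nbits total bit count (positive integer), default 1024.
#' @return An object of class `fingerprint` with elements `bits` (sorted
#'   unique integer positions) and `nbits`.
#' @examples
#' fingerprint(c(1, 5, 9), nbits = 16)
#' @export
fingerprint <- function(bits, nbits = 1024L) {
  nbits <- as.integer(nbits)
  if (length(nbits) != 1L || is.na(nbits) || nbits < 1L)
    stop("'nbits' must be a single positive integer")
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 1L || max(bits) > nbits))
    stop("bit positions must lie in 1..", nbits)
  structure(list(bits = bits, nbits = nbits), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d/%d bits set>\n", length(x$bits), x$nbits))
  invisible(x)
}

#' Number of set bits in a fingerprint
#' @param fp a [fingerprint()].
#' @return Integer count of set bits.
#' @export
n_set <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  length(fp$bits)
}

#' Tanimoto coefficient of two fingerprints
#'
#' \eqn{TC(A, B) = |A \cap B| / |A \cup B|} over the set bits of two
#' equal-length fingerprints. The Tanimoto coefficient is symmetric and lies
#' in \[0, 1\]. Two empty fingerprints share no substructure evidence at all,
#' so their TC is defined here as 0 (with a warning) rather than the
#' indeterminate 0/0.
#'
#' @param a,b [fingerprint()] objects with identical `nbits`.
#' @return TC value in \[0, 1\].
#' @examples
#' tanimoto(fingerprint(1:3, 16), fingerprint(2:4, 16)) # 0.5
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$nbits != b$nbits)
    stop("fingerprint lengths differ (", a$nbits, " vs ", b$nbits, ")")
  n_int <- length(intersect(a$bits, b$bits))
  n_uni <- length(a$bits) + length(b$bits) - n_int
  if (n_uni == 0L) {
    warning("TC of two empty fingerprints is undefined; returning 0")
    return(0)
  }
  n_int / n_uni
}

#' Pack a list of fingerprints into a dense 0/1 matrix
#'
#' @param fps named list of [fingerprint()] objects, all with equal `nbits`.
#' @return numeric matrix (one row per fingerprint, `nbits` columns) with
#'   rownames from `fps`.
#' @keywords internal
fp_matrix <- function(fps) {
  stopifnot(length(fps) > 0L)
  nb <- unique(vapply(fps, function(f) f$nbits, integer(1)))
  if (length(nb) != 1L) stop("fingerprints have differing lengths")
  m <- matrix(0, nrow = length(fps), ncol = nb)
  for (i in seq_along(fps)) m[i, fps[[i]]$bits] <- 1
  rownames(m) <- names(fps)
  m
}

#' All-pairs Tanimoto coefficients between two fingerprint sets
#'
#' Computes the full TC matrix by bit-matrix algebra; pairs where both
#' fingerprints are empty get TC 0.
#'
#' @param fps_a,fps_b named lists of [fingerprint()] objects sharing one
#'   `nbits`.
#' @return numeric matrix of TC values, `length(fps_a)` x `length(fps_b)`.
#' @export
tanimoto_matrix <- function(fps_a, fps_b = fps_a) {
  A <- fp_matrix(fps_a)
  B <- fp_matrix(fps_b)
  if (ncol(A) != ncol(B)) stop("fingerprint lengths differ between sets")
  n_int <- tcrossprod(A, B)
  n_uni <- outer(rowSums(A), rowSums(B), "+") - n_int
  tc <- ifelse(n_uni > 0, n_int / n_uni, 0)
  dimnames(tc) <- list(rownames(A), rownames(B))
  tc
}
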