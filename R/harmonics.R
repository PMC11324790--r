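#' Degree-normalized graph Laplacian
#'
#' Computes `L = I - D^{-1/2} C D^{-1/2}` where `D` is the diagonal degree
#' (strength) matrix of the weighted connectome `C`. Eigenvalues of this
#' operator lie in `[0, 2]`, with 0 attained exactly once per connected
#' component.
#'
#' @param C A symmetric nonnegative `connectome` (or matrix) with strictly
#'   positive node degrees.
#' @return List with `L` (the Laplacian matrix) and `degree` (row sums of
#'   `C`).
#' @export
normalized_laplacian <- function(C) {
  W <- unclass(as.matrix(C))
  if (max(abs(W - t(W))) > 1e-10) {
    stop("Laplacian requires a symmetric matrix", call. = FALSE)
  }
  d <- rowSums(W)
  if (any(d <= 0)) {
    bad <- rownames(W)[which(d <= 0)[1]] %||% which(d <= 0)[1]
    stop("isolated node (zero degree) at region ", bad, call. = FALSE)
  }
  inv_sqrt_d <- 1 / sqrt(d)
  L <- diag(nrow(W)) - (inv_sqrt_d * W) %*% diag(inv_sqrt_d)
  L <- (L + t(L)) / 2  # enforce exact symmetry against rounding
  dimnames(L) <- dimnames(W)
  list(L = L, degree = d)
}

#' Eigendecomposition of a graph Laplacian into a harmonic basis
#'
#' Returns the orthonormal eigenvectors (harmonics) of a symmetric Laplacian
#' with eigenvalues in ascending order. Eigenvector signs are arbitrary; a
#' fixed convention (entry of largest magnitude positive, ties broken by
#' lowest index) makes output reproducible across solvers. Within numerically
#' degenerate eigenvalue blocks the basis is solver-dependent and no canonical
#' ordering is promised; downstream matching is the canonicalization
#' mechanism.
#'
#' @param L Symmetric Laplacian matrix (from [normalized_laplacian()]).
#' @param degree_vector Node degrees of the connectome the Laplacian came
#'   from; retained for low-rank reconstruction.
#' @param source_id Free-text identifier recorded on the basis.
#' @return An object of class `harmonic_basis`: list with `vectors` (N x N,
#'   columns are harmonics), `eigenvalues` (ascending), `degree`,
#'   `region_ids`, `source_id`.
#' @export
eig_harmonics <- function(L, degree_vector = NULL, source_id = "unnamed") {
  L <- as.matrix(L)
  if (max(abs(L - t(L))) > 1e-8) {
    stop("eig_harmonics requires a symmetric matrix", call. = FALSE)
  }
  es <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(es$values))  # eigen() returns descending
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  vals[abs(vals) < 1e-12] <- pmax(vals[abs(vals) < 1e-12], 0)
  vecs <- fix_signs(vecs)
  ids <- rownames(L) %||% paste0("roi_", seq_len(nrow(L)))
  rownames(vecs) <- ids
  structure(list(vectors = vecs,
                 eigenvalues = vals,
                 degree = degree_vector,
                 region_ids = ids,
                 source_id = source_id),
            class = "harmonic_basis")
}

# sign convention: largest-|entry| positive, ties -> lowest index
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))  # which.max takes the first maximum
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Full harmonic decomposition of a connectome
#'
#' Convenience wrapper: Frobenius-normalize (optional), build the
#' degree-normalized Laplacian, and eigendecompose.
#'
#' @param C A `connectome`.
#' @param normalize Frobenius-normalize first (default TRUE).
#' @param source_id Identifier stored on the basis.
#' @return A `harmonic_basis`.
#' @export
connectome_harmonics <- function(C, normalize = TRUE, source_id = "unnamed") {
  if (normalize) C <- normalize_frobenius(C)
  lap <- normalized_laplacian(C)
  eig_harmonics(lap$L, degree_vector = lap$degree, source_id = source_id)
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat(sprintf("<harmonic_basis> %d harmonics (source: %s)\n",
              length(x$eigenvalues), x$source_id))
  cat(sprintf("  eigenvalues: [%.4g, %.4g]\n",
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a harmonic basis into a per-harmonic tibble
#' @param x A `harmonic_basis`.
#' @param ... Unused.
#' @return Tibble with `harmonic` (1-based index) and `eigenvalue`.
#' @export
tidy.harmonic_basis <- function(x, ...) {
  tibble::tibble(harmonic = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues)
}

#' One-row summary of a harmonic basis
#' @param x A `harmonic_basis`.
#' @param ... Unused.
#' @export
glance.harmonic_basis <- function(x, ...) {
  U <- x$vectors
  tibble::tibble(
    n_harmonics = length(x$eigenvalues),
    lambda_min = min(x$eigenvalues),
    lambda_max = max(x$eigenvalues),
    orthonormality_error = max(abs(crossprod(U) - diag(ncol(U)))),
    source_id = x$source_id
  )
}
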