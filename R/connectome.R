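#' Construct a connectome matrix
#'
#' A connectome is a symmetric, nonnegative, zero-diagonal weighted adjacency
#' matrix over labelled brain regions (streamline-count-like units, or unit
#' Frobenius norm once normalized).
#'
#' @param weights Square numeric matrix of nonnegative connection weights.
#' @param region_ids Character vector of region identifiers; defaults to the
#'   matrix dimnames, or `"roi_<i>"` if absent.
#' @param normalized Logical; `TRUE` if `weights` already has unit Frobenius
#'   norm (checked).
#' @return An object of class `connectome`: the weight matrix with region ids
#'   as dimnames and a `normalized` attribute.
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2)
#' connectome(W, c("A", "B"))
#' @export
connectome <- function(weights, region_ids = NULL, normalized = FALSE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome weights must be a square matrix", call. = FALSE)
  }
  if (is.null(region_ids)) {
    region_ids <- rownames(weights) %||% paste0("roi_", seq_len(nrow(weights)))
  }
  stopifnot(length(region_ids) == nrow(weights))
  dimnames(weights) <- list(region_ids, region_ids)
  obj <- structure(weights, class = c("connectome", "matrix", "array"),
                   normalized = isTRUE(normalized))
  validate_connectome(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
validate_connectome <- function(C, sym_tol = 1e-12) {
  W <- unclass(C)
  if (anyNA(W)) stop("connectome contains missing values", call. = FALSE)
  if (max(abs(W - t(W))) > sym_tol) {
    stop("connectome is not symmetric within tolerance ", sym_tol, call. = FALSE)
  }
  if (any(diag(W) != 0)) stop("connectome diagonal must be zero", call. = FALSE)
  if (any(W < 0)) stop("connectome weights must be nonnegative", call. = FALSE)
  if (isTRUE(attr(C, "normalized")) &&
      abs(frobenius_norm(W) - 1) > 1e-12) {
    stop("connectome flagged normalized but Frobenius norm != 1", call. = FALSE)
  }
  invisible(C)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d regions, %s, density %.3f\n",
              nrow(x),
              if (isTRUE(attr(x, "normalized"))) "unit Frobenius norm"
              else "unnormalized",
              mean(x[upper.tri(x)] > 0)))
  invisible(x)
}

#' Region identifiers of a connectome or harmonic basis
#' @param x A `connectome`, `adjacency`, or `harmonic_basis` object.
#' @return Character vector of region ids.
#' @export
region_ids <- function(x) {
  if (inherits(x, "harmonic_basis")) x$region_ids else rownames(x)
}

frobenius_norm <- function(W) sqrt(sum(W^2))

#' Normalize a connectome to unit Frobenius norm
#'
#' Rescales the weight matrix so that its Frobenius norm equals 1, the scale
#' on which all spectral operations are performed.
#'
#' @param C A `connectome`.
#' @return The rescaled `connectome` with the `normalized` attribute set.
#' @export
normalize_frobenius <- function(C) {
  validate_connectome(C)
  nf <- frobenius_norm(unclass(C))
  if (nf == 0) stop("cannot normalize an all-zero connectome", call. = FALSE)
  connectome(unclass(C) / nf, region_ids(C), normalized = TRUE)
}

#' Consensus connectome of a subject ensemble
#'
#' Each subject matrix is Frobenius-normalized (so dense subjects cannot
#' dominate), the elementwise mean is taken, and the mean is re-normalized to
#' unit Frobenius norm ready for Laplacian construction.
#'
#' @param subjects List of `connectome` objects sharing region ids and order.
#' @return A normalized `connectome`.
#' @export
consensus_connectome <- function(subjects) {
  stopifnot(length(subjects) >= 1)
  ids <- region_ids(subjects[[1]])
  for (k in seq_along(subjects)) {
    mism <- which(region_ids(subjects[[k]]) != ids)
    if (length(mism) > 0) {
      stop(sprintf(
        "subject %d region ids differ from subject 1 (first mismatch at position %d: '%s' vs '%s')",
        k, mism[1], region_ids(subjects[[k]])[mism[1]], ids[mism[1]]),
        call. = FALSE)
    }
  }
  normed <- lapply(subjects, function(s) unclass(normalize_frobenius(s)))
  M <- Reduce(`+`, normed) / length(normed)
  normalize_frobenius(connectome(M, ids))
}

#' Test graph connectedness of a connectome
#' @param C A `connectome` or symmetric nonnegative matrix.
#' @return Logical.
#' @export
is_connected_graph <- function(C) {
  g <- igraph::graph_from_adjacency_matrix(unclass(C) > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::is_connected(g)
}
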