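#' Threshold low-amplitude harmonic entries to zero
#'
#' Entries with `|u| <= T` are set to exactly zero to eliminate spurious
#' low-amplitude fluctuation around zero before frequency measures are
#' computed. The default threshold is 0.001.
#'
#' @param u Numeric harmonic vector.
#' @param T Nonnegative amplitude threshold.
#' @return Thresholded vector.
#' @export
apply_threshold <- function(u, T = 0.001) {
  stopifnot(T >= 0)
  u[abs(u) <= T] <- 0
  u
}

#' Harmonic sparsity
#'
#' Fraction of regions where the thresholded harmonic amplitude is zero.
#' Classical Fourier harmonics have sparsity zero (infinite support); sparse
#' harmonics defy that intuition.
#'
#' @inheritParams apply_threshold
#' @return Fraction in `[0, 1]`.
#' @export
sparsity <- function(u, T = 0.001) {
  mean(apply_threshold(u, T) == 0)
}

#' Zero-cross rate along the regional ordering
#'
#' Rate at which the harmonic changes polarity when scanned in the spatial
#' region ordering. Thresholded zeros are skipped: they neither count as
#' crossings nor reset the running sign. The denominator is fixed at `N - 1`
#' so the result is a rate in `[0, 1]`.
#'
#' @inheritParams apply_threshold
#' @return Rate in `[0, 1]`.
#' @export
zero_cross_rate <- function(u, T = 0.001) {
  ut <- apply_threshold(u, T)
  s <- sign(ut)
  s <- s[s != 0]
  if (length(s) == 0) {
    warning("all-zero vector after thresholding; zero-cross rate is 0")
    return(0)
  }
  sum(diff(s) != 0) / (length(u) - 1)
}

#' Network zero crossings (graph-cut weight of a harmonic's sign partition)
#'
#' Sums the connectome weight over all edges whose endpoints carry opposite
#' supra-threshold signs in the harmonic — the graph-cut weight described by
#' the harmonic's polarity pattern. High-frequency harmonics cut heavier
#' edges. The threshold is applied to `|u|` by default; `on_square = TRUE`
#' thresholds `u^2` instead.
#'
#' @param u Harmonic vector.
#' @param C `connectome` (or symmetric matrix) of the same dimension.
#' @param T Amplitude threshold.
#' @param on_square Threshold `u^2 > T` instead of `|u| > T`.
#' @return Nonnegative cut weight.
#' @export
network_zero_crossings <- function(u, C, T = 0.001, on_square = FALSE) {
  W <- unclass(as.matrix(C))
  stopifnot(length(u) == nrow(W))
  supra <- if (on_square) u^2 > T else abs(u) > T
  opp <- outer(u, u) < 0 & outer(supra, supra, `&`)
  sum(W[opp]) / 2
}

#' Regional adjacency from boundary-distance lists
#'
#' Builds the spatial adjacency whose entries are sums of reciprocal
#' boundary-point distances between region pairs: `a_ij = sum_k 1/d(i_k,
#' j_k)`. Cross-hemisphere entries are zeroed.
#'
#' @param boundaries Tibble/data frame with columns `region_i`, `region_j`,
#'   `distance` (one row per boundary point pair, distances > 0).
#' @param region_table Region metadata (needs `region_id`, `hemisphere`).
#' @return An `adjacency` matrix object.
#' @export
adjacency_from_boundaries <- function(boundaries, region_table) {
  if (any(boundaries$distance <= 0)) {
    stop("boundary distances must be strictly positive", call. = FALSE)
  }
  ids <- region_table$region_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(boundaries$region_i, ids)
  j <- match(boundaries$region_j, ids)
  if (anyNA(i) || anyNA(j)) stop("boundary regions not in region table", call. = FALSE)
  recip <- 1 / boundaries$distance
  for (k in seq_along(i)) {
    A[i[k], j[k]] <- A[i[k], j[k]] + recip[k]
  }
  A <- A + t(A)
  A[A != t(A)] <- 0  # defensive; construction is symmetric
  hemi <- stats::setNames(region_table$hemisphere, ids)
  cross <- outer(hemi, hemi, `!=`)
  A[cross] <- 0
  diag(A) <- 0
  structure(A, class = c("adjacency", "matrix", "array"), hemisphere = hemi)
}

#' Spatial roughness of a harmonic on a regional adjacency
#'
#' Measures how much the harmonic deviates from its adjacency-weighted
#' neighborhood average, `||u_h - A_bar_h u_h||_2`, computed separately per
#' hemisphere on the degree-normalized adjacency and averaged across
#' hemispheres (unweighted mean). Nodes isolated within the adjacency are
#' excluded from the norm. The input is thresholded first.
#'
#' @param u Harmonic vector.
#' @param A `adjacency` object (with `hemisphere` attribute) from
#'   [generate_lattice_adjacency()] or [adjacency_from_boundaries()].
#' @param T Amplitude threshold applied to `u` first.
#' @return Nonnegative roughness value.
#' @export
roughness <- function(u, A, T = 0.001) {
  hemi <- attr(A, "hemisphere")
  if (is.null(hemi)) stop("adjacency lacks hemisphere labels", call. = FALSE)
  u <- apply_threshold(u, T)
  vals <- vapply(unique(hemi), function(h) {
    idx <- which(hemi == h)
    Ah <- unclass(A)[idx, idx, drop = FALSE]
    d <- rowSums(Ah)
    if (all(d == 0)) {
      stop("hemisphere ", h, " has no adjacency edges", call. = FALSE)
    }
    keep <- d > 0
    Ah <- Ah[keep, keep, drop = FALSE]
    uh <- u[idx][keep]
    dh <- rowSums(Ah)
    Abar <- (1 / sqrt(dh)) * Ah %*% diag(1 / sqrt(dh), nrow = length(dh))
    sqrt(sum((uh - as.vector(Abar %*% uh))^2))
  }, numeric(1))
  mean(vals)
}

#' Per-harmonic spatial frequency measures
#'
#' Computes sparsity, zero-cross rate, network zero crossings, and roughness
#' for every harmonic of a basis, against the connectome and the regional
#' adjacency.
#'
#' @param basis A `harmonic_basis`.
#' @param C The `connectome` the basis came from.
#' @param A Regional `adjacency` (optional; roughness is `NA` without it).
#' @param T Amplitude threshold.
#' @return Tibble with columns `harmonic`, `eigenvalue`, `sparsity`, `zcr`,
#'   `net_zero_x`, `roughness`.
#' @export
harmonic_frequency <- function(basis, C, A = NULL, T = 0.001) {
  U <- basis$vectors
  N <- ncol(U)
  tibble::tibble(
    harmonic = seq_len(N),
    eigenvalue = basis$eigenvalues,
    sparsity = vapply(seq_len(N), function(i) sparsity(U[, i], T), numeric(1)),
    zcr = vapply(seq_len(N), function(i)
      suppressWarnings(zero_cross_rate(U[, i], T)), numeric(1)),
    net_zero_x = vapply(seq_len(N), function(i)
      network_zero_crossings(U[, i], C, T), numeric(1)),
    roughness = if (is.null(A)) NA_real_ else
      vapply(seq_len(N), function(i) roughness(U[, i], A, T), numeric(1))
  )
}

#' Sensitivity of frequency measures to the amplitude threshold
#'
#' Recomputes all per-harmonic measures over a grid of thresholds.
#'
#' @inheritParams harmonic_frequency
#' @param thresholds Numeric grid of thresholds.
#' @return Long tibble: the [harmonic_frequency()] table stacked with a
#'   `threshold` column.
#' @export
threshold_sweep <- function(basis, C, A = NULL,
                            thresholds = c(0, 5e-4, 1e-3, 2e-3, 5e-3)) {
  purrr::map_dfr(thresholds, function(T) {
    dplyr::mutate(harmonic_frequency(basis, C, A, T), threshold = T)
  })
}
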