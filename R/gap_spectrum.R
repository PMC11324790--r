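#' Raw eigenvalue gap-spectrum
#'
#' The nearest-neighbor spacing of each ascending eigenvalue,
#' `Gap(lambda_i) = min_{j != i} |lambda_i - lambda_j|`, which for a sorted
#' spectrum reduces to the smaller of the two adjacent spacings (one-sided at
#' the ends). A zero gap marks exact degeneracy.
#'
#' @param eigenvalues Ascending numeric eigenvalues.
#' @return Nonnegative vector of the same length.
#' @export
raw_gap_spectrum <- function(eigenvalues) {
  n <- length(eigenvalues)
  if (n < 2) stop("gap-spectrum requires at least 2 eigenvalues", call. = FALSE)
  if (is.unsorted(eigenvalues)) {
    stop("eigenvalues must be sorted ascending", call. = FALSE)
  }
  d <- diff(eigenvalues)
  pmin(c(d, Inf), c(Inf, d))
}

#' Spline-smoothed gap-spectrum of an eigenvalue curve
#'
#' Fits a least-squares B-spline (default degree 10, 3 interior knots at
#' index quartiles) to the ascending eigenvalues as a function of harmonic
#' index, then evaluates the analytic first derivative (the smooth
#' gap-spectrum, i.e. the local eigenvalue spacing) and second derivative
#' (the gap-spectrum's derivative, used for regime boundary detection) at
#' every index. Derivatives amplify noise, which is why the raw spacings are
#' smoothed before differentiation.
#'
#' @param eigenvalues Ascending eigenvalues.
#' @param degree Polynomial degree of the spline.
#' @param interior_knots Number of interior knots, placed at index quantiles.
#' @return A `gap_spectrum` object: eigenvalues, `raw_gaps`, fitted values,
#'   `gap_curve` (first derivative), `gap_derivative` (second derivative),
#'   `residual_rms`, and the fit configuration.
#' @export
smooth_gap_spectrum <- function(eigenvalues, degree = 10, interior_knots = 3) {
  n <- length(eigenvalues)
  if (n <= degree + interior_knots + 1) {
    stop("too few eigenvalues for a degree-", degree, " spline with ",
         interior_knots, " interior knots; lower the degree", call. = FALSE)
  }
  x <- seq_len(n)
  probs <- seq_len(interior_knots) / (interior_knots + 1)
  inner <- stats::quantile(x, probs, names = FALSE)
  knots <- c(rep(1, degree + 1), inner, rep(n, degree + 1))
  B <- splines::splineDesign(knots, x, ord = degree + 1)
  cf <- qr.coef(qr(B), eigenvalues)
  fitted <- as.vector(B %*% cf)
  d1 <- as.vector(splines::splineDesign(knots, x, ord = degree + 1,
                                        derivs = 1) %*% cf)
  d2 <- as.vector(splines::splineDesign(knots, x, ord = degree + 1,
                                        derivs = 2) %*% cf)
  structure(list(eigenvalues = eigenvalues,
                 raw_gaps = raw_gap_spectrum(eigenvalues),
                 fitted = fitted,
                 gap_curve = d1,
                 gap_derivative = d2,
                 residual_rms = sqrt(mean((eigenvalues - fitted)^2)),
                 degree = degree,
                 interior_knots = interior_knots,
                 knots = knots),
            class = "gap_spectrum")
}

#' @export
print.gap_spectrum <- function(x, ...) {
  cat(sprintf("<gap_spectrum> N = %d, spline degree %d (%d interior knots), residual RMS %.3g\n",
              length(x$eigenvalues), x$degree, x$interior_knots,
              x$residual_rms))
  invisible(x)
}

#' @export
tidy.gap_spectrum <- function(x, ...) {
  tibble::tibble(harmonic = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 raw_gap = x$raw_gaps,
                 fitted = x$fitted,
                 gap_curve = x$gap_curve,
                 gap_derivative = x$gap_derivative)
}

# interior local extrema with a plateau rule: the first index of a plateau
# counts; strictness tolerance `tol`
find_local_extrema <- function(g, tol = 1e-12) {
  d <- diff(g)
  s <- ifelse(d > tol, 1L, ifelse(d < -tol, -1L, 0L))
  nz <- which(s != 0L)
  maxima <- integer(0); minima <- integer(0)
  if (length(nz) >= 2) {
    for (k in seq_len(length(nz) - 1)) {
      if (s[nz[k]] == 1L && s[nz[k + 1]] == -1L) maxima <- c(maxima, nz[k] + 1L)
      if (s[nz[k]] == -1L && s[nz[k + 1]] == 1L) minima <- c(minima, nz[k] + 1L)
    }
  }
  list(maxima = maxima, minima = minima)
}

#' Degenerate-regime bounds from a gap-spectrum
#'
#' The lower and upper bounds of the degenerate regime are the first local
#' maximum and the last local minimum of the gap-spectrum's derivative
#' (`gap_derivative`). Indices `[lo, hi]` inclusive form the degenerate
#' regime; indices below `lo` are integrative, above `hi` segregative.
#'
#' @param gap A `gap_spectrum`.
#' @return Integer vector `c(lo, hi)`.
#' @export
regime_bounds <- function(gap) {
  ex <- find_local_extrema(gap$gap_derivative)
  if (length(ex$maxima) == 0 || length(ex$minima) == 0) {
    stop("no degenerate regime detectable: gap-spectrum derivative has no interior extrema",
         call. = FALSE)
  }
  lo <- ex$maxima[1]
  hi <- ex$minima[length(ex$minima)]
  if (lo >= hi) {
    stop("no degenerate regime detectable: first maximum does not precede last minimum",
         call. = FALSE)
  }
  c(lo = lo, hi = hi)
}

#' Regime labels from degenerate-regime bounds
#' @param n Number of harmonics.
#' @param lo,hi Degenerate bounds (inclusive).
#' @return Factor of length `n` with levels integrative, degenerate,
#'   segregative.
#' @export
regime_labels_from_bounds <- function(n, lo, hi) {
  stopifnot(lo >= 2, hi <= n - 1, lo <= hi)
  factor(c(rep("integrative", lo - 1),
           rep("degenerate", hi - lo + 1),
           rep("segregative", n - hi)),
         levels = c("integrative", "degenerate", "segregative"))
}

#' Per-subject regime labels from a subject's own spectrum
#'
#' Computes the subject's smoothed gap-spectrum and labels each of its
#' harmonics integrative/degenerate/segregative from the detected bounds.
#'
#' @param basis The subject's `harmonic_basis`.
#' @inheritParams smooth_gap_spectrum
#' @return Factor of regime labels in the subject's own harmonic ordering.
#' @export
subject_regime_labels <- function(basis, degree = 10, interior_knots = 3) {
  gap <- smooth_gap_spectrum(basis$eigenvalues, degree, interior_knots)
  b <- regime_bounds(gap)
  regime_labels_from_bounds(length(basis$eigenvalues), b["lo"], b["hi"])
}

#' Consensus regime partition by majority vote
#'
#' Each subject's harmonics are labelled from the subject's own gap-spectrum,
#' transported to consensus indexing through the subject's matching
#' permutation, and each consensus harmonic receives one vote per subject.
#' The final boundaries are the majority crossing points: the first and last
#' consensus indices where the degenerate vote reaches 0.5 (an exact 0.5 tie
#' resolves toward the degenerate label, widening the middle regime); labels
#' are made contiguous from those crossings.
#'
#' @param per_subject List of lists, each with elements `labels` (factor from
#'   [subject_regime_labels()], subject ordering) and `match` (the subject's
#'   `harmonic_match` to the consensus).
#' @param fallback Optional `c(lo, hi)` used (with a warning) when the
#'   degenerate vote never reaches 0.5 — typically the consensus-SC-only
#'   bounds.
#' @return A `regime_partition`: list with `bounds`, `labels`, `votes`
#'   (tibble of per-index vote fractions), `n_per_regime`.
#' @export
consensus_regimes <- function(per_subject, fallback = NULL) {
  stopifnot(length(per_subject) >= 1)
  N <- length(per_subject[[1]]$labels)
  lev <- c("integrative", "degenerate", "segregative")
  counts <- matrix(0, N, 3, dimnames = list(NULL, lev))
  for (s in per_subject) {
    p <- s$match$permutation
    transported <- as.character(s$labels)[p]  # consensus index i <- subject p(i)
    for (k in 1:3) counts[, k] <- counts[, k] + (transported == lev[k])
  }
  votes <- counts / length(per_subject)
  deg <- votes[, "degenerate"] >= 0.5
  if (!any(deg)) {
    if (is.null(fallback)) {
      stop("degenerate vote never reaches 0.5 and no fallback bounds supplied",
           call. = FALSE)
    }
    warning("degenerate vote never reaches 0.5; falling back to consensus-SC bounds")
    lo <- fallback[1]; hi <- fallback[2]
  } else {
    lo <- which(deg)[1]
    hi <- which(deg)[sum(deg)]
  }
  labels <- regime_labels_from_bounds(N, lo, hi)
  structure(list(bounds = c(lo = as.integer(lo), hi = as.integer(hi)),
                 labels = labels,
                 votes = tibble::tibble(harmonic = seq_len(N),
                                        integrative = votes[, 1],
                                        degenerate = votes[, 2],
                                        segregative = votes[, 3]),
                 n_per_regime = as.integer(table(labels))),
            class = "regime_partition")
}

#' Single-basis regime partition (no voting)
#'
#' Convenience for a lone connectome: detects bounds on its own gap-spectrum
#' and builds the partition directly.
#'
#' @param basis A `harmonic_basis`.
#' @inheritParams smooth_gap_spectrum
#' @return A `regime_partition`.
#' @export
regime_partition <- function(basis, degree = 10, interior_knots = 3) {
  gap <- smooth_gap_spectrum(basis$eigenvalues, degree, interior_knots)
  b <- regime_bounds(gap)
  N <- length(basis$eigenvalues)
  labels <- regime_labels_from_bounds(N, b["lo"], b["hi"])
  onehot <- sapply(levels(labels), function(l) as.numeric(labels == l))
  structure(list(bounds = c(lo = as.integer(b["lo"]), hi = as.integer(b["hi"])),
                 labels = labels,
                 votes = tibble::tibble(harmonic = seq_len(N),
                                        integrative = onehot[, "integrative"],
                                        degenerate = onehot[, "degenerate"],
                                        segregative = onehot[, "segregative"]),
                 n_per_regime = as.integer(table(labels))),
            class = "regime_partition")
}

#' @export
print.regime_partition <- function(x, ...) {
  cat(sprintf("<regime_partition> integrative 1-%d | degenerate %d-%d | segregative %d-%d\n",
              x$bounds["lo"] - 1, x$bounds["lo"], x$bounds["hi"],
              x$bounds["hi"] + 1, length(x$labels)))
  invisible(x)
}

#' @export
tidy.regime_partition <- function(x, ...) {
  dplyr::mutate(x$votes, label = x$labels)
}

#' Harmonic indices belonging to a regime
#' @param partition A `regime_partition`.
#' @param regime One of `"integrative"`, `"degenerate"`, `"segregative"`.
#' @return Integer indices.
#' @export
regime_indices <- function(partition, regime) {
  regime <- match.arg(regime, c("integrative", "degenerate", "segregative"))
  which(partition$labels == regime)
}
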