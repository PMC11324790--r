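#' Harmonic power basis
#'
#' Squares each harmonic elementwise and L2-normalizes the result:
#' `u_bar_i = u_i^2 / ||u_i^2||_2`. Power vectors are nonnegative and
#' sign-invariant, describing the spatial power distribution of each
#' harmonic irrespective of polarity.
#'
#' @param basis A `harmonic_basis`.
#' @return A `power_basis`: list with `vectors` (N x N nonnegative,
#'   unit-norm columns), `region_ids`, `source_id`.
#' @export
power_basis <- function(basis) {
  U2 <- basis$vectors^2
  nrm <- sqrt(colSums(U2^2))
  stopifnot(all(nrm > 0))
  structure(list(vectors = sweep(U2, 2, nrm, `/`),
                 region_ids = basis$region_ids,
                 source_id = basis$source_id),
            class = "power_basis")
}

#' @export
print.power_basis <- function(x, ...) {
  cat(sprintf("<power_basis> %d harmonics (source: %s)\n",
              ncol(x$vectors), x$source_id))
  invisible(x)
}

#' RSN participation of harmonic power vectors
#'
#' `Participation = U_bar^T Q` where `Q` is the binary region-by-RSN
#' membership matrix: how much of each harmonic's power falls inside each
#' resting-state network. With `normalize = TRUE` each RSN's column is
#' scaled by its maximum across harmonics, emphasizing relative
#' participation.
#'
#' @param power A `power_basis`.
#' @param Q N x n_rsn binary membership matrix (each row sums to 1), or a
#'   factor/character vector of per-region RSN labels.
#' @param normalize Scale each RSN by its maximum across harmonics.
#' @return Tibble: `harmonic`, one column per RSN.
#' @export
rsn_participation <- function(power, Q, normalize = TRUE) {
  if (!is.matrix(Q)) {
    f <- factor(Q)
    Q <- stats::model.matrix(~ f - 1)
    colnames(Q) <- levels(f)
  }
  if (any(rowSums(Q) != 1)) {
    stop("each region must belong to exactly one RSN", call. = FALSE)
  }
  if (any(colSums(Q) == 0)) stop("RSN with zero membership", call. = FALSE)
  P <- crossprod(power$vectors, Q)
  if (normalize) P <- sweep(P, 2, apply(P, 2, max), `/`)
  out <- tibble::as_tibble(as.data.frame(P))
  dplyr::bind_cols(tibble::tibble(harmonic = seq_len(nrow(P))), out)
}

#' Project functional time series onto harmonic power vectors
#'
#' Computes `s_hat(t) = U_bar^T s(t)` per timepoint (after optional
#' per-region z-scoring), along with the companion graph Fourier transform
#' `U^T s(t)`, per-harmonic energy (`sum_t s_hat_i(t)^2`), and per-harmonic
#' GFT energy.
#'
#' @param power A `power_basis`.
#' @param s A `timeseries_matrix` or N x T numeric matrix with region-id
#'   rownames matching the basis ordering.
#' @param basis Optional `harmonic_basis` for the companion GFT (defaults to
#'   none; supply to populate `gft`).
#' @param zscore Z-score each region's series first (default TRUE).
#' @return A `projection_series`: list with `s_hat` (N x T), `gft` (N x T or
#'   NULL), `energy`, `gft_energy`, `tr`.
#' @export
project_series <- function(power, s, basis = NULL, zscore = TRUE) {
  tr <- if (inherits(s, "timeseries_matrix")) s$tr else NA_real_
  S <- if (inherits(s, "timeseries_matrix")) s$values else as.matrix(s)
  if (!is.null(rownames(S)) &&
      !identical(rownames(S), power$region_ids)) {
    stop("time-series region ordering does not match the basis", call. = FALSE)
  }
  if (anyNA(S)) stop("time series contains missing values", call. = FALSE)
  if (zscore) {
    mu <- rowMeans(S)
    sd <- apply(S, 1, stats::sd)
    sd[sd == 0] <- 1
    S <- (S - mu) / sd
  }
  s_hat <- crossprod(power$vectors, S)
  gft <- if (!is.null(basis)) crossprod(basis$vectors, S) else NULL
  structure(list(s_hat = s_hat,
                 gft = gft,
                 energy = rowSums(s_hat^2),
                 gft_energy = if (is.null(gft)) NULL else rowSums(gft^2),
                 tr = tr, zscored = zscore),
            class = "projection_series")
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("<projection_series> %d harmonics x %d timepoints\n",
              nrow(x$s_hat), ncol(x$s_hat)))
  invisible(x)
}

#' @export
tidy.projection_series <- function(x, ...) {
  tibble::tibble(harmonic = seq_along(x$energy),
                 energy = x$energy,
                 gft_energy = x$gft_energy %||% NA_real_)
}

#' Sample entropy of a time series
#'
#' `SampEn = -ln(A/B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` of each other (self-matches excluded) and `A` the
#' same for length `m + 1`. `r` is interpreted as a fraction of the series'
#' standard deviation. Returns `NA` with a warning when no length-`m`
#' matches exist.
#'
#' @param x Numeric series (length > m + 1).
#' @param m Template length (default 5 samples).
#' @param r Tolerance as a fraction of `sd(x)` (default 0.2).
#' @return Nonnegative entropy value, or `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 5L, r = 0.2) {
  n <- length(x)
  if (n <= m + 1) stop("series too short for template length m", call. = FALSE)
  tol <- r * stats::sd(x)
  # both template lengths use the same n - m starting points (the standard
  # convention), so A/B is a conditional probability
  count_matches <- function(len) {
    k <- n - m
    emb <- sapply(seq_len(len), function(d) x[d:(d + k - 1)])
    D <- matrix(0, k, k)
    for (d in seq_len(len)) {
      D <- pmax(D, abs(outer(emb[, d], emb[, d], `-`)))
    }
    (sum(D <= tol) - k) / 2  # unordered pairs, self-matches excluded
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (B == 0) {
    warning("no template matches of length m; sample entropy undefined")
    return(NA_real_)
  }
  -log(A / B)  # A = 0 gives Inf: no sequence ever stays similar
}

#' Harmonic diversity of a regime's projected activity
#'
#' Shannon entropy of the per-timepoint distribution of absolute projected
#' signal across a regime's harmonics, normalized by the maximum `log(n)` so
#' values lie in `[0, 1]`: 1 when all harmonics contribute equally, 0 when
#' one dominates.
#'
#' @param s_hat_regime n x T matrix of projections restricted to one
#'   regime's harmonics (n >= 2).
#' @return Numeric length-T vector `H(t)`; timepoints with all-zero regime
#'   signal are `NA`.
#' @export
harmonic_diversity <- function(s_hat_regime) {
  n <- nrow(s_hat_regime)
  if (is.null(n) || n < 2) {
    stop("harmonic diversity requires a regime with at least 2 harmonics",
         call. = FALSE)
  }
  a <- abs(s_hat_regime)
  tot <- colSums(a)
  H <- rep(NA_real_, ncol(a))
  ok <- tot > 0
  if (any(ok)) {
    p <- sweep(a[, ok, drop = FALSE], 2, tot[ok], `/`)
    plogp <- ifelse(p > 0, p * log(p), 0)
    H[ok] <- -colSums(plogp) / log(n)
  }
  H
}

#' Ternary regime dynamics of projected activity
#'
#' Per timepoint, each regime's signal strength is the mean absolute
#' projection over its harmonics (mean rather than sum, removing
#' regime-size bias; `stat = "sum"` restores the raw total). Strengths are
#' normalized to sum to 1, giving coordinates on the 2-simplex per
#' timepoint. Also returns the time-averaged fraction triple and the leading
#' principal axis of the centered fraction matrix.
#'
#' @param s_hat N x T projection matrix (all harmonics).
#' @param partition A `regime_partition` covering all N harmonics.
#' @param stat `"mean"` (default) or `"sum"` regime aggregation.
#' @return A `ternary_dynamics`: list with `fractions` (T x 3, rows on the
#'   simplex; all-zero timepoints dropped with a warning), `mean_fractions`,
#'   `principal_axis`, `stat`.
#' @export
ternary_dynamics <- function(s_hat, partition, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(nrow(s_hat) == length(partition$labels))
  lev <- levels(partition$labels)
  agg <- if (stat == "mean") colMeans else colSums
  strengths <- sapply(lev, function(l) {
    idx <- which(partition$labels == l)
    agg(abs(s_hat[idx, , drop = FALSE]))
  })
  tot <- rowSums(strengths)
  drop <- tot == 0
  if (any(drop)) {
    warning(sum(drop), " timepoint(s) with zero total strength excluded")
    strengths <- strengths[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  frac <- sweep(strengths, 1, tot, `/`)
  centered <- scale(frac, center = TRUE, scale = FALSE)
  pc1 <- stats::prcomp(centered, center = FALSE)$rotation[, 1]
  structure(list(fractions = frac,
                 mean_fractions = colMeans(frac),
                 principal_axis = pc1,
                 stat = stat),
            class = "ternary_dynamics")
}

#' @export
print.ternary_dynamics <- function(x, ...) {
  mf <- x$mean_fractions
  cat(sprintf("<ternary_dynamics> mean fractions: integrative %.3f | degenerate %.3f | segregative %.3f (%s)\n",
              mf[1], mf[2], mf[3], x$stat))
  invisible(x)
}

#' Back-project regime energy into region space
#'
#' Region-space energy of a regime: `sum_{i in regime} u_bar_i * energy_i`,
#' the power-weighted linear back-projection of per-harmonic energies.
#'
#' @param power A `power_basis`.
#' @param energy Per-harmonic energy vector (length N).
#' @param partition A `regime_partition`.
#' @param regime Regime name.
#' @return Tibble with `region_id` and `energy`.
#' @export
regional_energy <- function(power, energy, partition, regime) {
  idx <- regime_indices(partition, regime)
  if (length(idx) == 0) stop("empty regime: ", regime, call. = FALSE)
  e <- as.vector(power$vectors[, idx, drop = FALSE] %*% energy[idx])
  tibble::tibble(region_id = power$region_ids, energy = e)
}

#' Percentile-threshold subject maps and average
#'
#' Values below the across-subject pooled percentile are zeroed (ties kept
#' under the `>=` rule), then maps are averaged across subjects — used for
#' group-level participation maps.
#'
#' @param maps Subjects x values numeric matrix (or a list of equal-length
#'   vectors).
#' @param percentile Percentile in `[0, 100)`; 0 gives the plain mean.
#' @return Numeric vector: the thresholded group average.
#' @export
participation_threshold <- function(maps, percentile = 80) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  stopifnot(percentile >= 0, percentile <= 100)
  if (percentile == 0) return(colMeans(maps))
  cut <- stats::quantile(as.vector(maps), percentile / 100, names = FALSE)
  maps[maps < cut] <- 0
  colMeans(maps)
}

#' Regime-level summary of a projection
#'
#' Per-regime mean energy, mean sample entropy, and time-averaged harmonic
#' diversity for a projected series.
#'
#' @param proj A `projection_series`.
#' @param partition A `regime_partition`.
#' @param m,r Sample-entropy parameters.
#' @return Tibble with one row per regime: `regime`, `n_harmonics`,
#'   `mean_energy`, `mean_sample_entropy`, `mean_diversity`.
#' @export
regime_projection_summary <- function(proj, partition, m = 5L, r = 0.2) {
  purrr::map_dfr(levels(partition$labels), function(l) {
    idx <- which(partition$labels == l)
    sh <- proj$s_hat[idx, , drop = FALSE]
    se <- vapply(seq_len(nrow(sh)), function(i)
      suppressWarnings(sample_entropy(sh[i, ], m, r)), numeric(1))
    se <- se[is.finite(se)]  # undefined/infinite entropies dropped from the mean
    H <- if (length(idx) >= 2) harmonic_diversity(sh) else NA_real_
    tibble::tibble(regime = l,
                   n_harmonics = length(idx),
                   mean_energy = mean(proj$energy[idx]),
                   mean_sample_entropy = mean(se),
                   mean_diversity = mean(H, na.rm = TRUE))
  })
}
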