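#' Perturbation configuration
#'
#' Rayleigh noise scales and realization counts for harmonic stability
#' estimation. The default grid spans sigma in `[0, 0.002]` with step
#' `2.5e-4` — noise on the scale of a unit-Frobenius-norm connectome's edge
#' weights. Rician noise with shape `nu = 0` reduces to a Rayleigh
#' distribution, the MRI-motivated choice.
#'
#' @param sigma_grid Ascending nonnegative scales, starting at 0.
#' @param n_realizations Independent noise draws averaged per sigma.
#' @param seed Master seed; per-(sigma, realization) seeds derive from it.
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(sigma_grid = seq(0, 2e-3, by = 2.5e-4),
                                n_realizations = 5L,
                                seed = 1L) {
  stopifnot(length(sigma_grid) >= 1, all(diff(sigma_grid) > 0),
            sigma_grid[1] == 0, n_realizations >= 1)
  structure(list(sigma_grid = sigma_grid, nu = 0,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Add symmetric Rayleigh noise to a connectome
#'
#' Draws i.i.d. Rayleigh(sigma) noise on the strict upper triangle, mirrors
#' it to the lower triangle (keeping the matrix a valid symmetric
#' eigenproblem), and leaves the diagonal at zero. Rayleigh draws are
#' nonnegative, so the perturbed matrix remains a valid connectome.
#'
#' @param C A `connectome` (typically Frobenius-normalized).
#' @param sigma Rayleigh scale; 0 returns `C` unchanged.
#' @param seed Integer seed.
#' @param renormalize Re-normalize the perturbed matrix to unit Frobenius
#'   norm (off by default: noise is added to the already-normalized matrix).
#' @return The perturbed `connectome`.
#' @export
perturb_connectome <- function(C, sigma, seed = 1L, renormalize = FALSE) {
  validate_connectome(C)
  stopifnot(sigma >= 0)
  if (sigma == 0) return(C)
  W <- unclass(C)
  ut <- upper.tri(W)
  set.seed(seed)
  r <- sigma * sqrt(-2 * log(stats::runif(sum(ut))))  # Rayleigh via inverse CDF
  W[ut] <- W[ut] + r
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  out <- connectome(W, region_ids(C))
  if (renormalize) out <- normalize_frobenius(out)
  out
}

#' Similarity of perturbed harmonics to the unperturbed basis
#'
#' Matches the perturbed basis to the unperturbed one (exact assignment on
#' absolute inner products) and returns `|diag(U_sigma^T U)|` after
#' reordering — one similarity in `[0, 1]` per harmonic.
#'
#' @param U_sigma Perturbed `harmonic_basis`.
#' @param U Unperturbed `harmonic_basis`.
#' @return Numeric N-vector of similarities.
#' @export
perturbation_similarity <- function(U_sigma, U) {
  m <- match_harmonics(U_sigma, U)
  m$per_pair_similarity
}

#' Least-squares log-linear decay slopes
#'
#' Per-harmonic slope of `ln P(sigma)` against `sigma` over the grid — the
#' numerical estimate of `d/dsigma ln P(sigma)`. Similarities of exactly 0
#' are clamped at machine epsilon before the log, with a warning.
#'
#' @param P Harmonics x sigma matrix of similarities.
#' @param sigma_grid Sigma values (length = `ncol(P)`, at least 2).
#' @return Numeric vector of slopes (one per harmonic; `<= 0` expected, with
#'   values nearer 0 indicating more stable harmonics).
#' @export
stability_slopes <- function(P, sigma_grid) {
  if (length(sigma_grid) < 2) {
    stop("stability slope undefined on a single-sigma grid", call. = FALSE)
  }
  stopifnot(ncol(P) == length(sigma_grid))
  if (any(P == 0)) {
    warning("similarity of 0 clamped at machine epsilon before log")
    P[P == 0] <- .Machine$double.eps
  }
  lp <- log(P)
  xc <- sigma_grid - mean(sigma_grid)
  as.vector((lp %*% xc) / sum(xc^2))
}

#' Estimate per-harmonic stability under Rayleigh perturbation
#'
#' For each sigma on the grid and each realization: perturb the connectome,
#' recompute its harmonic basis, match to the unperturbed basis, and record
#' the per-harmonic similarity `P(sigma)`. Realizations are averaged per
#' sigma, and stability is the least-squares slope of `ln P` versus sigma —
#' the log-linear decay rate of each harmonic's identity under noise.
#'
#' @param C A Frobenius-normalized `connectome`.
#' @param config A `perturbation_config`.
#' @param basis Optional precomputed unperturbed basis of `C`.
#' @return A `stability_result`: list with `P` (harmonics x sigma, averaged
#'   over realizations), `sigma_grid`, `stability` (N-vector of slopes), and
#'   the config.
#' @export
estimate_stability <- function(C, config = perturbation_config(), basis = NULL) {
  C <- if (isTRUE(attr(C, "normalized"))) C else normalize_frobenius(C)
  if (is.null(basis)) basis <- connectome_harmonics(C, normalize = FALSE)
  N <- length(basis$eigenvalues)
  sg <- config$sigma_grid
  P <- matrix(0, N, length(sg))
  P[, 1] <- 1  # sigma = 0: identical decomposition by construction
  for (k in seq_along(sg)[-1]) {
    acc <- numeric(N)
    for (r in seq_len(config$n_realizations)) {
      sub_seed <- (config$seed * 1009L + k * 97L + r) %% .Machine$integer.max
      Cp <- perturb_connectome(C, sg[k], seed = sub_seed)
      bp <- connectome_harmonics(Cp, normalize = FALSE)
      acc <- acc + perturbation_similarity(bp, basis)
    }
    P[, k] <- acc / config$n_realizations
  }
  structure(list(P = P, sigma_grid = sg,
                 stability = stability_slopes(P, sg),
                 config = config),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d harmonics x %d sigmas; mean slope %.1f\n",
              nrow(x$P), length(x$sigma_grid), mean(x$stability)))
  invisible(x)
}

#' @export
tidy.stability_result <- function(x, ...) {
  tibble::tibble(harmonic = seq_len(nrow(x$P)),
                 stability = x$stability)
}

#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(n_harmonics = nrow(x$P),
                 n_sigmas = length(x$sigma_grid),
                 sigma_max = max(x$sigma_grid),
                 n_realizations = x$config$n_realizations,
                 mean_stability = mean(x$stability))
}
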