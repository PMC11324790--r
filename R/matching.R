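#' Match subject harmonics to consensus harmonics
#'
#' Finds the permutation `p` maximizing `sum_i |<u_p(i), v_i>|` — the globally
#' optimal linear assignment between the columns of two orthonormal bases on
#' the absolute inner-product similarity. Sign flips are irrelevant by
#' construction. Exact ties between assignments of equal objective are
#' canonicalized toward the lexicographically smallest permutation by
#' objective-preserving pair swaps.
#'
#' @param U Subject `harmonic_basis` (or N x N matrix of columns to assign).
#' @param V Reference (consensus) `harmonic_basis` or matrix.
#' @param tie_tol Objective tolerance treated as an exact tie.
#' @return A `harmonic_match`: list with `permutation` (p, subject column
#'   assigned to each consensus index), `objective`, `per_pair_similarity`.
#' @export
match_harmonics <- function(U, V, tie_tol = 1e-12) {
  Um <- if (inherits(U, "harmonic_basis")) U$vectors else as.matrix(U)
  Vm <- if (inherits(V, "harmonic_basis")) V$vectors else as.matrix(V)
  if (!all(dim(Um) == dim(Vm))) {
    stop("bases have mismatched dimensions", call. = FALSE)
  }
  S <- abs(crossprod(Um, Vm))  # S[s, c] = |<u_s, v_c>|
  p <- solve_assignment(S)
  p <- canonicalize_ties(S, p, tie_tol)
  sims <- S[cbind(p, seq_along(p))]
  structure(list(permutation = p,
                 objective = sum(sims),
                 per_pair_similarity = sims),
            class = "harmonic_match")
}

# exact maximum-weight perfect matching on a complete bipartite graph;
# +1 offset guarantees a perfect matching is optimal under igraph
solve_assignment <- function(S) {
  n <- nrow(S)
  g <- igraph::graph_from_biadjacency_matrix(S + 1, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  col_of_row <- m$matching[seq_len(n)] - n  # consensus column matched to row s
  p <- integer(n)
  p[col_of_row] <- seq_len(n)
  p
}

# push toward the lexicographically smallest permutation among optima
canonicalize_ties <- function(S, p, tol) {
  n <- length(p)
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (p[j] < p[i]) {
          cur <- S[p[i], i] + S[p[j], j]
          swp <- S[p[j], i] + S[p[i], j]
          if (abs(cur - swp) <= tol) {
            tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  p
}

#' Reorder a subject basis by its match to the consensus
#'
#' Applies the matching permutation so that column `i` of the result is the
#' subject harmonic assigned to consensus harmonic `i`; eigenvalues are
#' carried along.
#'
#' @param basis A `harmonic_basis`.
#' @param match A `harmonic_match` against the consensus.
#' @return The permuted `harmonic_basis`.
#' @export
apply_match <- function(basis, match) {
  p <- match$permutation
  basis$vectors <- basis$vectors[, p, drop = FALSE]
  basis$eigenvalues <- basis$eigenvalues[p]
  basis
}

#' @export
print.harmonic_match <- function(x, ...) {
  cat(sprintf("<harmonic_match> N = %d, objective = %.4f (mean similarity %.4f)\n",
              length(x$permutation), x$objective,
              mean(x$per_pair_similarity)))
  invisible(x)
}

#' @export
tidy.harmonic_match <- function(x, ...) {
  tibble::tibble(consensus_index = seq_along(x$permutation),
                 subject_index = x$permutation,
                 similarity = x$per_pair_similarity)
}

#' Inter-subject agreement of harmonics
#'
#' For every unordered subject pair, computes `|diag(U_i^T U_j)|` — the
#' absolute cosine similarity between corresponding harmonics. With
#' `matched = TRUE` each subject is first independently matched to the
#' consensus basis so that indices refer to the consensus ordering.
#'
#' @param ensemble List of `harmonic_basis` objects (one per subject).
#' @param consensus Consensus `harmonic_basis` (required when `matched`).
#' @param matched Match each subject to the consensus first.
#' @return An `agreement_profile`: list with `per_pair` (pairs x N matrix),
#'   `pairs` (tibble of i, j), and `summary` tibble (per-harmonic median,
#'   IQR and 5–95 percentile bands).
#' @export
intersubject_agreement <- function(ensemble, consensus = NULL, matched = TRUE) {
  if (length(ensemble) < 2) {
    stop("agreement requires at least 2 subjects", call. = FALSE)
  }
  if (matched) {
    if (is.null(consensus)) stop("matched agreement needs a consensus basis",
                                 call. = FALSE)
    ensemble <- lapply(ensemble, function(b)
      apply_match(b, match_harmonics(b, consensus)))
  }
  n <- length(ensemble)
  N <- ncol(ensemble[[1]]$vectors)
  pairs <- utils::combn(n, 2)
  per_pair <- t(apply(pairs, 2, function(ij) {
    abs(colSums(ensemble[[ij[1]]]$vectors * ensemble[[ij[2]]]$vectors))
  }))
  summary <- tibble::tibble(
    harmonic = seq_len(N),
    median = apply(per_pair, 2, stats::median),
    q25 = apply(per_pair, 2, stats::quantile, 0.25),
    q75 = apply(per_pair, 2, stats::quantile, 0.75),
    p05 = apply(per_pair, 2, stats::quantile, 0.05),
    p95 = apply(per_pair, 2, stats::quantile, 0.95)
  )
  structure(list(per_pair = per_pair,
                 pairs = tibble::tibble(i = pairs[1, ], j = pairs[2, ]),
                 matched = matched,
                 summary = summary),
            class = "agreement_profile")
}

#' @export
print.agreement_profile <- function(x, ...) {
  cat(sprintf("<agreement_profile> %d pairs x %d harmonics (%s)\n",
              nrow(x$per_pair), ncol(x$per_pair),
              if (x$matched) "matched" else "unmatched"))
  invisible(x)
}

#' @export
tidy.agreement_profile <- function(x, ...) x$summary

#' Regional variation of matched harmonics across subjects
#'
#' Rescales each subject's absolute-valued matched harmonic to `[0, 1]`
#' (min–max over regions), takes the per-region variance across subjects,
#' and averages across harmonics. Constant harmonics (zero range) are
#' skipped with a warning.
#'
#' @param ensemble List of matched `harmonic_basis` objects.
#' @return Tibble with `region_id` and `variation` (bounded by 0.25).
#' @export
regional_variation <- function(ensemble) {
  n <- length(ensemble)
  stopifnot(n >= 2)
  N <- ncol(ensemble[[1]]$vectors)
  ids <- ensemble[[1]]$region_ids
  acc <- matrix(0, N, nrow(ensemble[[1]]$vectors))
  used <- logical(N)
  for (h in seq_len(N)) {
    M <- vapply(ensemble, function(b) {
      u <- abs(b$vectors[, h])
      rng <- range(u)
      if (diff(rng) == 0) return(rep(NA_real_, length(u)))
      (u - rng[1]) / diff(rng)
    }, numeric(nrow(acc) * 0 + length(ids)))
    if (anyNA(M)) next
    acc[h, ] <- apply(M, 1, stats::var)
    used[h] <- TRUE
  }
  if (!all(used)) warning(sum(!used), " constant harmonic(s) skipped")
  tibble::tibble(region_id = ids,
                 variation = colMeans(acc[used, , drop = FALSE]))
}
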