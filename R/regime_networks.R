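#' Truncated spectral Laplacian over a harmonic interval
#'
#' `L_tilde = sum_{i=j}^{k} lambda_i u_i u_i^T`, the rank-limited part of the
#' Laplacian spanned by harmonics `j..k`.
#'
#' @param basis A `harmonic_basis`.
#' @param j,k 1-based inclusive harmonic interval.
#' @return N x N matrix.
#' @export
truncated_laplacian <- function(basis, j, k) {
  N <- length(basis$eigenvalues)
  if (j < 1 || k > N || j > k) {
    stop("invalid harmonic interval [", j, ", ", k, "] for N = ", N,
         call. = FALSE)
  }
  U <- basis$vectors[, j:k, drop = FALSE]
  lam <- basis$eigenvalues[j:k]
  Lt <- U %*% (lam * t(U))
  dimnames(Lt) <- list(basis$region_ids, basis$region_ids)
  (Lt + t(Lt)) / 2
}

#' Reconstruct a low-rank structural connectome from a truncated Laplacian
#'
#' Inverts the degree normalization: `C_tilde = D^{1/2} (D_tilde - L_tilde)
#' D^{1/2}` with `D_tilde = diag(L_tilde)` and `D` the original degree
#' matrix. Truncation produces negative weights for excluded connections;
#' these are thresholded to zero, and the result is normalized to unit
#' Frobenius norm.
#'
#' @param L_tilde Truncated Laplacian from [truncated_laplacian()].
#' @param degree_vector Degrees of the original connectome.
#' @param interval The `(j, k)` interval, recorded on the result.
#' @return A `regime_sc`: list with `C_tilde` (thresholded, unit Frobenius
#'   norm), `C_pre` (pre-threshold reconstruction), `L_tilde`, `D_tilde`,
#'   `interval`, `zero_norm` flag.
#' @export
reconstruct_sc <- function(L_tilde, degree_vector, interval = c(NA, NA)) {
  stopifnot(length(degree_vector) == nrow(L_tilde))
  sqd <- sqrt(degree_vector)
  Dt <- diag(L_tilde)
  M <- diag(Dt) - L_tilde
  C_pre <- sqd * M %*% diag(sqd)
  C_pre <- (C_pre + t(C_pre)) / 2
  dimnames(C_pre) <- dimnames(L_tilde)
  Ct <- pmax(C_pre, 0)
  diag(Ct) <- 0
  nf <- frobenius_norm(Ct)
  zero_norm <- nf < .Machine$double.eps
  if (!zero_norm) Ct <- Ct / nf
  structure(list(C_tilde = Ct, C_pre = C_pre, L_tilde = L_tilde,
                 D_tilde = Dt, interval = interval, zero_norm = zero_norm),
            class = "regime_sc")
}

#' @export
print.regime_sc <- function(x, ...) {
  cat(sprintf("<regime_sc> harmonics %s-%s, %d regions%s\n",
              x$interval[1], x$interval[2], nrow(x$C_tilde),
              if (x$zero_norm) " (zero reconstruction)" else ""))
  invisible(x)
}

#' Regime-specific reconstructed connectomes
#'
#' Reconstructs one low-rank connectome per regime of a partition.
#'
#' @param basis A `harmonic_basis` (with `degree` recorded).
#' @param partition A `regime_partition`.
#' @return Named list of `regime_sc` (integrative, degenerate, segregative).
#' @export
regime_connectomes <- function(basis, partition) {
  stopifnot(!is.null(basis$degree))
  lo <- partition$bounds["lo"]; hi <- partition$bounds["hi"]
  N <- length(basis$eigenvalues)
  ivals <- list(integrative = c(1, lo - 1),
                degenerate = c(lo, hi),
                segregative = c(hi + 1, N))
  lapply(ivals, function(iv) {
    reconstruct_sc(truncated_laplacian(basis, iv[1], iv[2]), basis$degree,
                   interval = iv)
  })
}

#' Weighted graph metrics of a connectome
#'
#' Integration/segregation battery for a weighted undirected network:
#' modularity (Louvain maximization at resolution `gamma`, best of seeded
#' restarts), global efficiency and characteristic path length on edge
#' lengths `1/w` (or `-log(w)`), geometric-mean (Onnela) weighted clustering,
#' small-worldness against degree-preserving weight-resorted null networks,
#' and weighted s-core coreness (mean nodal maximal core level, normalized
#' by its maximum).
#'
#' @param C Symmetric nonnegative weighted matrix (or `connectome`).
#' @param n_null Number of randomized nulls for small-worldness.
#' @param gamma Modularity resolution.
#' @param seed Integer seed for community restarts and nulls.
#' @param n_restarts Louvain restarts; best modularity kept.
#' @param distance `"inverse"` (lengths `1/w`, default) or `"neglog"`.
#' @return One-row tibble: `modularity`, `global_efficiency`, `clustering`,
#'   `char_path_length`, `small_worldness`, `coreness`, plus null means
#'   `clustering_null` and `path_length_null`.
#' @export
graph_metrics <- function(C, n_null = 10L, gamma = 1, seed = 1L,
                          n_restarts = 20L, distance = c("inverse", "neglog")) {
  distance <- match.arg(distance)
  W <- unclass(as.matrix(C))
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    stop("graph_metrics requires at least one edge", call. = FALSE)
  }
  w <- igraph::E(g)$weight
  len <- edge_lengths(w, distance)

  set.seed(seed)
  Q <- max(vapply(seq_len(n_restarts), function(r) {
    cl <- igraph::cluster_louvain(g, weights = w, resolution = gamma)
    igraph::modularity(g, igraph::membership(cl), weights = w)
  }, numeric(1)))

  D <- igraph::distances(g, weights = len)
  eff <- global_efficiency_from_distances(D)
  cpl <- char_path_length_from_distances(D)
  chi <- onnela_clustering(W)

  null_chi <- numeric(n_null)
  null_cpl <- numeric(n_null)
  for (b in seq_len(n_null)) {
    Wn <- null_network(W, seed = seed + b)
    gn <- igraph::graph_from_adjacency_matrix(Wn, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    Dn <- igraph::distances(gn, weights = edge_lengths(igraph::E(gn)$weight,
                                                       distance))
    null_chi[b] <- onnela_clustering(Wn)
    null_cpl[b] <- char_path_length_from_distances(Dn)
  }
  sw <- (chi / mean(null_chi)) / (cpl / mean(null_cpl))

  tibble::tibble(modularity = Q,
                 global_efficiency = eff,
                 clustering = chi,
                 char_path_length = cpl,
                 small_worldness = sw,
                 coreness = score_coreness(W),
                 clustering_null = mean(null_chi),
                 path_length_null = mean(null_cpl))
}

edge_lengths <- function(w, distance) {
  if (distance == "inverse") 1 / w else -log(w / max(w)) + .Machine$double.eps
}

global_efficiency_from_distances <- function(D) {
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv) # pairs in other components contribute 0 efficiency
}

char_path_length_from_distances <- function(D) {
  d <- D[upper.tri(D)]
  if (any(!is.finite(d))) {
    warning("disconnected network: path length computed on reachable pairs")
    d <- d[is.finite(d)]
  }
  mean(d)
}

# geometric-mean weighted clustering coefficient (Onnela), averaged over
# nodes with degree >= 2
onnela_clustering <- function(W) {
  Wh <- (W / max(W))^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  ok <- k >= 2
  if (!any(ok)) return(0)
  mean(num[ok] / (k[ok] * (k[ok] - 1)))
}

# degree-preserving topology rewiring with the original weight multiset
# re-sorted onto the new edges by expected strength (emulates a
# strength-aware randomized null for positive weights)
null_network <- function(W, seed = 1L) {
  set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
  s <- rowSums(W)
  el <- igraph::as_edgelist(gr, names = FALSE)
  expected <- s[el[, 1]] * s[el[, 2]]
  wsorted <- sort(igraph::E(g)$weight, decreasing = TRUE)
  wn <- numeric(nrow(el))
  wn[order(expected, decreasing = TRUE)] <- wsorted
  Wn <- matrix(0, nrow(W), ncol(W))
  Wn[el] <- wn
  Wn[el[, c(2, 1)]] <- wn
  dimnames(Wn) <- dimnames(W)
  Wn
}

# weighted s-core decomposition: iteratively remove the weakest node; a
# node's core level is the running maximum of the minimum strength at its
# removal. Returns mean nodal core level normalized by the maximum level.
score_coreness <- function(W) {
  n <- nrow(W)
  alive <- rep(TRUE, n)
  core <- numeric(n)
  level <- 0
  Wc <- W
  for (step in seq_len(n)) {
    s <- rowSums(Wc[alive, alive, drop = FALSE])
    i_rel <- which.min(s)
    level <- max(level, s[i_rel])
    idx <- which(alive)[i_rel]
    core[idx] <- level
    alive[idx] <- FALSE
    if (!any(alive)) break
  }
  if (max(core) == 0) return(0)
  mean(core) / max(core)
}

#' Compare graph metrics across regimes
#'
#' Per metric: one-way ANOVA across regime groups, then all pairwise
#' two-sided t-tests with Bonferroni correction across the pairwise family.
#'
#' @param metrics Long tibble with columns `regime`, `subject`, `metric`,
#'   `value` (e.g. stacked [graph_metrics()] rows per subject and regime,
#'   optionally including the full connectome as a fourth group).
#' @return Tibble with `metric`, `comparison` (`"anova"` or `"a vs b"`),
#'   `statistic` (F or t), `p_value`, `p_adjusted`.
#' @export
compare_regime_metrics <- function(metrics) {
  stopifnot(all(c("regime", "value", "metric") %in% names(metrics)))
  if (length(unique(metrics$subject %||% 1)) < 2) {
    stop("regime comparison requires at least 2 subjects", call. = FALSE)
  }
  purrr::map_dfr(split(metrics, metrics$metric), function(df) {
    df$regime <- factor(df$regime)
    if (stats::var(df$value) < .Machine$double.eps) {
      warning("metric '", df$metric[1], "' has zero variance; tests degenerate")
      return(tibble::tibble(metric = df$metric[1], comparison = "anova",
                            statistic = 0, p_value = 1, p_adjusted = 1))
    }
    fit <- stats::aov(value ~ regime, data = df)
    sm <- summary(fit)[[1]]
    out <- tibble::tibble(metric = df$metric[1], comparison = "anova",
                          statistic = sm$`F value`[1],
                          p_value = sm$`Pr(>F)`[1],
                          p_adjusted = sm$`Pr(>F)`[1])
    lev <- levels(df$regime)
    prs <- utils::combn(lev, 2)
    tt <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
      a <- df$value[df$regime == prs[1, k]]
      b <- df$value[df$regime == prs[2, k]]
      res <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      tibble::tibble(metric = df$metric[1],
                     comparison = paste(prs[1, k], "vs", prs[2, k]),
                     statistic = if (is.null(res)) NA_real_ else unname(res$statistic),
                     p_value = if (is.null(res)) NA_real_ else res$p.value)
    })
    tt$p_adjusted <- pmin(1, tt$p_value * ncol(prs))
    dplyr::bind_rows(out, tt)
  })
}

#' Within-module weight fraction of a reconstructed connectome
#'
#' Fraction of total edge weight that falls inside planted modules — a
#' segregation summary for regime reconstructions.
#'
#' @param W Weight matrix.
#' @param module_id Integer module label per node.
#' @return Fraction in `[0, 1]`.
#' @export
within_module_fraction <- function(W, module_id) {
  W <- unclass(as.matrix(W))
  same <- outer(module_id, module_id, `==`)
  tot <- sum(W)
  if (tot == 0) return(NA_real_)
  sum(W[same]) / tot
}
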