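# fixtures are built in code: small canonical graphs, random orthonormal
# bases, and brute-force oracles used across test files

ring_connectome <- function(n, weight = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    W[i, j] <- W[j, i] <- weight
  }
  connectome(W, paste0("r", seq_len(n)))
}

complete_connectome <- function(n, weight = 1) {
  W <- matrix(weight, n, n)
  diag(W) <- 0
  connectome(W, paste0("r", seq_len(n)))
}

chain_connectome <- function(n, weight = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- weight
  connectome(W, paste0("r", seq_len(n)))
}

random_orthonormal <- function(n, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * n), n, n)))
}

# random connected weighted connectome (Erdos-Renyi + bridge repair)
random_connected_sc <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- ifelse(runif(sum(ut)) < p, exp(rnorm(sum(ut), 0, 0.5)), 0)
  W <- W + t(W)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  while (length(unique(comp)) > 1) {
    a <- which(comp == unique(comp)[1])[1]
    b <- which(comp == unique(comp)[2])[1]
    W[a, b] <- W[b, a] <- 0.5
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
  }
  connectome(W, paste0("r", seq_len(n)))
}

# all permutations of 1..n, one per row (exhaustive matching oracle)
perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    m <- cbind(k, sub)
    m[, -1][m[, -1] >= k] <- m[, -1][m[, -1] >= k] + 1L
    m
  }))
}

# brute-force maximum of sum_i |<u_p(i), v_i>| over all permutations
brute_force_match <- function(U, V) {
  S <- abs(crossprod(U, V))
  n <- nrow(S)
  P <- perm_all(n)
  max(apply(P, 1, function(p) sum(S[cbind(p, seq_len(n))])))
}

# hand-built adjacency object (e.g. rings, which the lattice generator
# deliberately does not produce)
make_adjacency <- function(A, hemisphere) {
  ids <- paste0("r", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  structure(A, class = c("adjacency", "matrix", "array"),
            hemisphere = stats::setNames(hemisphere, ids))
}

ring_adjacency <- function(n, hemisphere = rep("L", n)) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- 1
  }
  make_adjacency(A, hemisphere)
}
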