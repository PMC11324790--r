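test_that("amplitude thresholding zeroes only sub-threshold entries", {
  expect_equal(apply_threshold(c(0.5, 0.0005, -0.5), 0.001), c(0.5, 0, -0.5))
  u <- c(0.3, 0, -0.2)
  expect_equal(apply_threshold(u, 0), u)
  expect_equal(apply_threshold(u, max(abs(u))), c(0, 0, 0))
})

test_that("sparsity counts the thresholded-zero fraction", {
  expect_equal(sparsity(c(0.5, 0, -0.5, 0), 0.001), 0.5)
  # dense sinusoid well above threshold
  u <- cos(2 * pi * (1:16) / 16 + 0.3)
  expect_equal(sparsity(u, 0.001), 0)
})

test_that("zero-cross rate skips thresholded zeros and uses N - 1", {
  expect_equal(zero_cross_rate(c(1, -1, 1, -1), 0.001), 1)
  expect_equal(zero_cross_rate(c(1, 1, 1, 1), 0.001), 0)
  # the sub-threshold middle entry neither crosses nor resets the sign
  expect_equal(zero_cross_rate(c(0.5, 0.0005, -0.5), 0.001), 0.5)
  expect_warning(r <- zero_cross_rate(c(0, 0, 0), 0.001), "all-zero")
  expect_equal(r, 0)
})

test_that("network zero crossings sum the harmonic's graph cut", {
  W2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(network_zero_crossings(c(0.7, -0.7), connectome(W2), 0.001), 2)
  expect_equal(network_zero_crossings(c(0.7, 0.7), connectome(W2), 0.001), 0)

  # triangle, weights w12 = 1, w13 = 2, w23 = 3; signs (+, +, -): the cut
  # contains edges (1,3) and (2,3) -> 2 + 3
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 1; W3[1, 3] <- W3[3, 1] <- 2; W3[2, 3] <- W3[3, 2] <- 3
  expect_equal(network_zero_crossings(c(0.5, 0.5, -0.5), connectome(W3), 0.001), 5)
  # sub-threshold nodes do not contribute to the cut
  expect_equal(network_zero_crossings(c(0.5, 0.0005, -0.5), connectome(W3), 0.001), 2)
})

test_that("boundary lists aggregate reciprocal distances into adjacency", {
  rt <- tibble::tibble(region_id = c("L1", "L2", "L3", "R1"),
                       hemisphere = c("L", "L", "L", "R"))
  b <- tibble::tibble(region_i = c("L1", "L2", "L2", "L2", "L1"),
                      region_j = c("L2", "L3", "L3", "L3", "R1"),
                      distance = c(1, 2, 2, 2, 1))
  A <- adjacency_from_boundaries(b, rt)
  expect_equal(unclass(A)["L1", "L2"], 1)          # one pair at distance 1
  expect_equal(unclass(A)["L2", "L3"], 1.5)        # three pairs at distance 2
  expect_equal(unclass(A)["L1", "L3"], 0)          # no shared boundary
  expect_equal(unclass(A)["L1", "R1"], 0)          # cross-hemisphere zeroed
  expect_error(adjacency_from_boundaries(dplyr::mutate(b, distance = 0), rt),
               "positive")
})

test_that("roughness measures deviation from the neighborhood average", {
  n <- 8
  A <- ring_adjacency(n)
  # constant vector on a regular ring: A_bar u = u exactly
  expect_lt(roughness(rep(0.5, n), A, T = 0), 1e-12)
  # alternating +-c: neighbors average to -u, so roughness = 2 ||u||
  c0 <- 0.3
  u <- rep(c(c0, -c0), n / 2)
  expect_equal(roughness(u, A, T = 0), 2 * sqrt(sum(u^2)), tolerance = 1e-12)
  # absolute homogeneity
  set.seed(2); v <- rnorm(n)
  expect_equal(roughness(3 * v, A, T = 0), 3 * roughness(v, A, T = 0),
               tolerance = 1e-10)
  # two hemispheres: unweighted mean of per-hemisphere norms
  A2 <- ring_adjacency(n, hemisphere = rep(c("L", "R"), each = n / 2))
  A2m <- unclass(A2)
  A2m[1:4, 5:8] <- 0; A2m[5:8, 1:4] <- 0
  A2m[1, 4] <- A2m[4, 1] <- 1; A2m[5, 8] <- A2m[8, 5] <- 1  # close both rings
  A2 <- make_adjacency(A2m, rep(c("L", "R"), each = 4))
  u2 <- rep(c(c0, -c0), 4)
  expect_equal(roughness(u2, A2, T = 0), 2 * sqrt(sum(u2[1:4]^2)),
               tolerance = 1e-12)
  # a hemisphere with no edges is an error
  A3 <- make_adjacency(rbind(cbind(unclass(ring_adjacency(4)), matrix(0, 4, 2)),
                             matrix(0, 2, 6)),
                       c(rep("L", 4), "R", "R"))
  expect_error(roughness(rnorm(6), A3, T = 0), "no adjacency edges")
})

test_that("planted-modular harmonics are sparse at the top of the spectrum", {
  # ensemble-level contrasts: single SBM instances fluctuate, so the
  # qualitative claims are asserted on averages over a fixed set of seeds.
  # The amplitude threshold is scaled to the eigenvector entry magnitude
  # O(1/sqrt(N)) so that "near zero" is meaningful at this network size.
  sparsity_diff <- numeric(8)
  rough_diff <- numeric(8)
  for (seed in 1:8) {
    cfg <- synthetic_config(seed = seed)
    C <- generate_consensus_sc(cfg)
    basis <- connectome_harmonics(C)
    A <- generate_lattice_adjacency(generate_region_table(cfg))
    N <- length(basis$eigenvalues)
    freq <- harmonic_frequency(basis, normalize_frobenius(C), A,
                               T = 1 / (2 * sqrt(N)))
    sparsity_diff[seed] <- mean(freq$sparsity[(N - 2):N]) -
      mean(freq$sparsity[2:4])
    full <- cor(freq$roughness, freq$eigenvalue, method = "spearman")
    half <- seq_len(N %/% 2)
    rough_diff[seed] <- cor(freq$roughness[half], freq$eigenvalue[half],
                            method = "spearman") - full
  }
  # top-of-spectrum harmonics are sparser than low nontrivial ones
  expect_gt(mean(sparsity_diff), 0)
  # roughness vs eigenvalue is non-monotonic: the full-spectrum rank
  # correlation falls below the bottom-half correlation on average
  expect_gt(mean(rough_diff), 0)
})

test_that("ring harmonics behave like Fourier modes on all measures", {
  # analytic sinusoidal eigenbasis of C_12 with a generic phase (so no
  # sample point lands exactly on a node zero); the solver's choice of
  # basis inside degenerate pairs is arbitrary, the measures are not
  n <- 12
  ks <- c(0, rep(1:5, each = 2), 6)
  kind <- c("c", rep(c("c", "s"), 5), "c")
  phase <- 0.3
  U <- sapply(seq_along(ks), function(j) {
    arg <- 2 * pi * ks[j] * (0:(n - 1)) / n - phase
    v <- if (kind[j] == "c") cos(arg) else sin(arg)
    v / sqrt(sum(v^2))
  })
  expect_gt(min(abs(U)), 1e-3)  # generic phase: no exact node zeros
  lambda <- 1 - cos(2 * pi * ks / n)
  C <- ring_connectome(n)
  zcr <- apply(U, 2, zero_cross_rate, T = 1e-6)
  nzx <- apply(U, 2, network_zero_crossings, C = C, T = 1e-6)
  spars <- apply(U, 2, sparsity, T = 1e-6)
  expect_true(all(spars == 0))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (lambda[i] < lambda[j] - 1e-9) {
        expect_lte(zcr[i], zcr[j] + 1e-12)
        expect_lte(nzx[i], nzx[j] + 1e-9)
      }
    }
  }
})

test_that("threshold sweep stacks the measure table over a grid", {
  C <- ring_connectome(8)
  basis <- connectome_harmonics(C, normalize = FALSE)
  sw <- threshold_sweep(basis, C, thresholds = c(0, 0.01))
  expect_equal(nrow(sw), 16)
  expect_setequal(unique(sw$threshold), c(0, 0.01))
})
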