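test_that("power vectors are squared, unit-norm, and sign-invariant", {
  u <- c(1 / sqrt(2), -1 / sqrt(2), 0)
  U <- unname(cbind(u, c(0, 0, 1), c(1 / sqrt(2), 1 / sqrt(2), 0)))
  mk <- function(M) structure(list(vectors = M, eigenvalues = seq_len(ncol(M)),
                                   degree = NULL,
                                   region_ids = paste0("r", seq_len(nrow(M))),
                                   source_id = "x"),
                              class = "harmonic_basis")
  pb <- power_basis(mk(U))
  expect_equal(pb$vectors[, 1], c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  expect_equal(pb$vectors[, 2], c(0, 0, 1))  # one-hot is a fixed point
  expect_equal(sqrt(colSums(pb$vectors^2)), rep(1, 3), tolerance = 1e-12)
  pb_flip <- power_basis(mk(U %*% diag(c(-1, 1, -1))))
  expect_identical(pb$vectors, pb_flip$vectors)
})

test_that("RSN participation measures power mass per network", {
  N <- 8
  U <- diag(N)  # one-hot harmonics
  mk <- function(M) structure(list(vectors = M, eigenvalues = seq_len(ncol(M)),
                                   degree = NULL,
                                   region_ids = paste0("r", seq_len(nrow(M))),
                                   source_id = "x"),
                              class = "harmonic_basis")
  pb <- power_basis(mk(U))
  labels <- rep(c("A", "B"), each = 4)
  part <- rsn_participation(pb, labels, normalize = FALSE)
  expect_equal(part$A[1], 1)   # harmonic 1 sits entirely in RSN A
  expect_equal(part$B[1], 0)

  # uniform power vector: participation = |RSN| / sqrt(N)
  Uu <- cbind(rep(1, N) / sqrt(N), diag(N)[, 2:N])
  pu <- power_basis(mk(Uu))
  part_u <- rsn_participation(pu, labels, normalize = FALSE)
  expect_equal(part_u$A[1], 4 / sqrt(N), tolerance = 1e-12)

  # max-normalization makes every RSN column peak at exactly 1
  part_n <- rsn_participation(pb, labels, normalize = TRUE)
  expect_equal(max(part_n$A), 1)
  expect_equal(max(part_n$B), 1)

  expect_error(rsn_participation(pb, matrix(0, N, 2)), "exactly one")
})

test_that("projection obeys Parseval for U but not for the power basis", {
  C <- random_connected_sc(12, seed = 1)
  basis <- connectome_harmonics(C)
  pb <- power_basis(basis)
  set.seed(2)
  S <- matrix(rnorm(12 * 40), 12, 40)
  rownames(S) <- basis$region_ids
  proj <- project_series(pb, S, basis = basis, zscore = FALSE)
  expect_equal(sum(proj$gft_energy), sum(S^2), tolerance = 1e-8)
  # the power projection is not an isometry for generic signals
  expect_gt(abs(sum(proj$energy) - sum(S^2)), 1e-6)

  # replicating a power column recovers a constant unit projection
  Sk <- matrix(rep(pb$vectors[, 4], 25), 12, 25)
  rownames(Sk) <- basis$region_ids
  pk <- project_series(pb, Sk, zscore = FALSE)
  expect_equal(pk$s_hat[4, ], rep(1, 25), tolerance = 1e-12)
  expect_equal(pk$energy[4], 25, tolerance = 1e-12)

  # zero input gives zero projections and energies
  p0 <- project_series(pb, matrix(0, 12, 5,
                                  dimnames = list(basis$region_ids, NULL)),
                       zscore = FALSE)
  expect_true(all(p0$s_hat == 0) && all(p0$energy == 0))
})

test_that("sample entropy matches a brute-force enumeration oracle", {
  # independent O(T^2 m) loop-based oracle
  sampen_oracle <- function(x, m, r) {
    n <- length(x); tol <- r * sd(x); k <- n - m
    cnt <- function(len) {
      total <- 0
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= tol) {
          total <- total + 1
        }
      }
      total
    }
    -log(cnt(m + 1) / cnt(m))
  }
  set.seed(3)
  x <- rnorm(200)
  # white noise at m = 2 has abundant template matches
  expect_equal(sample_entropy(x, m = 2, r = 0.2), sampen_oracle(x, 2, 0.2),
               tolerance = 1e-12)
  expect_equal(sample_entropy(x, m = 2, r = 0.15), sampen_oracle(x, 2, 0.15),
               tolerance = 1e-12)
  # a smooth (band-limited) series keeps m = 5 well-defined
  xs <- as.vector(scale(stats::filter(cumsum(rnorm(220)), rep(0.2, 5))[6:205]))
  expect_equal(sample_entropy(xs, m = 5, r = 0.2), sampen_oracle(xs, 5, 0.2),
               tolerance = 1e-12)
  # undefined case: no length-m matches at all
  expect_warning(na <- sample_entropy(x, m = 5, r = 0.05), "undefined")
  expect_true(is.na(na))

  # constant series: all templates match at both lengths
  expect_equal(sample_entropy(rep(1, 50)), 0)

  # white noise is less regular than a sinusoid
  for (seed in 1:20) {
    set.seed(seed)
    noise <- rnorm(150)
    sine <- sin(2 * pi * (1:150) / 25)
    expect_gt(sample_entropy(noise, m = 2, r = 0.2),
              sample_entropy(sine, m = 2, r = 0.2))
  }
})

test_that("harmonic diversity spans [0, 1] with the documented anchor points", {
  expect_equal(harmonic_diversity(matrix(1, 4, 3)), rep(1, 3))
  onehot <- rbind(c(1, 2), 0, 0, 0)
  expect_equal(harmonic_diversity(onehot), c(0, 0))
  half <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(harmonic_diversity(half), log(2) / log(4))
  expect_equal(harmonic_diversity(half), 0.5)
  # all-zero timepoint is NA
  expect_true(is.na(harmonic_diversity(cbind(c(1, 1, 1), 0))[2]))
  expect_error(harmonic_diversity(matrix(1, 1, 3)), "at least 2")
})

test_that("ternary fractions live on the simplex with size-corrected strengths", {
  N <- 12
  part <- list(bounds = c(lo = 4L, hi = 9L),
               labels = regime_labels_from_bounds(N, 4, 9),
               votes = NULL, n_per_regime = c(3L, 6L, 3L))
  class(part) <- "regime_partition"

  # equal magnitudes everywhere: (1/3, 1/3, 1/3) at every timepoint
  td <- ternary_dynamics(matrix(0.7, N, 10), part)
  expect_true(all(abs(td$fractions - 1 / 3) < 1e-12))

  # activity confined to integrative projections: (1, 0, 0)
  sh <- matrix(0, N, 5); sh[1:3, ] <- 1
  td2 <- ternary_dynamics(sh, part)
  expect_equal(unname(td2$mean_fractions), c(1, 0, 0))

  # mean strengths in ratio 2:1:1 across regimes (size-corrected by the
  # mean aggregation) give fractions (0.5, 0.25, 0.25)
  sh3 <- matrix(0, N, 200)
  set.seed(4)
  sh3[1:3, ] <- abs(rnorm(3 * 200, 0, 2 * sqrt(pi / 2)))
  sh3[4:9, ] <- abs(rnorm(6 * 200, 0, 1 * sqrt(pi / 2)))
  sh3[10:12, ] <- abs(rnorm(3 * 200, 0, 1 * sqrt(pi / 2)))
  td3 <- ternary_dynamics(sh3, part)
  expect_true(all(abs(rowSums(td3$fractions) - 1) < 1e-9))
  expect_lt(max(abs(td3$mean_fractions - c(0.5, 0.25, 0.25))), 0.05)

  # sum aggregation restores regime-size bias
  td4 <- ternary_dynamics(matrix(0.7, N, 4), part, stat = "sum")
  expect_equal(unname(td4$mean_fractions), c(3, 6, 3) / 12)
})

test_that("regional energy back-projection is linear in the power columns", {
  C <- random_connected_sc(10, seed = 6)
  basis <- connectome_harmonics(C)
  pb <- power_basis(basis)
  part <- list(bounds = c(lo = 4L, hi = 7L),
               labels = regime_labels_from_bounds(10, 4, 7))
  class(part) <- "regime_partition"

  e <- rep(0, 10); e[5] <- 2.5
  re <- regional_energy(pb, e, part, "degenerate")
  expect_equal(re$energy, 2.5 * pb$vectors[, 5], tolerance = 1e-12,
               ignore_attr = TRUE)
  re0 <- regional_energy(pb, rep(0, 10), part, "integrative")
  expect_true(all(re0$energy == 0))
  # uniform energies: row sums of the regime's power columns
  reu <- regional_energy(pb, rep(1, 10), part, "segregative")
  expect_equal(reu$energy, rowSums(pb$vectors[, 8:10]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("percentile thresholding keeps ties and reduces to the mean at 0", {
  maps <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(participation_threshold(maps, 0), c(2.5, 2.5, 2.5, 2.5))
  # percentile 100: only the global maximum survives (ties kept)
  expect_equal(participation_threshold(maps, 100), c(2, 0, 0, 2))
  # constant maps survive thresholding unchanged under the >= rule
  expect_equal(participation_threshold(matrix(1, 3, 4), 80), rep(1, 4))
})

test_that("known harmonic amplitudes are recovered from projection energies", {
  C <- random_connected_sc(20, seed = 7)
  basis <- connectome_harmonics(C)
  amps <- seq(2, 0.1, length.out = 20)
  # calibrate noise to SNR 10 on the clean mixture
  clean <- generate_time_series(basis, amps, 300, noise_sd = 0, seed = 8)
  noise_sd <- sqrt(stats::var(as.vector(clean$values)) / 10)
  ts <- generate_time_series(basis, amps, 300, noise_sd = noise_sd, seed = 8)
  gft <- crossprod(basis$vectors, ts$values)
  energy <- rowSums(gft^2)
  expect_gt(cor(energy, amps^2, method = "spearman"), 0.95)
})
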