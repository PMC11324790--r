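test_that("raw gaps are nearest-neighbor spacings with one-sided ends", {
  expect_equal(raw_gap_spectrum(c(0, 1, 1, 2)), c(1, 0, 0, 1))
  expect_equal(raw_gap_spectrum(c(0, 4 / 3, 4 / 3, 4 / 3)), c(4 / 3, 0, 0, 0))
  expect_equal(raw_gap_spectrum(c(0, 0.5, 1, 1.5)), rep(0.5, 4))
  expect_error(raw_gap_spectrum(1), "at least 2")
  expect_error(raw_gap_spectrum(c(1, 0.5)), "ascending")
})

test_that("raw gaps vanish exactly on analytically degenerate spectra", {
  # K_n has an (n-1)-fold eigenvalue n/(n-1)
  b <- connectome_harmonics(complete_connectome(6), normalize = FALSE)
  expect_true(any(raw_gap_spectrum(b$eigenvalues) < 1e-10))

  # identical pendant nodes on the same hub: the pendant-permutation
  # automorphism forces a repeated eigenvalue (differences of pendant
  # indicators span a 2-dim eigenspace)
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1  # path core
  for (p in 4:6) W[3, p] <- W[p, 3] <- 0.7          # triplet pendants
  bt <- connectome_harmonics(connectome(W), normalize = FALSE)
  expect_lt(min(raw_gap_spectrum(bt$eigenvalues)), 1e-10)
})

test_that("spline smoothing reproduces polynomial eigenvalue curves", {
  n <- 80
  # linear: first derivative constant, second ~ 0
  gs <- smooth_gap_spectrum(0.01 * seq_len(n), degree = 10, interior_knots = 3)
  expect_lt(max(abs(gs$gap_curve - 0.01)), 1e-8)
  expect_lt(max(abs(gs$gap_derivative)), 1e-6)
  expect_lt(gs$residual_rms, 1e-10)

  # quadratic: first derivative 2 * scale * i
  sc <- 1e-4
  gq <- smooth_gap_spectrum(sc * seq_len(n)^2, degree = 10, interior_knots = 3)
  expect_lt(max(abs(gq$gap_curve - 2 * sc * seq_len(n))), 1e-6)

  expect_error(smooth_gap_spectrum(1:10, degree = 10, interior_knots = 3),
               "lower the degree")
})

test_that("logistic eigenvalue curves localize the gap-curve peak and regime bounds", {
  n <- 101
  i0 <- 51; s <- 12
  lam <- 1 / (1 + exp(-(seq_len(n) - i0) / s))
  gs <- smooth_gap_spectrum(lam)
  # first derivative peaks at the inflection
  expect_lte(abs(which.max(gs$gap_curve) - i0), 2)
  # second-derivative extrema of a logistic sit at i0 -+ log(2 + sqrt(3)) s
  offset <- log(2 + sqrt(3)) * s
  b <- regime_bounds(gs)
  expect_lte(abs(b["lo"] - (i0 - offset)), 2)
  expect_lte(abs(b["hi"] - (i0 + offset)), 2)
})

test_that("symmetric eigenvalue curves give bounds symmetric about the center", {
  n <- 101
  t <- (seq_len(n) - 1) / (n - 1)
  # second derivative proportional to sin(2 pi t): interior max at t = 1/4,
  # min at t = 3/4, symmetric about the center
  lam <- t - sin(2 * pi * t) / (2 * pi)^2
  b <- regime_bounds(smooth_gap_spectrum(lam))
  expect_lte(abs((b["lo"] + b["hi"]) / 2 - (n + 1) / 2), 1)

  # monotone second derivative: no detectable degenerate regime
  expect_error(regime_bounds(smooth_gap_spectrum(exp(seq(0, 2, length.out = 60)))),
               "no degenerate regime")
})

test_that("regime bounds read off a constructed derivative curve", {
  n <- 214
  x <- seq_len(n)
  d2 <- dnorm(x, 25, 8) - dnorm(x, 190, 8)  # single max at 25, single min at 190
  gap <- structure(list(gap_derivative = d2), class = "gap_spectrum")
  b <- regime_bounds(gap)
  expect_equal(unname(b), c(25, 190))
})

test_that("partition labels are contiguous, non-empty, and cover the spectrum", {
  cfg <- synthetic_config(seed = 2)
  basis <- connectome_harmonics(generate_consensus_sc(cfg))
  part <- regime_partition(basis)
  lab <- part$labels
  expect_equal(length(lab), 60)
  expect_true(all(table(lab) >= 1))
  expect_true(all(diff(as.integer(lab)) >= 0))  # contiguous blocks in order
  # the degenerate regime contains the eigenvalue closest to 1
  i1 <- which.min(abs(basis$eigenvalues - 1))
  expect_equal(as.character(lab[i1]), "degenerate")
})

test_that("consensus voting follows the majority-crossing rule", {
  N <- 214
  id_match <- structure(list(permutation = 1:N, objective = N,
                             per_pair_similarity = rep(1, N)),
                        class = "harmonic_match")
  mk <- function(lo, hi) list(labels = regime_labels_from_bounds(N, lo, hi),
                              match = id_match)
  # single subject: consensus equals that subject's partition
  p1 <- consensus_regimes(list(mk(30, 180)))
  expect_equal(unname(p1$bounds), c(30, 180))

  # identical subjects: consensus equals any subject
  p2 <- consensus_regimes(list(mk(30, 180), mk(30, 180), mk(30, 180)))
  expect_equal(unname(p2$bounds), c(30, 180))

  # lo votes uniform on {24, 25, 26, 27}: at index 25 exactly half the
  # subjects vote degenerate, and the tie resolves toward degenerate
  p3 <- consensus_regimes(list(mk(24, 190), mk(25, 190), mk(26, 190), mk(27, 190)))
  expect_equal(unname(p3$bounds["lo"]), 25)
  expect_equal(unname(p3$bounds["hi"]), 190)
  expect_equal(sum(p3$n_per_regime), N)

  # disjoint degenerate blocks never reach a majority: fallback with warning
  expect_warning(
    pf <- consensus_regimes(list(mk(10, 20), mk(30, 40), mk(50, 60)),
                            fallback = c(25, 45)),
    "falling back")
  expect_equal(unname(pf$bounds), c(25, 45))
})

test_that("labels transport through the matching permutation", {
  N <- 20
  # subject harmonic p(i) is assigned to consensus index i
  p <- c(2:N, 1L)
  m <- structure(list(permutation = p, objective = N,
                      per_pair_similarity = rep(1, N)),
                 class = "harmonic_match")
  labels <- regime_labels_from_bounds(N, 5, 15)
  part <- consensus_regimes(list(list(labels = labels, match = m)))
  # transported degenerate votes sit at consensus indices 4..14; the final
  # labels are made contiguous from the crossing points
  expect_equal(unname(part$bounds), c(4, 14))
})
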