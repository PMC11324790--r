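#' Configuration for a synthetic connectome ensemble
#'
#' Describes a planted-modular weighted connectome shared by an ensemble of
#' subjects: a stochastic block structure with within/between-module edge
#' probabilities and weight scales, an optional hub fraction emulating
#' rich-club cross-module wiring, and multiplicative log-normal subject
#' jitter.
#'
#' @param n_regions Number of regions N.
#' @param module_sizes Integer vector summing to `n_regions`.
#' @param p_within,p_between Edge probabilities in `[0, 1]`.
#' @param weight_scale_within,weight_scale_between Positive weight scales.
#' @param n_subjects Ensemble size.
#' @param subject_jitter_sd SD of the log-normal multiplicative weight jitter.
#' @param hub_fraction Fraction of nodes given extra cross-module edges.
#' @param bridge_disconnected If a sampled graph is disconnected, add
#'   minimum-weight bridges (`TRUE`, default) or retry/resample (`FALSE`).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_regions = 60,
                             module_sizes = c(20, 20, 20),
                             p_within = 0.8,
                             p_between = 0.05,
                             weight_scale_within = 1,
                             weight_scale_between = 0.4,
                             n_subjects = 10,
                             subject_jitter_sd = 0.1,
                             hub_fraction = 0.1,
                             bridge_disconnected = TRUE,
                             seed = 1L) {
  if (sum(module_sizes) != n_regions) {
    stop("module_sizes must sum to n_regions", call. = FALSE)
  }
  if (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (subject_jitter_sd < 0) stop("subject_jitter_sd must be >= 0", call. = FALSE)
  structure(list(n_regions = n_regions, module_sizes = module_sizes,
                 p_within = p_within, p_between = p_between,
                 weight_scale_within = weight_scale_within,
                 weight_scale_between = weight_scale_between,
                 n_subjects = n_subjects,
                 subject_jitter_sd = subject_jitter_sd,
                 hub_fraction = hub_fraction,
                 bridge_disconnected = bridge_disconnected,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Synthetic region metadata table
#'
#' Regions are split into two contiguous hemisphere blocks (L then R) so that
#' spatially close regions are adjacent in index order, labelled with a
#' cyclic assignment of resting-state-network-like labels, given their
#' planted module id, and placed on a line with unit spacing per hemisphere
#' (an arbitrary spatial unit).
#'
#' @param config A `synthetic_config`.
#' @param rsn_labels Labels cycled over regions; default emulates 7 canonical
#'   RSNs plus subcortex.
#' @return Tibble with `region_id`, `index` (0-based), `hemisphere`,
#'   `rsn_label`, `module_id`, `x`, `y`, `z`.
#' @export
generate_region_table <- function(config,
                                  rsn_labels = c("Vis", "SomMot", "DorsAttn",
                                                 "SalVentAttn", "Limbic",
                                                 "Cont", "Default", "Subcortex")) {
  n <- config$n_regions
  module_id <- rep(seq_along(config$module_sizes), config$module_sizes)
  hemi <- rep(c("L", "R"), c(ceiling(n / 2), floor(n / 2)))
  pos <- c(seq_len(ceiling(n / 2)), seq_len(floor(n / 2)))
  tibble::tibble(
    region_id = sprintf("%s_roi%03d", hemi, seq_len(n)),
    index = seq_len(n) - 1L,
    hemisphere = hemi,
    rsn_label = rep_len(rsn_labels, n),
    module_id = module_id,
    x = as.numeric(pos),
    y = ifelse(hemi == "L", -1, 1),
    z = 0
  )
}

#' Generate the consensus structural connectome of a synthetic study
#'
#' Samples a weighted stochastic-block-model connectome: edges occur with
#' probability `p_within` inside modules and `p_between` across them, with
#' log-normal weights around the respective scale. A `hub_fraction` of nodes
#' receives extra cross-module edges at within-module strength (rich-club
#' emulation). Disconnected draws are repaired with minimum-weight bridges or
#' resampled, per config.
#'
#' @param config A `synthetic_config`.
#' @param max_retries Resampling budget when `bridge_disconnected = FALSE`.
#' @return A `connectome` (unnormalized weights).
#' @export
generate_consensus_sc <- function(config, max_retries = 20L) {
  rt <- generate_region_table(config)
  set.seed(config$seed)
  for (attempt in seq_len(max_retries)) {
    W <- sample_block_weights(config, rt$module_id)
    if (is_connected_matrix(W)) {
      return(connectome(W, rt$region_id))
    }
    if (config$bridge_disconnected) {
      W <- bridge_components(W, config$weight_scale_between)
      return(connectome(W, rt$region_id))
    }
  }
  stop(sprintf(
    paste0("could not generate a connected connectome after %d attempts ",
           "(n=%d, p_within=%.3g, p_between=%.3g); increase densities or ",
           "enable bridge_disconnected"),
    max_retries, config$n_regions, config$p_within, config$p_between),
    call. = FALSE)
}

sample_block_weights <- function(config, module_id) {
  n <- config$n_regions
  same <- outer(module_id, module_id, `==`)
  p <- ifelse(same, config$p_within, config$p_between)
  scale <- ifelse(same, config$weight_scale_within, config$weight_scale_between)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  m <- sum(ut)
  present <- stats::runif(m) < p[ut]
  w <- scale[ut] * exp(stats::rnorm(m, 0, 0.25))
  W[ut] <- ifelse(present, w, 0)
  # rich-club emulation: hubs get within-strength edges to every module
  n_hubs <- round(config$hub_fraction * n)
  if (n_hubs > 0) {
    hubs <- sample.int(n, n_hubs)
    for (h in hubs) {
      targets <- setdiff(which(module_id != module_id[h]), h)
      extra <- targets[stats::runif(length(targets)) < config$p_within / 2]
      if (length(extra) > 0) {
        wex <- config$weight_scale_within * exp(stats::rnorm(length(extra), 0, 0.25))
        i <- pmin(h, extra); j <- pmax(h, extra)
        W[cbind(i, j)] <- pmax(W[cbind(i, j)], wex)
      }
    }
  }
  W[lower.tri(W)] <- 0
  W <- W + t(W)
  diag(W) <- 0
  W
}

is_connected_matrix <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
  igraph::is_connected(g)
}

# join components with minimum-weight edges between lowest-index nodes
bridge_components <- function(W, bridge_scale) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  while (length(unique(comp)) > 1) {
    a <- which(comp == unique(comp)[1])[1]
    b <- which(comp == unique(comp)[2])[1]
    w <- bridge_scale * 0.1  # deliberately weak: a repair, not structure
    W[a, b] <- W[b, a] <- w
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
  }
  W
}

#' Generate a jittered subject ensemble from a consensus connectome
#'
#' Each subject's matrix is the consensus with symmetric elementwise
#' log-normal multiplicative jitter on existing edges; topology is shared so
#' that harmonic matching across subjects is meaningful. Optionally a
#' fraction of the weakest edges is deleted and an equal number of new weak
#' edges added per subject, to stress matching.
#'
#' @param consensus A `connectome`.
#' @param n_subjects Number of subjects.
#' @param subject_jitter_sd SD of `log` weights; 0 returns exact copies.
#' @param seed Integer seed.
#' @param edge_flip_fraction Fraction of edges rewired per subject (default 0).
#' @return List of `connectome` objects.
#' @export
generate_subject_ensemble <- function(consensus, n_subjects,
                                      subject_jitter_sd = 0.1,
                                      seed = 1L,
                                      edge_flip_fraction = 0) {
  validate_connectome(consensus)
  stopifnot(subject_jitter_sd >= 0, n_subjects >= 1)
  W0 <- unclass(consensus)
  n <- nrow(W0)
  ut <- upper.tri(W0)
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    W <- matrix(0, n, n)
    jit <- if (subject_jitter_sd > 0) {
      exp(stats::rnorm(sum(ut), 0, subject_jitter_sd))
    } else rep(1, sum(ut))
    W[ut] <- W0[ut] * jit
    if (edge_flip_fraction > 0) {
      present <- which(W[ut] > 0)
      absent <- which(W0[ut] == 0)
      k <- round(edge_flip_fraction * length(present))
      if (k > 0 && length(absent) >= k) {
        wvals <- W[ut]
        drop_idx <- present[order(wvals[present])[seq_len(k)]]
        add_idx <- sample(absent, k)
        wvals[add_idx] <- stats::quantile(wvals[present], 0.1)
        wvals[drop_idx] <- 0
        W[ut] <- wvals
      }
    }
    W <- W + t(W)
    connectome(W, region_ids(consensus))
  })
}

#' Within-hemisphere lattice adjacency from region coordinates
#'
#' Builds a spatial regional adjacency: each region is connected to its
#' `neighbors_per_side` nearest index-neighbors within the same hemisphere,
#' with weight equal to the reciprocal centroid distance. Entries between
#' hemispheres are zero (roughness is computed per hemisphere).
#'
#' @param region_table Tibble from [generate_region_table()] (needs
#'   `region_id`, `hemisphere`, `x`, `y`, `z`).
#' @param neighbors_per_side Chain depth (1 = simple chain).
#' @return An `adjacency` matrix object with a `hemisphere` attribute.
#' @export
generate_lattice_adjacency <- function(region_table, neighbors_per_side = 1L) {
  n <- nrow(region_table)
  A <- matrix(0, n, n, dimnames = list(region_table$region_id,
                                       region_table$region_id))
  xyz <- as.matrix(region_table[, c("x", "y", "z")])
  for (h in unique(region_table$hemisphere)) {
    idx <- which(region_table$hemisphere == h)
    for (k in seq_len(neighbors_per_side)) {
      if (length(idx) <= k) next
      i <- idx[seq_len(length(idx) - k)]
      j <- idx[seq_len(length(idx) - k) + k]
      d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
      if (any(d == 0)) {
        stop("regions with identical centroids: reciprocal distance undefined",
             call. = FALSE)
      }
      A[cbind(i, j)] <- 1 / d
      A[cbind(j, i)] <- 1 / d
    }
  }
  structure(A, class = c("adjacency", "matrix", "array"),
            hemisphere = stats::setNames(region_table$hemisphere,
                                         region_table$region_id))
}

#' Synthesize region-by-time signals as a noisy mixture of harmonics
#'
#' Each harmonic contributes a seeded band-limited random-walk waveform
#' scaled by its amplitude; signals are mixed through the harmonic basis and
#' i.i.d. Gaussian noise is added. The ground-truth per-harmonic energy
#' share (proportional to amplitude squared) is recorded for recovery tests.
#'
#' @param basis A `harmonic_basis`.
#' @param amplitudes Length-N nonnegative amplitude per harmonic.
#' @param n_timepoints Number of timepoints T.
#' @param noise_sd SD of additive Gaussian region noise.
#' @param seed Integer seed.
#' @param tr Sampling interval in seconds (metadata only).
#' @param smooth_window Moving-average window (in samples) band-limiting the
#'   waveforms; 1 disables smoothing.
#' @return A `timeseries_matrix`: list with `values` (N regions x T),
#'   `tr`, and `truth` (tibble of harmonic, amplitude, energy_share).
#' @export
generate_time_series <- function(basis, amplitudes, n_timepoints = 200,
                                 noise_sd = 0.1, seed = 1L, tr = 0.6,
                                 smooth_window = 5L) {
  U <- basis$vectors
  N <- ncol(U)
  if (length(amplitudes) != N) {
    stop("amplitudes must have one entry per harmonic", call. = FALSE)
  }
  set.seed(seed)
  # band-limited unit-variance random walk per harmonic
  Wav <- matrix(0, N, n_timepoints)
  active <- which(amplitudes != 0)
  for (i in active) {
    w <- cumsum(stats::rnorm(n_timepoints + 2 * smooth_window))
    if (smooth_window > 1) {
      w <- stats::filter(w, rep(1 / smooth_window, smooth_window), sides = 2)
      w <- w[!is.na(w)]
    }
    w <- w[seq_len(n_timepoints)]
    w <- (w - mean(w)) / stats::sd(w)
    Wav[i, ] <- amplitudes[i] * w
  }
  S <- U %*% Wav
  if (noise_sd > 0) {
    S <- S + matrix(stats::rnorm(length(S), 0, noise_sd), nrow(S), ncol(S))
  }
  rownames(S) <- basis$region_ids
  colnames(S) <- paste0("t", seq_len(n_timepoints))
  a2 <- amplitudes^2
  structure(list(values = S, tr = tr,
                 truth = tibble::tibble(
                   harmonic = seq_len(N),
                   amplitude = amplitudes,
                   energy_share = if (sum(a2) > 0) a2 / sum(a2) else a2)),
            class = "timeseries_matrix")
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("<timeseries_matrix> %d regions x %d timepoints (TR %.3gs)\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Generate a complete synthetic study
#'
#' One call producing everything downstream stages need: region table,
#' consensus connectome, subject ensemble, lattice adjacency, and (optional)
#' per-subject time series driven by regime-structured amplitudes.
#'
#' @param config A `synthetic_config`.
#' @param with_time_series Also synthesize per-subject time series.
#' @param n_timepoints,noise_sd Passed to [generate_time_series()].
#' @return List with `config`, `region_table`, `consensus`, `subjects`,
#'   `adjacency`, and optionally `time_series` (list per subject).
#' @export
generate_study <- function(config, with_time_series = FALSE,
                           n_timepoints = 200, noise_sd = 0.1) {
  rt <- generate_region_table(config)
  consensus <- generate_consensus_sc(config)
  subjects <- generate_subject_ensemble(consensus, config$n_subjects,
                                        config$subject_jitter_sd,
                                        seed = config$seed + 1L)
  adjacency <- generate_lattice_adjacency(rt)
  out <- list(config = config, region_table = rt, consensus = consensus,
              subjects = subjects, adjacency = adjacency)
  if (with_time_series) {
    cons_basis <- connectome_harmonics(consensus, source_id = "consensus")
    N <- config$n_regions
    amps <- exp(-seq_len(N) / N)  # mildly low-frequency-dominant resting mix
    out$time_series <- lapply(seq_len(config$n_subjects), function(s) {
      generate_time_series(cons_basis, amps, n_timepoints, noise_sd,
                           seed = config$seed + 100L + s)
    })
  }
  out
}
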