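#' Run the full harmonic-regime analysis on a synthetic study
#'
#' End-to-end driver: generate a seeded synthetic ensemble, decompose every
#' subject and the consensus, match subjects to the consensus, compute
#' agreement, frequency measures, the gap-spectrum and consensus regimes,
#' perturbation stability of the consensus, regime-specific reconstructions
#' with graph metrics, and (optionally) functional projections. All outputs
#' are plain TSV/JSON when `out_dir` is given; identical config + seed gives
#' byte-identical files.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Optional output directory (created if missing).
#' @param with_time_series Include time-series synthesis and projection.
#' @param stability_realizations Noise realizations per sigma.
#' @param sigma_grid Perturbation scales.
#' @param n_null Null networks per graph-metric call.
#' @return Invisible list of all intermediate results.
#' @export
run_pipeline <- function(config, out_dir = NULL, with_time_series = TRUE,
                         stability_realizations = 3L,
                         sigma_grid = seq(0, 2e-3, by = 2.5e-4),
                         n_null = 5L) {
  study <- generate_study(config, with_time_series = with_time_series)
  consensus <- consensus_connectome(study$subjects)
  cons_basis <- connectome_harmonics(consensus, normalize = FALSE,
                                     source_id = "consensus")
  subj_bases <- lapply(seq_along(study$subjects), function(s)
    connectome_harmonics(study$subjects[[s]], source_id = paste0("subject_", s)))

  matches <- lapply(subj_bases, match_harmonics, V = cons_basis)
  agreement <- intersubject_agreement(subj_bases, cons_basis, matched = TRUE)

  freq <- harmonic_frequency(cons_basis, consensus, study$adjacency)
  gap <- smooth_gap_spectrum(cons_basis$eigenvalues)
  cons_bounds <- tryCatch(regime_bounds(gap), error = function(e) NULL)

  per_subject <- lapply(seq_along(subj_bases), function(s) {
    list(labels = subject_regime_labels(subj_bases[[s]]),
         match = matches[[s]])
  })
  partition <- consensus_regimes(per_subject, fallback = cons_bounds)

  stability <- estimate_stability(
    consensus,
    perturbation_config(sigma_grid = sigma_grid,
                        n_realizations = stability_realizations,
                        seed = config$seed + 7L),
    basis = cons_basis)

  regime_sc <- regime_connectomes(cons_basis, partition)
  metrics <- purrr::map_dfr(names(regime_sc), function(r) {
    Ct <- regime_sc[[r]]$C_tilde
    if (regime_sc[[r]]$zero_norm || all(Ct[upper.tri(Ct)] == 0)) {
      # an empty reconstruction (e.g. an integrative regime holding only the
      # constant harmonic) has no defined graph metrics
      return(tibble::tibble(regime = r, modularity = NA_real_,
                            global_efficiency = NA_real_, clustering = NA_real_,
                            char_path_length = NA_real_,
                            small_worldness = NA_real_, coreness = NA_real_,
                            clustering_null = NA_real_,
                            path_length_null = NA_real_))
    }
    dplyr::mutate(graph_metrics(Ct, n_null = n_null,
                                seed = config$seed + 11L),
                  regime = r, .before = 1)
  })

  out <- list(study = study, consensus = consensus, cons_basis = cons_basis,
              subj_bases = subj_bases, matches = matches,
              agreement = agreement, frequency = freq, gap = gap,
              partition = partition, stability = stability,
              regime_sc = regime_sc, regime_metrics = metrics)

  if (with_time_series) {
    pw <- power_basis(cons_basis)
    projections <- lapply(study$time_series, function(ts)
      project_series(pw, ts, basis = cons_basis))
    out$projections <- projections
    out$regime_summary <- purrr::map_dfr(seq_along(projections), function(s)
      dplyr::mutate(regime_projection_summary(projections[[s]], partition),
                    subject = s, .before = 1))
    out$ternary <- lapply(projections, function(p)
      ternary_dynamics(p$s_hat, partition))
  }

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, config)
  invisible(out)
}

write_pipeline_outputs <- function(out, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_matrix_tsv(unclass(out$consensus), p("consensus_sc.tsv"))
  write_region_table(out$study$region_table, p("region_table.tsv"))
  write_harmonics(out$cons_basis, p("consensus_harmonics"))
  readr::write_tsv(tidy(out$agreement), p("agreement_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(out$frequency, p("frequency_measures.tsv"), progress = FALSE)
  readr::write_tsv(tidy(out$gap), p("gap_spectrum.tsv"), progress = FALSE)
  readr::write_tsv(tidy(out$partition), p("regimes.tsv"), progress = FALSE)
  readr::write_tsv(tidy(out$stability), p("stability.tsv"), progress = FALSE)
  readr::write_tsv(out$regime_metrics, p("regime_metrics.tsv"), progress = FALSE)
  for (r in names(out$regime_sc)) {
    write_matrix_tsv(out$regime_sc[[r]]$C_tilde, p(paste0("regime_sc_", r, ".tsv")))
  }
  if (!is.null(out$regime_summary)) {
    readr::write_tsv(out$regime_summary, p("projection_summary.tsv"),
                     progress = FALSE)
    mf <- t(sapply(out$ternary, function(t3) t3$mean_fractions))
    readr::write_tsv(tibble::tibble(subject = seq_len(nrow(mf)),
                                    integrative = mf[, 1],
                                    degenerate = mf[, 2],
                                    segregative = mf[, 3]),
                     p("ternary_mean_fractions.tsv"), progress = FALSE)
  }
  write_sidecar(list(config = unclass(config),
                     bounds = as.list(out$partition$bounds),
                     n_per_regime = out$partition$n_per_regime),
                p("pipeline.json"))
  invisible(out_dir)
}
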