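---
title: "Harmonic regimes of structural connectomes: model, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic regimes of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connharm)
```

## The model

A structural connectome is a symmetric, nonnegative, zero-diagonal weight
matrix $C$ over $N$ brain regions. After rescaling $C$ to unit Frobenius
norm, the package forms the degree-normalized graph Laplacian

$$\mathcal{L} = I - D^{-1/2} C D^{-1/2},$$

where $D$ is the diagonal strength matrix, and eigendecomposes it,
$\mathcal{L} = U \Lambda U^T$. The columns $u_i$ of $U$ — the *connectome
harmonics* — form an orthonormal basis of spatial patterns, ordered by
ascending eigenvalue $\lambda_i \in [0, 2]$. For a connected graph
$\lambda_1 = 0$ with kernel proportional to $D^{1/2}\mathbf{1}$, and
$\lambda = 2$ is attained only by bipartite structure. Eigenvalues are
conventionally read as graph frequencies, but several of the package's
measures exist precisely to probe where that Fourier intuition breaks down.

Eigenvector signs are mathematically arbitrary; the package fixes each
column's sign so its largest-magnitude entry is positive (ties broken by
lowest index), making outputs reproducible across solvers. Within
numerically degenerate eigenvalue blocks (tie tolerance $10^{-10}$) the
returned basis is solver-dependent; no canonical basis is promised there,
because cross-subject matching (below) is the canonicalization mechanism.

## Spatial frequency measures

Four per-harmonic measures quantify Fourier-like character. All apply an
amplitude threshold $T$ first (entries with $|u_i| \le T$ set to zero) to
suppress spurious near-zero fluctuation; the default $T = 0.001$ follows
the convention for empirical connectomes of a few hundred regions. Since
eigenvector entries scale as $1/\sqrt{N}$, analyses at other sizes may pass
a scaled threshold — the test suite uses $T = 1/(2\sqrt{N})$ on 60-node
synthetic networks for exactly this reason, and `threshold_sweep()`
recomputes everything over a grid of $T$.

- **Sparsity**: fraction of thresholded-zero regions. Classical Fourier
  harmonics have none.
- **Zero-cross rate**: polarity switches scanned along the spatial region
  ordering, divided by $N - 1$. Thresholded zeros are skipped — they
  neither count as crossings nor reset the running sign.
- **Network zero crossings**: the connectome weight cut by the harmonic's
  sign partition, restricted to supra-threshold regions. The printed form
  of this measure thresholds $u^2$; the package thresholds $|u|$ for
  consistency with the other measures and exposes `on_square = TRUE` for
  the alternative.
- **Roughness**: $\lVert u_h - \bar{A}_h u_h \rVert_2$ per hemisphere on the
  degree-normalized regional adjacency $\bar A$ (reciprocal boundary
  distances), averaged across hemispheres with an unweighted mean. Nodes
  isolated in the adjacency are excluded.

## Matching, agreement, and regimes

Subject bases are aligned to a consensus basis (the decomposition of the
Frobenius-normalized mean of the normalized subject matrices) by an exact
maximum-weight bipartite assignment on $|U^T V|$ — any exact solver attains
the same objective; ties are canonicalized toward the lexicographically
smallest permutation. Procrustes-style rotation is deliberately not used:
rotation would mix subject-specific harmonics, which are the object of
study. Inter-subject agreement between two subjects is
$|\mathrm{diag}(U_i^T U_j)|$ after each is independently matched to the
consensus.

The *gap-spectrum* smooths the ascending eigenvalue curve with a
least-squares B-spline (degree 10, 3 interior knots at index quartiles;
both are arguments, since "order" and knot placement are convention-laden)
and takes analytic derivatives. The first derivative is the smooth local
eigenvalue spacing — the degeneracy profile; the degenerate regime's bounds
are the first local maximum and last local minimum of the second
derivative, with a plateau rule (first index of a plateau) and strictness
tolerance $10^{-12}$. The degenerate regime is the inclusive interval
$[lo, hi]$; integrative harmonics sit below, segregative above. Each
subject is labelled from its own spectrum, labels are transported through
the subject's matching permutation, and per-index majority votes (an exact
0.5 tie resolves toward the degenerate label) define the consensus bounds.
When votes never reach 0.5 the consensus-spectrum bounds are used with a
warning.

## Stability, regime networks, and function

**Perturbation stability.** Rayleigh($\sigma$) noise (the $\nu = 0$ Rician,
MRI-motivated) is added symmetrically to the unit-norm connectome over
$\sigma \in [0, 0.002]$ in steps of $2.5\times10^{-4}$; each perturbed
basis is re-matched to the unperturbed one and the per-harmonic similarity
$P(\sigma) = |\mathrm{diag}(U_\sigma^T U)|$ recorded. Stability is the
least-squares slope of $\ln P$ versus $\sigma$. Realizations per $\sigma$
(default 5; 3 in the fast pipeline) are averaged, with per-$(\sigma,
r)$ seeds derived from the master seed; the perturbed matrix is not
re-normalized (a flag enables it for sensitivity analysis).

**Regime-specific networks.** For an interval $[j, k]$,
$\tilde{\mathcal{L}} = \sum_{i=j}^k \lambda_i u_i u_i^T$ and
$\tilde C = D^{1/2}(\tilde D - \tilde{\mathcal{L}})D^{1/2}$ with $\tilde D =
\mathrm{diag}(\tilde{\mathcal{L}})$; negative weights (excluded structure)
are clipped to zero and the result normalized to unit Frobenius norm. Graph
metrics use: Louvain modularity (best of 20 seeded restarts), global
efficiency and path length on lengths $1/w$ (configurable to $-\log w$),
Onnela geometric-mean weighted clustering, small-worldness against
degree-preserving nulls whose original weight multiset is re-sorted onto
the randomized topology by expected strength, and a weighted $s$-core
coreness (mean nodal maximal core level, normalized). The $s$-core choice
is one of several "coreness" conventions; it was selected because it is the
natural weighted analogue of $k$-core level and is deterministic.

**Functional projection.** Harmonic power vectors $\bar u_i = u_i^2 /
\lVert u_i^2 \rVert_2$ are nonnegative and sign-free; functional series are
projected as $\hat s(t) = \bar U^T s(t)$ (per-region z-scoring on by
default, since empirical series arrive in arbitrary units), alongside the
companion graph Fourier transform $U^T s(t)$, which satisfies Parseval —
the power projection intentionally does not. Downstream summaries: energy
$\sum_t \hat s_i(t)^2$; sample entropy (Chebyshev distance, both template
lengths over the same $n - m$ starting points, $r = 0.2 \times$ SD, $m = 5$
samples matching a few-second dynamic timescale at fMRI sampling rates;
undefined when no length-$m$ templates match); harmonic diversity — Shannon
entropy of $p_i(t) \propto |\hat s_i(t)|$ within a regime, normalized by
$\log n$ (the printed form divides signed projections by their signed sum,
which is sign-ill-defined for real projections; absolute values are used);
and ternary regime dynamics, where each regime's strength is the *mean*
absolute projection over its harmonics — the mean (rather than sum) removes
regime-size bias, and `stat = "sum"` restores the raw convention.
Group-level participation maps zero values below the pooled 80th percentile
(ties kept under `>=`) before averaging.

## The synthetic study

`synthetic_config()` defines the study conditions used throughout the tests
and the acceptance script: 60 regions in two contiguous hemisphere blocks,
three planted modules of 20, within/between edge probabilities 0.8/0.05,
weight scales 1/0.4 with mild log-normal heterogeneity (sdlog 0.25), 10%
hub nodes with extra cross-module edges emulating a rich club, 10 subjects
with multiplicative log-normal weight jitter (sd 0.1) on a shared topology,
a within-hemisphere chain adjacency at unit spacing, and time series mixed
from harmonics with amplitudes $e^{-i/N}$ (mildly low-frequency-dominant,
resting-like) plus Gaussian noise. Waveforms are band-limited random walks,
chosen so sample-entropy contrasts are nondegenerate. Disconnected draws
are repaired with deliberately weak bridges (or resampled, by flag) because
the $\lambda_1 = 0$ uniqueness underlying the whole framework assumes
connectedness.

These sizes keep every ensemble analysis in seconds on a laptop while
leaving the spectra rich enough for regime detection; they are the
package's reference problem sizes.

What the generator does *not* emulate — tractography biases,
distance-dependent false positives, realistic streamline-count
distributions, spatially embedded multi-scale clusters — bounds what
passing tests show about real data. One concrete consequence: on planted
block-model ensembles the regime reconstructions robustly reproduce
*integrative highest efficiency* and *segregative more within-module weight
than integrative*, but the fine ordering between degenerate and segregative
reconstructions differs from what is observed on real connectomes, whose
high-eigenvalue harmonics localize in spatially compact dense clusters that
a flat block model does not contain. Similarly, sparsity and
roughness-vs-eigenvalue contrasts are ensemble-level tendencies on these
synthetics rather than per-instance certainties, and are tested as
averages over fixed seed sets.

## Numerical choices and degenerate inputs

- Symmetry is enforced to $10^{-12}$ on input and re-symmetrized after
  floating-point Laplacian assembly; eigenvalues within $10^{-12}$ of zero
  are clipped to zero.
- Isolated nodes (zero strength) are an error naming the region; an
  all-zero connectome cannot be normalized.
- `stability_slopes()` clamps $P = 0$ at machine epsilon before the log,
  with a warning.
- Empty regime reconstructions (e.g. an integrative regime containing only
  the constant harmonic) carry a `zero_norm` flag and yield `NA` graph
  metrics in the pipeline rather than an error.
- All randomness flows from explicit integer seeds; identical config and
  seed give byte-identical TSV/JSON output, which the test suite asserts by
  comparing raw bytes across pipeline runs.

## Known limitations

The regime trichotomy assumes a unimodal degenerate bulk; spectra without
interior curvature extrema raise an error rather than guessing. Matching is
one-to-one; subspace (block) matching across strongly degenerate subspaces
is out of scope. The CLI reader reconstructs bases from TSV at reduced
(written) precision, which is ample for all shipped analyses but not for
re-deriving $10^{-12}$-level identities from files.
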