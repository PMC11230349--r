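---
title: "SNR-guided thresholding and partition fitness for functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNR-guided thresholding and partition fitness for functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snrthresh)
```

## The model

`snrthresh` treats a weighted functional connectome `FC` (symmetric,
zero-diagonal, correlation-valued) together with an a-priori community
partition `sigma` of its `n` nodes into `k` communities as an observed
stochastic block model: both the graph and the labels are given, so the SBM
parameters are estimated by plug-in (law-of-large-numbers) inference rather
than by latent-label search. With community sizes `Omega` and prior
`p = Omega / n`:

* `C` accumulates, over unordered node pairs `u < v`, the block edge
  statistics — edge counts for a binarized graph, sums of absolute weights
  `|w_uv|` for a weighted graph (only the magnitude of a coupling carries
  prominence information; its sign does not).
* `C_max[i, j] = Omega_i * Omega_j` is the pair capacity between blocks;
  on the diagonal the package uses `Omega_i (Omega_i - 1) / 2`, the number
  of unordered within-block pairs. See *Numerical conventions* below.
* `W = C / C_max` entrywise (with `0/0 = 0` for singleton-block diagonals),
  `Q = n W` (expected degrees at the constant degree-regime scale
  `s_t = 1`), and the community profile matrix `PQ = n P W`.

The prominence statistic is `SNR = lambda_2^2 / lambda_1` with the
eigenvalues of `PQ` ordered by descending magnitude. `SNR > 1` is the
Kesten–Stigum condition under which weak recovery of the partition —
community detection strictly better than chance — is efficiently solvable.
Both extremes carry no mesoscopic information and correctly score low:
near-complete graphs make `PQ` close to rank one (`lambda_2 ~ 0`, too much
noise), near-empty graphs drive `lambda_1` to zero (too little signal).

`analytic_snr(p, q)` evaluates the same statistic directly on model
parameters; for the symmetric two-community model `p = (1/2, 1/2)`,
`q = [[a, b], [b, a]]` it reduces to `(a - b)^2 / (2 (a + b))`, which equals
1 exactly at `q = [[6, 2], [2, 6]]` — the configuration used as the
package's exact reference value.

## The threshold-selection pipeline

`snr_threshold(cohort, partition)` runs four steps:

1. **Group average.** Entrywise arithmetic mean of the subjects' signed
   weights. No Fisher-z transform is applied: the pipeline consumes the
   averaged couplings on their native scale, and averaging is itself part of
   the phenomenon being modelled (it damps subject-specific fingerprints).
2. **Vetting.** The group average is binarized at each `tau` on the grid
   (default `[0, 1]` in steps of 0.05) by `|w_uv| > tau`, and the binary SNR
   profile determines the weak-recoverability interval `[a_w, b_w]`, the
   range of grid points with SNR > 1.
3. **Prominence.** The weighted SNR profile (mean absolute retained
   couplings) is computed for the group average and for every subject.
4. **Selection.** `tau_opt` is the grid argmax of each weighted profile
   (ties break toward the smaller threshold — the less destructive choice),
   and every optimum is checked for membership in `[a_w, b_w]`. Vetting
   failures are flagged in the returned object, never raised as errors.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `grid` step | 0.05 | threshold line-search increment on `[0, 1]`; dimensionless correlation units |
| `rule` | `"magnitude"` | retain `|w| > tau` (strict); `"positive"` keeps only `w > tau` for sign-sensitivity analyses |
| `mask` | `"own"` | subjects are thresholded on their own entries; `"group_average"` additionally intersects each subject's support with the group-average support at the same `tau` |
| `cmax` | `"pairs"` | block-capacity diagonal convention (see below) |

The strict inequality makes `tau = 0` keep exactly the nonzero support.
`mask = "own"` is the default because an individualized threshold should
reflect the individual's own coupling distribution; the masked variant
exists because a group-level mask is a defensible alternative reading of
the pipeline and is worth a sensitivity check.

## Null models and condition ordering

`null_snr_distribution()` destroys the community–topology alignment while
keeping everything else fixed: it re-scores uniformly random permutations of
the label vector (preserving the size multiset `Omega`, hence `P`) on the
same thresholded graphs. The default of 100 shuffles with an explicit seed
makes ensembles bit-reproducible. Permutation — rather than i.i.d.
relabeling or degree-preserving graph rewiring — is the right null here: the
question is whether *this* partition fits *this* graph, so only the
assignment is randomized. `snr_ordering_report()` then compares named
condition profiles (e.g. rest vs. task) and the null at their respective
optima.

## The community-detection back-test

`agreement_curves()` solves the forward problem at each threshold with two
deliberately different detector families — multi-level modularity
maximization (via `igraph`) and a non-degree-corrected Poisson-SBM greedy
fit with `k` fixed to the reference partition's — and scores each detected
partition against the reference by adjusted mutual information (AMI). A
threshold criterion is useful for an a-priori partition exactly when it
peaks where the detected and reference partitions agree; raw modularity
instead keeps rising into the sparse high-`tau` regime, where the graph
fragments and modularity rewards the fragments themselves.

Choices made here, each behind an argument:

* **AMI** uses the permutation-model expected mutual information and
  arithmetic-mean entropy normalization (the common default; `max` and
  `sqrt` variants available, and plain NMI behind `method = "nmi"`). No
  installed clustering package provides AMI, so it is implemented in the
  package and verified in the tests against reference values computed with
  an independent implementation.
* **Poisson SBM** treats `round(100 |w|)` as counts for weighted graphs
  (scale configurable). The greedy optimizer accepts only
  likelihood-increasing single-node moves, rejects moves that would empty a
  block (keeping `k` fixed), and restarts from several seeded random
  initializations.
* **Modularity** implements the `alpha`-tunable Newman score normalized by
  `2m`; it is cross-checked in the tests against both a brute-force double
  loop and `igraph::modularity`.

## The synthetic cohort generator

`simulate_fc_cohort()` emulates the statistical shape of Pearson-correlation
FC cohorts — bounded, noisy, assortative, with subject idiosyncrasy — not
BOLD time-series physiology. Per subject, each community has a latent factor
over `t_points` time points; factors are jointly Gaussian with pairwise
correlation `rho_between / rho_within`; node `u` loads on its community
factor as `x_u = sqrt(rho_u) f + sqrt(1 - rho_u) eps`, and the connectome is
the sample correlation matrix of the node signals. The node coupling
`rho_u` has three components:

* the target within-community correlation `rho_within`;
* a **cohort-level** node-specific draw `N(0, coupling_sd^2)`, shared by all
  subjects — regions differ stably in how strongly they couple to their
  network, and this heterogeneity is what gives the *group-average* FC a
  realistically wide entry distribution (without it the group average's
  entries concentrate so sharply around the two target correlations that
  its optimal threshold pins to `rho_between` and decouples from the
  individual optima, which no empirical cohort shows);
* a **subject-level** fingerprint draw `N(0, fingerprint_sd^2)` — the
  reproducible individual idiosyncrasy that makes individual FCs noisier
  and later-peaking than their group average.

Defaults (chosen once as a realistic desk-scale cohort and used by the test
suite): `n = 100` nodes, `k = 7` equal communities, `gamma = 20` subjects,
`rho_within = 0.45`, `rho_between = 0.25`, `t_points = 600`,
`fingerprint_sd = 0.1`, `coupling_sd = 0.1`. Within/between correlations of
0.45/0.25 and a few hundred time points are in the range practitioners see
in parcellated resting-state data; 20 subjects keep every pipeline stage
fast while leaving group-averaging with real work to do.

`split_factor = m` (and the standalone `refine_parcellation()`) models
parcellation refinement: each parent node contributes `m` children sharing
its community and latent loading, so the community profile matrix — and
with it the SNR — scales up with `n` at a fixed threshold, mirroring what
finer parcellations do on empirical data.

What the generator does **not** emulate: spatial embedding and
distance-dependent correlations, hemodynamics and autocorrelated
time series, heavy-tailed motion artefacts, subcortical structures, and
global-signal effects. Tests passing on these cohorts therefore demonstrate
the estimator's correctness and the pipeline's qualitative phenomenology
(non-monotone profiles, vetted optima, group-vs-individual ordering,
detector agreement), not quantitative claims about any empirical dataset.

## Numerical conventions and degenerate inputs

* **Pair convention.** All block statistics accumulate over unordered pairs
  `u < v`; self-pairs are excluded (diagonals are forced to zero on read).
  `C_max`'s diagonal is therefore `Omega_i (Omega_i - 1) / 2`, so that `W`
  is a per-pair probability with numerator and denominator under the same
  convention. The literal capacity `Omega_i^2` — which double-counts pairs
  and includes self-pairs — is available as `cmax = "literal"` for
  sensitivity analyses; off-diagonal entries agree between the conventions.
* **Eigenvalues.** `PQ = n P W` is similar to the symmetric matrix
  `n P^{1/2} W P^{1/2}`, so its spectrum is real; the package computes it
  through the symmetric form for stability and orders by `|lambda|`. SNR
  uses `lambda_2^2`, making the subdominant eigenvalue's sign irrelevant.
* **Degenerate SNR.** `k = 1`, an (almost) empty graph
  (`lambda_1 <= 1e-12`), or a rank-one profile all return SNR = 0 — "no
  mesoscopic signal" — rather than NaN.
* **Ties and flags.** Threshold ties break toward the smaller `tau`;
  all-zero profiles return the smallest grid point flagged degenerate;
  a non-contiguous super-threshold set is reported as its (min, max) with a
  warning; edgeless thresholded graphs in the back-test are flagged rows
  with AMI recorded as 0.
* **I/O.** Matrices are comma- or tab-delimited (auto-detected), written
  with 15 significant digits; node order is a hard contract between cohort
  members and the partition — mismatches are errors, never silently
  reordered.

## Problem sizes used by the tests

The bundled suite exercises: exact and closed-form SNR values; randomized
brute-force oracle comparisons on graphs with `n <= 30` (several hundred
cases); parameter recovery on one sampled SBM with `n = 400` and four
blocks; null ensembles of 100 shuffles on a planted `n = 200` graph; and the
full pipeline, back-test and refinement phenomenology on the default
`n = 100`, 20-subject cohort at fixed seeds. These sizes were chosen so the
whole suite runs in well under a minute on a laptop while every qualitative
property has room to fail visibly.

## Known limitations

* Weak recovery theory is asymptotic; at `n` of a few hundred the SNR = 1
  boundary is indicative, not sharp, and shuffle nulls on dense correlation
  graphs can graze 1.
* The weighted-mode SNR is a prominence *measure*, not an inferred
  generative parameter: absolute-value couplings are not Bernoulli
  probabilities, so its value has no recovery guarantee attached — only the
  binary vetting step does.
* The Poisson SBM fit is a greedy heuristic with restarts: deterministic
  given its seed but not guaranteed to find the global likelihood optimum
  on hard instances.
* Exact recovery criteria, degree-corrected SBM variants and
  proportional/percolation/spanning-tree thresholding schemes are out of
  scope.
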