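# snrthresh

Partition fitness and threshold selection for weighted functional
connectomes via the stochastic block model (SBM) signal-to-noise ratio.

## The problem

Functional connectomes (FCs) — symmetric matrices of pairwise correlations
between brain regions' activity — are routinely thresholded to suppress
spurious couplings, and routinely analysed through an *a-priori* set of
functional sub-circuits (communities) such as the seven canonical
resting-state networks. Two questions then arise for anyone working with
such data:

1. **Fitness.** How prominently is a given community partition actually
   expressed in a given (thresholded) connectome?
2. **Thresholding.** Which threshold best preserves that partition's
   structure, and over which threshold range is the partition detectable at
   all?

`snrthresh` answers both with one statistic. For a graph with `n` nodes, a
partition into `k` communities with prior `P = diag(p)`, and a block
connectivity matrix `W` (edge probability in binary mode, mean absolute
coupling in weighted mode), the *community profile matrix* is

    PQ = n P W,

whose entry (i, j) is the expected number of community-`j` neighbours of a
community-`i` node. With eigenvalues of `PQ` ordered by magnitude, the
signal-to-noise ratio is

    SNR = lambda_2^2 / lambda_1.

`SNR > 1` is the Kesten–Stigum condition: *weak recovery* of the partition
(detecting it better than chance) is efficiently solvable. On binarized
graphs the SNR vets thresholds — the *weak-recoverability interval*
`[a_w, b_w]` is the threshold range with SNR > 1. On weighted graphs the
same quantity, computed from mean absolute couplings, acts as a prominence
score whose maximizer is the selected threshold `tau_opt`, at the
group-average or individual-subject level.

The package also provides partition-shuffle null models, a
community-detection back-test (modularity maximization and a Poisson SBM
fit, each compared to the reference partition by adjusted mutual
information), and a synthetic planted-partition cohort generator, so the
whole pipeline runs without access-restricted neuroimaging data.

## Worked example

```r
library(snrthresh)

sim <- simulate_fc_cohort(sim_config(seed = 42))  # 20 subjects, 100 nodes, 7 planted communities
fit <- snr_threshold(sim$cohort, sim$partition)
fit
#> SNR-guided threshold selection
#>   weak-recoverability interval: [0.25, 0.50]
#>   tau_opt (group average): 0.35  [max weighted SNR 5.607]
#>   tau_opt (individual):    mean 0.383, range [0.35, 0.40] over 20 subject(s)
#>   vetting: 21/21 optima inside the weak-recoverability interval
```

Reading the output: thresholding the binarized group-average FC keeps the
planted partition weakly recoverable (binary SNR > 1) for `tau` in
[0.25, 0.50]; the weighted prominence of the group average peaks at
`tau_opt = 0.35` (SNR 5.6, well above the boundary); each subject's
individualized optimum and the group optimum all fall inside the vetted
interval, so the selected thresholds are information-theoretically sound.
`summary(fit)` tabulates per-subject optima, `plot(fit)` draws the
profiles, and `write_snr_threshold(fit, dir)` exports a JSON report plus
tidy CSV profiles.

A partition-shuffle null puts those numbers in context:

```r
nul <- null_snr_distribution(group_average(sim$cohort), sim$partition,
                             mode = "binary", n_shuffles = 100, seed = 43)
nul
#> Partition-shuffle null ensemble: 100 shuffles x 21 thresholds (binary mode, seed 43)
#>   max null SNR over all shuffles and taus: 1.012
```

Size-preserving shuffles of the same partition hover at the weak-recovery
boundary while the planted partition's binary SNR exceeds 13 — the SNR
responds to genuine community–topology alignment, not to graph density.

A command-line wrapper over the same functions ships in `exec/snrthresh`
(subcommands `simulate`, `fit`, `null`, `validate`).

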