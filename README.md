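# dsenorm

Detection and normalization of **skewed high-dimensional experiments**:
two-group studies (ChIP-chip / tiling arrays, expression, copy-number) in
which the truly altered variables are not symmetrically distributed around
zero — e.g. enrichment assays where essentially all real signal is positive.

## The problem

Standard normalization (quantile, MA) assumes that few variables are
altered and that their true log-ratios are symmetric around zero.  When a
large fraction of variables is shifted in one direction, these methods
absorb real signal into the normalization function: fold changes shrink
toward zero (bias) and fewer altered variables clear any detection cut-off
(lost sensitivity).  `dsenorm` implements a complete work-flow for this
situation:

1. **Standard quantile normalization** (`quantile_normalize()`), generalized
   to an arbitrary reference set: the target distribution is the
   across-sample mean of each sample's sorted values restricted to the
   reference variables, and each sample is mapped through a monotone
   piecewise-linear quantile function (linear tail extrapolation, mean
   collapsing of ties).
2. **The DSE-test** (`dse_test()`, *Detection of Skewed Experiments*).  For
   sample pairs the per-variable log-ratios are summarized by the Bowley
   quartile-skewness coefficient

   `qs = (Q3 + Q1 - 2·median) / (Q3 - Q1)`,

   computed for *heterogeneous* pairs (one treatment, one reference sample)
   and *homogeneous* pairs (same arm).  Technical variation affects both
   pair kinds alike, so Welch's t-test comparing the two groups of
   qs-coefficients detects genuine asymmetry of the treatment effect.  A
   *dependent* variant reuses every sample in both pair groups (maximal
   power for small designs); an *independent* variant keeps the groups
   disjoint and controls the false-positive rate.
3. **HMM-assisted normalization** (`hmm_normalize()`) for experiments found
   or believed to be skewed: after a first standard normalization, a
   two-state Gaussian hidden Markov model (Baum–Welch EM, Viterbi decoding,
   chains restarted at block boundaries such as chromosomes) segments the
   ordered M-value track (M = log2 ratio of group-average intensities).
   Variables in the state whose mean is closest to zero are classified as
   unaltered and become the reference set for an invariant quantile
   re-normalization of the original data.
4. **Evaluation tools** (`evaluate_normalizations()`, `dse_power()`,
   `sensitivity_at_fpr()`, `m_density()`): moving-median smoothing, calling
   at the `0.7·log2(δ)` cut-off, sensitivity/specificity/bias against a
   known truth, comparisons against rank-invariant and oracle ("ideal")
   reference sets, and power estimation over simulation grids.

A region-structured simulator (`simulate_experiment()`) generates skewed
experiments with equally spaced runs of positively altered variables
(`x_R ~ N(μ_i, σ_i)`, `x_T ~ N(δ·μ_i, σ_i)` inside altered regions), with
per-variable parameters either synthetic (`synth_variable_params()`) or
estimated from real replicate data with regularized variances
(`estimate_variable_params()`).

## Worked example

```r
library(dsenorm)

# a skewed experiment: 20,000 variables, 4 samples per arm, 25% of the
# variables positively altered (delta = 1.5) in regions of 50
vp  <- synth_variable_params(20000, seed = 1)
sim <- simulate_experiment(
  simulation_config(n = 20000, k = 4, alpha = 0.25, m = 50, delta = 1.5,
                    seed = 2), vp)
logm <- to_log2(sim$matrix)

# 1. is the experiment skewed?
dse_test(logm, sim$design, variant = "dependent", pre_normalize = TRUE)
#> DSE-test (dependent): t = 23.591, df = 4.02, p = 1.821e-05
#>   qs heterogeneous: 0.202, 0.205, 0.204, 0.190
#>   qs homogeneous:   -0.011, -0.004, 0.016, -0.022

# 2. re-normalize with the HMM-assisted pipeline and benchmark
evaluate_normalizations(sim)
#>      method sensitivity specificity        bias    cutoff
#> 1  standard      0.5660   1.0000000  0.14784838 0.4094738
#> 2 invariant      0.8350   0.9998000  0.09440301 0.4094738
#> 3       hmm      0.9658   0.9982667 -0.01156625 0.4094738
#> 4     ideal      0.9652   0.9983333 -0.01073471 0.4094738
```

Reading the output: the heterogeneous pairs' log-ratio distributions are
clearly right-skewed (qs ≈ 0.2) while the homogeneous pairs are symmetric
(qs ≈ 0), so the experiment is flagged as skewed (p ≈ 2e-5).  Standard
quantile normalization then finds only 57% of the altered variables and
shrinks their fold changes by 0.15 log2 units; the HMM-assisted
normalization recovers 97% at essentially unchanged specificity and
near-zero bias — indistinguishable from the oracle normalization that knows
the truth.

## Command line

A thin CLI over the same functions ships in `inst/cli/dsenorm`
(subcommands `simulate`, `dse`, `normalize`, `evaluate`, `power`,
`density`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/dsenorm", package = "dsenorm"))')
Rscript $CLI simulate --n 100000 --k 2 --alpha 0.25 --m 50 --delta 1.5 \
        --seed 7 --out matrix.tsv --truth truth.tsv --design design.tsv
Rscript $CLI dse --in matrix.tsv --design design.tsv --scale raw \
        --pre-normalize false --out dse.json
Rscript $CLI normalize --method hmm --in matrix.tsv --design design.tsv \
        --scale raw --out normalized.tsv --sidecar fit.json
```

## Vignette

`vignettes/skewed-normalization.Rmd` documents the model, the estimators,
the numerical choices and the limitations of the simulation-based
evaluation.
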