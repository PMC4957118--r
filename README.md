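# bmsdiff

Bayesian differential protein abundance for mass-spectrometry data, with
missing values treated as evidence rather than nuisance.

## The problem

Label-free and isobaric-tag MS experiments routinely report 10–40% missing
intensities, and those values are not missing at random: a protein drops
out mostly because its abundance fell below the instrument's detection
limit. Standard practice — impute (or zero-fill) and run a two-sample test —
discards exactly that information. `bmsdiff` uses it: a protein that is
observed in every control sample but missing in most treatment samples is
a priori likely to be differentially expressed, before a single intensity
is compared.

## The model

For each protein with missing-value frequencies `f_CTRL` and `f_TRT`, the
prior probability of differential expression (hypothesis H1) is a function
of `|Δf| = |f_CTRL − f_TRT|` with sensitivity coefficient `φ > 0`:

    polynomial:   p_H1 = (1 + |Δf|^φ) / 2
    exponential:  p_H1 = 1 − exp(−|Δf|/φ) / 2

Both give `p_H1 = 1/2` at equal frequencies and approach 1 (`φ → 0`) or 1/2
(`φ → ∞`) at intermediate `|Δf|`. Observed log intensities are modelled as
Normal: under H0 both groups share mean `μ`; under H1 the treatment mean is
`μ + τ`. With conjugate priors

    μ  ~ N(μ0, σ²),   τ ~ N(τ0, κσ²),   σ² ~ Inv-Gamma(α, β)

the marginal likelihoods of the observed values under H0 and H1 are
available in closed form (all parameters integrated out), and Bayes' rule
updates the missingness prior into a posterior probability of differential
expression. The hyperparameters `(μ0, α, β, κ, φ)` are shared across
proteins (small-sample designs cannot support more), fitted by maximizing
the dataset-level marginal likelihood on per-protein standardized data,
with `τ0 = 0`. Proteins are called by thresholding posteriors at a
controlled Bayesian FDR — the average posterior probability of H0 within
the call set.

The package also ships the full simulation benchmark: Normal, Gamma and
Rician intensity generators with detection-limit censoring (the globally
smallest values go missing), five classical comparator tests (t, Wilcoxon
rank-sum, Kruskal–Wallis, Kolmogorov–Smirnov, permutation) with KNN or
iterative-PCA imputation, and AUROC evaluation against ground truth.

## Worked example

```r
library(bmsdiff)

ds <- simulate_dataset(simulation_config(family = "normal", n_proteins = 1000,
                                         n_per_group = 5, sigma = 2,
                                         missing_fraction = 0.3, seed = 1))
ds$matrix
#> intensity_matrix: 1000 proteins x 10 samples (5 CTRL, 5 TRT), 30.0% missing

res <- differential_abundance(ds$matrix, form = "polynomial", fdr_level = 0.05)
res
#> differential abundance (polynomial prior): 571 of 1000 proteins called
#> fit_result: objective -10831.9447 (from -11009.8193), converged: TRUE
#> hyperparams: mu0=-0.1143 alpha=4.2 beta=3.137 tau0=0 kappa=1.168 phi=0.1808
#> fdr_curve: threshold 0.869004 at FDR <= 0.05; 571 call(s)

head(res$table[, c("id", "f_ctrl", "f_trt", "prior_h1", "posterior_h1", "called")])
#>   id f_ctrl f_trt prior_h1 posterior_h1 called
#> 1 P1    0.0   0.0    0.500        0.355  FALSE
#> 2 P2    0.2   0.0    0.874        0.778  FALSE
#> 3 P3    0.6   1.0    0.924        0.924   TRUE
#> 4 P4    0.4   0.0    0.924        0.879   TRUE
#> 5 P5    0.0   0.2    0.874        0.780  FALSE
#> 6 P6    0.0   0.4    0.924        0.926   TRUE

auroc(res$table$posterior_h1, ds$truth$lambda)
#> [1] 0.906
```

Reading the output: the empirical-Bayes fit raised the dataset marginal
log-likelihood from −11009.8 to −10831.9; the small fitted `φ = 0.18` means
the data supported a missingness prior that reacts strongly to frequency
differences (30% of entries were detection-limit censored). `P1`, observed
everywhere, starts at the indifferent prior 0.5 and its intensities argue
against a difference (posterior 0.36); `P3`, missing in 60% of control and
all treatment samples, keeps a high posterior with almost no intensity data.
At the selected threshold 0.869 the expected Bayesian FDR of the 571 calls
is at most 5%. Under this deliberately hard setting (σ = 2, n = 5) the
posterior ranks proteins with AUROC ≈ 0.91 against the simulation's ground
truth; note the realized FDR in such harsh regimes can exceed the nominal
level (see the vignette on calibration).

## Command line

```sh
Rscript inst/cli/bmsdiff simulate --family normal --sigma 2 --missing 0.3 --seed 1 --out sim
Rscript inst/cli/bmsdiff run sim_intensities.tsv --groups sim_groups.tsv --fdr 0.05 --out results.tsv
Rscript inst/cli/bmsdiff normality sim_intensities.tsv --groups sim_groups.tsv
Rscript inst/cli/bmsdiff benchmark --replicates 10 --methods bayes_polynomial,t+knn --out bench.tsv
```

Real tables: first column protein ids, header row sample names, one row per
protein; declare the missing-value encoding explicitly
(`--missing-encoding NA|blank|zero|<sentinel>`) and the group of every
sample in a two-column file.

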