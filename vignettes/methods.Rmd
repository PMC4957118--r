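---
title: "Methods: informative missingness, conjugate marginals, and the simulation benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: informative missingness, conjugate marginals, and the simulation benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsdiff)
```

# The model and its assumptions

`bmsdiff` tests, per protein, whether two groups of mass-spectrometry
samples differ in mean log intensity. Its distinguishing assumption is that
missingness is informative: MS missing values arise predominantly from
detection-limit censoring, so the *pattern* of missingness carries evidence
about differential abundance. The method therefore has two evidence
channels:

1. **Missingness prior.** With per-group missing-value frequencies
   $f_{CTRL}$ and $f_{TRT}$ and $\Delta f = |f_{CTRL}-f_{TRT}|$, the prior
   probability of differential expression is either
   $p_{H1} = (1+\Delta f^{\phi})/2$ (polynomial) or
   $p_{H1} = 1 - e^{-\Delta f/\phi}/2$ (exponential). Both satisfy the
   properties the construction requires: $p_{H1}=1/2$ exactly at
   $\Delta f = 0$; $p_{H1}\to 1$ as $\phi \to 0$ and $p_{H1}\to 1/2$ as
   $\phi\to\infty$ for $0<\Delta f<1$; symmetry in the two groups; and
   monotonicity in $\Delta f$ at fixed $\phi$. The two forms differ only in
   how abruptly sensitivity sets in; the benchmark finds them
   interchangeable in ranking performance, and both are exposed behind the
   `form` argument. These closed forms are this package's own choice of
   parameterization among the functions satisfying those constraints.

2. **Intensity likelihood.** Observed log intensities are Normal with
   common variance: under $H_0$ both groups share mean $\mu$; under $H_1$
   the treatment mean is $\mu+\tau$. Conjugate priors
   $\mu \sim N(\mu_0,\sigma^2)$, $\tau \sim N(\tau_0,\kappa\sigma^2)$,
   $\sigma^2 \sim IG(\alpha,\beta)$ let all parameters be integrated out
   analytically. Writing the observed vector as $y = A\theta + \varepsilon$
   with $\theta = (\mu,\tau)$ and design rows $(1,0)$ / $(1,1)$, the
   marginal is a multivariate-$t$ density whose quadratic form and
   determinant reduce, via the Woodbury identity and the matrix-determinant
   lemma, to $2\times 2$ algebra in the per-protein sufficient statistics
   $(n, n_{TRT}, \sum r, \sum_{TRT} r, \sum r^2)$. This is what makes the
   whole-dataset objective cheap enough to optimize. The derivation was
   validated exclusively against nested adaptive quadrature (never against
   transcribed algebra); the test suite re-checks 20 randomized fixtures
   against that oracle under both hypotheses at every run.

Bayes' rule then combines the two channels:
$p(H_1\mid y) = p_{H1} L_1 / (p_{H1} L_1 + (1-p_{H1}) L_0)$, computed in
log space.

**Empty groups.** A protein observed in neither group has log marginal 0
(empty product), so its posterior equals its prior — which its total
missingness has typically pushed toward 1. A protein observed in only one
group is evaluated on that group alone (the empty group's parameters
integrate to one). This is deliberate: proteins entirely censored in one
condition are precisely the strongest detection-limit signals and must not
be dropped.

# Hyperparameter fitting

The six hyperparameters cannot be estimated per protein in 3–6-sample
designs, so they are shared across the dataset. $\tau_0$ is pinned to 0
(up-/down-regulation a priori symmetric), leaving
$(\mu_0, \alpha, \beta, \kappa, \phi)$ to maximize
$\sum_i \log[p_{H1,i} L_{1,i} + (1-p_{H1,i}) L_{0,i}]$.

* **Standardization.** Each protein's observed values (both groups pooled)
  are centred and scaled to unit sample sd first. Pooling preserves the
  between-group shift relative to the pooled spread — the signal — while
  making the shared-hyperparameter assumption ($\mu_0 \approx 0$, unit
  variance scale) approximately true. Proteins with fewer than two observed
  values, or zero variance, are flagged and left unscaled.
* **Optimizer.** L-BFGS-B within box bounds; the contract is monotone
  improvement inside a box, not a particular algorithm, and the
  implementation falls back to the initial point in the (never observed)
  case of a deterioration. Default start is the unit-scale neutral point
  $(0, 2, 1, 1, 1)$; optional seeded multi-start exists behind a flag but
  single-start is the default so fits are bit-reproducible.
* **Bounds.** $\mu_0 \in [-5,5]$, $\alpha \in [0.5,50]$,
  $\beta \in [0.01,50]$, $\kappa \in [0.01,100]$, $\phi \in [0.01,100]$.
  On standardized data everything lives on unit scale, so these are diffuse
  but proper; nothing in the fitted optima approaches the edges in the
  simulation studies.
* A dataset with no missing values makes every prior exactly 0.5, so the
  objective is flat in $\phi$; the optimizer simply leaves it at its start,
  which is harmless and covered by a test.

# FDR control

The expected Bayesian FDR at threshold $p_{th}$ is the average posterior
probability of $H_0$ among proteins with $p_i \ge p_{th}$, with an offset
$c \ge 0$ in the denominator. The selected threshold is the smallest
candidate whose expected FDR is at or below the target — the largest call
set compatible with the bound. Numerical choices:

* The candidate grid is the sorted unique posteriors: the expected-FDR step
  function changes only there, so this is lossless (no $\varepsilon$-grid).
* Calls are inclusive ($p_i \ge p_{th}$), matching the indicator in the
  definition.
* Default $c = 0$; an empty call set at $c=0$ makes the estimate undefined
  and is flagged rather than silently reported as 0. $c$ is exposed as a
  CLI flag because no canonical value exists.
* **Calibration caveat.** The control is on the *model's* expected FDR.
  On model-matched data at moderate noise (Normal family, $\sigma = 1$,
  $n = 25$/group, no censoring) the realized FDR at a nominal 5% sits
  around 8% in the acceptance suite — empirical-Bayes posteriors are
  slightly overconfident because hyperparameters are plugged in rather than
  integrated over. Under harsh settings (small $n$, heavy censoring,
  model-violating families) the gap grows; the README example shows a
  realized FDR of about 0.24 at nominal 5% with $\sigma=2$, $n=5$, 30%
  missingness. Treat the nominal level as an ordering device plus
  approximate guarantee, not an exact frequency.

# What the simulator emulates — and what it does not

`simulate_dataset()` builds a two-group experiment of 1000 proteins by
default. Per protein: baseline mean $\mu_i$; differential indicator
$\lambda_i \sim \mathrm{Bern}(1/2)$; direction $\delta_i = \pm 1$
equiprobably; magnitude $\tau_i \sim \Gamma(\text{shape }10,
\text{scale }0.5)$, so the average effect is $10\times 0.5 = 5$. Group
means are $\mu_i$ and $\mu_i + \lambda_i\delta_i\tau_i$. Families:

* **normal**: entries $N(\text{mean}, \sigma^2)$ with
  $\mu_i \sim N(15, 3)$. The second argument is read as a *variance*
  (sd $=\sqrt 3 \approx 1.73$), consistent with the $N(\mu,\sigma^2)$
  convention used everywhere else in the model.
* **gamma**: entries Gamma with shape $\text{mean}^2/\sigma^2$ and scale
  $\sigma^2/\text{mean}$ — moment matching at the target group mean and
  variance $\sigma^2$, the minimal reconstruction given that only the
  mean/variance targets are stated. $\mu_i \sim \Gamma(56.25, 0.2667)$
  (mean 15, sd 2). A treatment mean near zero yields an extremely skewed
  Gamma whose draws can underflow to numeric 0; non-positive implied means
  trigger a flagged resample of $\tau_i$.
* **rician**: entries $\mathrm{Rice}(\text{mean}, \sigma)$, sampled as
  $\sqrt{(\nu+X)^2+Y^2}$, $X,Y \sim N(0,\sigma^2)$;
  $\mu_i \sim \mathrm{Rice}(15,\sigma)$.

**Censoring is global.** Detection-limit missingness is introduced by
marking the `floor(fraction × entries)` globally smallest values of the
whole matrix as missing (ties broken by first occurrence, for
determinism). Global — not per protein or per group — censoring is what
couples missingness to abundance and creates the frequency differences the
prior exploits. Missing entries are stored as 0 under an explicit mask;
downstream code consults only the mask.

The noise grid $\sigma \in \{1,2,3\}$ stops at 3 because the average
effect is 5: beyond that, effects drown in noise for any method. The full
factorial design (3 families × 3 noise levels × 6 missingness levels × 2
sample sizes × 100 replicates) enumerates 3600 datasets per family, 10800
in total; `generate_benchmark_grid()` derives a deterministic per-dataset
seed from the base seed, a stable hash of the factor tuple and the
replicate index, so any cell is recomputable in isolation. The default CLI
profile is a reduced grid (10 replicates, 500 proteins); the full design
sits behind `--full` and is cluster-sized.

What the generator does *not* emulate: peptide-to-protein roll-up,
batch/run-order effects, correlated proteins, intensity-dependent variance,
or stochastic (non-threshold) missingness. A green benchmark therefore
establishes correct behaviour under idealized MNAR censoring, not
performance on any particular real instrument's quirks.

`simulate_from_model()` is a second, deliberately different generator that
draws from the inferential model itself (per-protein
$\sigma_i^2 \sim IG$, $\tau_i \sim N(0,\kappa\sigma_i^2)$); it exists for
parameter-recovery and calibration studies where the generating
hyperparameters must be known exactly.

# Comparator methods

* **Zero-fill** (`imputation = "none"`): missing entries enter the test as
  0 — the simplest historical convention, kept as the reference point.
* **KNN** operates across proteins (rows as neighbours), the standard
  expression-matrix orientation; distance is Euclidean over co-observed
  samples normalized by their number; a missing entry takes the average of
  the $k = 10$ nearest proteins observed in that sample.
* **PCA-KDR / PCA-TSR**: iterative PCA model-based imputation — fill with
  column means, fit a rank-$a$ PCA ($a = 2$ by default), re-estimate each
  row's missing block from its observed block (known-data regression: the
  conditional mean under the rank-$a$ covariance; trimmed-scores
  regression: through the score space), iterate to convergence.
  Pseudo-inverses guard singular blocks; both variants exactly recover
  planted low-rank matrices, which the tests assert.
* **Tests**: pooled-variance t, Wilcoxon rank-sum, Kruskal–Wallis,
  Kolmogorov–Smirnov, and a permutation test on the difference of means
  (seeded, $B = 1000$, add-one convention; exhaustive enumeration when at
  most $10^4$ distinct assignments exist). Kruskal–Wallis with two groups
  is essentially a recast rank-sum test, but it is retained as a distinct
  comparator because the benchmark treats it as one. All scores are
  $1 - p$ so the AUROC machinery is shared with the Bayesian posterior;
  constant proteins score 0 instead of erroring.

# Evaluation

AUROC uses the Mann–Whitney midrank formulation, with tied pairs counted
half. An explicit trapezoidal ROC integration is kept as a second,
independent implementation, and the suite checks the two agree to 1e-12
with and without ties. Replicate aggregation reports mean and sd per
design cell; a method failing on a dataset becomes a flagged `NA` cell,
not a run abort.

# Numerical choices, in one place

* All densities in log space; the posterior via log-sum-exp; the mixture
  objective likewise.
* `prior_h1` returns exactly 0.5 at $\Delta f = 0$, guarding $0^\phi$ for
  $\phi<1$.
* Standardization uses the $n-1$ sd; zero-variance proteins are centred
  only, sub-2-observation proteins left untouched, both flagged.
* The quadrature oracle in the tests bounds its inner integrals using the
  stationary point of the (log-quadratic) integrand exponent — elementary
  calculus, independent of the closed form under test — because
  infinite-range adaptive rules can silently miss single narrow peaks.
* Benchmark seeds are derived as
  `(base + 1000 × hash(cell) + replicate) mod (2^31 − 1)` with a 31-adic
  string hash, keeping every seed a valid 32-bit integer.

# Known limitations

* Normality of observed intensities is assumed; the screen
  (`normality_screen()`, with KS, Lilliefors, Shapiro–Wilk and
  Anderson–Darling options) is advisory only. Heavy-tailed data degrade
  the method — as they do most of the comparators.
* One shared $(\mu_0,\alpha,\beta,\kappa,\phi)$ per dataset: proteins with
  genuinely heterogeneous variance structure are shrunk toward the common
  scale.
* Hyperparameters are plugged in, not integrated over, so posterior
  probabilities are mildly overconfident (see the FDR calibration caveat).
* The KS and Lilliefors screens use estimated parameters; the plain KS
  p-value is conservative in that regime, which is acceptable for an
  advisory report.
* Real-data conveniences (MaxQuant/Proteome Discoverer adapters, peptide
  roll-up) are out of scope; the reader expects a plain wide table with an
  explicit missing-value encoding.
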