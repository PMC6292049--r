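---
title: "Clustering RNA-seq samples with Negative Binomial mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering RNA-seq samples with Negative Binomial mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbmixclust)
```

## The model

`nbmixclust` clusters the **samples** (rows) of an N × G matrix of
non-negative, library-size-normalized RNA-seq expression values. Sample row
$x_i$ is modeled as a draw from a K-component mixture in which component $k$
has independent Negative Binomial margins:

$$
x_i \sim \sum_{k=1}^{K} p_k \prod_{g=1}^{G}
  f(x_{ig} \mid \mu_{kg}, \theta_{kg}),
\qquad
f(x \mid \mu, \theta) =
  \frac{\Gamma(x + \theta)}{\Gamma(\theta)\,\Gamma(x + 1)}
  \left(\frac{\mu}{\theta + \mu}\right)^{x}
  \left(\frac{\theta}{\theta + \mu}\right)^{\theta}.
$$

The NB variance is $\mu + \mu^2/\theta$, so small $\theta$ means strong
over-dispersion and $\theta \to \infty$ recovers the Poisson. Two modeling
assumptions matter in practice:

* **Independence across genes (and samples).** The per-sample density is a
  product over genes. Co-expression correlation is ignored; it inflates the
  apparent information content of correlated gene sets, which mostly affects
  the confidence (posteriors) rather than the partition itself.
* **Continuous support.** Normalized expression (e.g. CPM) is not integer,
  so $x!$ is generalized to $\Gamma(x + 1)$ throughout. The density then
  integrates (rather than sums) to slightly less than one, which is harmless
  for likelihood comparisons because all components share the same support
  treatment. The model must be applied to *normalized counts without any
  further transformation* — log or rank transforms would destroy the
  mean–variance relation the NB captures.

Zero-mean genes are treated as a point mass at zero (log density 0 at
$x = 0$, $-\infty$ otherwise), which keeps degenerate genes that survive
filtering from generating non-finite likelihoods.

## The fitting algorithm

`fit_nbmix()` maximizes the observed log-likelihood
$L = \sum_i \log \sum_k p_k f(x_i \mid \mu_k, \theta_k)$ by EM with three
modifications.

**Initialization from the gene-wise MLEs.** For each gene,
`fit_gene_nb_mle()` estimates the mean by the sample mean and the dispersion
by bounded one-dimensional maximization of the profile log-likelihood on
$\log \theta$ (`stats::optimize`, tolerance $10^{-8}$, bounds
$[10^{-3}, 10^{5}]$). The bounds span biologically plausible dispersions; a
gene whose sample variance does not exceed its mean (no over-dispersion,
including constant genes) is pinned at the upper cap, the Poisson limit. All
K components start at these shared estimates with a small multiplicative
offset $1 + s(k-1)$, $s = 0.01$ by default: with no offset, every E-step
responsibility would be exactly $1/K$ forever (a symmetric fixed point); the
offset breaks the symmetry while leaving components nearly exchangeable, so
the annealed EM — not the initialization — decides the partition. Large
offsets are allowed but clipped back into the dispersion bounds with a
warning.

**Fixed dispersions.** $\theta_k$ is never updated after initialization.
This makes both M-step updates closed-form —
$p_k = \tfrac1N \sum_i p_{ik}$ and
$\mu_k = \sum_i p_{ik} x_i / \sum_i p_{ik}$ — and avoids the numerically
fragile joint re-estimation of dispersion inside EM. The cost is that
between-cluster dispersion differences are not used for discrimination: with
a single pooled $\theta$ per gene (up to the 1% initialization offset), the
partition is driven by mean differences. Scenarios whose only signal is a
dispersion shift are therefore hard for this model by construction.

**Deterministic annealing with density rescaling.** The E-step computes
$p_{ik} \propto p_k \left[f(x_i \mid \mu_k, \theta_k)\,
e^{-M_i}\right]^{1/\tau}$, where
$M_i = \frac{1}{KG} \sum_k \sum_g \log f_g$ is the per-sample mean log
density. Subtracting $M_i$ keeps products over thousands of genes
representable; responsibilities are algebraically invariant to it (the test
suite verifies agreement with a plain log-sum-exp evaluation to $10^{-12}$,
and the implementation additionally stabilizes with a row-maximum shift, so
no overflow can occur at any G). The temperature ladder is
$\tau_{s+1} = \max(1, r\,\tau_s)$ with $\tau_0 = 10$ and $r = 0.9$ by
default ($\tau_0 = 2$ is the common lighter preset); raising
responsibilities to $1/\tau$ flattens them early on, letting components
explore before committing. Convergence (relative change of $L$ below
$10^{-6}$, `max_iter` 1000) is only tested once $\tau = 1$: testing during
the ladder could freeze the fit at high temperature, and classical EM
monotonicity of $L$ only holds at $\tau = 1$ (asserted to $10^{-8}$
throughout the test suite). The priors used in the annealed E-step are the
current iteration's updated values, consistent with the non-annealed E-step.
The whole algorithm is deterministic — no random restarts — so a fit is
exactly reproducible from its inputs.

**Model selection.** `select_nbmix_k()` fits every candidate K and picks the
smallest BIC, $-2L + \nu \log N$ with $\nu = (K-1) + KG$: mixing proportions
and component means are free; the frozen dispersions are not counted
(`count_theta = TRUE` switches to $\nu = (K-1) + 2KG$ for sensitivity
checks). Ties break toward smaller K. Labels are the row-argmax of the
$\tau = 1$ posterior, ties toward the lowest component index. Empty
components are floored at a prior of $10^{-10}$, renormalized, and flagged
with a warning rather than an error, so a single degenerate K does not abort
a selection sweep. Because the gene-wise MLEs do not depend on K, they are
computed once per dataset and shared across the sweep.

Note the BIC penalty grows with $KG \log N$ while the likelihood gain from a
real partition grows only with the number of *informative* genes. With a
small DE fraction and no gene filtering, BIC will under-select K; this is
the statistical reason the real-data pipeline filters to the top-MAD genes
before clustering rather than a defect of the selection rule.

## Preprocessing

* `upper_quartile_cpm()` — per-sample factor = 75th percentile of the
  sample's nonzero counts *relative to its total count*, factors rescaled to
  geometric mean 1, effective library size = total × factor, output
  $10^6 x / \text{eff. lib}$. Basing the quantile on depth-relative counts
  makes the output invariant to a sample's sequencing depth (a raw-count
  quantile would double-count depth). With one sample this reduces to plain
  CPM.
* `mad_top_genes()` — keeps the `top_n` genes by median absolute deviation
  across samples (no 1.4826 consistency constant; the ranking is
  scale-invariant either way), ties by original gene order; 1000 genes is
  the conventional operating point.
* `log_transform()` (natural log, pseudocount 1 by default) and
  `blom_transform()` (per-gene normal scores
  $\Phi^{-1}\!\big((r_i - 3/8)/(N + 1/4)\big)$, average ranks for ties) are
  provided **for the Gaussian comparators only** — the NB mixture itself is
  always applied to untransformed normalized counts.

## The simulator and what it does (not) emulate

`simulate_nbmix_counts()` generates the study conditions used throughout the
tests. Per-gene baselines $(\mu_{1g}, \theta_{1g})$ stand in for estimates
from a highly-variable-gene set of a real tumor cohort, which are not
publicly printed; the default stand-in draws
$\log \mu_1 \sim N(\log 50, 1.5^2)$ truncated to $[1, 10^4]$ (spanning low-
to high-expression genes on the CPM scale) and
$\theta_1 \sim \text{Gamma}(2, 1)$ truncated to $[0.1, 50]$ (strong to mild
over-dispersion), via exact inverse-CDF truncated sampling; explicit vectors
can be supplied instead. Cluster $k$ shifts a seeded random subset of
$\lceil \text{DE} \cdot G \rceil$ genes multiplicatively:
$\mu_k = \mu_1 e^{(k-1)\Delta\mu}$, $\theta_k = \theta_1 e^{(k-1)\Delta\theta}$;
non-DE genes are identical across clusters. Restricting the shift to the DE
subset is a deliberate reading of the design — if shifts applied to all
genes, the DE-fraction axis would change nothing (`de_mode = "all"` gives the
other interpretation). Labels are i.i.d. uniform over clusters
(`exact_split = TRUE` for equal blocks), counts are independent NB draws,
and every dataset is bit-reproducible from its scenario seed.
`scenario_grid()` enumerates the full factorial benchmark —
K ∈ 2–6, Δμ ∈ {0.1, 0.5, 1}, Δθ ∈ {0, 1}, DE ∈ {5, 10%}, N ∈ {50–200},
G ∈ {1000, 5000}, i.e. 480 scenarios — with per-scenario seeds derived from
one master seed.

What the simulator does **not** emulate: gene–gene correlation, library-size
and batch effects (assumed removed upstream), zero inflation beyond what the
NB produces, and ordered-shift structure other than the geometric ladder.
Passing tests on simulated data therefore demonstrate correctness of the
algorithm under its own model, not robustness to the full messiness of real
cohorts.

## Benchmarking

`adjusted_rand_index()` implements the chance-corrected pair-counting
agreement from the contingency table; when both partitions are degenerate in
the same way (denominator zero) the value is 1, since the partitions are
identical. The test suite checks it against exhaustive pair enumeration and
an independent implementation. `gmm_cluster()` delegates the Gaussian EM and
its BIC to `mclust::Mclust`. The default covariance family is the diagonal
set (`EII`–`VVI`) rather than per-component-variance `VVI` alone: with
$G \gg N$, near-constant genes give zero within-component variance and the
per-component models are frequently singular (mclust returns no fit), while
pooled-variance diagonal models remain estimable; offering the family and
letting BIC choose keeps the comparator fittable everywhere and mirrors how
such comparators are run in practice. `run_simulation_study()` crosses
scenarios × replicates × methods with replicate seeds derived from the
scenario seed, so results are reproducible and independent of execution
order; failures are recorded per replicate, never fatal.

## Problem sizes used by the shipped checks

The package's own verification runs at desk scale, chosen to give each check
statistical teeth while keeping the whole suite fast: oracle equivalences at
tiny n; EM properties on 30–60-sample fits; recovery at N = 100, G = 200,
K = 3 over 20 seeds; the small-sample breakdown at N = 50, G = 1000,
K_true = 5 over 20 replicates; null behavior over 20 replicates; the
NB-vs-Blom-GMM directional comparison at N = 50, G = 200 over 10 replicates
— the small-sample regime where the NB model's advantage over rank-normalized
Gaussian mixtures is expected; at larger N the two methods run at ceiling on
strong-signal scenarios and their ordering is decided by single ambiguous
samples.

## Known limitations

* Dispersion differences between clusters are not exploited (fixed pooled
  $\theta$); the model discriminates on means.
* BIC with $\nu \approx KG$ under-selects K when few genes are informative —
  filter first.
* No covariates, no gene selection inside the model, no infinite-mixture
  extension; correlated genes violate the independence assumption.
* The deterministic algorithm has a single basin of attraction per
  temperature ladder; pathological data could still find a poor optimum that
  random-restart methods would escape.
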