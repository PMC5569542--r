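---
title: "Combining G-BLUP and Bayes-C: models, algorithm and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining G-BLUP and Bayes-C: models, algorithm and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbcpred)
```

## The problem

Genomic prediction estimates the additive genetic merit (GEBV) of
selection candidates from dense SNP genotypes, using a reference
population of animals with both genotypes and phenotypes. In dairy-cattle
progeny testing the phenotype of a bull is a *daughter yield deviation*
(DYD): the mean performance of his daughters corrected for non-genetic
effects and mates' genetics, with an information content measured by the
effective number of daughters $d_e$.

Two families of methods dominate. Linear methods (G-BLUP) treat every SNP
as contributing equally to covariance between animals; they exploit
*relationships* and are cheap. Non-linear methods (Bayes-C and kin) give
each SNP its own chance of a large effect; they exploit *linkage
disequilibrium* with major genes but are usually run by MCMC and are
expensive. This package implements both, plus a combined model — here
called GBC — that fits a Bayes-C large-effect SNP term *simultaneously*
with a G-BLUP polygenic term and replaces MCMC with a fast deterministic
algorithm.

## Models

With one record per animal (the incidence matrix is the identity
everywhere below), and $M$ the matrix of centered allele counts
$M_{ij} = x_{ij} - 2p_j$:

* **G-BLUP**: $y = 1\mu + g + e$, $g \sim MVN(0, \sigma^2_g G)$,
  $e \sim MVN(0, \sigma^2_e I)$, with
  $G = MM' / 2\sum_j p_j(1-p_j)$ (VanRaden method 1), computed from all
  animals — reference and validation together — so the validation block
  is available for projection. Solved by the dense mixed-model equations;
  the full inverse coefficient matrix is retained because GBC needs the
  complete prediction-error-variance (PEV) matrix, not just its diagonal.
* **Bayes-C**: $y = 1\mu + MQq + e$, where $Q$ is diagonal with
  indicator entries: SNP $j$ has a normal effect
  $q_j \sim N(0, \sigma^2_q)$ with prior probability $\pi$ and no effect
  otherwise. Fitted by single-site Gibbs sampling.
* **GBC**: $y = 1\mu + MQq + g + e$ — both of the above at once. The $g$
  term is called the *residual breeding value*: the genetic merit left
  after the few large SNP effects are fitted.

## The ICE algorithm

GBC is fitted by iterative conditional expectation: each SNP effect is
replaced by its conditional posterior *mean* given all other effects
(the posterior is often bimodal, which makes the mode an arbitrary
choice). One outer iteration updates, in order: the mean $\mu$; the
polygenic vector $g$ (a linear smoother $G_{rr}(G_{rr} + \lambda_g
I)^{-1}$ applied to the SNP-corrected data, precomputed once); then every
SNP in fixed ascending order. For SNP $j$, with $y^*$ the records
corrected for everything except SNP $j$:

$$\log LR_j = \tfrac12\log\lambda - \tfrac12\log(m_j'm_j + \lambda)
  + \tfrac12\,\frac{(m_j'y^*)^2 + m_j'\,PEV\,m_j}{\sigma^2_e\,(m_j'm_j + \lambda)},
  \qquad \lambda = \sigma^2_e/\sigma^2_q,$$

$$PostProb_j = \frac{PPR \cdot LR_j}{PPR \cdot LR_j + 1}, \qquad
  \hat q_j = PostProb_j \cdot \frac{m_j'y^*}{m_j'm_j + \lambda}.$$

The working residual is maintained incrementally (add back
$m_j \hat q_j$, update, subtract), so one sweep is $O(nm)$; the sweep is
implemented in C++. Convergence is declared when the largest change in
any reference GEBV ($M\hat q + \hat g$) over one outer iteration falls
below `tol * sd(y)` (`tol = 1e-6` by default). Non-convergence at
`max_outer_iter` is a *flagged* result with a warning, not an error,
because cross-validation sweeps must not abort on one bad grid cell.

Numerical/design choices a maintainer should know:

* **PPR is prior odds.** The formula source prints the
  "prior-probability-ratio" as $\pi(1-\pi)$, but a probability ratio is
  $\pi/(1-\pi)$, and only the odds form gives $PostProb = 1/2$ at even
  prior odds with $LR = 1$. We implement odds;
  `gbc_config(ppr_literal = TRUE)` reproduces the literal printed form
  for comparison. At small $\pi$ the two differ by a factor
  $(1-\pi)^2 \approx 1$, so downstream conclusions barely move.
* **PostProb is computed in log space** (`plogis(log PPR + log LR)`), so
  likelihood ratios up to $e^{700}$ and beyond saturate cleanly at 1.
* **PEV is computed once**, from the SNP-free G-BLUP fit, and held fixed;
  the per-SNP quadratic forms $m_j' PEV\, m_j$ are precomputed. The
  correction term is what lets a SNP whose signal is partially absorbed
  by $g$ still reach a high likelihood ratio; it only ever increases
  $\log LR$.
* **Slab variance**: a "large" SNP is assumed to explain a fraction $f$
  (default 0.001, alternative 0.01) of the genetic variance, so
  $\sigma^2_q = f\,\sigma^2_g/\bar v$ with
  $\bar v = 2\sum_j p_j(1-p_j)/m$ the average column variance of $M$.
  The G-BLUP term keeps the full $\sigma^2_g$; the SNP term is capacity
  *on top*, which is also how the combined model is stated.
* **Fixed SNP order, fixed update order** ($\mu$, then $g$, then the
  sweep): unspecified in the method's description; fixed here for bit
  reproducibility.
* **Singular $G$** (duplicated genotypes): one retry with $10^{-6}$
  added to the diagonal, with a warning, then an error.

## Bayes-C sampler

Single-site Gibbs with the standard add-back/subtract residual scheme and
per-sweep recomputation of every right-hand side. Defaults: 20,000
iterations, 2000 burn-in, thinning 100 — with these (or longer) chains
the prediction accuracy is insensitive to chain length on well-specified
data (see below). Variances are *fixed* by default at
$\sigma^2_q = \sigma^2_g/(\pi \cdot 2\sum p_j(1-p_j))$, which makes the
sampler directly checkable against ridge-regression oracles ($\pi = 1$
collapses the model to SNP-BLUP); scaled-inverse-$\chi^2$ sampling of
$\sigma^2_q$ and $\sigma^2_e$ is available behind
`sample_variances = TRUE`, with $\nu = 4.2$ degrees of freedom and prior
scales centring the prior mode on the fixed values (the reference
implementation the method used leaves its parameterization unstated; this
is a documented divergence). R's RNG drives the chain, so `set.seed`
gives bit-identical fits.

## Evaluation statistics

* Reliability of a DYD: $r^2 = d_e/(d_e + K)$, $K = (4-h^2)/h^2$. Two
  variants of $K$ circulate in print; this (Fikse–Banos) form is the one
  that reproduces published reliability tables (e.g. $h^2 = 0.277$,
  $d_e = 177$ gives 0.93), the other does not.
* Accuracy: $\mathrm{cor}(GEBV, DYD)/\sqrt{\bar r^2}$ — the observable
  correlation rescaled toward the GEBV–true-breeding-value scale. Signs
  are preserved and nothing is clamped.
* Bias: OLS slope of DYD on GEBV, *with* intercept (a slope without an
  intercept would conflate location shifts with dispersion); 1 is
  unbiased, < 1 means GEBV spread too wide.
* Bootstrap: GEBV–DYD *pairs* resampled jointly, 10,000 times by
  default; degenerate resamples are redrawn and counted, more than 1% of
  them is an error.
* Hotelling–Williams $t$ for two dependent correlations sharing the DYD,
  with $n-3$ degrees of freedom; validated by Monte-Carlo type-I error
  at $n = 124$.

## What the simulator emulates — and what it does not

`make_scenario()` builds a desk-scale analogue of a progeny-tested bull
population. Its defaults are the stated world of the tests:

| parameter | default | why |
|---|---|---|
| `n_ref`, `n_val` | 1000, 124 | validation-set size mirrors a young-sire cohort; reference scaled down ~3× from a real 3000-bull set |
| `n_sires` | 20 | half-sib families; validation animals are offspring of reference sires, so validation-to-reference Relmax clusters near 0.5 (observed ≈ 0.48) |
| `m_snps`, `maf_range` | 2000, [0.05, 0.5] | unlinked biallelic SNPs; the 0.05 MAF filter then removes (almost) nothing, as in a post-QC chip |
| `n_large_qtl`, `large_qtl_fraction` | 2, 0.10 | few major genes on a polygenic background, the architecture the combined model targets |
| `h2`, `sigma2_g` | 0.25, 1 | mid-range production-trait heritability |
| `d_e` | N(177, 31), min 108 | published moments of effective daughter counts |

DYD are built as $TBV + \varepsilon$ with noise variance
$\sigma^2_g(1-r^2)/r^2$, so each animal's DYD attains its target
reliability by construction.

Deliberate omissions: no linkage map or LD beyond family co-segregation
(an exchangeable block-correlation mode exists for qualitative
experiments but is off by default), no selection, no genotyping error,
no imputation artefacts. Consequently a green test establishes that the
algorithms do what their formulas say under the stated architecture — it
does **not** establish field performance on selected, LD-structured
data; in particular real validation cohorts under selection show bias
slopes far from 1, which the unselected simulator will not reproduce.

Missing genotype calls are mean-imputed at centering (entry 0 in $M$), a
neutral stand-in for the imputed data the method expects. Allele
frequencies are computed from all genotyped animals, and the boundary
MAF is kept (only frequencies strictly below the threshold drop).

## Findings worth recording

Two empirical observations from this implementation, both reproducible
from the test suite:

* **CV over $\pi$ is nearly flat when the background term is in.** With
  the G-BLUP term carrying the full $\sigma^2_g$, the cross-validated
  score moves by ~$10^{-3}$ across $\pi \in [0.01, 0.30]$ and often
  *rises* slightly with $\pi$: extra heavily-shrunk SNP effects act as
  additional capacity, not overfitting. This matches the original
  study's real-data optima of 10–20% and its report that results are
  insensitive to these settings. The classic "sparse truth selects
  sparse $\pi$" direction re-emerges exactly when the mixture governs
  the fit alone (`include_gblup = FALSE`) with a slab matched to the
  QTL size, and that is the regime in which the directional test runs.
* **Chain-length insensitivity requires a well-specified sampler.** On
  data drawn from the Bayes-C model itself the accuracy difference
  between (20,000 / 2,000) and (50,000 / 10,000) chains is ~0.004. On a
  polygenic half-sib trait with the *fixed* slab, the included-SNP set
  keeps evolving past 20,000 iterations and accuracy moves by 0.05–0.1:
  misspecification, not a sampler defect. The acceptance test uses the
  well-specified world; users fitting strongly polygenic traits with
  fixed variances should prefer G-BLUP or GBC, which is the combined
  model's point.

## Limitations

* Dense solvers throughout: fine to ~5000 animals (the intended scale),
  not for national evaluations.
* Variance components are user inputs; no REML estimation.
* The GBC outer loop is a fixed-point iteration without an acceleration
  scheme; convergence is linear (typically 30–80 outer iterations at the
  default preset).
* No Bayes-A/B/R, no multi-trait models, no pedigree relationship
  matrix.
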