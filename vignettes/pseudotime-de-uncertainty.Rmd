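---
title: "Testing differential expression along uncertain pseudotime"
author: "ptDE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential expression along uncertain pseudotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptDE)
```

## The problem

After trajectory inference assigns each cell a pseudotime $T_i \in [0,1]$,
the canonical follow-up question is which genes change expression along the
trajectory. The standard approach regresses each gene's counts on
pseudotime and tests whether the fitted curve is flat. The catch is that
$T_i$ is not data: it is an *estimate* produced by an algorithm (Slingshot,
Monocle3, a principal curve, ...) from the same expression matrix being
tested. Rerunning inference on a slightly perturbed dataset yields a
different ordering, sometimes a different topology. Treating $T_i$ as fixed
ignores that randomness, and the resulting p-values are not calibrated:
they are too small for some genes, inflating false discoveries at any
nominal FDR.

ptDE addresses this by estimating the *distribution* of the test statistic
under the null hypothesis while letting pseudotime stay random, via
subsampling and permutation, and then reading the observed statistic off
that estimated null.

## The per-gene model

For gene $j$ with counts $Y_{ij}$ in cells $i = 1,\dots,n$:

$$Y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_j), \qquad
  \log \mu_{ij} = \beta_{j0} + f_j(T_i),$$

where $f_j(t) = \sum_{k} b_k(t)\,\beta_{jk}$ is a cubic spline with basis
dimension $K = 6$ (the default; results are insensitive to $K$ in this
range), and $\phi_j$ is the NB size parameter (variance
$\mu + \mu^2/\phi$). The basis is a cubic B-spline with interior knots at
pseudotime quantiles and a second-derivative roughness penalty; the
sum-to-zero constraint over observed cells is absorbed so $f_j$ is
identifiable next to the intercept, and within the knot range the basis
reproduces cubic polynomials exactly. The null hypothesis is
$H_0\!: f_j \equiv 0$ (no change along pseudotime) against
$H_1\!: f_j \neq 0$.

Fitting maximizes the penalized NB likelihood by iteratively reweighted
least squares. The smoothing parameter is selected by a Laplace-approximate
REML criterion (GCV is available as an alternative) by golden-section
search on $\log_{10}\lambda$ over $[-4, 7]$, and $\phi_j$ by alternating
profile maximum likelihood. The engine is compiled (RcppArmadillo) because
a single analysis requires on the order of $m \times B$ refits. Fits agree
closely with `mgcv::gam(..., family = nb(), method = "REML")` on the same
basis (the test suite cross-checks fitted smooths, dispersions and
log-likelihoods), but exact equality with any particular smoother is *not*
the contract. What matters for validity is that observed and null
statistics travel the identical fitting path — same basis construction,
penalty, optimizer and tolerances — so that permutation exchangeability
holds. That equivalence-of-path rule is enforced structurally: both paths
call the same internal routine.

### Zero inflation

Droplet and some plate protocols produce more zeros than NB predicts. The
zero-inflated variant assumes each count is observed with probability
$p_{ij}$, $\operatorname{logit}(p_{ij}) = \alpha_{j0} +
\alpha_{j1}\log\mu_{ij}$, and is otherwise replaced by zero. Fitting is by
EM: the E-step computes the posterior probability that each observed zero
came from the NB component; the M-step runs a prior-weighted NB-GAM and a
logistic regression of those posteriors on $\log\hat\mu$. The smoothing
parameter is frozen after the first M-step so subsequent iterations ascend
a fixed penalized observed-data likelihood; the trace is stored
(`emTrace`) and tested for monotonicity up to inner-solver tolerance
(relative $10^{-5}$). EM stops at relative log-likelihood change
$10^{-6}$ or 100 iterations; separation in the logistic step clips the
alphas at $\pm 30$ with a warning.

Per gene, the flavor is chosen by AIC (parameter count: total effective
degrees of freedom + 1 for $\phi$, + 2 for the alphas): the ZINB model is
used only when its AIC improves on NB by at least 10. The asymmetric
margin reflects that ZINB extends NB, so small AIC gains are expected by
chance; requiring a margin of 10 keeps NB for genes without genuine excess
zeros. Unconverged ZINB fits always fall back to NB. On data without
excess zeros the fitted $p_{ij}$ approach 1 and the selection returns NB.

## The test statistic

With $\hat f_j$ the fitted smooth at the observed cells and
$\hat V_{f_j}$ its Bayesian covariance,

$$s_j = \hat f_j^{\top}\, \hat V_{f_j}^{\,r-}\, \hat f_j,$$

where $\hat V^{r-}$ is the rank-$r$ pseudoinverse: eigenvalues below
$\sqrt{\varepsilon}\,\lambda_{\max}$ are dropped, and $r$ is additionally
capped at $\operatorname{round}(\mathrm{edf}) + 1$ so that heavily
penalized (near-linear) fits are not tested against noise dimensions. The
computation uses the low-rank factorization
$\hat V_f = X V_\beta X^\top$, reducing the eigenproblem to the spline
dimension; a dense-eigendecomposition route exists for arbitrary
covariances and the two are cross-checked in tests. The statistic is
invariant to reversing pseudotime direction, which is essential because
direction is not identifiable across subsamples.

## Propagating pseudotime uncertainty

The workflow has four steps:

1. **Subsample.** Draw $B$ subsamples of $n' = \lfloor 0.8\,n \rfloor$
   cells *without* replacement ($B = 1000$ by default; $B = 100$ already
   gives very similar p-values and is what the scaled validation uses).
   Sampling with replacement would duplicate cells, which many pseudotime
   tools cannot handle. With pre-defined cell groups, sampling is
   stratified: $\lfloor 0.8\,g_k \rfloor$ per group, any shortfall filled
   uniformly from the remaining cells.
2. **Re-infer.** Run the *same* pseudotime method with the same settings on
   every subsample. This is the step that captures inference uncertainty:
   the subsample's pseudotime values are newly inferred, not copied from
   the full-data estimate. Failures (method error, constant output) are
   recorded and dropped; the analysis aborts if fewer than
   `minSubsamples` (default 50) remain.
3. **Permute.** Independently permute each subsample's inferred pseudotime.
   Permutation severs any expression–pseudotime association while
   preserving both marginals, so refitting the gene model on a permuted
   subsample draws from the statistic's null distribution *with pseudotime
   still random*.
4. **Test.** Fit the selected model flavor to each permuted subsample,
   collect $\{s_j^1, \dots, s_j^{B'}\}$, and compare the observed $s_j$
   against them.

The empirical p-value is
$p^{\mathrm{emp}}_j = \bigl(\#\{b : s_j^b \ge s_j\} + 1\bigr)/(B' + 1)$,
with resolution floor $1/(B'+1)$. To refine small p-values beyond that
floor, a parametric estimate of the null CDF is fitted to the null sample:
a gamma distribution (maximum likelihood via **fitdistrplus**) and a
two-component gamma mixture (EM with five restarts — a median split, an
upper-quantile split, a duplicated-gamma split that starts the EM exactly
at the nested single-gamma solution and thereby guarantees the mixture
log-likelihood never falls below it, and two random-responsibility draws;
tolerance $10^{-8}$ relative, mixing weight clipped to $[0.01, 0.99]$
against component collapse). A likelihood ratio test on 3 degrees of
freedom chooses the mixture when its p-value is $\le 0.01$; the chi-square
reference is a boundary-irregular approximation here, used deliberately as
the conventional rule. The parametric p-value is
$p^{\mathrm{param}}_j = 1 - \hat F_j(s_j)$, floored at $10^{-300}$. An
Anderson–Darling statistic against the chosen CDF is logged per gene as a
goodness-of-fit diagnostic (its p-value uses the classical asymptotic
approximation with parameters treated as known); it never filters genes.
Exact zeros among the null statistics (degenerate refits) are kept in the
empirical p-value but excluded from the parametric fit; a gene with more
than 10% zero null values, or with fewer than 50 usable null values,
reports the empirical p-value only. BH adjustment is applied to the
parametric p-values (both flavors are reported; the parametric one has
higher resolution, which is why it drives the adjusted column).

### Fixed-pseudotime mode

When pseudotime really is fixed (e.g., physical time points), or as a fast
screen, `fixed = TRUE` skips subsampling and computes a right-tail p-value
from the smooth-term asymptotic approximation: the fractional-rank
pseudoinverse construction with reference df equal to the upper-bound edf,
and the tail of the implied weighted chi-square sum (via
`mgcv::psum.chisq`). Like all asymptotic tests of penalized smooths with
estimated dispersion and adaptively chosen smoothness, it carries a small
liberal bias in finite samples; the test suite verifies its rejection rate
at 0.05 stays within a few points of nominal and its p-value distribution
is close to uniform. When pseudotime is inferred, the permutation-based
p-values are the calibrated ones and should be preferred.

## The synthetic-data generator

`simulateLineage()` emulates lineage count data for validation: latent
times uniform on $[0,1]$ (rescaled to span it exactly), NB counts with
gene-level size parameters drawn log-uniformly within a dispersion tier,
and for DE genes a smooth log-mean trend drawn from three shape families —
monotone ($\pm t^{p}$, $p \in [0.5, 2]$), sigmoidal (logistic in $t$ with
slope 5–15 and midpoint in $[0.25, 0.75]$) and transient (Gaussian bump
centered in $[0.2, 0.8]$, width 0.1–0.25) — scaled to a max/min mean ratio
between 2- and 6-fold. Baseline log-means are $N(\log 3, 1)$. The tier
ranges for the NB size are low $(20, 200)$, medium $(5, 50)$ and high
$(1, 10)$; these constants are this package's convention for
low/medium/high dispersion and are deliberately documented rather than
hidden. In the bifurcation topology each cell belongs to one of two
branches; trends agree on the root segment ($t \le 0.4$, a fixed
convention) and diverge smoothly (quadratic ramp, $C^1$ at the split)
afterwards. `simulateZeroInflation()` thins counts with exactly the
logistic dropout mechanism the ZINB model assumes, recording the latent
keep indicators so EM recovery is testable. `shuffleNullGenes()` permutes
chosen genes across cells to make realistic negative controls.

What the generator does *not* emulate: ambient RNA, batch effects,
cell-cycle structure, UMI saturation, doublets, or any particular
real-data protocol. Passing tests on these simulations therefore
demonstrates statistical correctness of the method under its own model
class (plus robustness to the mild misspecification introduced by
pseudotime estimation error), not performance on any specific real
dataset.

The built-in pseudotime method (`builtinPseudotime()`) is a deterministic
principal-component ordering: library-size normalization, $\log(1+x)$,
restriction to the top 20% most variable genes (minimum 50 — the standard
feature-selection step), projection on the first principal axis, sign
fixed by correlation with library size. It is a surrogate for a principal curve that lets the whole
pipeline run offline and reproducibly; real analyses should plug in a
trajectory method via the callable interface or supply per-subsample
pseudotime computed out-of-band (`subsamplePseudotime`).

## Numerical and design choices

* **Smoothing engine.** Own penalized-IRLS implementation with REML-type
  smoothness selection rather than per-gene calls to a general GAM
  package: the permutation stage needs $\sim 10^5$ small identical-shape
  fits per analysis, and basis construction is shared across genes within
  a subsample. Validity rests on the equivalence-of-path rule, not on
  matching any external smoother exactly.
* **Rank rule.** $r$ = number of eigenvalues above
  $\sqrt{\varepsilon}\lambda_{\max}$, capped at round(edf) + 1 — a
  reproducible pin of the usual "rank of the smooth" notion.
* **Direction alignment.** Subsample pseudotime is flipped (to $1-T$) for
  *reporting* in `uncertaintySummary()` when its Spearman correlation with
  the full-data pseudotime is negative. Testing never needs alignment
  because permutation destroys direction anyway.
* **Seeds.** Every randomized sub-task (each subsample draw, each
  permutation, each shuffled gene) uses a seed derived from the master
  seed, a purpose tag, and a counter, so results are bit-identical across
  worker counts and execution orders. The manifest stored with results
  suffices to reproduce a run exactly.
* **Failure containment.** Per-gene fit failures yield missing rows, never
  abort the run; subsample failures decrement $B'$; cells with zero total
  counts are dropped with a warning before pseudotime inference.
* **Gene filter.** Genes with more than 90% zeros are removed by default
  before testing: an almost-all-zero gene cannot support a smooth fit and
  wastes permutation effort.
* **No expression offset.** The model regresses raw counts on pseudotime
  without a library-size offset, matching the model equations above;
  library size varies smoothly along a lineage and an offset would absorb
  part of the signal under test. (The built-in *pseudotime* method does
  normalize before its PCA, which is a separate concern.)
* **Multi-lineage data.** The package tests one lineage at a time. The
  pseudotime callable must return a single lineage's pseudotime; matching
  lineages between subsamples and the full data in branching topologies is
  the user's responsibility (e.g., keep only subsamples whose inferred
  topology matches).

## Problem sizes used for validation

The test suite and the acceptance script run scaled-down study conditions
chosen so the full statistical claims are exercised at workstation scale:
FDR control and power on single-lineage high-dispersion data with 200
cells, 500 genes, 20% DE genes, $B = 100$, five simulation seeds; null
calibration with 300 genes and no DE; subsample-count stability comparing
$B = 100$ against $B = 1000$ on a 100-gene panel; ZINB parameter recovery
over 100 genes of 500 cells; and a transient-trend power comparison
against a linear NB GLM baseline on 300 cells. These sizes are the
package's validation conventions; the method itself has no scale limits
beyond runtime (per-gene work is embarrassingly parallel and the `workers`
argument shards it without changing results).

## Known limitations

* The permutation null is exact for the *given* pseudotime mechanism but
  approximate in two ways the procedure inherits by design: null
  statistics come from subsamples of $n'$ cells rather than $n$, and the
  observed statistic retains whatever alignment the pseudotime method has
  with each tested gene's own noise. The second effect scales like $n/m$:
  it is negligible on transcriptome-wide panels but measurable when the
  same few hundred genes both drive the ordering and are tested (the test
  suite quantifies this, and shows exact calibration when pseudotime comes
  from a source independent of the tested genes). On small panels, prefer
  inferring pseudotime from genes outside the test set.
* The asymptotic (fixed-pseudotime) p-value shares the mild finite-sample
  liberalism of all smooth-term tests with estimated smoothness; the
  permutation path exists precisely to avoid relying on it.
* The gamma/gamma-mixture family is an approximation to the permutation
  null; the Anderson–Darling diagnostic is logged per gene so poor fits
  are visible, but the p-value is still produced.
* The LRT between gamma and mixture uses a 3-df chi-square despite the
  boundary irregularity of mixture testing; this conventional rule is
  slightly conservative for the mixture.
* Branch-specific tests (differences *between* lineages), covariate
  adjustment, and FDR procedures beyond BH are out of scope.
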