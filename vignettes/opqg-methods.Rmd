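---
title: "Models and methods in opqg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in opqg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opqg)
```

`opqg` analyses open-pollinated (OP) conifer progeny trials: families
with a known mother and unknown wind-borne fathers, planted in
replicated designs across several test sites, phenotyped for growth,
wood quality and drought-response traits, and genotyped at genome-wide
SNPs. This vignette documents the models, the parameters that matter,
the synthetic-data generator, and the numerical choices, in that
order.

## The individual-tree mixed model

The single-trait, single-site model is

$$ y = X\beta + Z_d d + Z_a a + e, $$

with genetic groups (provenances) as fixed effects $\beta$, a random
replication effect $d \sim N(0, I\sigma^2_d)$, additive genetic
effects $a \sim N(0, K\sigma^2_a)$, and residuals
$e \sim N(0, I\sigma^2_e)$. The kernel $K$ is either the pedigree
numerator matrix $A$ (tabular method; founders assumed unrelated and
non-inbred — the standard base-population assumption), the VanRaden
genomic matrix $G = WW'/(2\sum_i p_i(1-p_i))$ with $W = M - 2p$, or a
blend. Allele frequencies default to the full filtered sample; a
`freq_source = "provided"` path accepts externally estimated (e.g.
per-site) frequencies.

The multivariate model stacks responses — different traits on the same
trees, or the same trait measured at different sites ("sites as
traits") — with genetic covariance $\Sigma_a \otimes K$ and residual
covariance free between responses measured on the same trees but
*structurally zero* across sites, since no tree grows at two sites.
Narrow-sense heritability is reported as
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$: the replication variance
is deliberately excluded from the denominator, matching the
individual-trait re-parameterization this package targets. This
definition runs higher than one that includes design variance in the
denominator; users comparing across studies should check which
convention the other study used. Genetic correlations are
$r_a = \sigma_{a,ij}/\sqrt{\sigma^2_{a,ii}\sigma^2_{a,jj}}$, with
strength labels strong ($|r_a| \ge 0.70$), moderate
($0.40 < |r_a| < 0.70$) and low/weak ($|r_a| \le 0.40$).

### Estimation: EM-REML with one AI step

Variance components are estimated by EM-REML and the asymptotic
covariance of the estimates comes from a single average-information
(AI) evaluation at the EM optimum; the AI step never moves the
estimates, it only prices them. EM was chosen over full AI-REML
because its log-likelihood trace is provably non-decreasing — the
engine asserts this on every fit — and it cannot step outside the
parameter space; the cost is slow terminal convergence, which the
tolerance below accounts for.

Two computational paths produce identical results (tested to 1e-10):

* an **eigen path** when every individual carries every response and
  no replication effect is fitted: one eigendecomposition of $K$ plus,
  per EM iteration, a $t \times t$ canonical transform that
  simultaneously diagonalizes $\Sigma_a$ and $\Sigma_e$, making each
  iteration $O(n\,t^2 p)$;
* a **dense path** for unbalanced layouts (cross-site models, random
  replication effects): the projection matrix $P$ is formed explicitly
  each iteration, and the residual E-step runs per individual over its
  observed responses, which is what keeps cross-site residual
  covariances exactly zero rather than approximately zero.

Missing responses are handled by row deletion per response; residual
covariances are updated from jointly observed individuals
(observed-pairs E-step, exact EM whenever the pattern is complete).

Numerical choices:

* **Starting values**: genetic and residual components each start at
  half the phenotypic (co)variance, the covariance diagonally loaded
  (0.9 C + 0.1 diag C); replication variance starts at a tenth of the
  phenotypic variance.
* **Convergence**: maximum relative change of any free parameter
  below 1e-8, or 2,000 EM iterations; non-convergence is flagged on
  the result, never silently ignored. Components below 1e-6 of the
  phenotypic variance are flagged "near zero" (boundary estimates —
  expect them where a site shows no heritable variation).
* **PSD projection**: after each EM update, $\Sigma_a$ (and each
  same-site residual block) is projected to the nearest positive
  semidefinite matrix by eigenvalue clipping at 1e-10 of the largest
  eigenvalue. Consequently every reported $|r_a| \le 1$.
* **Cholesky with ridge fallback** everywhere a factorization can fail
  on a semidefinite matrix; `stabilize_G()` (ridge, default 1e-6, or
  blending with A) should precede fits with a raw genomic matrix,
  which is singular whenever clones or near-duplicates are present.
* **Degenerate inputs** error early and by name: responses with zero
  observations, trees measured at two sites, relationship matrices not
  covering the phenotyped trees, pedigree cycles (cycle members are
  listed), zero-variance traits.

BLUP breeding values are recovered for all individuals in the
relationship matrix (including non-phenotyped parents) from the
mixed-model solutions at the final components, with accuracy
$\sqrt{1 - PEV/(K_{ii}\sigma^2_a)}$.

## Pedigree verification and correction

OP pedigrees carry recording errors and pollen contamination. The
screen compares each recorded parent-offspring pair's genomic
coefficient against 0.5 and each recorded sib pair against its class
expectation (0.5 full-sib, 0.25 half-sib); deviations beyond the
threshold (default 0.15) are flagged. Correction searches candidate
parents of the flagged slot among recorded parents with $g$ inside the
parent window (default [0.35, 0.65]): a unique candidate is assigned;
ties are not guessed — a phantom parent is created instead (phantom
ids share a reserved `PH` prefix; no-candidate offspring that are
mutually related at $g \ge 0.2$ share one phantom, so a replaced
seed-lot surfaces as one phantom mother rather than many); three or
more in-window candidates mark the offspring for removal. The 0.15 /
[0.35, 0.65] defaults are this package's codification of what is
usually a manual procedure; both are configurable, and the defaults
leave a wide margin at realistic SNP counts — mean imputation at 10%
missingness attenuates a true parent-offspring $g$ from 0.50 toward
roughly 0.40, still inside the window. Phantom parents default to the
genetic group of their offspring, flagged in the correction report,
since provenance of an unrecorded parent is unknowable.

## What the synthetic-data generator emulates — and what it does not

The generator reproduces the structural features the analysis depends
on: maternal families of configurable size (defaults: 80 dams × 8
progeny) with true sires drawn from a finite pollen pool (default 100,
selfing excluded), so nominal half-sib families contain true full-sibs;
recorded pedigrees that hide sires and carry dam errors at a
configurable rate; biallelic SNPs gene-dropped through the true
pedigree from uniform founder frequencies with completely-at-random
missingness; multivariate phenotypes with breeding values drawn from
$\Sigma_a \otimes K$, unit phenotypic variance per response (so target
heritabilities are variances), iid replication effects and zero
cross-site residual covariance; and BAI ring series with a
multiplicative drought-year dip $1 - s\,\delta_i$, where the per-tree
deviate $\delta_i$ (mean 1, CV 0.326, half of its variance shared
within maternal family) makes drought resistance heritable. The
severity default 0.43 and deviate CV were set once so the population
resistance index averages 0.57, and the year-noise default 0.18 so
mean sensitivity lands near 0.23 — the magnitudes reported for a real
2015-type drought in a spruce trial series; they were not revisited
afterwards.

Deliberately *not* emulated: linkage and LD (loci independent),
selection or multi-generation breeding, spatial field autocorrelation
beyond replication effects, sequencing-depth artifacts, and
genotyping error. Passing recovery tests therefore demonstrate that
the estimators are consistent and their SEs calibrated under the
stated generative model — not that real GBS data are free of the
confounders above.

## Trait preprocessing

Log transforms use the natural log (the base only scales variances;
heritabilities and correlations are unchanged). Design adjustment
subtracts per-site replication means (count-weighted, sum-to-zero), is
idempotent, and preserves the grand mean; no spatial surface is
fitted beyond this. Standardization is per trait within site by
default (z-scores, n−1 denominator). Univariate fits model the
replication effect as random on unadjusted data; multivariate fits
take pre-adjusted, standardized data with the replication effect off —
fitting the design effect once, before the multivariate stage, keeps
the cross-site covariance structure simple. Mean sensitivity counts
only consecutive observed years; pairs straddling a gap are dropped
and the divisor is the retained pair count. Responses with fewer than
30 observations (configurable) are excluded from model fitting and
reported NA — never zero.

## Problem sizes and verification

The test suite runs entirely on generated data, at sizes chosen to
make every check sharp but desk-fast: oracle equivalence of the
A-matrix against an independent recursive-coancestry implementation on
100 random pedigrees up to 50 individuals (agreement to 1e-12) and
against Monte-Carlo gene-dropping IBD at 20,000 drops on pedigrees up
to 20; G-matrix identities (zero grand sum; unit mean diagonal for 200
Hardy-Weinberg founders at 2,000 SNPs); exact agreement of animal-model
REML with the one-way ANOVA method of moments on a balanced 100 × 10
half-sib design; parameter recovery at truth $h^2 = 0.5$,
$r_a = 0.7$ over 20 seeds of 800 trees × 3,000 SNPs; and pedigree
correction recovery at 5% injected dam errors on 640 progeny × 5,000
SNPs. Replicate-based SE calibration uses 100 phenotype replicates on
a fixed 50-family structure.

## Known limitations

* No sparse A-inverse (Henderson's rules) or sparse mixed-model
  solvers: the dense engine targets desk-scale data (a few thousand
  trees, up to ~6 responses). Cross-site fits on thousands of records
  take minutes, not seconds.
* No single-step (H-matrix) GBLUP, dominance, epistasis, or spatial
  residual structures; no full AI-REML optimizer.
* EM's terminal convergence is slow near variance boundaries; fits at
  the iteration cap are flagged and their boundary components labelled
  near-zero rather than treated as converged interior estimates.
* The pedigree-correction thresholds are declared defaults, not values
  inferred from any particular dataset; sensitivity to them should be
  checked when error rates are high.
* Parentage correction assigns dams from the recorded-dam pool;
  fathers remain unknown unless genotyped candidates are supplied as
  recorded parents.
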