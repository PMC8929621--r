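# opqg — quantitative genetics of open-pollinated conifer progeny trials

`opqg` is an R package for individual-tree quantitative-genetic analysis
of open-pollinated (OP) progeny trials that have been genotyped at
genome-wide SNPs — the design used in operational tree-breeding
programs, where each family has a known mother and unknown, wind-borne
fathers. It is aimed at forest geneticists who want to estimate
heritabilities, genetic correlations, and genotype-by-environment (G×E)
correlations for growth, wood-quality, and drought-response traits,
comparing pedigree-based and marker-based relationship information on
the same data.

## What it computes

**Relationship matrices.** The pedigree numerator relationship matrix
**A** by the tabular method (a_ii = 1 + F_i; half-sibs 0.25, full-sibs
0.5 in non-inbred pedigrees) and the VanRaden genomic relationship
matrix

    G = W W' / (2 Σ_i p_i (1 − p_i)),   W = M − 2p,

from SNP dosages M coded 0/1/2, after missingness/minor-allele-count
filtering and per-locus mean imputation.

**SNP-based pedigree verification.** OP pedigrees are error-prone
(seed-lot mixups, pollen contamination). `detect_conflicts()` screens
every recorded parent-offspring and sib pair for deviations of the
genomic coefficient from its class expectation (0.5, 0.25, ...);
`correct_pedigree()` reassigns offspring to the unique candidate parent
with g in a configurable window, creates phantom parents when no
candidate exists, and lists irreconcilable cases for removal.

**Drought indices from tree rings.** From per-tree basal area
increment (BAI) series: Resistance = BAI(drought year) / mean BAI of
the four preceding years (1 = unaffected), and mean Sensitivity,
(1/(n−1)) Σ |2(BAI_{t+1} − BAI_t)/(BAI_{t+1} + BAI_t)|. Both are
scale-invariant. `bai_weighted_mean()` gives BAI-weighted whole-tree
wood density.

**Mixed models.** The univariate individual-tree ("animal") model
y = Xβ + Z_d d + Z_a a + e with genetic groups (provenances) as fixed
effects, an optional random replication effect, and var(a) = K σ²_a for
K ∈ {A, G, blend}; and the multivariate model treating traits — or the
same trait at different sites — as correlated responses with
var(a) = Σ_a ⊗ K and residual covariance free within site,
structurally zero across sites. Variance components are estimated by
EM-REML (monotone log-likelihood, PSD projection each iteration)
followed by one average-information (AI) step that supplies asymptotic
standard errors. From the fits: h² = σ²_a/(σ²_a + σ²_e) and
r_a = σ_a,ij/√(σ²_a,ii σ²_a,jj) with delta-method SEs, BLUP breeding
values with accuracies, and site-by-site (type-B) correlation matrices.

**Synthetic data with known truth.** `simulate_pedigree()` (OP families
with a finite pollen pool and recordable dam errors),
`simulate_genotypes()` (gene dropping through the true pedigree),
`simulate_phenotypes()` (breeding values drawn from Σ_a ⊗ K), and
`simulate_ring_series()` (a drought-year dip calibrated to a 0.57 mean
resistance) make every stage testable end to end, and power the
parameter-recovery tests.

## Worked example

```r
library(opqg)

truth <- simulate_pedigree(n_dams = 40, progeny_per_dam = 8,
                           pollen_pool_size = 50,
                           contamination_rate = 0, seed = 42)
geno  <- impute_mean(filter_genotypes(
           simulate_genotypes(truth, n_snps = 2000,
                              missing_rate = 0.1, seed = 43)))
G     <- stabilize_G(compute_G(geno), method = "ridge", param = 1e-6)

cfg <- trait_config(c("height", "resistance"), "CALL", h2 = c(0.6, 0.4),
                    genetic_cor = matrix(c(1, -0.3, -0.3, 1), 2))
pheno <- simulate_phenotypes(truth, G, cfg, seed = 44)$phenotypes

fit_h <- fit_univariate(pheno, "height", G, site = "CALL",
                        fit_replication = FALSE)
heritability(fit_h)
#>      response        h2    h2_raw        se near_zero
#> 1 height@CALL 0.5318435 0.5318435 0.1130526     FALSE

fit2 <- fit_multivariate(pheno,
          data.frame(trait = c("height", "resistance"), site = "CALL"), G)
genetic_correlation(fit2)
#>    response_i      response_j        r_a        se    label
#> 1 height@CALL resistance@CALL -0.6443634 0.2372922 moderate
```

The 320 trees were simulated with true h² = 0.6 for height and a true
height-resistance genetic correlation of −0.3; the fitted h² of 0.53
(SE 0.11) covers the truth, and the correlation estimate −0.64
(SE 0.24) illustrates the sampling spread of r_a at this family count —
the strength label ("moderate", |r| between 0.40 and 0.70) is applied
to the point estimate. At 20 replicate datasets of n = 800 the mean
estimates recover the simulated truth to within 0.05 (h²) and 0.07
(r_a); see `tests/testthat/test-acceptance.R`.

A full pipeline — load CSV/VCF inputs, filter and impute genotypes,
build G, verify/correct the pedigree, build A, derive drought indices,
pre-adjust and standardize traits, fit all univariate and cross-site
models under both A and G, and write TSV/JSON reports — is driven by a
single config: `run_pipeline("config.yaml")`. Column contracts:
pedigree CSV `id,sire,dam[,group]` (`UNKNOWN`/empty for missing
parents); phenotype CSV `tree,site,replication,group,<traits...>`;
ring CSV `tree,year,bai`; genotypes as VCF (GT field) or dosage TSV.

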