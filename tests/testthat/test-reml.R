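sim_uni <- function(n_dams, k, h2, seed, sites = "S1") {
  tr <- simulate_pedigree(n_dams = n_dams, progeny_per_dam = k,
                          pollen_pool_size = n_dams,
                          contamination_rate = 0, seed = seed)
  A <- compute_A(tr$true_pedigree)
  cfg <- trait_config("y", sites, h2 = h2)
  sp <- simulate_phenotypes(tr, A, cfg, seed = seed + 1)
  list(tr = tr, A = A, ph = sp$phenotypes, truth = sp$truth)
}

test_that("reml_loglik matches an independent dense-formula oracle", {
  ped <- validate_and_order(pedigree(
    c("D", "a", "b", "c", "d"), dam = c(NA, "D", "D", NA, NA)))
  A <- compute_A(ped)
  ph <- data.frame(tree = c("a", "b", "c", "d"), site = "S",
                   replication = "R1",
                   group = c("g1", "g1", "g2", "g2"),
                   y = c(1.2, -0.4, 0.7, 2.1))
  sa <- 0.6; se <- 1.3
  ll <- reml_loglik(ph, data.frame(trait = "y", site = "S"), A, sa, se)
  # oracle: direct dense matrices built from scratch
  Ka <- unclass(A)[ph$tree, ph$tree]
  V <- sa * Ka + se * diag(4)
  X <- cbind(1, c(0, 0, 1, 1))
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  be <- solve(XtVX, t(X) %*% Vi %*% ph$y)
  yPy <- t(ph$y) %*% Vi %*% (ph$y - X %*% be)
  oracle <- -0.5 * (determinant(V)$modulus[1] +
                      determinant(XtVX)$modulus[1] + as.numeric(yPy))
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("reml_loglik obeys the scale-transformation identity", {
  d <- sim_uni(15, 5, 0.4, 100)
  resp <- data.frame(trait = "y", site = "S1")
  ll1 <- reml_loglik(d$ph, resp, d$A, 0.5, 0.8)
  for (c_ in c(0.3, 2, 10)) {
    ph2 <- d$ph; ph2$y <- c_ * ph2$y
    ll2 <- reml_loglik(ph2, resp, d$A, c_^2 * 0.5, c_^2 * 0.8)
    n <- nrow(d$ph); rk <- length(unique(d$ph$group))
    expect_equal(ll2, ll1 - (n - rk) * log(c_), tolerance = 1e-8)
  }
})

test_that("REML equals the ANOVA method of moments on balanced half-sibs", {
  d <- balanced_halfsib(100, 10, 0.4, 0.6, seed = 42)
  A <- compute_A(d$ped)
  fit <- fit_univariate(d$pheno, "y", A, site = "S",
                        fit_replication = FALSE)
  expect_lt(abs(fit$vc$Sigma_a[1, 1] - d$anova_s2a), 1e-4)
  expect_lt(abs(fit$vc$Sigma_e[1, 1] - d$anova_s2e), 1e-4)
  expect_true(fit$monotone)
  expect_true(fit$converged)
})

test_that("pure-noise data yields near-zero heritability", {
  # half-sib families of pure noise (true sigma2_a = 0, n = 1000); the
  # family structure in A is what identifies the genetic component
  d <- balanced_halfsib(100, 10, s2a = 0, s2e = 1, seed = 77)
  A <- compute_A(d$ped)
  fit <- suppressWarnings(
    fit_univariate(d$pheno, "y", A, site = "S", fit_replication = FALSE))
  h <- heritability(fit)
  expect_lt(h$h2, 0.05)
  expect_true(h$near_zero || h$h2 < 0.05)
})

test_that("eigen and dense EM paths agree on identical complete data", {
  tr <- simulate_pedigree(n_dams = 12, progeny_per_dam = 5,
                          pollen_pool_size = 10, contamination_rate = 0,
                          seed = 31)
  A <- compute_A(tr$true_pedigree)
  cfg <- trait_config(c("y1", "y2"), "S1", h2 = 0.4,
                      genetic_cor = matrix(c(1, .6, .6, 1), 2))
  ph <- simulate_phenotypes(tr, A, cfg, seed = 32)$phenotypes
  des <- opqg:::assemble_design(
    ph, data.frame(trait = c("y1", "y2"), site = "S1"), A, FALSE)
  ctrl <- reml_control(max_iter = 200)
  fe <- opqg:::fit_eigen(des, ctrl)
  fd <- opqg:::fit_dense(des, ctrl)
  expect_lt(max(abs(fe$Sigma_a - fd$Sigma_a)), 1e-10)
  expect_lt(max(abs(fe$Sigma_e - fd$Sigma_e)), 1e-10)
  expect_equal(fe$loglik, fd$loglik, tolerance = 1e-10)
})

test_that("estimates are invariant to permutation of the rows", {
  d <- sim_uni(20, 5, 0.5, 51)
  fit1 <- fit_univariate(d$ph, "y", d$A, site = "S1",
                         fit_replication = FALSE)
  set.seed(1)
  ph2 <- d$ph[sample(nrow(d$ph)), ]
  fit2 <- fit_univariate(ph2, "y", d$A, site = "S1",
                         fit_replication = FALSE)
  expect_equal(fit1$vc$Sigma_a, fit2$vc$Sigma_a, tolerance = 1e-8)
  expect_equal(fit1$vc$Sigma_e, fit2$vc$Sigma_e, tolerance = 1e-8)
})

test_that("the replication variance component is recovered", {
  tr <- simulate_pedigree(n_dams = 50, progeny_per_dam = 8,
                          contamination_rate = 0, seed = 61)
  A <- compute_A(tr$true_pedigree)
  cfg <- trait_config("y", "S1", h2 = 0.4, rep_sd = 0.5)
  ph <- simulate_phenotypes(tr, A, cfg, n_replications = 8,
                            seed = 62)$phenotypes
  fit <- suppressWarnings(
    fit_univariate(ph, "y", A, site = "S1", fit_replication = TRUE,
                   control = reml_control(max_iter = 800)))
  expect_true(fit$monotone)
  expect_gt(fit$vc$sigma2_d, 0.05)   # true 0.25, few levels: wide sampling
  expect_lt(fit$vc$sigma2_d, 1.0)
})

test_that("a duplicated trait gives genetic correlation near one", {
  d <- sim_uni(15, 6, 0.5, 71)
  ph <- d$ph
  set.seed(72)
  ph$y2 <- ph$y + rnorm(nrow(ph), 0, 0.02)
  fit <- suppressWarnings(fit_multivariate(
    ph, data.frame(trait = c("y", "y2"), site = "S1"), d$A,
    control = reml_control(max_iter = 500)))
  expect_gte(genetic_correlation(fit)$r_a, 0.99)
})

test_that("cross-site fits keep the residual covariance structurally zero", {
  tr <- simulate_pedigree(n_dams = 30, progeny_per_dam = 6,
                          contamination_rate = 0, seed = 81)
  A <- compute_A(tr$true_pedigree)
  cfg <- trait_config("y", c("S1", "S2"), h2 = 0.5,
                      genetic_cor = matrix(c(1, .5, .5, 1), 2))
  ph <- simulate_phenotypes(tr, A, cfg, seed = 82)$phenotypes
  # no tree is measured at both sites
  expect_equal(max(table(ph$tree)), 1L)
  fit <- suppressWarnings(fit_multivariate(
    ph, data.frame(trait = "y", site = c("S1", "S2")), A,
    control = reml_control(max_iter = 600)))
  expect_identical(fit$vc$Sigma_e[1, 2], 0)
  expect_true(fit$monotone)
  # the cross-site genetic correlation is still estimable
  expect_false(is.na(genetic_correlation(fit)$r_a))
})

test_that("BLUPs shrink and track true breeding values as expected", {
  # total shrinkage: near-zero genetic variance drives EBVs to zero
  d0 <- balanced_halfsib(50, 8, s2a = 0, s2e = 1, seed = 91)
  fit0 <- suppressWarnings(
    fit_univariate(d0$pheno, "y", compute_A(d0$ped), site = "S",
                   fit_replication = FALSE))
  expect_lt(sd(predict_blup(fit0)$ebv), 0.1 * sd(d0$pheno$y))

  # no shrinkage: with K = I and tiny residual, EBVs approach the
  # fixed-effect-adjusted phenotypes
  set.seed(91)
  ids <- sprintf("I%03d", 1:300)
  K <- relmat(diag(1, 300) |>
                (\(m) {dimnames(m) <- list(ids, ids); m})(), kind = "A")
  bv <- rnorm(300)
  ph1 <- data.frame(tree = ids, site = "S", replication = "R1",
                    group = "g", y = 5 + bv + rnorm(300, 0, 0.05))
  fit1 <- suppressWarnings(
    fit_univariate(ph1, "y", K, site = "S", fit_replication = FALSE))
  b <- predict_blup(fit1)
  expect_gt(cor(b$ebv, ph1$y - mean(ph1$y)), 0.99)

  # accuracy of EBVs rises with heritability (fixed seed)
  cors <- vapply(c(0.1, 0.5, 0.9), function(h2) {
    d <- sim_uni(40, 6, h2, 95)
    fit <- suppressWarnings(
      fit_univariate(d$ph, "y", d$A, site = "S1",
                     fit_replication = FALSE))
    b <- predict_blup(fit)
    tbv <- d$truth$true_breeding_values[, "y@S1"]
    cor(b$ebv[match(names(tbv), b$id)], tbv)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("AI-based standard errors match replicate-based SEs", {
  # one fixed relationship structure; phenotypes re-simulated per
  # replicate, so the SD of the estimates is the sampling SD the
  # reported asymptotic SE is meant to approximate
  tr <- simulate_pedigree(n_dams = 50, progeny_per_dam = 7,
                          pollen_pool_size = 50,
                          contamination_rate = 0, seed = 141)
  A <- compute_A(tr$true_pedigree)
  cfg <- trait_config("y", "S1", h2 = 0.5)
  est <- se <- numeric(100)
  for (s in seq_len(100)) {
    ph <- simulate_phenotypes(tr, A, cfg, seed = 1400 + s)$phenotypes
    fit <- suppressWarnings(
      fit_univariate(ph, "y", A, site = "S1", fit_replication = FALSE))
    h <- heritability(fit)
    est[s] <- h$h2; se[s] <- h$se
  }
  expect_lt(abs(mean(se) - sd(est)) / sd(est), 0.20)
})

test_that("model assembly rejects degenerate inputs", {
  d <- sim_uni(8, 3, 0.3, 99)
  expect_error(fit_univariate(d$ph, "nope", d$A, site = "S1"),
               "not in phenotype")
  expect_error(fit_univariate(d$ph, "y", d$A, site = "SX"),
               "zero observations")
  ph2 <- rbind(d$ph, d$ph[1, ])
  expect_error(fit_univariate(ph2, "y", d$A, site = "S1",
                              fit_replication = FALSE),
               "exactly one site|more than once")
  # relationship matrix must cover every phenotyped tree
  A2 <- relmat(unclass(d$A)[-1, -1], kind = "A")
  ph3 <- d$ph; ph3$tree[1] <- rownames(unclass(d$A))[1]
  small <- relmat(unclass(d$A)[1:2, 1:2], kind = "A")
  expect_error(fit_univariate(d$ph, "y", small, site = "S1"),
               "does not cover")
})
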