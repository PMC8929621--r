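test_that("simulate_pedigree builds the open-pollinated structure", {
  # zero contamination: every recorded dam is the true dam
  tr <- simulate_pedigree(n_dams = 10, progeny_per_dam = 4,
                          pollen_pool_size = 5, contamination_rate = 0,
                          seed = 1)
  rec <- tr$recorded_pedigree; tru <- tr$true_pedigree
  prog <- rec$id[!is.na(rec$dam)]
  expect_equal(rec$dam[match(prog, rec$id)],
               tru$dam[match(prog, tru$id)])
  expect_equal(nrow(tr$contamination_events), 0L)
  # recorded pedigree hides all sires; true pedigree has them
  expect_true(all(is.na(rec$sire)))
  expect_true(all(!is.na(tru$sire[match(prog, tru$id)])))

  # counting: 80 dams x 8 progeny = 640 progeny records
  tr2 <- simulate_pedigree(n_dams = 80, progeny_per_dam = 8, seed = 2)
  expect_equal(sum(!is.na(tr2$recorded_pedigree$dam)), 640L)

  # contamination fraction within 3 binomial SE at n = 1000
  tr3 <- simulate_pedigree(n_dams = 125, progeny_per_dam = 8,
                           contamination_rate = 0.3, seed = 3)
  frac <- nrow(tr3$contamination_events) / 1000
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  expect_error(simulate_pedigree(contamination_rate = 1.5), "rate")
})

test_that("generators replay byte-identically under the same seed", {
  a <- simulate_pedigree(n_dams = 12, progeny_per_dam = 3, seed = 9)
  b <- simulate_pedigree(n_dams = 12, progeny_per_dam = 3, seed = 9)
  expect_identical(a, b)
  ga <- simulate_genotypes(a, n_snps = 100, missing_rate = 0.2, seed = 4)
  gb <- simulate_genotypes(b, n_snps = 100, missing_rate = 0.2, seed = 4)
  expect_identical(unclass(ga), unclass(gb))
  ra <- simulate_ring_series(a, seed = 5)
  rb <- simulate_ring_series(b, seed = 5)
  expect_identical(ra, rb)
})

test_that("gene dropping respects Mendelian transmission", {
  # single dam x single sire, many progeny
  tr <- simulate_pedigree(n_dams = 1, progeny_per_dam = 400,
                          pollen_pool_size = 1, contamination_rate = 0,
                          seed = 6)
  gm <- simulate_genotypes(tr, n_snps = 300, seed = 7)
  M <- unclass(gm)
  prog <- tr$recorded_pedigree$id[!is.na(tr$recorded_pedigree$dam)]
  mid <- (M["D001", ] + M["S001", ]) / 2
  # fixed case: both parents dosage 0 forces offspring dosage 0
  zero <- which(M["D001", ] == 0 & M["S001", ] == 0)
  expect_true(length(zero) > 0)
  expect_true(all(M[prog, zero] == 0))
  # per-locus offspring mean approximates the mid-parent value (3 SE)
  off_mean <- colMeans(M[prog, ])
  se <- sqrt(pmax(mid * (2 - mid), 1e-9) / (2 * length(prog)))
  expect_gt(mean(abs(off_mean - mid) <= 3 * se + 1e-12), 0.98)
})

test_that("gene-dropped relatedness converges to pedigree expectations", {
  tr <- simulate_pedigree(n_dams = 15, progeny_per_dam = 5,
                          pollen_pool_size = 20, contamination_rate = 0,
                          seed = 8)
  gm <- simulate_genotypes(tr, n_snps = 5000, seed = 9)
  G <- compute_G(gm)
  tru <- tr$true_pedigree
  prog <- tru$id[!is.na(tru$dam)]
  po <- cbind(prog, tru$dam[match(prog, tru$id)])
  expect_lt(mean(abs(unclass(G)[po] - 0.5)), 0.03)
})

test_that("phenotype generator reproduces the requested covariances", {
  ids <- sprintf("I%04d", 1:2000)
  K <- relmat(diag(1, 2000) |>
                (\(m) {dimnames(m) <- list(ids, ids); m})(), kind = "A")
  tr <- simulate_pedigree(n_dams = 4, progeny_per_dam = 2, seed = 10)
  cfg <- trait_config(c("u", "v"), "S1", h2 = 0.36,
                      genetic_cor = matrix(c(1, 0.9, 0.9, 1), 2))
  sp <- simulate_phenotypes(tr, K, cfg,
                            site_assignment = setNames(rep("S1", 2000),
                                                       ids),
                            seed = 11)
  bv <- sp$truth$true_breeding_values
  # sample variance of breeding values near sigma2_a = h2 (3 SE)
  se_var <- 0.36 * sqrt(2 / 1999)
  expect_lt(abs(var(bv[, "u@S1"]) - 0.36), 3 * se_var)
  # correlation of true breeding values near 0.9
  expect_lt(abs(cor(bv[, "u@S1"], bv[, "v@S1"]) - 0.9), 0.05)
  # regression of phenotype on breeding value has slope ~ 1
  ph <- sp$phenotypes
  sl <- coef(lm(ph$u ~ bv[match(ph$tree, rownames(bv)), "u@S1"]))[2]
  expect_lt(abs(sl - 1), 3 * sqrt((1 - 0.36) / (2000 * 0.36)))
})

test_that("zero heritability produces no family signal", {
  tr <- simulate_pedigree(n_dams = 40, progeny_per_dam = 10,
                          contamination_rate = 0, seed = 12)
  A <- compute_A(tr$recorded_pedigree)
  cfg <- trait_config("y", "S1", h2 = 0)
  sp <- simulate_phenotypes(tr, A, cfg, seed = 13)
  ph <- sp$phenotypes
  fam <- tr$recorded_pedigree$dam[match(ph$tree, tr$recorded_pedigree$id)]
  av <- anova(lm(ph$y ~ fam))
  s2_fam <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / 10
  expect_lt(abs(s2_fam), 0.05)
  expect_true(all(abs(sp$truth$true_breeding_values) < 1e-12))
})

test_that("ring-series generator matches its drought calibration", {
  tr <- simulate_pedigree(n_dams = 60, progeny_per_dam = 8, seed = 14)
  # no drought and no noise: resistance exactly 1 for every tree
  rs0 <- simulate_ring_series(tr, drought_severity = 0,
                              sensitivity_noise = 0, year_sd = 0,
                              seed = 15)
  expect_equal(unname(sapply(rs0, resistance)), rep(1, length(rs0)))
  # default severity: population mean resistance near the observed 0.57
  rs <- simulate_ring_series(tr, seed = 16)
  expect_lt(abs(mean(sapply(rs, resistance)) - 0.57), 0.05)
  # mean sensitivity strictly increases with the noise level
  m <- sapply(c(0.05, 0.18, 0.45), function(s) {
    mean(sapply(simulate_ring_series(tr, sensitivity_noise = s, seed = 17),
                mean_sensitivity))
  })
  expect_true(all(diff(m) > 0))
  expect_error(simulate_ring_series(tr, years = integer(0)), "empty")
  expect_error(simulate_ring_series(tr, drought_year = 1900), "outside")
})

test_that("degrade_pedigree swaps the requested fraction of dams", {
  tr <- simulate_pedigree(n_dams = 80, progeny_per_dam = 8,
                          contamination_rate = 0, seed = 18)
  # zero rate: identical pedigree
  d0 <- degrade_pedigree(tr, error_rate = 0, seed = 19)
  expect_equal(as.data.frame(d0$pedigree),
               as.data.frame(tr$recorded_pedigree))
  # rate 1 with two families: every dam label becomes the other dam
  tr2 <- simulate_pedigree(n_dams = 2, progeny_per_dam = 5,
                           contamination_rate = 0, seed = 20)
  d2 <- degrade_pedigree(tr2, error_rate = 1, seed = 21)
  rec <- tr2$recorded_pedigree
  prog <- rec$id[!is.na(rec$dam)]
  old <- rec$dam[match(prog, rec$id)]
  new <- d2$pedigree$dam[match(prog, d2$pedigree$id)]
  expect_true(all(new != old))
  # swap count within the binomial 99% interval at rate 0.05, n = 640
  d3 <- degrade_pedigree(tr, error_rate = 0.05, seed = 22)
  expect_true(abs(nrow(d3$swaps) - 32) <= qnorm(0.995) *
                sqrt(640 * 0.05 * 0.95) + 1)
  expect_error(degrade_pedigree(tr, error_rate = 2), "error_rate")
})
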