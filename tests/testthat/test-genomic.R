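make_gm <- function(M, ids = sprintf("I%d", seq_len(nrow(M)))) {
  rownames(M) <- ids
  genotype_matrix(M)
}

test_that("filter_genotypes applies inclusive missingness and MAC rules", {
  # 100 individuals: locus missing in exactly 30% retained, 31% removed
  n <- 100
  M <- matrix(rep(c(0, 1, 2, 1), length.out = 4 * n), n, 4)
  M[seq_len(30), 1] <- NA   # 30% missing -> kept
  M[seq_len(31), 2] <- NA   # 31% missing -> dropped
  M[, 4] <- 0               # monomorphic -> dropped at min_mac = 1
  gm <- make_gm(M)
  out <- filter_genotypes(gm)
  expect_setequal(colnames(out), c("L1", "L3"))

  # complete polymorphic matrix passes unchanged
  M2 <- matrix(c(0, 1, 2, 1, 0, 2), 3, 2)
  expect_equal(dim(filter_genotypes(make_gm(M2))), c(3L, 2L))

  # toy 5 x 4 with a constructed pattern: hand-enumerated survivors
  M3 <- rbind(c(NA, 0, 0, 1), c(NA, 0, 2, NA), c(NA, 0, 1, 0),
              c(0, 0, NA, 1), c(1, 0, 2, 2))
  # L1: 60% missing (out); L2 monomorphic (out); L3 20% missing, poly (in);
  # L4 20% missing, poly (in)
  expect_setequal(colnames(filter_genotypes(make_gm(M3), 0.30, 1)),
                  c("L3", "L4"))
  expect_error(filter_genotypes(make_gm(matrix(0, 3, 2))), "no loci")
})

test_that("impute_mean fills missing with locus means and changes nothing else", {
  gm <- make_gm(matrix(c(0, 2, NA, 1, 1, 1), 3, 2))
  out <- impute_mean(gm)
  expect_identical(unclass(out)[3, 1], 1.0)      # mean of (0, 2)
  expect_identical(unclass(out)[, 2], unclass(gm)[, 2])
  # per-locus means are preserved by imputation
  expect_equal(colMeans(unclass(out)), colMeans(unclass(gm), na.rm = TRUE),
               ignore_attr = TRUE)
  # identity on complete data
  gm2 <- make_gm(matrix(c(0, 1, 2, 2, 1, 0), 3, 2))
  expect_equal(unclass(impute_mean(gm2)), unclass(gm2), ignore_attr = TRUE)
})

test_that("compute_G reproduces the VanRaden form", {
  # hand computation: M = [[0,2],[2,0]], p = (0.5, 0.5), denom = 1
  gm <- make_gm(matrix(c(0, 2, 2, 0), 2, 2))
  G <- compute_G(gm)
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2, 2),
               ignore_attr = TRUE)

  # all-heterozygous matrix: W = 0 so G = 0
  gm2 <- make_gm(matrix(1, 4, 3))
  expect_equal(max(abs(compute_G(gm2, freq_source = "provided",
                                 p = c(0.5, 0.5, 0.5)))), 0)

  # with sample frequencies columns of W sum to zero: grand sum of G is 0
  set.seed(5)
  gm3 <- make_gm(matrix(rbinom(50 * 40, 2, 0.3), 50, 40))
  expect_lt(abs(sum(compute_G(gm3))), 1e-8)

  expect_error(compute_G(make_gm(matrix(c(0, NA), 1, 2))), "impute")
})

test_that("stabilize_G yields an invertible matrix", {
  set.seed(6)
  gm <- make_gm(matrix(rbinom(30 * 50, 2, 0.4), 30, 50))
  G <- compute_G(gm)
  # ridge 0 on an already-PD matrix is the identity transform
  Gpd <- relmat(unclass(G) + diag(0.5, 30), kind = "G")
  expect_equal(unclass(stabilize_G(Gpd, "ridge", 0)), unclass(Gpd))
  # blend weight 1 returns G
  A <- relmat(diag(1, 30, 30) |>
                (\(m) {dimnames(m) <- dimnames(G); m})(), kind = "A")
  expect_equal(unclass(stabilize_G(G, "blend_with_A", 1, A)), unclass(G),
               ignore_attr = TRUE)
  # duplicated individuals make G singular; ridge restores a floor
  M <- matrix(rbinom(10 * 60, 2, 0.4), 10, 60)
  Gdup <- compute_G(make_gm(rbind(M, M)))
  ev <- eigen(unclass(stabilize_G(Gdup, "ridge", 1e-6)),
              symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-6 * (1 - 1e-9))
  expect_error(stabilize_G(G, "blend_with_A", 0.5, relmat(diag(2) |>
    (\(m) {dimnames(m) <- list(c("a", "b"), c("a", "b")); m})(), "A")),
    "conformable")
})

test_that("filtering and imputing commute with individual reordering", {
  set.seed(7)
  M <- matrix(rbinom(20 * 30, 2, 0.3), 20, 30)
  M[runif(length(M)) < 0.2] <- NA
  gm <- make_gm(M)
  perm <- sample(nrow(M))
  gmp <- make_gm(unclass(gm)[perm, , drop = FALSE],
                 ids = rownames(gm)[perm])
  a <- impute_mean(filter_genotypes(gm))
  b <- impute_mean(filter_genotypes(gmp))
  expect_equal(unclass(b), unclass(a)[perm, colnames(b), drop = FALSE],
               ignore_attr = TRUE)
})

test_that("detect_conflicts flags deviations from class expectations", {
  ped <- validate_and_order(pedigree(
    c("D", "X", "Y"), dam = c(NA, "D", "D")))
  # a "genomic" matrix equal to pedigree expectations raises nothing
  G0 <- relmat(unclass(compute_A(ped)), kind = "G")
  expect_equal(nrow(detect_conflicts(ped, G0)), 0L)

  # recorded half-sibs with g = 0.49 deviate by 0.24 > 0.15: flagged
  Gm <- unclass(compute_A(ped))
  Gm["X", "Y"] <- Gm["Y", "X"] <- 0.49
  conf <- detect_conflicts(ped, relmat(Gm, "G"))
  sib <- conf[conf$check == "sib", ]
  expect_equal(nrow(sib), 1L)
  expect_equal(sib$deviation, 0.24)

  # offspring unrelated to its recorded dam: parent check fires
  Gm2 <- unclass(compute_A(ped))
  Gm2["X", "D"] <- Gm2["D", "X"] <- 0
  conf2 <- detect_conflicts(ped, relmat(Gm2, "G"))
  expect_true(any(conf2$check == "parent" & conf2$id1 == "X"))
  expect_error(detect_conflicts(ped, relmat(diag(1) |>
    (\(m) {dimnames(m) <- list("Q", "Q"); m})(), "G")), "no shared ids")
})

test_that("correct_pedigree reassigns to the unique in-window candidate", {
  ped <- validate_and_order(pedigree(
    c("D1", "D2", "X", "Y"), dam = c(NA, NA, "D1", "D2")))
  Gm <- diag(1, 4)
  dimnames(Gm) <- list(ped$id, ped$id)
  Gm["X", "D1"] <- Gm["D1", "X"] <- 0    # conflict with recorded dam
  Gm["X", "D2"] <- Gm["D2", "X"] <- 0.5  # clear candidate
  Gm["Y", "D2"] <- Gm["D2", "Y"] <- 0.5  # consistent record
  G <- relmat(Gm, "G")
  conf <- detect_conflicts(ped, G)
  out <- correct_pedigree(ped, G, conf)
  expect_equal(out$pedigree$dam[out$pedigree$id == "X"], "D2")
  expect_equal(unname(out$counts["reassigned"]), 1L)

  # no conflicts: pedigree unchanged
  G0 <- relmat(unclass(compute_A(ped)), "G")
  out0 <- correct_pedigree(ped, G0, detect_conflicts(ped, G0))
  expect_equal(as.data.frame(out0$pedigree)[, 1:3],
               as.data.frame(ped)[, 1:3])

  # no candidate anywhere: a phantom parent is created
  Gm3 <- diag(1, 4)
  dimnames(Gm3) <- list(ped$id, ped$id)
  Gm3["Y", "D2"] <- Gm3["D2", "Y"] <- 0.5
  G3 <- relmat(Gm3, "G")
  out3 <- correct_pedigree(ped, G3, detect_conflicts(ped, G3))
  expect_equal(unname(out3$counts["phantom_parents"]), 1L)
  expect_true(any(grepl("^PH", out3$pedigree$id)))
})

test_that("injected dam errors are detected and corrected on simulation", {
  tr <- simulate_pedigree(n_dams = 30, progeny_per_dam = 6,
                          pollen_pool_size = 40, contamination_rate = 0,
                          seed = 41)
  deg <- degrade_pedigree(tr, error_rate = 0.08, seed = 42)
  gm <- impute_mean(filter_genotypes(
    simulate_genotypes(tr, n_snps = 2000, missing_rate = 0.1, seed = 43)))
  G <- compute_G(gm)
  conf <- detect_conflicts(deg$pedigree, G)
  pc <- conf[conf$check == "parent", ]
  wrong <- deg$swaps$offspring
  prog <- tr$recorded_pedigree$id[!is.na(tr$recorded_pedigree$dam)]
  expect_gte(mean(wrong %in% pc$id1), 0.9)                   # sensitivity
  expect_lte(mean(setdiff(prog, wrong) %in% pc$id1), 0.05)   # FPR
  out <- correct_pedigree(deg$pedigree, G, conf)
  restored <- out$pedigree$dam[match(wrong, out$pedigree$id)] ==
    tr$true_pedigree$dam[match(wrong, tr$true_pedigree$id)]
  expect_gte(mean(restored), 0.9)
})
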