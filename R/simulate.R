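# All generators draw from one seeded RNG per call and restore the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Simulate an open-pollinated progeny pedigree with known truth
#'
#' Emulates an open-pollinated progeny trial: each dam produces
#' `progeny_per_dam` offspring whose true sires are drawn at random from
#' a finite pollen pool (selfing excluded), so true full-sibs can arise
#' within nominally half-sib families. The recorded (field) pedigree
#' hides all sires, and with probability `contamination_rate` a
#' progeny's recorded dam is replaced by a wrong dam; every such error
#' is logged in `contamination_events`.
#'
#' @param n_dams number of maternal founders (default 80, a typical
#'   open-pollinated trial series).
#' @param progeny_per_dam offspring per dam (default 8).
#' @param pollen_pool_size number of paternal founders (default 100).
#' @param contamination_rate probability a recorded dam is wrong
#'   (default 0.05).
#' @param n_provenances number of genetic groups the dams are assigned
#'   to (default 3).
#' @param seed integer seed.
#' @return An `opqg_truth` list: `true_pedigree`, `recorded_pedigree`,
#'   `contamination_events` (offspring, recorded_dam, true_dam), `seed`.
#' @export
simulate_pedigree <- function(n_dams = 80, progeny_per_dam = 8,
                              pollen_pool_size = 100,
                              contamination_rate = 0.05,
                              n_provenances = 3, seed = 1) {
  stopifnot(n_dams >= 1, progeny_per_dam >= 1, pollen_pool_size >= 1)
  if (contamination_rate < 0 || contamination_rate > 1) {
    stop("contamination_rate must lie in [0, 1]")
  }
  with_seed(seed, {
    dams <- sprintf("D%03d", seq_len(n_dams))
    sires <- sprintf("S%03d", seq_len(pollen_pool_size))
    dam_group <- sample(sprintf("P%d", seq_len(n_provenances)),
                        n_dams, replace = TRUE)
    n_off <- n_dams * progeny_per_dam
    off <- sprintf("T%04d", seq_len(n_off))
    true_dam <- rep(dams, each = progeny_per_dam)
    true_sire <- sample(sires, n_off, replace = TRUE)
    wrong <- stats::runif(n_off) < contamination_rate & n_dams > 1
    rec_dam <- true_dam
    for (k in which(wrong)) {
      rec_dam[k] <- sample(setdiff(dams, true_dam[k]), 1)
    }
    grp <- dam_group[match(rec_dam, dams)]
    true_ped <- validate_and_order(pedigree(
      id = c(dams, sires, off),
      sire = c(rep(NA, n_dams + pollen_pool_size), true_sire),
      dam = c(rep(NA, n_dams + pollen_pool_size), true_dam),
      group = c(dam_group, rep(NA, pollen_pool_size), grp)))
    rec_ped <- validate_and_order(pedigree(
      id = c(dams, off),
      sire = NA,
      dam = c(rep(NA, n_dams), rec_dam),
      group = c(dam_group, grp)))
    ev <- data.frame(offspring = off[wrong], recorded_dam = rec_dam[wrong],
                     true_dam = true_dam[wrong], stringsAsFactors = FALSE)
    structure(list(true_pedigree = true_ped, recorded_pedigree = rec_ped,
                   contamination_events = ev,
                   true_variance_components = NULL,
                   true_breeding_values = NULL, seed = seed),
              class = "opqg_truth")
  })
}

#' @export
print.opqg_truth <- function(x, ...) {
  cat(sprintf(
    "<opqg_truth> %d individuals, %d dam-record errors, seed %d\n",
    nrow(x$true_pedigree), nrow(x$contamination_events), x$seed))
  invisible(x)
}

#' Gene-drop SNP genotypes through the true pedigree
#'
#' Founder alternative-allele frequencies are drawn uniform on
#' `[maf_low, maf_high]`; founders are sampled in Hardy-Weinberg
#' equilibrium and every non-founder receives one allele per parent per
#' locus (gene dropping, loci independent). Missing entries are masked
#' completely at random at `missing_rate`.
#'
#' @param truth an `opqg_truth` from [simulate_pedigree()].
#' @param n_snps number of biallelic loci.
#' @param maf_low,maf_high founder allele-frequency range,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param missing_rate proportion of dosages masked as missing.
#' @param seed integer seed.
#' @return An [genotype_matrix()] over all pedigree individuals.
#' @export
simulate_genotypes <- function(truth, n_snps = 3000, maf_low = 0.05,
                               maf_high = 0.5, missing_rate = 0,
                               seed = 1) {
  stopifnot(inherits(truth, "opqg_truth"),
            maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  ped <- truth$true_pedigree
  with_seed(seed, {
    n <- nrow(ped); m <- n_snps
    p <- stats::runif(m, maf_low, maf_high)
    idx <- stats::setNames(seq_len(n), ped$id)
    si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
    di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
    H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      H1[i, ] <- if (si[i] > 0L) {
        pick <- stats::runif(m) < 0.5
        ifelse(pick, H1[si[i], ], H2[si[i], ])
      } else as.integer(stats::runif(m) < p)
      H2[i, ] <- if (di[i] > 0L) {
        pick <- stats::runif(m) < 0.5
        ifelse(pick, H1[di[i], ], H2[di[i], ])
      } else as.integer(stats::runif(m) < p)
    }
    M <- H1 + H2
    storage.mode(M) <- "double"
    dimnames(M) <- list(ped$id, sprintf("SNP%05d", seq_len(m)))
    if (missing_rate > 0) {
      M[stats::runif(length(M)) < missing_rate] <- NA_real_
    }
    genotype_matrix(M)
  })
}

#' Trait-simulation configuration
#'
#' Parameterizes the multivariate generative model: response list
#' (trait-by-site combinations), target narrow-sense heritabilities,
#' the genetic correlation matrix across responses, site means,
#' replication-effect SD and per-trait log-normal flags. Phenotypic
#' variance is 1 per response on the latent scale, so the genetic
#' variance of a response is its h-squared and its residual variance
#' 1 - h-squared.
#'
#' @param traits character vector of trait names.
#' @param sites character vector of site names.
#' @param h2 heritability per response: a single value, a vector over
#'   traits, or a traits-by-sites matrix. All in [0, 1].
#' @param genetic_cor genetic correlation matrix across the
#'   `length(traits) * length(sites)` responses (trait fastest), or a
#'   single exchangeable correlation value. Must be symmetric PSD with
#'   unit diagonal.
#' @param site_mean mean per trait (added to every site).
#' @param rep_sd replication-effect SD (default 0.25).
#' @param lognormal logical per trait: simulate on the log scale and
#'   exponentiate (for traits analysed after log transform).
#' @param missing_rate per-trait probability a phenotype is missing
#'   completely at random (default 0).
#' @return An `opqg_trait_config` list with the expanded `Sigma_a`.
#' @export
trait_config <- function(traits, sites, h2 = 0.3, genetic_cor = 0,
                         site_mean = 0, rep_sd = 0.25,
                         lognormal = FALSE, missing_rate = 0) {
  nt <- length(traits); ns <- length(sites); nr <- nt * ns
  H <- matrix(rep_len(h2, nr), nt, ns)
  if (any(H < 0 | H > 1)) stop("heritabilities must lie in [0, 1]")
  R <- if (is.matrix(genetic_cor)) genetic_cor else {
    Rm <- matrix(genetic_cor, nr, nr); diag(Rm) <- 1; Rm
  }
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
    stop("genetic_cor must be symmetric with unit diagonal")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("genetic_cor is not positive semidefinite")
  }
  responses <- as.vector(outer(traits, sites, paste, sep = "@"))
  sa <- sqrt(as.vector(H))
  Sigma_a <- outer(sa, sa) * R
  dimnames(Sigma_a) <- list(responses, responses)
  structure(list(traits = traits, sites = sites, responses = responses,
                 h2 = H, Sigma_a = Sigma_a,
                 site_mean = rep_len(site_mean, nt),
                 rep_sd = rep_sd,
                 lognormal = rep_len(lognormal, nt),
                 missing_rate = rep_len(missing_rate, nt)),
            class = "opqg_trait_config")
}

# symmetric PSD square root via eigen decomposition
mat_sqrt <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate multi-trait multi-site phenotypes with known breeding values
#'
#' Breeding values over all individuals of the relationship matrix are
#' drawn multivariate normal with covariance `Sigma_a (x) K` (Kronecker
#' product); replication effects are iid normal within site; residuals
#' are independent across responses with zero cross-site covariance.
#' Every tree is phenotyped at exactly one site, for all traits of the
#' configuration (subject to the configured missing rate).
#'
#' @param truth an `opqg_truth`; its recorded pedigree supplies genetic
#'   groups, and the truth object is returned updated with
#'   `true_variance_components` and `true_breeding_values`.
#' @param relationship an `opqg_relmat` covering all phenotyped trees
#'   (typically `compute_A(truth$true_pedigree)`).
#' @param config an [trait_config()].
#' @param site_assignment named character vector tree id -> site; by
#'   default all progeny (individuals with a recorded dam) are split
#'   evenly across the configured sites.
#' @param n_replications replications per site (trees assigned at
#'   random), or a named vector tree id -> replication label.
#' @param seed integer seed.
#' @return A list: `phenotypes` (data.frame tree, site, replication,
#'   group, one column per trait), `truth` (updated).
#' @export
simulate_phenotypes <- function(truth, relationship, config,
                                site_assignment = NULL,
                                n_replications = 4, seed = 1) {
  stopifnot(inherits(truth, "opqg_truth"),
            inherits(relationship, "opqg_relmat"),
            inherits(config, "opqg_trait_config"))
  rec <- truth$recorded_pedigree
  with_seed(seed, {
    if (is.null(site_assignment)) {
      prog <- rec$id[!is.na(rec$dam)]
      site_assignment <- stats::setNames(
        sample(rep_len(config$sites, length(prog))), prog)
    }
    trees <- names(site_assignment)
    if (!all(trees %in% rownames(relationship))) {
      stop("relationship matrix does not cover all phenotyped trees")
    }
    ids <- rownames(relationship)
    nr <- length(config$responses)
    # a ~ N(0, Sigma_a (x) K):  L_K Z L_Sigma'
    LK <- mat_sqrt(unclass(relationship))
    LS <- mat_sqrt(config$Sigma_a)
    bv <- LK %*% matrix(stats::rnorm(length(ids) * nr), length(ids), nr) %*%
      t(LS)
    dimnames(bv) <- list(ids, config$responses)

    reps <- if (length(n_replications) == 1 && is.numeric(n_replications)) {
      stats::setNames(paste0("R", sample.int(n_replications, length(trees),
                                             replace = TRUE)), trees)
    } else stats::setNames(as.character(n_replications), names(n_replications))
    rep_eff <- stats::rnorm(length(unique(paste(site_assignment,
                                                reps[trees]))),
                            0, config$rep_sd)
    names(rep_eff) <- unique(paste(site_assignment, reps[trees]))

    grp <- rec$group[match(trees, rec$id)]
    out <- data.frame(tree = trees, site = unname(site_assignment[trees]),
                      replication = unname(reps[trees]),
                      group = grp, stringsAsFactors = FALSE)
    nt <- length(config$traits)
    for (ti in seq_len(nt)) {
      tr <- config$traits[ti]
      resp <- paste(tr, out$site, sep = "@")
      h2r <- config$h2[ti, match(out$site, config$sites)]
      e <- stats::rnorm(nrow(out), 0, sqrt(pmax(1 - h2r, 0)))
      y <- config$site_mean[ti] + rep_eff[paste(out$site, out$replication)] +
        bv[cbind(out$tree, resp)] + e
      if (config$lognormal[ti]) y <- exp(y)
      if (config$missing_rate[ti] > 0) {
        y[stats::runif(length(y)) < config$missing_rate[ti]] <- NA_real_
      }
      out[[tr]] <- unname(y)
    }
    truth$true_variance_components <- list(
      Sigma_a = config$Sigma_a,
      Sigma_e = diag(pmax(1 - as.vector(config$h2), 0),
                     nr, nr),
      sigma2_d = config$rep_sd^2)
    truth$true_breeding_values <- bv
    list(phenotypes = out, truth = truth)
  })
}

#' Simulate tree-ring BAI series with a drought year
#'
#' Per-tree basal area increment series with a tree-specific level,
#' log-normal year-to-year noise (`sensitivity_noise`), a common annual
#' signal, and a multiplicative drought-year dip
#' `1 - severity * deviate`, where the per-tree resistance deviate has
#' mean 1, a maternal-family genetic component, and coefficient of
#' variation `resistance_cv`. At the defaults (severity 0.43, CV 0.326)
#' the population mean and SD of the resistance index match a typical
#' observed 0.57 (SD 0.14) drought response.
#'
#' @param truth an `opqg_truth` (maternal families structure the
#'   genetic resistance deviates).
#' @param years year range (default 1995:2016).
#' @param drought_year drought year within `years` (default 2015).
#' @param drought_severity expected proportional BAI reduction in the
#'   drought year, in (0, 1]; the `0` limit (with zero noise) gives
#'   resistance exactly 1.
#' @param sensitivity_noise SD of per-tree log BAI year noise
#'   (default 0.18, giving mean sensitivity near 0.23).
#' @param year_sd SD of the common log-scale annual signal.
#' @param resistance_cv coefficient of variation of the resistance
#'   deviate.
#' @param mean_bai population mean BAI level (area units).
#' @param seed integer seed.
#' @return A named list of [ring_series()] (one per progeny), with the
#'   per-tree drought multipliers in attribute `drought_multiplier`.
#' @export
simulate_ring_series <- function(truth, years = 1995:2016,
                                 drought_year = 2015,
                                 drought_severity = 0.43,
                                 sensitivity_noise = 0.18,
                                 year_sd = 0.05, resistance_cv = 0.326,
                                 mean_bai = 500, seed = 1) {
  stopifnot(inherits(truth, "opqg_truth"))
  if (!length(years)) stop("empty year range")
  if (!(drought_year %in% years)) stop("drought_year outside years")
  if (drought_severity < 0 || drought_severity > 1) {
    stop("drought_severity must lie in (0, 1]")
  }
  rec <- truth$recorded_pedigree
  trees <- rec$id[!is.na(rec$dam)]
  fam <- rec$dam[match(trees, rec$id)]
  with_seed(seed, {
    # deviate = 1 + genetic(family) + individual, CV split half-half
    fam_z <- stats::rnorm(length(unique(fam)))
    names(fam_z) <- unique(fam)
    z <- sqrt(0.5) * fam_z[fam] + sqrt(0.5) * stats::rnorm(length(trees))
    deviate <- 1 + resistance_cv * z
    mult <- pmax(1 - drought_severity * deviate, 0.02)
    names(mult) <- trees
    year_eff <- exp(stats::rnorm(length(years), 0, year_sd))
    level <- mean_bai * exp(stats::rnorm(length(trees), 0, 0.3))
    out <- lapply(seq_along(trees), function(i) {
      b <- level[i] * year_eff *
        exp(stats::rnorm(length(years), 0, sensitivity_noise))
      b[years == drought_year] <- b[years == drought_year] * mult[i]
      ring_series(trees[i], years, b)
    })
    names(out) <- trees
    attr(out, "drought_multiplier") <- mult
    out
  })
}

#' Inject dam-record errors into the recorded pedigree
#'
#' Returns a degraded field pedigree in which each progeny's dam label
#' is, with probability `error_rate`, swapped to a different family's
#' dam. The swap list is stored in the returned truth object
#' (`degrade_events`).
#'
#' @param truth an `opqg_truth`.
#' @param error_rate per-progeny swap probability in [0, 1].
#' @param seed integer seed.
#' @return A list: `pedigree` (degraded), `swaps` (offspring, old_dam,
#'   new_dam), `truth` (updated).
#' @export
degrade_pedigree <- function(truth, error_rate = 0.05, seed = 1) {
  stopifnot(inherits(truth, "opqg_truth"))
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  rec <- truth$recorded_pedigree
  with_seed(seed, {
    prog <- which(!is.na(rec$dam))
    dams <- unique(rec$dam[prog])
    hit <- prog[stats::runif(length(prog)) < error_rate & length(dams) > 1]
    new_dam <- rec$dam
    for (k in hit) new_dam[k] <- sample(setdiff(dams, rec$dam[k]), 1)
    swaps <- data.frame(offspring = rec$id[hit], old_dam = rec$dam[hit],
                        new_dam = new_dam[hit], stringsAsFactors = FALSE)
    ped <- validate_and_order(pedigree(rec$id, rec$sire, new_dam, rec$group))
    truth$degrade_events <- swaps
    list(pedigree = ped, swaps = swaps, truth = truth)
  })
}
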