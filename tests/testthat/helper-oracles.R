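# Independent oracles used to cross-check the package's A-matrix and
# REML code. These deliberately share no code with the implementation:
# the kinship oracle is a direct recursive-coancestry memoisation, the
# gene-dropping oracle a Monte-Carlo identity-by-descent simulation.

# recursive coancestry: A = 2 * phi, phi(i,i) = (1 + phi(s,d)) / 2,
# phi(i,j) = (phi(s_i, j) + phi(d_i, j)) / 2 for i after j
coancestry_oracle_A <- function(ped) {
  ped <- validate_and_order(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      a <- max(i, j); b <- min(i, j)  # a is later in topological order
      0.5 * (phi(si[a], b) + phi(di[a], b))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# Monte-Carlo gene dropping: founders carry unique allele labels, each
# offspring inherits one random allele per parent; A is estimated from
# the IBD sharing of randomly drawn alleles (2 * estimated coancestry,
# diagonal 1 + estimated inbreeding). Returns the estimate and its
# per-cell Monte-Carlo standard error.
gene_drop_oracle_A <- function(ped, n_drops = 20000) {
  ped <- validate_and_order(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  H1 <- matrix(0L, n_drops, n); H2 <- matrix(0L, n_drops, n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) {
      pick <- runif(n_drops) < 0.5
      H1[, i] <- ifelse(pick, H1[, si[i]], H2[, si[i]])
    } else H1[, i] <- 2L * i - 1L
    if (di[i] > 0L) {
      pick <- runif(n_drops) < 0.5
      H2[, i] <- ifelse(pick, H1[, di[i]], H2[, di[i]])
    } else H2[, i] <- 2L * i
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  SE <- A
  for (i in seq_len(n)) for (j in seq_len(i)) {
    share <- ((H1[, i] == H1[, j]) + (H1[, i] == H2[, j]) +
                (H2[, i] == H1[, j]) + (H2[, i] == H2[, j])) / 4
    if (i == j) {
      f <- H1[, i] == H2[, i]
      A[i, i] <- 1 + mean(f)
      SE[i, i] <- sd(f) / sqrt(n_drops)
    } else {
      A[i, j] <- A[j, i] <- 2 * mean(share)
      SE[i, j] <- SE[j, i] <- 2 * sd(share) / sqrt(n_drops)
    }
  }
  list(A = A, SE = SE)
}

# random pedigree with arbitrary (possibly inbred) structure
random_pedigree <- function(n, p_parent = 0.7) {
  id <- sprintf("I%02d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2 && runif(1) < p_parent) {
      pr <- sample(i - 1L, 2)
      sire[i] <- id[pr[1]]
      dam[i] <- id[pr[2]]
    }
  }
  validate_and_order(pedigree(id, sire, dam))
}

# balanced one-way half-sib dataset + ANOVA method-of-moments estimates
balanced_halfsib <- function(n_dams, k, s2a, s2e, seed) {
  set.seed(seed)
  dams <- sprintf("D%03d", seq_len(n_dams))
  off <- sprintf("T%04d", seq_len(n_dams * k))
  ped <- validate_and_order(
    pedigree(c(dams, off), dam = c(rep(NA, n_dams), rep(dams, each = k))))
  fam <- rnorm(n_dams, 0, sqrt(s2a / 4))
  y <- rep(fam, each = k) + rnorm(n_dams * k, 0, sqrt(0.75 * s2a + s2e))
  pheno <- data.frame(tree = off, site = "S", replication = "R1",
                      group = "g", y = y, stringsAsFactors = FALSE)
  m <- tapply(y, rep(dams, each = k), mean)
  MSB <- k * var(m)
  MSW <- sum((y - rep(m, each = k))^2) / (n_dams * (k - 1))
  s2B <- (MSB - MSW) / k
  list(ped = ped, pheno = pheno,
       anova_s2a = 4 * s2B, anova_s2e = MSW - 3 * s2B)
}
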