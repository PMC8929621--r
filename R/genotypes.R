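#' Genotype dosage matrix
#'
#' Individuals-by-loci matrix of alternative-allele dosages coded 0, 1, 2
#' (`NA` for missing before imputation; real-valued after mean
#' imputation).
#'
#' @param M numeric matrix, rows individuals, columns loci, with dimnames.
#' @param imputed logical, whether missing entries have been imputed.
#' @return An `opqg_genotypes` object.
#' @export
genotype_matrix <- function(M, imputed = FALSE) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("L", seq_len(ncol(M)))
  rng <- range(M, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  structure(M, imputed = imputed,
            class = c("opqg_genotypes", class(M)))
}

#' @export
print.opqg_genotypes <- function(x, ...) {
  cat(sprintf("<opqg_genotypes> %d individuals x %d loci, %.1f%% missing%s\n",
              nrow(x), ncol(x), 100 * mean(is.na(x)),
              if (isTRUE(attr(x, "imputed"))) " (imputed)" else ""))
  invisible(x)
}

#' Filter loci on missingness and minor allele count
#'
#' Drops loci whose missing-data proportion exceeds `max_missing`
#' (boundary inclusive: a locus missing in exactly 30% of individuals is
#' retained at the default) and loci whose minor allele count among
#' observed calls falls below `min_mac` (so monomorphic loci are removed
#' at the default `min_mac = 1`). Individuals are never dropped.
#'
#' @param gm an [genotype_matrix()].
#' @param max_missing maximum retained missing proportion per locus.
#' @param min_mac minimum minor allele count per locus.
#' @return The filtered `opqg_genotypes`.
#' @export
filter_genotypes <- function(gm, max_missing = 0.30, min_mac = 1) {
  stopifnot(inherits(gm, "opqg_genotypes"))
  miss <- colMeans(is.na(gm))
  alt <- colSums(gm, na.rm = TRUE)
  ncall <- 2 * colSums(!is.na(gm))
  mac <- pmin(alt, ncall - alt)
  keep <- miss <= max_missing & mac >= min_mac
  if (!any(keep)) stop("no loci survive filtering")
  genotype_matrix(unclass(gm)[, keep, drop = FALSE],
                  imputed = attr(gm, "imputed"))
}

#' Mean-impute missing dosages
#'
#' Replaces each missing entry with the per-locus mean of the observed
#' dosages, leaving observed entries (and hence per-locus means)
#' unchanged.
#'
#' @param gm a filtered [genotype_matrix()].
#' @return The imputed `opqg_genotypes` (real-valued, no missing).
#' @export
impute_mean <- function(gm) {
  stopifnot(inherits(gm, "opqg_genotypes"))
  M <- unclass(gm)
  nobs <- colSums(!is.na(M))
  if (any(nobs == 0)) {
    stop("locus with zero observed calls: ",
         paste(colnames(M)[nobs == 0], collapse = ", "))
  }
  mu <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- mu[idx[, 2]]
  genotype_matrix(M, imputed = TRUE)
}

#' Genomic relationship matrix (VanRaden)
#'
#' \deqn{G = W W' / (2 \sum_i p_i (1 - p_i))} where \eqn{W = M - P},
#' \eqn{M} is the dosage matrix and \eqn{P} the row-replicated vector of
#' twice the alternative-allele frequencies \eqn{p_i}. With sample
#' frequencies the columns of W sum to zero, so the grand sum of G is 0.
#'
#' @param gm an imputed [genotype_matrix()].
#' @param freq_source `"sample"` to estimate \eqn{p_i} from the matrix,
#'   `"provided"` to use `p`.
#' @param p per-locus alternative-allele frequencies when
#'   `freq_source = "provided"`.
#' @return An `opqg_relmat` with `kind = "G"`.
#' @export
compute_G <- function(gm, freq_source = c("sample", "provided"), p = NULL) {
  stopifnot(inherits(gm, "opqg_genotypes"))
  freq_source <- match.arg(freq_source)
  M <- unclass(gm)
  if (anyNA(M)) stop("impute missing dosages before computing G")
  if (freq_source == "sample") {
    p <- colMeans(M) / 2
  } else {
    stopifnot(is.numeric(p), length(p) == ncol(M))
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all loci monomorphic: zero denominator in G")
  W <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(W) / denom
  relmat(G, kind = "G")
}

#' Stabilize a genomic relationship matrix for inversion
#'
#' Either adds a ridge (`G + eps * I`) or blends with a conformable
#' pedigree matrix (`w * G + (1 - w) * A`) so that the result is
#' positive definite and safely invertible inside the REML engine.
#'
#' @param G an `opqg_relmat`.
#' @param method `"ridge"` or `"blend_with_A"`.
#' @param param ridge epsilon, or blend weight w on G.
#' @param A pedigree relationship matrix (required for blending).
#' @return A stabilized `opqg_relmat` (kind `"blended"` when blended).
#' @export
stabilize_G <- function(G, method = c("ridge", "blend_with_A"),
                        param = 1e-6, A = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(G, "opqg_relmat"))
  if (method == "ridge") {
    out <- unclass(G) + diag(param, nrow(G))
    dimnames(out) <- dimnames(G)
    return(relmat(out, kind = attr(G, "kind")))
  }
  stopifnot(!is.null(A))
  if (!identical(dim(A), dim(G)) || !identical(rownames(A), rownames(G))) {
    stop("A is not conformable with G (ids/dimensions differ)")
  }
  relmat(param * unclass(G) + (1 - param) * unclass(A)[, , drop = FALSE],
         kind = "blended")
}
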