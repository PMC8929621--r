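#' Construct a pedigree object
#'
#' A pedigree is a set of (individual, sire, dam) records. Unknown parents
#' are coded `NA` (the strings `"UNKNOWN"`, `"0"` and `""` are accepted on
#' input and normalised to `NA`). Parents that are named but have no record
#' of their own are auto-inserted as founders. An optional genetic group
#' (provenance) may be attached per individual; founders inserted
#' automatically inherit the group of their first-listed offspring.
#'
#' @param id character vector of individual ids (unique).
#' @param sire,dam character vectors of parent ids, `NA` when unknown.
#' @param group optional character vector of genetic groups (provenances).
#' @return An object of class `opqg_pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam`, `group`.
#' @export
pedigree <- function(id, sire = NA_character_, dam = NA_character_,
                     group = NA_character_) {
  id <- as.character(id)
  sire <- normalize_parent(rep_len(as.character(sire), length(id)))
  dam  <- normalize_parent(rep_len(as.character(dam), length(id)))
  group <- rep_len(as.character(group), length(id))
  if (anyNA(id) || any(id == "")) stop("individual ids must be non-missing")
  if (anyDuplicated(id)) {
    stop("duplicate individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  ped <- data.frame(id = id, sire = sire, dam = dam, group = group,
                    stringsAsFactors = FALSE)
  # auto-insert missing parents as founders, inheriting offspring group
  parents <- unique(c(ped$sire, ped$dam))
  parents <- parents[!is.na(parents)]
  missing_par <- setdiff(parents, ped$id)
  if (length(missing_par)) {
    grp <- vapply(missing_par, function(p) {
      off <- which(ped$sire == p | ped$dam == p)
      ped$group[off[1]]
    }, character(1))
    ped <- rbind(data.frame(id = missing_par, sire = NA_character_,
                            dam = NA_character_, group = unname(grp),
                            stringsAsFactors = FALSE),
                 ped)
  }
  rownames(ped) <- NULL
  structure(ped, class = c("opqg_pedigree", "data.frame"), ordered = FALSE)
}

normalize_parent <- function(x) {
  x[x %in% c("UNKNOWN", "0", "", "NA")] <- NA_character_
  x
}

#' @export
print.opqg_pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("<opqg_pedigree> %d individuals (%d founders)%s\n",
              nrow(x), nf,
              if (isTRUE(attr(x, "ordered"))) ", topologically ordered" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Validate a pedigree and order parents before offspring
#'
#' Checks ids are unique and parentage is acyclic, then returns the
#' pedigree sorted so that every parent precedes its offspring
#' (a topological order, required by [compute_A()]).
#'
#' @param ped an [pedigree()] object.
#' @return The pedigree, reordered, with attribute `ordered = TRUE`.
#' @export
validate_and_order <- function(ped) {
  stopifnot(inherits(ped, "opqg_pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  # Kahn's algorithm on the parent -> offspring DAG
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ped$id[setdiff(seq_len(n), order)]
    stop("pedigree contains a parentage cycle involving: ",
         paste(sort(cyc), collapse = ", "))
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ordered") <- TRUE
  class(out) <- class(ped)
  out
}

#' Numerator relationship matrix (A) by the tabular method
#'
#' Computes the pedigree-expected additive relationship matrix A with the
#' recursive tabular method: \eqn{a_{ii} = 1 + \tfrac12 a_{s_i d_i}} and
#' \eqn{a_{ij} = \tfrac12 (a_{j s_i} + a_{j d_i})} for \eqn{j} preceding
#' \eqn{i}; unknown parents contribute 0. Founders are assumed unrelated
#' and non-inbred, so for a non-inbred pedigree the diagonal is exactly 1,
#' full-sibs 0.5 and half-sibs 0.25.
#'
#' @param ped a pedigree; ordered with [validate_and_order()] if needed.
#' @return An `opqg_relmat`: the dense symmetric A matrix with ids as
#'   dimnames and attribute `kind = "A"`.
#' @export
compute_A <- function(ped) {
  stopifnot(inherits(ped, "opqg_pedigree"))
  if (!isTRUE(attr(ped, "ordered"))) ped <- validate_and_order(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  relmat(A, kind = "A")
}

#' Relationship-matrix container
#'
#' Wraps a dense symmetric relationship matrix (pedigree A, genomic G, or
#' a blend) keyed by individual ids.
#'
#' @param M symmetric numeric matrix with id dimnames.
#' @param kind one of `"A"`, `"G"`, `"blended"`.
#' @return An `opqg_relmat` object.
#' @export
relmat <- function(M, kind = c("A", "G", "blended")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(M), nrow(M) == ncol(M), !is.null(rownames(M)))
  if (max(abs(M - t(M))) > 1e-8) stop("relationship matrix is not symmetric")
  M <- (M + t(M)) / 2
  structure(M, kind = kind, class = c("opqg_relmat", class(M)))
}

#' @export
print.opqg_relmat <- function(x, ...) {
  cat(sprintf("<opqg_relmat kind=%s> %d x %d, mean diagonal %.4f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Inbreeding coefficients from a pedigree
#'
#' F is the diagonal of the numerator relationship matrix minus one;
#' founders have F = 0 under the base-population assumption.
#'
#' @inheritParams compute_A
#' @return Named numeric vector of per-individual F.
#' @export
inbreeding <- function(ped) {
  A <- compute_A(ped)
  diag(A) - 1
}

#' Expected relationship class of a pair under the recorded pedigree
#'
#' Classifies a pair as `self`, `full-sib` (both recorded parents shared
#' and known), `half-sib` (exactly one shared known parent),
#' `parent-offspring` (one is a recorded parent of the other) or
#' `unrelated` — the classes of the pairwise-relatedness summaries used
#' when screening genomic relatedness against pedigree expectations.
#'
#' @param ped a pedigree.
#' @param i,j individual ids.
#' @return A single string naming the class.
#' @export
expected_class <- function(ped, i, j) {
  stopifnot(inherits(ped, "opqg_pedigree"))
  pos <- match(c(i, j), ped$id)
  if (anyNA(pos)) stop("unknown id(s): ",
                       paste(c(i, j)[is.na(pos)], collapse = ", "))
  if (i == j) return("self")
  s <- ped$sire[pos]; d <- ped$dam[pos]
  shared <- sum(!is.na(s[1]) && !is.na(s[2]) && s[1] == s[2],
                !is.na(d[1]) && !is.na(d[2]) && d[1] == d[2])
  if (shared == 2) return("full-sib")
  if (shared == 1) return("half-sib")
  par1 <- c(s[1], d[1]); par2 <- c(s[2], d[2])
  if (j %in% par1[!is.na(par1)] || i %in% par2[!is.na(par2)]) {
    return("parent-offspring")
  }
  "unrelated"
}

relationship_classes <- c("self", "full-sib", "half-sib",
                          "parent-offspring", "unrelated")

# vectorised classification of all n x n cells; returns a factor matrix code
classify_cells <- function(ped, ids) {
  pos <- match(ids, ped$id)
  if (anyNA(pos)) stop("ids absent from pedigree: ",
                       paste(ids[is.na(pos)], collapse = ", "))
  s <- ped$sire[pos]; d <- ped$dam[pos]
  n <- length(ids)
  same_sire <- outer(s, s, function(a, b) !is.na(a) & !is.na(b) & a == b)
  same_dam  <- outer(d, d, function(a, b) !is.na(a) & !is.na(b) & a == b)
  shared <- same_sire + same_dam
  po <- outer(ids, s, function(a, b) !is.na(b) & a == b) |
        outer(ids, d, function(a, b) !is.na(b) & a == b)
  po <- po | t(po)
  cls <- matrix("unrelated", n, n)
  cls[po] <- "parent-offspring"
  cls[shared == 1] <- "half-sib"
  cls[shared == 2] <- "full-sib"
  diag(cls) <- "self"
  cls
}

#' Relationship-class summary of a relationship matrix
#'
#' Classifies every cell of the matrix (diagonal plus both ordered
#' off-diagonal cells, so counts sum to n squared) by the recorded
#' pedigree and reports n, mean, minimum, maximum, SD and CV per class —
#' the layout of pairwise-relatedness summary tables for A- and
#' G-matrices.
#'
#' @param R an `opqg_relmat` whose ids are a subset of the pedigree ids.
#' @param ped the recorded pedigree used for classification.
#' @param collapse if `TRUE`, merge the `parent-offspring` class into
#'   `unrelated` to reproduce the four-class layout used when all matrix
#'   individuals are progeny.
#' @return A data.frame with one row per class. CV is reported as 0 when
#'   the class SD is 0 (degenerate pedigree-expected classes).
#' @export
relationship_summary <- function(R, ped, collapse = FALSE) {
  ids <- rownames(R)
  cls <- classify_cells(ped, ids)
  if (collapse) cls[cls == "parent-offspring"] <- "unrelated"
  levels <- if (collapse) setdiff(relationship_classes, "parent-offspring")
            else relationship_classes
  vals <- as.vector(unclass(R))
  fac <- factor(as.vector(cls), levels = levels)
  out <- do.call(rbind, lapply(levels, function(l) {
    v <- vals[fac == l]
    if (!length(v)) {
      return(data.frame(class = l, n = 0L, mean = NA_real_, min = NA_real_,
                        max = NA_real_, sd = NA_real_, cv = NA_real_))
    }
    m <- mean(v); s <- stats::sd(v)
    if (length(v) == 1L) s <- 0
    data.frame(class = l, n = length(v), mean = m, min = min(v),
               max = max(v), sd = s, cv = if (s == 0) 0 else s / m)
  }))
  stopifnot(sum(out$n) == length(ids)^2)
  rownames(out) <- NULL
  out
}
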