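#' Detect pedigree-genotype conflicts from genomic relatedness
#'
#' Screens the genomic relationship matrix against pedigree
#' expectations. Two checks are run: every (offspring, recorded parent)
#' pair whose genomic coefficient deviates from the 0.5 parent-offspring
#' expectation by more than `deviation_threshold`, and every recorded
#' sib pair (full-sib expectation 0.5, half-sib 0.25) deviating by more
#' than the threshold. The parent check is the actionable one; sib
#' flags are reported for corroboration.
#'
#' @param ped recorded pedigree.
#' @param G genomic `opqg_relmat`; ids shared with the pedigree are used.
#' @param deviation_threshold absolute deviation from the class
#'   expectation above which a pair is flagged.
#' @return An `opqg_conflicts` data.frame: `id1`, `id2`, `check`
#'   (`"parent"`/`"sib"`), `class`, `expected`, `observed`, `deviation`.
#' @export
detect_conflicts <- function(ped, G, deviation_threshold = 0.15) {
  stopifnot(inherits(ped, "opqg_pedigree"), inherits(G, "opqg_relmat"))
  ids <- intersect(rownames(G), ped$id)
  if (!length(ids)) stop("no shared ids between pedigree and G")
  pos <- match(ped$id, ids)

  rows <- list()
  # parent check: offspring x each recorded, genotyped parent
  for (slot in c("sire", "dam")) {
    par <- ped[[slot]]
    ok <- !is.na(par) & ped$id %in% ids & par %in% ids
    if (any(ok)) {
      g <- unclass(G)[cbind(ped$id[ok], par[ok])]
      dev <- abs(g - 0.5)
      fl <- dev > deviation_threshold
      if (any(fl)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = ped$id[ok][fl], id2 = par[ok][fl], check = "parent",
          class = "parent-offspring", expected = 0.5, observed = g[fl],
          deviation = dev[fl], stringsAsFactors = FALSE)
      }
    }
  }
  # sib check: recorded full/half sibs among genotyped individuals
  cls <- classify_cells(ped, ids)
  expected <- c("full-sib" = 0.5, "half-sib" = 0.25)
  for (k in names(expected)) {
    w <- which(cls == k & upper.tri(cls), arr.ind = TRUE)
    if (nrow(w)) {
      g <- unclass(G)[ids, ids][w]
      dev <- abs(g - expected[[k]])
      fl <- dev > deviation_threshold
      if (any(fl)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = ids[w[fl, 1]], id2 = ids[w[fl, 2]], check = "sib",
          class = k, expected = expected[[k]], observed = g[fl],
          deviation = dev[fl], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(), id2 = character(), check = character(),
               class = character(), expected = numeric(),
               observed = numeric(), deviation = numeric())
  rownames(out) <- NULL
  structure(out, threshold = deviation_threshold,
            class = c("opqg_conflicts", "data.frame"))
}

#' Correct a pedigree from genomic evidence
#'
#' Codifies the manual parentage-correction procedure: for each offspring
#' flagged by the parent check of [detect_conflicts()], candidate parents
#' are searched among recorded parents of the same slot (dams for a
#' flagged dam, sires for a flagged sire) whose genomic coefficient with
#' the offspring lies inside `parent_window`. A unique candidate is
#' assigned; no candidate leads to a phantom parent (a fresh reserved-id
#' founder, shared by no-candidate offspring that are themselves related
#' at `g >= phantom_link`); two or more candidates below
#' `ambiguity_limit` also yield a phantom (the tie is not guessed);
#' `ambiguity_limit` or more in-window candidates is treated as an
#' irreconcilable multi-way conflict and the offspring is listed for
#' removal.
#'
#' @param ped recorded pedigree.
#' @param G genomic relationship matrix.
#' @param report an `opqg_conflicts` report from [detect_conflicts()].
#' @param parent_window genomic-coefficient interval accepted for a
#'   candidate parent.
#' @param ambiguity_limit number of in-window candidates at or above
#'   which the offspring is listed for removal.
#' @param phantom_link minimum g at which no-candidate offspring share a
#'   phantom parent.
#' @param phantom_prefix reserved id prefix for phantom parents.
#' @return A list: `pedigree` (corrected), `actions` (per-offspring
#'   action table), `counts` (named vector: reassigned, phantom,
#'   phantom_parents, removed), `removed` (ids listed for removal).
#' @export
correct_pedigree <- function(ped, G, report,
                             parent_window = c(0.35, 0.65),
                             ambiguity_limit = 3,
                             phantom_link = 0.2,
                             phantom_prefix = "PH") {
  stopifnot(inherits(report, "opqg_conflicts"))
  Gm <- unclass(G)
  pc <- report[report$check == "parent", , drop = FALSE]
  new_ped <- as.data.frame(ped)
  actions <- list()
  phantom_needed <- character(0)  # offspring ids needing a phantom
  phantom_slot <- character(0)
  removed <- character(0)

  for (r in seq_len(nrow(pc))) {
    off <- pc$id1[r]; old_par <- pc$id2[r]
    row <- match(off, new_ped$id)
    slot <- if (!is.na(new_ped$dam[row]) && new_ped$dam[row] == old_par)
      "dam" else "sire"
    pool <- unique(new_ped[[slot]])
    pool <- setdiff(pool[!is.na(pool)], off)
    pool <- intersect(pool, rownames(Gm))
    g <- Gm[off, pool]
    cand <- pool[g >= parent_window[1] & g <= parent_window[2]]
    if (length(cand) == 1L) {
      new_ped[[slot]][row] <- cand
      actions[[length(actions) + 1L]] <- data.frame(
        offspring = off, slot = slot, old = old_par, new = cand,
        action = "reassigned", stringsAsFactors = FALSE)
    } else if (length(cand) >= ambiguity_limit) {
      removed <- c(removed, off)
      actions[[length(actions) + 1L]] <- data.frame(
        offspring = off, slot = slot, old = old_par, new = NA_character_,
        action = "removed", stringsAsFactors = FALSE)
    } else {
      phantom_needed <- c(phantom_needed, off)
      phantom_slot <- c(phantom_slot, slot)
    }
  }

  # cluster no-candidate offspring into shared phantom parents
  n_phantom <- 0L
  if (length(phantom_needed)) {
    uoff <- unique(phantom_needed)
    comp <- seq_along(uoff)
    if (length(uoff) > 1L) {
      for (a in seq_len(length(uoff) - 1L)) {
        for (b in seq(a + 1L, length(uoff))) {
          if (uoff[a] %in% rownames(Gm) && uoff[b] %in% rownames(Gm) &&
              Gm[uoff[a], uoff[b]] >= phantom_link) {
            comp[comp == comp[b]] <- comp[a]
          }
        }
      }
    }
    for (cl in unique(comp)) {
      n_phantom <- n_phantom + 1L
      pid <- sprintf("%s%03d", phantom_prefix, n_phantom)
      for (off in uoff[comp == cl]) {
        slot <- phantom_slot[match(off, phantom_needed)]
        row <- match(off, new_ped$id)
        old <- new_ped[[slot]][row]
        new_ped[[slot]][row] <- pid
        actions[[length(actions) + 1L]] <- data.frame(
          offspring = off, slot = slot, old = old, new = pid,
          action = "phantom", stringsAsFactors = FALSE)
      }
      new_ped <- rbind(new_ped,
                       data.frame(id = pid, sire = NA_character_,
                                  dam = NA_character_,
                                  group = NA_character_,
                                  stringsAsFactors = FALSE))
    }
  }

  actions <- if (length(actions)) do.call(rbind, actions) else
    data.frame(offspring = character(), slot = character(),
               old = character(), new = character(), action = character())
  out_ped <- validate_and_order(
    pedigree(new_ped$id, new_ped$sire, new_ped$dam, new_ped$group))
  counts <- c(reassigned = sum(actions$action == "reassigned"),
              phantom = sum(actions$action == "phantom"),
              phantom_parents = n_phantom,
              removed = length(unique(removed)))
  list(pedigree = out_ped, actions = actions, counts = counts,
       removed = unique(removed))
}
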