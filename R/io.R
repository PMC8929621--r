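# Readers and writers share one set of dialects so that everything the
# simulators write is read back identically (round-trip guaranteed).

#' Read a pedigree CSV (columns id, sire, dam, optional group)
#'
#' `UNKNOWN`, `0` or an empty field denote an unknown parent.
#'
#' @param path CSV file path.
#' @return A validated, topologically ordered [pedigree()].
#' @export
read_pedigree_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(d))) {
    stop("pedigree CSV must have columns id, sire, dam (got: ",
         paste(names(d), collapse = ", "), ")")
  }
  validate_and_order(pedigree(d$id, d$sire, d$dam,
                              if ("group" %in% names(d)) d$group else NA))
}

#' Write a pedigree CSV
#' @param ped a pedigree.
#' @param path output path.
#' @export
write_pedigree_csv <- function(ped, path) {
  d <- as.data.frame(ped)
  d$sire[is.na(d$sire)] <- "UNKNOWN"
  d$dam[is.na(d$dam)] <- "UNKNOWN"
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a wide phenotype CSV
#'
#' Columns `tree`, `site`, `replication`, `group`, then one column per
#' trait; empty or `NA` fields are missing.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_phenotypes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("tree", "site", "replication", "group")
  if (!all(need %in% names(d))) {
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  }
  d$tree <- as.character(d$tree)
  d
}

#' Write a wide phenotype CSV
#' @param pheno phenotype data.frame.
#' @param path output path.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a dosage TSV (rows individuals, columns loci, NA missing)
#' @param path TSV path; first column must be `id`.
#' @return An [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (names(d)[1] != "id") stop("dosage TSV must start with an id column")
  M <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(d$id)
  genotype_matrix(M)
}

#' Write a dosage TSV
#' @param gm a genotype matrix.
#' @param path output path.
#' @export
write_dosage_tsv <- function(gm, path) {
  d <- data.frame(id = rownames(gm), unclass(gm), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read genotypes from a VCF into a dosage matrix
#'
#' Biallelic records only; the GT field is converted to the count of
#' alternative alleles (`0/0` = 0, `0/1` = 1, `1/1` = 2, `./.` =
#' missing). Any read-depth filtering is assumed to have happened
#' upstream in the variant-calling pipeline.
#'
#' @param path VCF file path.
#' @return An [genotype_matrix()] (individuals x loci).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    gt <- gt[!multi, , drop = FALSE]
    warning(sum(multi), " multiallelic record(s) dropped")
  }
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- rownames(dos)
  genotype_matrix(structure(t(dos), dimnames = list(colnames(dos), ids)))
}

#' Write integer dosages as a minimal VCF
#'
#' Emits a VCFv4.2 text file with GT fields only (0/0, 0/1, 1/1, ./.),
#' round-tripping with [read_vcf_genotypes()]. Requires un-imputed
#' (integer) dosages.
#'
#' @param gm a genotype matrix with integer dosages.
#' @param path output path.
#' @export
write_vcf_genotypes <- function(gm, path) {
  M <- unclass(gm)
  if (any(!is.na(M) & M != round(M))) {
    stop("VCF writer requires integer (un-imputed) dosages")
  }
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(M)), collapse = "\t")), con)
  for (i in seq_len(ncol(M))) {
    calls <- ifelse(is.na(M[, i]), "./.", gt[M[, i] + 1])
    writeLines(paste(c("1", i, colnames(M)[i], "A", "C", ".", "PASS", ".",
                       "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read ring series from a long CSV (tree, year, bai)
#' @param path CSV path.
#' @return Named list of [ring_series()].
#' @export
read_ring_series_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tree", "year", "bai") %in% names(d))) {
    stop("ring CSV must have columns tree, year, bai")
  }
  d$tree <- as.character(d$tree)
  out <- lapply(split(d, d$tree), function(s) {
    s <- s[order(s$year), ]
    ring_series(s$tree[1], s$year, s$bai)
  })
  out[unique(d$tree)]
}

#' Write ring series to a long CSV
#' @param rings named list of ring series.
#' @param path output path.
#' @export
write_ring_series_csv <- function(rings, path) {
  d <- do.call(rbind, lapply(rings, function(s) {
    data.frame(tree = attr(s, "tree"), year = s$year, bai = s$bai)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a simulation-truth object to JSON
#' @param truth an `opqg_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    true_pedigree = as.data.frame(truth$true_pedigree),
    recorded_pedigree = as.data.frame(truth$recorded_pedigree),
    contamination_events = truth$contamination_events,
    seed = truth$seed)
  jsonlite::write_json(obj, path, na = "null", digits = NA)
  invisible(path)
}

#' Recover a simulation-truth object from JSON
#' @param path JSON path written by [write_truth_json()].
#' @return An `opqg_truth` (pedigrees and events; generated values such
#'   as breeding values are replayable from the stored seed).
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_ped <- function(d) {
    validate_and_order(pedigree(d$id, d$sire, d$dam, d$group))
  }
  structure(list(true_pedigree = to_ped(obj$true_pedigree),
                 recorded_pedigree = to_ped(obj$recorded_pedigree),
                 contamination_events =
                   as.data.frame(obj$contamination_events),
                 true_variance_components = NULL,
                 true_breeding_values = NULL,
                 seed = obj$seed),
            class = "opqg_truth")
}

#' Read a run-configuration YAML file
#'
#' Fills defaults for the filter thresholds, conflict threshold,
#' parent window, drought settings and minimum response size.
#'
#' @param path YAML path, or a list already in memory.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(max_missing = 0.30, min_mac = 1,
                   conflict_threshold = 0.15,
                   parent_window = c(0.35, 0.65),
                   drought_year = 2015, pre_window = 4,
                   min_n = 30, seed = 1, ridge = 1e-6,
                   log_traits = character(0), outdir = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  stopifnot(cfg$max_missing >= 0, cfg$max_missing <= 1,
            cfg$min_mac >= 0, cfg$conflict_threshold > 0,
            length(cfg$parent_window) == 2, cfg$min_n >= 1)
  cfg
}

#' Load and cross-validate a full dataset from a run configuration
#'
#' Reads the pedigree, phenotypes, genotypes (VCF or dosage TSV) and
#' optional ring series named in the config, and reconciles ids:
#' phenotyped or genotyped trees absent from the pedigree are listed in
#' the reconciliation report (never silently dropped).
#'
#' @param config list or YAML path (see [read_run_config()]) with
#'   entries `pedigree`, `phenotypes`, and `genotypes_vcf` or
#'   `genotypes_tsv`, optionally `rings`.
#' @return A list: `pedigree`, `genotypes`, `phenotypes`, `rings`,
#'   `reconciliation` (data.frame of orphan ids and their source).
#' @export
load_dataset <- function(config) {
  cfg <- read_run_config(config)
  ped <- read_pedigree_csv(cfg$pedigree)
  pheno <- read_phenotypes_csv(cfg$phenotypes)
  gm <- if (!is.null(cfg$genotypes_vcf)) read_vcf_genotypes(cfg$genotypes_vcf)
        else if (!is.null(cfg$genotypes_tsv)) read_dosage_tsv(cfg$genotypes_tsv)
        else stop("config must name genotypes_vcf or genotypes_tsv")
  rings <- if (!is.null(cfg$rings)) read_ring_series_csv(cfg$rings) else NULL
  orph_p <- setdiff(pheno$tree, ped$id)
  orph_g <- setdiff(rownames(gm), ped$id)
  rec <- data.frame(
    id = c(orph_p, orph_g),
    source = c(rep("phenotypes", length(orph_p)),
               rep("genotypes", length(orph_g))),
    stringsAsFactors = FALSE)
  list(pedigree = ped, genotypes = gm, phenotypes = pheno, rings = rings,
       reconciliation = rec)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: genotype filtering and mean
#' imputation; VanRaden G; pedigree conflict detection and correction;
#' numerator A from the corrected pedigree; trait preparation (log
#' transforms, ring-derived drought indices, replication-effect
#' adjustment, standardization); univariate fits per trait and site
#' under both A and G; sites-as-traits multivariate fits per trait for
#' cross-site genetic correlations; and the report tables. All outputs
#' are deterministic given the config.
#'
#' @param config list or YAML path; in addition to the input paths of
#'   [load_dataset()]: `traits` (character), `log_traits`,
#'   `drought_year`, `pre_window`, `min_n`, `outdir` (optional; TSV and
#'   JSON reports are written there when set).
#' @return (invisibly) a list bundle with all intermediate and final
#'   objects.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  data <- load_dataset(cfg)
  log <- list(config = cfg[setdiff(names(cfg), "outdir")])

  gm <- impute_mean(filter_genotypes(data$genotypes,
                                     max_missing = cfg$max_missing,
                                     min_mac = cfg$min_mac))
  G <- stabilize_G(compute_G(gm), method = "ridge", param = cfg$ridge)

  conf <- detect_conflicts(data$pedigree, G,
                           deviation_threshold = cfg$conflict_threshold)
  corr <- correct_pedigree(data$pedigree, G, conf,
                           parent_window = cfg$parent_window)
  ped <- corr$pedigree
  A <- compute_A(ped)

  pheno <- data$phenotypes
  traits <- cfg$traits
  if (is.null(traits)) {
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      c("replication", "year"))
  }
  for (tr in intersect(cfg$log_traits, traits)) {
    pheno[[tr]] <- log_transform(pheno[[tr]])
  }
  if (!is.null(data$rings)) {
    idx <- lapply(data$rings, function(s) {
      res <- tryCatch(resistance(s, cfg$drought_year, cfg$pre_window),
                      error = function(e) NA_real_)
      sen <- tryCatch(mean_sensitivity(s), error = function(e) NA_real_)
      c(res, sen)
    })
    di <- do.call(rbind, idx)
    pheno$resistance <- di[match(pheno$tree, names(data$rings)), 1]
    pheno$sensitivity <- di[match(pheno$tree, names(data$rings)), 2]
    traits <- union(traits, c("resistance", "sensitivity"))
  }
  summary_raw <- trait_summary(pheno, traits)

  adj <- pheno
  for (tr in traits) {
    adj[[tr]] <- design_adjust(adj, tr)
    for (s in unique(adj$site)) {
      rows <- adj$site == s
      if (sum(!is.na(adj[[tr]][rows])) >= 2 &&
          stats::sd(adj[[tr]][rows], na.rm = TRUE) > 0) {
        adj[[tr]][rows] <- standardize(replace(adj[[tr]], !rows, NA))[rows]
      }
    }
  }

  sites <- sort(unique(pheno$site))
  sources <- list(A = A, G = G)
  keep_ids <- intersect(pheno$tree, rownames(G))
  h2_rows <- list()
  fits <- list()
  for (src in names(sources)) {
    K <- sources[[src]]
    for (tr in traits) {
      for (s in sites) {
        n_obs <- sum(pheno$site == s & !is.na(pheno[[tr]]) &
                       pheno$tree %in% rownames(K))
        if (n_obs < cfg$min_n) {
          h2_rows[[length(h2_rows) + 1L]] <- data.frame(
            trait = tr, site = s, source = src, n = n_obs,
            h2 = NA_real_, se = NA_real_, stringsAsFactors = FALSE)
          next
        }
        sub <- pheno[pheno$tree %in% rownames(K), , drop = FALSE]
        fit <- fit_univariate(sub, tr, K, site = s,
                              fit_replication =
                                length(unique(sub$replication[
                                  sub$site == s])) > 1)
        h <- heritability(fit)
        h2_rows[[length(h2_rows) + 1L]] <- data.frame(
          trait = tr, site = s, source = src, n = n_obs, h2 = h$h2,
          se = h$se, stringsAsFactors = FALSE)
        fits[[paste(src, tr, s, sep = ":")]] <- fit
      }
    }
  }
  h2_table <- do.call(rbind, h2_rows)

  cross_site <- list()
  for (src in names(sources)) {
    K <- sources[[src]]
    sub <- adj[adj$tree %in% rownames(K), , drop = FALSE]
    per_trait <- list()
    for (tr in traits) {
      ok_sites <- sites[vapply(sites, function(s) {
        sum(sub$site == s & !is.na(sub[[tr]])) >= cfg$min_n
      }, logical(1))]
      if (length(ok_sites) < 2) next
      per_trait[[tr]] <- fit_multivariate(
        sub, data.frame(trait = tr, site = ok_sites,
                        stringsAsFactors = FALSE), K)
    }
    if (length(per_trait)) {
      cross_site[[src]] <- cross_site_report(per_trait, sites = sites)
    }
  }

  bundle <- list(
    log = log, genotypes = gm, G = G, A = A, pedigree = ped,
    conflicts = conf, correction = corr$counts,
    relationship_summary = list(
      A = relationship_summary(relmat(unclass(A)[keep_ids, keep_ids],
                                      "A"), ped),
      G = relationship_summary(relmat(unclass(G)[keep_ids, keep_ids],
                                      "G"), ped)),
    trait_summary = summary_raw, phenotypes = pheno, adjusted = adj,
    h2_table = h2_table, fits = fits, cross_site = cross_site)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(cfg$outdir, f), sep = "\t", row.names = FALSE,
      quote = FALSE)
    wt(h2_table, "heritability.tsv")
    wt(summary_raw, "trait_summary.tsv")
    wt(bundle$relationship_summary$A, "relatedness_A.tsv")
    wt(bundle$relationship_summary$G, "relatedness_G.tsv")
    wt(as.data.frame(conf), "conflicts.tsv")
    jsonlite::write_json(
      list(correction = as.list(corr$counts),
           n_conflicts = nrow(conf),
           cross_site = lapply(cross_site, function(src) {
             lapply(src, function(m) m$estimate)
           })),
      file.path(cfg$outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(bundle)
}
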