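#' Ring-series container
#'
#' Per-tree annual basal area increments (BAI).
#'
#' @param tree tree id (single string).
#' @param years integer vector of years, strictly increasing.
#' @param bai non-negative BAI per year (area units).
#' @return An `opqg_rings` object (data.frame `year`, `bai` with a
#'   `tree` attribute).
#' @export
ring_series <- function(tree, years, bai) {
  years <- as.integer(years)
  if (length(years) != length(bai)) stop("years and bai lengths differ")
  if (is.unsorted(years, strictly = TRUE)) {
    stop("years must be strictly increasing")
  }
  if (any(bai < 0, na.rm = TRUE)) stop("BAI must be non-negative")
  structure(data.frame(year = years, bai = as.numeric(bai)),
            tree = as.character(tree),
            class = c("opqg_rings", "data.frame"))
}

#' Convert ring widths to basal area increments
#'
#' \eqn{BAI_t = \pi (R_t^2 - R_{t-1}^2)} with cumulative radius
#' \eqn{R_t = R_0 + \sum_{s \le t} w_s}.
#'
#' @param tree tree id.
#' @param years ring years.
#' @param widths non-negative ring widths (length units).
#' @param initial_radius radius before the first ring.
#' @return An [ring_series()].
#' @export
ring_width_to_bai <- function(tree, years, widths, initial_radius = 0) {
  if (any(widths < 0, na.rm = TRUE)) stop("negative ring width")
  r <- initial_radius + cumsum(widths)
  bai <- pi * (r^2 - c(initial_radius, r[-length(r)])^2)
  ring_series(tree, years, bai)
}

#' Drought resistance index
#'
#' Ratio of the drought-year BAI to the mean BAI of the `pre_window`
#' years immediately before it: values near 1 mean growth was
#' unaffected by the drought, smaller values mean stronger reduction.
#'
#' @param series an [ring_series()].
#' @param drought_year the drought year (default 2015).
#' @param pre_window number of pre-drought years averaged (default 4,
#'   i.e. 2011-2014 for a 2015 drought).
#' @return The resistance ratio (unitless).
#' @export
resistance <- function(series, drought_year = 2015, pre_window = 4) {
  stopifnot(inherits(series, "opqg_rings"))
  pre_years <- seq(drought_year - pre_window, drought_year - 1)
  need <- c(pre_years, drought_year)
  got <- need %in% series$year[!is.na(series$bai)]
  if (!all(got)) {
    stop("ring series does not cover year(s): ",
         paste(need[!got], collapse = ", "))
  }
  pre <- mean(series$bai[series$year %in% pre_years])
  if (pre <= 0) stop("pre-drought mean BAI is zero: resistance undefined")
  series$bai[series$year == drought_year] / pre
}

#' Mean sensitivity of a ring series
#'
#' Mean absolute relative year-to-year change,
#' \deqn{\frac{1}{n-1} \sum_{t=1}^{n-1}
#'   \left| \frac{2 (BAI_{t+1} - BAI_t)}{BAI_{t+1} + BAI_t} \right|}
#' over the n measured years. High values indicate climate-responsive
#' growth. Missing years break the series into runs; pairs straddling a
#' gap are excluded and the divisor is the number of retained pairs.
#'
#' @param series an [ring_series()].
#' @param skip_zero_pairs if `TRUE`, consecutive pairs summing to zero
#'   are skipped instead of raising an error.
#' @return The mean sensitivity (unitless, in [0, 2]).
#' @export
mean_sensitivity <- function(series, skip_zero_pairs = FALSE) {
  stopifnot(inherits(series, "opqg_rings"))
  ok <- !is.na(series$bai)
  yr <- series$year[ok]; b <- series$bai[ok]
  if (length(b) < 2) stop("need at least two measured years")
  consec <- which(diff(yr) == 1L)
  if (!length(consec)) stop("no consecutive year pairs")
  s <- b[consec + 1L] + b[consec]
  d <- b[consec + 1L] - b[consec]
  if (any(s == 0)) {
    if (!skip_zero_pairs) stop("consecutive BAI pair sums to zero")
    d <- d[s != 0]; s <- s[s != 0]
    if (!length(s)) stop("no usable year pairs")
  }
  mean(abs(2 * d / s))
}

#' BAI-weighted mean of a per-ring measurement
#'
#' Weighted mean of per-ring values (e.g. ring wood density) with the
#' annual basal area increment as weight, discarding rings before
#' `first_year` (juvenile rings with unreliable measurements).
#'
#' @param values per-ring measurements.
#' @param weights per-ring BAI weights (non-negative).
#' @param years ring years aligned with `values`.
#' @param first_year first ring year retained.
#' @return The weighted mean.
#' @export
bai_weighted_mean <- function(values, weights, years = NULL,
                              first_year = 1995) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0, na.rm = TRUE)) stop("negative BAI weight")
  if (!is.null(years)) {
    stopifnot(length(years) == length(values))
    keep <- years >= first_year
    values <- values[keep]; weights <- weights[keep]
  }
  ok <- !is.na(values) & !is.na(weights)
  if (sum(weights[ok]) <= 0) stop("all BAI weights zero after year cut")
  sum(values[ok] * weights[ok]) / sum(weights[ok])
}

#' Natural-log transform a positive trait vector
#'
#' @param values positive trait values (`NA` allowed and preserved).
#' @return `log(values)`.
#' @export
log_transform <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    stop("non-positive values at rows: ", paste(bad, collapse = ", "))
  }
  log(values)
}

#' Subtract estimated replication effects from a trait
#'
#' Per site, fits value = mean + replication effect + residual with
#' effects constrained to sum to zero weighted by replication size
#' (i.e. the effect of replication r is its mean minus the site grand
#' mean) and returns value minus its replication effect. The grand mean
#' is preserved and the operation is idempotent.
#'
#' @param table a phenotype data.frame with columns `site`,
#'   `replication` and the trait.
#' @param trait trait column name.
#' @return Numeric vector of adjusted values (same order as `table`).
#' @export
design_adjust <- function(table, trait) {
  stopifnot(all(c("site", "replication", trait) %in% names(table)))
  y <- table[[trait]]
  out <- y
  for (s in unique(table$site)) {
    rows <- which(table$site == s & !is.na(y))
    if (!length(rows)) next
    reps <- table$replication[rows]
    if (length(unique(reps)) < 2) {
      warning("site ", s, ": single replication, trait returned unadjusted")
      next
    }
    grand <- mean(y[rows])
    eff <- tapply(y[rows], reps, mean) - grand
    out[rows] <- y[rows] - eff[as.character(reps)]
  }
  out
}

#' Standardize a trait vector to mean zero and unit variance
#'
#' z-scores with the sample (n-1) variance denominator; missing values
#' stay missing.
#'
#' @param values numeric trait vector.
#' @return Standardized vector.
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least two non-missing values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero variance: cannot standardize")
  (values - mean(values[ok])) / s
}

#' Per-trait summary statistics
#'
#' n (non-missing), mean, SD, CV = SD/mean (signed, so a negative-mean
#' trait such as a carbon isotope ratio yields a negative CV), minimum
#' and maximum for each trait column.
#'
#' @param table phenotype data.frame.
#' @param traits character vector of trait column names; defaults to all
#'   numeric columns except design columns.
#' @return A data.frame with one row per trait.
#' @export
trait_summary <- function(table, traits = NULL) {
  if (is.null(traits)) {
    num <- vapply(table, is.numeric, logical(1))
    traits <- setdiff(names(table)[num],
                      c("tree", "site", "replication", "group", "year"))
  }
  out <- do.call(rbind, lapply(traits, function(tr) {
    v <- table[[tr]]; v <- v[!is.na(v)]
    if (!length(v)) {
      return(data.frame(trait = tr, n = 0L, mean = NA_real_, sd = NA_real_,
                        cv = NA_real_, min = NA_real_, max = NA_real_))
    }
    s <- if (length(v) > 1) stats::sd(v) else 0
    data.frame(trait = tr, n = length(v), mean = mean(v), sd = s,
               cv = if (s == 0) 0 else s / mean(v),
               min = min(v), max = max(v))
  }))
  rownames(out) <- NULL
  out
}
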