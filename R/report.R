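param_index <- function(fit, type, i, j = i) {
  pt <- fit$vc$params
  w <- which(pt$type == type &
               ((pt$i == i & pt$j == j) | (pt$i == j & pt$j == i)))
  if (!length(w)) NA_integer_ else w[1]
}

delta_se <- function(fit, grad) {
  C <- fit$vc$asycov
  if (is.null(C) || any(!is.finite(C))) return(NA_real_)
  v <- as.numeric(t(grad) %*% C %*% grad)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Narrow-sense heritability with standard error
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)} for one response
#' of a fitted model; the replication (design) variance is excluded
#' from the denominator, matching the individual-trait
#' re-parameterization of the fitted components. The SE is obtained by
#' the delta method from the AI-based asymptotic covariance.
#'
#' @param fit an `opqg_fit`.
#' @param response response name (defaults to the first).
#' @return A data.frame: `response`, `h2` (clamped to [0, 1]),
#'   `h2_raw`, `se`, `near_zero`.
#' @export
heritability <- function(fit, response = fit$responses[1]) {
  j <- match(response, fit$responses)
  if (is.na(j)) stop("unknown response: ", response)
  sa <- fit$vc$Sigma_a[j, j]; se_ <- fit$vc$Sigma_e[j, j]
  tot <- sa + se_
  if (tot <= 0) stop("zero total variance: heritability undefined")
  h2 <- sa / tot
  grad <- numeric(nrow(fit$vc$params))
  ia <- param_index(fit, "a", j); ie <- param_index(fit, "e", j)
  grad[ia] <- se_ / tot^2
  grad[ie] <- -sa / tot^2
  data.frame(response = response, h2 = min(max(h2, 0), 1), h2_raw = h2,
             se = delta_se(fit, grad),
             near_zero = paste0("sigma2_a(", response, ")") %in%
               fit$near_zero,
             stringsAsFactors = FALSE)
}

#' Genetic correlation between two responses with standard error
#'
#' \eqn{r_a = \sigma_{a_{ij}} / \sqrt{\sigma^2_{a_{ii}}
#' \sigma^2_{a_{jj}}}}; reported `NA` when either genetic variance is
#' zero (undefined correlation, mirroring NA cells for responses
#' without heritable variation). SE by the delta method.
#'
#' @param fit an `opqg_fit` with at least two responses.
#' @param pair character vector of two response names (default: first
#'   two).
#' @return A data.frame: `response_i`, `response_j`, `r_a`, `se`,
#'   `label`.
#' @export
genetic_correlation <- function(fit, pair = fit$responses[1:2]) {
  idx <- match(pair, fit$responses)
  if (anyNA(idx)) stop("unknown response(s): ",
                       paste(pair[is.na(idx)], collapse = ", "))
  j <- idx[1]; k <- idx[2]
  sjj <- fit$vc$Sigma_a[j, j]; skk <- fit$vc$Sigma_a[k, k]
  sjk <- fit$vc$Sigma_a[j, k]
  near0 <- 1e-10 * mean(diag(fit$vc$Sigma_e) + diag(fit$vc$Sigma_a))
  if (sjj <= near0 || skk <= near0) {
    return(data.frame(response_i = pair[1], response_j = pair[2],
                      r_a = NA_real_, se = NA_real_, label = NA_character_,
                      stringsAsFactors = FALSE))
  }
  r <- sjk / sqrt(sjj * skk)
  r <- min(max(r, -1), 1)
  grad <- numeric(nrow(fit$vc$params))
  grad[param_index(fit, "a", j, k)] <- 1 / sqrt(sjj * skk)
  grad[param_index(fit, "a", j)] <- -r / (2 * sjj)
  grad[param_index(fit, "a", k)] <- -r / (2 * skk)
  data.frame(response_i = pair[1], response_j = pair[2], r_a = r,
             se = delta_se(fit, grad), label = classify_correlation(r),
             stringsAsFactors = FALSE)
}

#' Classify the strength of a genetic correlation
#'
#' `strong` if |r| >= 0.70, `moderate` if 0.40 < |r| < 0.70, and
#' `low/weak` if |r| <= 0.40.
#'
#' @param r correlation in [-1, 1] (vectorised).
#' @return Character vector of labels.
#' @export
classify_correlation <- function(r) {
  if (any(!is.na(r) & (r < -1 | r > 1))) stop("correlation outside [-1, 1]")
  out <- rep(NA_character_, length(r))
  a <- abs(r)
  out[!is.na(a) & a >= 0.70] <- "strong"
  out[!is.na(a) & a > 0.40 & a < 0.70] <- "moderate"
  out[!is.na(a) & a <= 0.40] <- "low/weak"
  out
}

#' Cross-site genetic-correlation matrices per trait
#'
#' Assembles, for each trait's sites-as-traits multivariate fit, the
#' symmetric site-by-site matrix of genetic correlations (type-B
#' correlations, whose departure from 1 measures genotype-by-
#' environment interaction), with SEs and strength labels. Sites
#' absent from a fit (insufficient data) appear as NA.
#'
#' @param fits named list (trait -> `opqg_fit`) of sites-as-traits
#'   fits.
#' @param sites optional character vector fixing the site order; by
#'   default the union over fits.
#' @return A named list per trait with matrices `estimate`, `se`,
#'   `label`.
#' @export
cross_site_report <- function(fits, sites = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  all_sites <- sites
  if (is.null(all_sites)) {
    all_sites <- sort(unique(unlist(lapply(fits, `[[`, "sites"))))
  }
  if (anyNA(all_sites)) stop("inconsistent site labels: NA site in a fit")
  lapply(fits, function(fit) {
    if (!all(fit$sites %in% all_sites)) {
      stop("inconsistent site labels: ",
           paste(setdiff(fit$sites, all_sites), collapse = ", "))
    }
    ns <- length(all_sites)
    est <- matrix(NA_real_, ns, ns, dimnames = list(all_sites, all_sites))
    sem <- est
    lab <- matrix(NA_character_, ns, ns,
                  dimnames = list(all_sites, all_sites))
    # unit diagonal for fitted sites; absent sites stay NA throughout
    diag(est) <- ifelse(all_sites %in% fit$sites, 1, NA_real_)
    pos <- match(fit$sites, all_sites)
    for (a in seq_along(fit$sites)) {
      for (b in seq_along(fit$sites)) {
        if (a >= b) next
        g <- genetic_correlation(fit, fit$responses[c(a, b)])
        est[pos[a], pos[b]] <- est[pos[b], pos[a]] <- g$r_a
        sem[pos[a], pos[b]] <- sem[pos[b], pos[a]] <- g$se
        lab[pos[a], pos[b]] <- lab[pos[b], pos[a]] <- g$label
      }
    }
    list(estimate = est, se = sem, label = lab)
  })
}

#' Parameter-recovery report against simulation truth
#'
#' Scores replicated estimates against known true values: mean bias,
#' RMSE and empirical coverage of the 95% Wald interval
#' (estimate +/- 1.96 SE) per parameter.
#'
#' @param estimates data.frame with columns `parameter`, `replicate`,
#'   `estimate`, `se`.
#' @param truth named numeric vector of true values, one per parameter
#'   appearing in `estimates`.
#' @return A data.frame: `parameter`, `true`, `n`, `mean_estimate`,
#'   `bias`, `rmse`, `coverage`.
#' @export
recovery_report <- function(estimates, truth) {
  stopifnot(all(c("parameter", "estimate", "se") %in% names(estimates)))
  pars <- unique(estimates$parameter)
  if (!all(pars %in% names(truth))) {
    stop("truth values missing for: ",
         paste(setdiff(pars, names(truth)), collapse = ", "))
  }
  out <- do.call(rbind, lapply(pars, function(p) {
    e <- estimates[estimates$parameter == p, , drop = FALSE]
    tv <- truth[[p]]
    cov <- mean(abs(e$estimate - tv) <= 1.96 * e$se, na.rm = TRUE)
    data.frame(parameter = p, true = tv, n = nrow(e),
               mean_estimate = mean(e$estimate),
               bias = mean(e$estimate) - tv,
               rmse = sqrt(mean((e$estimate - tv)^2)),
               coverage = cov, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
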