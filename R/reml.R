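#' REML engine control parameters
#'
#' @param tol convergence tolerance: maximum relative change of any
#'   free variance parameter between EM iterations.
#' @param max_iter maximum number of EM iterations.
#' @param near_zero_frac a component smaller than this fraction of the
#'   phenotypic variance is flagged "near zero" (boundary estimate).
#' @param monotone_tol largest tolerated decrease of the REML
#'   log-likelihood between EM iterations before the trace is flagged
#'   non-monotone.
#' @return A list of control values.
#' @export
reml_control <- function(tol = 1e-8, max_iter = 2000,
                         near_zero_frac = 1e-6, monotone_tol = 1e-8) {
  list(tol = tol, max_iter = max_iter, near_zero_frac = near_zero_frac,
       monotone_tol = monotone_tol)
}

# ---- design assembly -------------------------------------------------------

# responses: data.frame(trait, site) with site NA meaning all sites pooled
assemble_design <- function(pheno, responses, relmat,
                            fit_replication = FALSE) {
  stopifnot(inherits(relmat, "opqg_relmat"),
            all(c("tree", "site", "group") %in% names(pheno)))
  resp <- list()
  for (r in seq_len(nrow(responses))) {
    tr <- responses$trait[r]; st <- responses$site[r]
    if (!tr %in% names(pheno)) stop("trait not in phenotype table: ", tr)
    rows <- if (is.na(st)) seq_len(nrow(pheno)) else which(pheno$site == st)
    rows <- rows[!is.na(pheno[[tr]][rows])]
    if (!length(rows)) {
      stop("response has zero observations: ", tr,
           if (!is.na(st)) paste0(" at ", st) else "")
    }
    ids <- pheno$tree[rows]
    if (anyDuplicated(ids)) {
      stop("tree measured more than once for response ", tr,
           ": trees must appear at exactly one site")
    }
    grp <- as.character(pheno$group[rows])
    grp[is.na(grp)] <- "<none>"
    X <- if (length(unique(grp)) > 1) {
      stats::model.matrix(~grp)
    } else matrix(1, length(rows), 1, dimnames = list(NULL, "(Intercept)"))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop("confounded (aliased) fixed effects for response ", tr, ": ",
           paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]],
                 collapse = ", "))
    }
    name <- if (is.na(st)) tr else paste(tr, st, sep = "@")
    resp[[r]] <- list(name = name, trait = tr, site = st, ids = ids,
                      y = pheno[[tr]][rows], X = X,
                      rep = if (fit_replication)
                        paste(pheno$site[rows], pheno$replication[rows])
                      else NULL)
  }
  missing_ids <- setdiff(unique(unlist(lapply(resp, `[[`, "ids"))),
                         rownames(relmat))
  if (length(missing_ids)) {
    stop("relationship matrix does not cover phenotyped trees: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  sub_ids <- rownames(relmat)[rownames(relmat) %in%
                                unique(unlist(lapply(resp, `[[`, "ids")))]
  t <- length(resp)
  # residual covariance free iff same (non-NA-equal) site label
  site_of <- vapply(resp, function(r) {
    if (is.na(r$site)) "<pooled>" else r$site
  }, character(1))
  free_e <- outer(site_of, site_of, "==")
  list(resp = resp, t = t, sub_ids = sub_ids,
       K = unclass(relmat)[sub_ids, sub_ids, drop = FALSE],
       K_full = unclass(relmat), free_e = free_e,
       names = vapply(resp, `[[`, character(1), "name"),
       fit_replication = fit_replication)
}

psd_project <- function(S, clip_frac = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lo <- clip_frac * max(e$values, 0)
  if (min(e$values) >= lo) return(list(S = (S + t(S)) / 2, projected = FALSE))
  v <- pmax(e$values, lo)
  list(S = e$vectors %*% (v * t(e$vectors)), projected = TRUE)
}

# project Sigma_e per same-site block so structural zeros stay exact
psd_project_blocked <- function(S, free) {
  out <- S * 0
  done <- rep(FALSE, nrow(S))
  projected <- FALSE
  for (j in seq_len(nrow(S))) {
    if (done[j]) next
    blk <- which(free[j, ])
    pr <- psd_project(S[blk, blk, drop = FALSE])
    out[blk, blk] <- pr$S
    projected <- projected || pr$projected
    done[blk] <- TRUE
  }
  list(S = out, projected = projected)
}

start_values <- function(des) {
  t <- des$t
  ylist <- lapply(des$resp, `[[`, "y")
  vp <- vapply(ylist, stats::var, numeric(1))
  C <- diag(vp, t, t)
  if (t > 1) {
    for (j in seq_len(t - 1)) for (k in seq(j + 1, t)) {
      if (!des$free_e[j, k]) next
      shared <- intersect(des$resp[[j]]$ids, des$resp[[k]]$ids)
      if (length(shared) > 2) {
        cjk <- stats::cov(
          des$resp[[j]]$y[match(shared, des$resp[[j]]$ids)],
          des$resp[[k]]$y[match(shared, des$resp[[k]]$ids)])
        C[j, k] <- C[k, j] <- cjk
      }
    }
  }
  # half the phenotypic covariance, diagonal-loaded, for both components
  S0 <- 0.5 * (0.9 * C + 0.1 * diag(diag(C), t, t))
  Sigma_e0 <- S0 * des$free_e
  list(Sigma_a = S0, Sigma_e = Sigma_e0,
       sigma2_d = if (des$fit_replication) 0.1 * mean(vp) else NULL,
       vp = mean(vp))
}

param_table <- function(des, fit_replication) {
  t <- des$t
  rows <- list()
  for (j in seq_len(t)) for (k in j:t) {
    rows[[length(rows) + 1L]] <- data.frame(type = "a", i = j, j = k)
  }
  for (j in seq_len(t)) for (k in j:t) {
    if (des$free_e[j, k]) {
      rows[[length(rows) + 1L]] <- data.frame(type = "e", i = j, j = k)
    }
  }
  if (fit_replication) {
    rows[[length(rows) + 1L]] <- data.frame(type = "d", i = 0L, j = 0L)
  }
  pt <- do.call(rbind, rows)
  pt$label <- ifelse(pt$type == "d", "sigma2_d",
                     paste0("sigma_", pt$type, "(", des$names[pt$i], ",",
                            des$names[pmax(pt$j, 1)], ")"))
  pt
}

# ---- eigen fast path (complete multi-trait, Z = I, no replication) --------

fit_eigen <- function(des, control) {
  t <- des$t
  n <- length(des$resp[[1]]$ids)
  Y <- vapply(des$resp, function(r) r$y[match(des$sub_ids, r$ids)],
              numeric(n))
  eK <- eigen(des$K, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  U <- eK$vectors
  Yt <- crossprod(U, Y)
  Xl <- lapply(des$resp, function(r) {
    crossprod(U, r$X[match(des$sub_ids, r$ids), , drop = FALSE])
  })
  pj <- vapply(Xl, ncol, integer(1))
  p <- sum(pj)
  colof <- split(seq_len(p), rep(seq_len(t), pj))

  sv <- start_values(des)
  Sa <- sv$Sigma_a; Se <- sv$Sigma_e
  loglik <- numeric(0)
  projected_any <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # canonical transform: T' Se T = I, T' Sa T = diag(lam), so every
    # per-component inverse (d_i Sa + Se)^{-1} = T diag(1/(d_i lam + 1)) T'
    cSe <- tryCatch(chol(Se), error = function(e) {
      chol(Se + diag(1e-10 * (sum(diag(Se)) / t + 1), t))
    })
    Bc <- forwardsolve(t(cSe), t(forwardsolve(t(cSe), Sa)))
    eB <- eigen((Bc + t(Bc)) / 2, symmetric = TRUE)
    lam <- eB$values
    Tm <- backsolve(cSe, eB$vectors)
    W <- 1 / (outer(d, lam) + 1)             # n x t canonical weights
    Ytc <- Yt %*% Tm
    XtVX <- matrix(0, p, p); XtVy <- numeric(p)
    for (j in seq_len(t)) for (k in seq_len(t)) {
      for (cc in seq_len(t)) {
        XtVX[colof[[j]], colof[[k]]] <- XtVX[colof[[j]], colof[[k]]] +
          Tm[j, cc] * Tm[k, cc] * crossprod(Xl[[j]], Xl[[k]] * W[, cc])
      }
    }
    for (j in seq_len(t)) for (cc in seq_len(t)) {
      XtVy[colof[[j]]] <- XtVy[colof[[j]]] +
        Tm[j, cc] * crossprod(Xl[[j]], Ytc[, cc] * W[, cc])
    }
    cholXVX <- chol(XtVX)
    Q <- chol2inv(cholXVX)
    gamma <- Q %*% XtVy
    E <- Yt
    for (j in seq_len(t)) E[, j] <- E[, j] - Xl[[j]] %*% gamma[colof[[j]]]
    Rm <- ((E %*% Tm) * W) %*% t(Tm)         # rows are r_i = P y components
    yPy <- sum(Yt * Rm)
    logdetV <- sum(log1p(outer(d, lam))) + 2 * n * sum(log(diag(cSe)))
    ll <- -0.5 * (logdetV + 2 * sum(log(diag(cholXVX))) + yPy)
    loglik <- c(loglik, ll)

    # EM updates:  Sigma + (1/q) Sigma (M - TK) Sigma, with
    # TK = sum_i w(i) P_i computed through the canonical factors
    M1 <- crossprod(Rm * d, Rm)              # sum_i d_i r_i r_i'
    M0 <- crossprod(Rm)                      # sum_i r_i r_i'
    s1 <- colSums(W * d); s0 <- colSums(W)
    TK1 <- Tm %*% (s1 * t(Tm))
    TK0 <- Tm %*% (s0 * t(Tm))
    Zs <- lapply(seq_len(t), function(cc) {
      z <- matrix(0, n, p)
      for (j in seq_len(t)) z[, colof[[j]]] <- Tm[j, cc] * Xl[[j]]
      z
    })
    ZQ <- lapply(Zs, function(z) z %*% Q)
    for (cc in seq_len(t)) for (cp in seq_len(t)) {
      gv <- rowSums(ZQ[[cc]] * Zs[[cp]])
      TK1 <- TK1 - sum(d * W[, cc] * W[, cp] * gv) *
        outer(Tm[, cc], Tm[, cp])
      TK0 <- TK0 - sum(W[, cc] * W[, cp] * gv) *
        outer(Tm[, cc], Tm[, cp])
    }
    Sa_new <- Sa + (Sa %*% (M1 - TK1) %*% Sa) / n
    Se_new <- Se + (Se %*% (M0 - TK0) %*% Se) / n
    pra <- psd_project(Sa_new); Sa_new <- pra$S
    Se_new <- Se_new * des$free_e
    pre <- psd_project_blocked(Se_new, des$free_e)
    Se_new <- pre$S
    projected_any <- projected_any || pra$projected || pre$projected

    delta <- max(abs(c(Sa_new - Sa, Se_new - Se)) /
                   pmax(abs(c(Sa, Se)), control$near_zero_frac * sv$vp))
    Sa <- Sa_new; Se <- Se_new
    if (delta < control$tol || iter >= control$max_iter) break
  }
  list(Sigma_a = Sa, Sigma_e = Se, sigma2_d = NULL, loglik = loglik,
       iterations = iter, converged = iter < control$max_iter,
       projected = projected_any, path = "eigen",
       state = list(d = d, U = U, Yt = Yt, Xl = Xl, colof = colof, p = p,
                    Rm = NULL, gamma = NULL),
       vp = sv$vp)
}

# P applied to a rotated record matrix F (n x t), given current fit state
eigen_apply_P <- function(Fm, d, Sa, Se, Xl, colof, t, Qcache) {
  n <- nrow(Fm)
  W <- matrix(0, n, t)
  XtVf <- numeric(Qcache$p)
  for (i in seq_len(n)) {
    Ai <- Qcache$Ai[[i]]
    wi <- Ai %*% Fm[i, ]
    W[i, ] <- wi
    Bi <- Qcache$Bi[[i]]
    XtVf <- XtVf + crossprod(Bi, wi)
  }
  gf <- Qcache$Q %*% XtVf
  for (i in seq_len(n)) {
    W[i, ] <- W[i, ] - Qcache$Ai[[i]] %*% (Qcache$Bi[[i]] %*% gf)
  }
  W
}

# ---- dense generic path ----------------------------------------------------

fit_dense <- function(des, control) {
  t <- des$t
  resp <- des$resp
  K <- des$K
  kidx <- lapply(resp, function(r) match(r$ids, des$sub_ids))
  nrec <- vapply(resp, function(r) length(r$y), integer(1))
  N <- sum(nrec)
  rows <- split(seq_len(N), rep(seq_len(t), nrec))
  y <- unlist(lapply(resp, `[[`, "y"))
  X <- matrix(0, N, sum(vapply(resp, function(r) ncol(r$X), integer(1))))
  cn <- character(0); col0 <- 0L
  for (j in seq_len(t)) {
    X[rows[[j]], col0 + seq_len(ncol(resp[[j]]$X))] <- resp[[j]]$X
    cn <- c(cn, paste0(des$names[j], ":", colnames(resp[[j]]$X)))
    col0 <- col0 + ncol(resp[[j]]$X)
  }
  colnames(X) <- cn
  Zd <- NULL
  if (des$fit_replication) {
    lab <- unlist(lapply(resp, `[[`, "rep"))
    Zd <- stats::model.matrix(~ 0 + factor(lab))
    qd <- ncol(Zd)
  }
  # per-individual record lists for the residual E-step
  recs_of <- list()
  for (j in seq_len(t)) {
    for (i in seq_along(resp[[j]]$ids)) {
      id <- resp[[j]]$ids[i]
      recs_of[[id]] <- rbind(recs_of[[id]], c(j, rows[[j]][i]))
    }
  }
  multi <- Filter(function(m) nrow(m) > 1, recs_of)
  n_jk <- matrix(0, t, t)
  for (j in seq_len(t)) n_jk[j, j] <- nrec[j]
  for (m in multi) {
    js <- m[, 1]
    for (a in seq_len(nrow(m) - 1)) for (b in seq(a + 1, nrow(m))) {
      n_jk[js[a], js[b]] <- n_jk[js[a], js[b]] + 1
      n_jk[js[b], js[a]] <- n_jk[js[b], js[a]] + 1
    }
  }

  Kblocks <- lapply(seq_len(t), function(j) {
    lapply(seq_len(t), function(k) K[kidx[[j]], kidx[[k]], drop = FALSE])
  })

  sv <- start_values(des)
  Sa <- sv$Sigma_a; Se <- sv$Sigma_e; s2d <- sv$sigma2_d
  q <- length(des$sub_ids)
  loglik <- numeric(0)
  projected_any <- FALSE
  iter <- 0L
  final <- NULL
  repeat {
    iter <- iter + 1L
    V <- matrix(0, N, N)
    for (j in seq_len(t)) for (k in seq_len(t)) {
      if (Sa[j, k] != 0) {
        V[rows[[j]], rows[[k]]] <- V[rows[[j]], rows[[k]]] +
          Sa[j, k] * Kblocks[[j]][[k]]
      }
    }
    diag(V) <- diag(V) + rep(diag(Se), nrec)
    for (m in multi) {
      for (a in seq_len(nrow(m) - 1)) for (b in seq(a + 1, nrow(m))) {
        se <- Se[m[a, 1], m[b, 1]]
        V[m[a, 2], m[b, 2]] <- V[m[a, 2], m[b, 2]] + se
        V[m[b, 2], m[a, 2]] <- V[m[b, 2], m[a, 2]] + se
      }
    }
    if (!is.null(Zd)) V <- V + s2d * tcrossprod(Zd)
    cholV <- tryCatch(chol(V), error = function(e) {
      chol(V + diag(1e-8 * mean(diag(V)), N))
    })
    Vinv <- chol2inv(cholV)
    XtVinv <- crossprod(X, Vinv)
    XtVX <- XtVinv %*% X
    cholXVX <- chol(XtVX)
    Q <- chol2inv(cholXVX)
    gamma <- Q %*% (XtVinv %*% y)
    r <- Vinv %*% (y - X %*% gamma)
    P <- Vinv - crossprod(XtVinv, Q %*% XtVinv)
    ll <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cholXVX))) +
                    sum(y * r))
    loglik <- c(loglik, ll)

    # genetic update
    S <- matrix(0, q, t)
    for (j in seq_len(t)) S[kidx[[j]], j] <- r[rows[[j]]]
    KS <- K %*% S
    M1 <- crossprod(S, KS)
    TK1 <- matrix(0, t, t)
    for (j in seq_len(t)) for (k in j:t) {
      TK1[j, k] <- sum(P[rows[[j]], rows[[k]]] * Kblocks[[j]][[k]])
      TK1[k, j] <- TK1[j, k]
    }
    Sa_new <- Sa + (Sa %*% (M1 - TK1) %*% Sa) / q
    pra <- psd_project(Sa_new); Sa_new <- pra$S

    # residual update: per-individual E-step
    #   num_jk = sum_i [ e_ij e_ik + (S_loc - S_loc P_loc S_loc)_jk ]
    # over individuals observed for both j and k; divided by n_jk below.
    num <- matrix(0, t, t)
    dP <- diag(P)
    multi_rows <- if (length(multi)) unlist(lapply(multi, function(m) m[, 2]))
                  else integer(0)
    for (j in seq_len(t)) {
      # individuals whose only record is response j (vectorised)
      ss <- setdiff(rows[[j]], multi_rows)
      if (length(ss)) {
        num[j, j] <- num[j, j] +
          sum((Se[j, j] * r[ss])^2) +
          length(ss) * Se[j, j] - Se[j, j]^2 * sum(dP[ss])
      }
    }
    for (m in multi) {
      js <- m[, 1]; rr <- m[, 2]
      Sloc <- Se[js, js, drop = FALSE]
      eloc <- Sloc %*% r[rr]
      E2 <- Sloc - Sloc %*% P[rr, rr, drop = FALSE] %*% Sloc
      contrib <- tcrossprod(eloc) + E2
      num[js, js] <- num[js, js] + contrib
    }
    Se_new <- matrix(0, t, t)
    for (j in seq_len(t)) for (k in j:t) {
      if (des$free_e[j, k] && n_jk[j, k] > 0) {
        Se_new[j, k] <- Se_new[k, j] <- num[j, k] / n_jk[j, k]
      }
    }
    pre <- psd_project_blocked(Se_new, des$free_e)
    Se_new <- pre$S
    projected_any <- projected_any || pra$projected || pre$projected

    if (!is.null(Zd)) {
      Zr <- crossprod(Zd, r)
      trPZ <- sum((P %*% Zd) * Zd)
      s2d_new <- s2d + (s2d^2 / qd) * (sum(Zr^2) - trPZ)
      s2d_new <- max(s2d_new, 0)
    } else s2d_new <- NULL
    theta_old <- c(Sa, Se, s2d)
    theta_new <- c(Sa_new, Se_new, s2d_new)
    delta <- max(abs(theta_new - theta_old) /
                   pmax(abs(theta_old), control$near_zero_frac * sv$vp))
    Sa <- Sa_new; Se <- Se_new; s2d <- s2d_new
    if (delta < control$tol || iter >= control$max_iter) {
      final <- list(P = P, r = r, Vinv = Vinv, Q = Q, gamma = gamma,
                    rows = rows, kidx = kidx, X = X, y = y, Zd = Zd,
                    KS = KS, S = S, multi = multi, Kblocks = Kblocks)
      break
    }
  }
  list(Sigma_a = Sa, Sigma_e = Se, sigma2_d = s2d, loglik = loglik,
       iterations = iter, converged = iter < control$max_iter,
       projected = projected_any, path = "dense", state = final, vp = sv$vp)
}

# ---- AI step and BLUPs -----------------------------------------------------

ai_matrix_dense <- function(des, fit) {
  st <- fit$state; t <- des$t
  pt <- param_table(des, des$fit_replication)
  m <- nrow(pt)
  K <- des$K
  r <- st$r
  Fs <- vector("list", m)
  N <- length(r)
  Smat <- st$S
  KS <- st$KS
  for (pidx in seq_len(m)) {
    ty <- pt$type[pidx]; j <- pt$i[pidx]; k <- pt$j[pidx]
    f <- numeric(N)
    if (ty == "a") {
      f[st$rows[[j]]] <- (K %*% Smat[, k])[st$kidx[[j]]]
      if (j != k) f[st$rows[[k]]] <- f[st$rows[[k]]] + KS[st$kidx[[k]], j]
    } else if (ty == "e") {
      if (j == k) {
        f[st$rows[[j]]] <- r[st$rows[[j]]]
      } else {
        for (mm in st$multi) {
          a <- which(mm[, 1] == j); b <- which(mm[, 1] == k)
          if (length(a) && length(b)) {
            f[mm[a, 2]] <- f[mm[a, 2]] + r[mm[b, 2]]
            f[mm[b, 2]] <- f[mm[b, 2]] + r[mm[a, 2]]
          }
        }
      }
    } else {
      f <- st$Zd %*% crossprod(st$Zd, r)
    }
    Fs[[pidx]] <- as.numeric(f)
  }
  Fm <- do.call(cbind, Fs)
  PF <- st$P %*% Fm
  AI <- 0.5 * crossprod(Fm, PF)
  dimnames(AI) <- list(pt$label, pt$label)
  list(AI = AI, params = pt)
}

ai_matrix_eigen <- function(des, fit) {
  st <- fit$state; t <- des$t
  d <- st$d
  n <- length(d)
  Sa <- fit$Sigma_a; Se <- fit$Sigma_e
  # rebuild per-component inverses at the optimum
  Ai <- vector("list", n); Bi <- vector("list", n)
  p <- st$p
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  for (i in seq_len(n)) {
    Vi <- d[i] * Sa + Se
    Ai[[i]] <- tryCatch(chol2inv(chol(Vi)), error = function(e) {
      chol2inv(chol(Vi + diag(1e-8 * (sum(diag(Vi)) / t + 1), t)))
    })
    B <- matrix(0, t, p)
    for (j in seq_len(t)) B[j, st$colof[[j]]] <- st$Xl[[j]][i, ]
    Bi[[i]] <- B
    XtVX <- XtVX + crossprod(B, Ai[[i]] %*% B)
    XtVy <- XtVy + crossprod(B, Ai[[i]] %*% st$Yt[i, ])
  }
  Q <- chol2inv(chol(XtVX))
  gamma <- Q %*% XtVy
  Rm <- matrix(0, n, t)
  for (i in seq_len(n)) {
    Rm[i, ] <- Ai[[i]] %*% (st$Yt[i, ] - Bi[[i]] %*% gamma)
  }
  cache <- list(Ai = Ai, Bi = Bi, Q = Q, p = p)
  pt <- param_table(des, FALSE)
  m <- nrow(pt)
  Fs <- vector("list", m)
  for (pidx in seq_len(m)) {
    j <- pt$i[pidx]; k <- pt$j[pidx]
    Fm <- matrix(0, n, t)
    w <- if (pt$type[pidx] == "a") d else rep(1, n)
    Fm[, j] <- w * Rm[, k]
    if (j != k) Fm[, k] <- Fm[, k] + w * Rm[, j]
    Fs[[pidx]] <- Fm
  }
  PFs <- lapply(Fs, eigen_apply_P, d = d, Sa = Sa, Se = Se, Xl = st$Xl,
                colof = st$colof, t = t, Qcache = cache)
  AI <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in a:m) {
    AI[a, b] <- AI[b, a] <- 0.5 * sum(Fs[[a]] * PFs[[b]])
  }
  dimnames(AI) <- list(pt$label, pt$label)
  list(AI = AI, params = pt, Rm = Rm, cache = cache, gamma = gamma)
}

safe_inverse <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    out <- tryCatch(solve(A + diag(1e-8 * (mean(abs(diag(A))) + 1),
                                   nrow(A))),
                    error = function(e) matrix(NA_real_, nrow(A), ncol(A)))
  }
  dimnames(out) <- dimnames(A)
  out
}

blups_from_fit <- function(des, fit, ai) {
  t <- des$t
  Kf <- des$K_full
  ids_all <- rownames(Kf)
  Sa <- fit$Sigma_a
  out <- list()
  if (fit$path == "eigen") {
    U <- fit$state$U
    Rm <- ai$Rm
    # s_j in original space over sub_ids
    Sorig <- U %*% Rm
    Ksub <- Kf[, des$sub_ids, drop = FALSE]
    KS <- Ksub %*% Sorig                       # n_all x t:  K[all,sub] s_l
    d <- fit$state$d
    Krot <- Ksub %*% U
    Krot2 <- Krot^2
    for (j in seq_len(t)) {
      ahat <- as.numeric(KS %*% Sa[j, ])
      cvec <- vapply(seq_along(d), function(i) {
        as.numeric(Sa[j, ] %*% ai$cache$Ai[[i]] %*% Sa[, j])
      }, numeric(1))
      Hrows <- matrix(vapply(seq_along(d), function(i) {
        as.numeric(crossprod(ai$cache$Bi[[i]],
                             ai$cache$Ai[[i]] %*% Sa[, j]))
      }, numeric(fit$state$p)), ncol = fit$state$p, byrow = TRUE)
      v1 <- as.numeric(Krot2 %*% cvec)
      H <- Krot %*% Hrows
      term2 <- rowSums((H %*% ai$cache$Q) * H)
      pev <- pmax(Sa[j, j] * diag(Kf) - (v1 - term2), 0)
      denom <- Sa[j, j] * diag(Kf)
      acc <- ifelse(denom > 1e-12, sqrt(pmax(1 - pev / denom, 0)), 0)
      out[[j]] <- data.frame(id = ids_all, response = des$names[j],
                             ebv = ahat, pev = pev, accuracy = acc,
                             stringsAsFactors = FALSE)
    }
  } else {
    st <- fit$state
    r <- st$r
    Ksub <- Kf[, des$sub_ids, drop = FALSE]
    KS <- Ksub %*% st$S
    N <- length(r)
    for (j in seq_len(t)) {
      ahat <- as.numeric(KS %*% Sa[j, ])
      G <- matrix(0, length(ids_all), N)
      for (l in seq_len(t)) {
        if (Sa[j, l] != 0) {
          G[, st$rows[[l]]] <- G[, st$rows[[l]]] +
            Sa[j, l] * Kf[, des$sub_ids[st$kidx[[l]]], drop = FALSE]
        }
      }
      term <- rowSums((G %*% st$P) * G)
      pev <- pmax(Sa[j, j] * diag(Kf) - term, 0)
      denom <- Sa[j, j] * diag(Kf)
      acc <- ifelse(denom > 1e-12, sqrt(pmax(1 - pev / denom, 0)), 0)
      out[[j]] <- data.frame(id = ids_all, response = des$names[j],
                             ebv = ahat, pev = pev, accuracy = acc,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

finish_fit <- function(des, fit, control) {
  ai <- if (fit$path == "eigen") ai_matrix_eigen(des, fit)
        else ai_matrix_dense(des, fit)
  asycov <- safe_inverse(ai$AI)
  blup <- blups_from_fit(des, fit, ai)
  mono <- if (length(fit$loglik) > 1) {
    all(diff(fit$loglik) > -control$monotone_tol)
  } else TRUE
  if (!mono && !fit$projected) {
    warning("EM log-likelihood trace decreased beyond tolerance")
  }
  near_zero <- character(0)
  for (j in seq_len(des$t)) {
    if (fit$Sigma_a[j, j] < control$near_zero_frac * fit$vp) {
      near_zero <- c(near_zero, paste0("sigma2_a(", des$names[j], ")"))
    }
  }
  if (!fit$converged) {
    warning("EM did not converge in ", control$max_iter, " iterations")
  }
  dimnames(fit$Sigma_a) <- list(des$names, des$names)
  dimnames(fit$Sigma_e) <- list(des$names, des$names)
  beta <- if (fit$path == "eigen") {
    nm <- unlist(lapply(seq_len(des$t), function(j) {
      paste0(des$names[j], ":", colnames(des$resp[[j]]$X))
    }))
    stats::setNames(as.numeric(ai$gamma), nm)
  } else {
    stats::setNames(as.numeric(fit$state$gamma), colnames(fit$state$X))
  }
  structure(list(
    converged = fit$converged, iterations = fit$iterations,
    loglik = fit$loglik, monotone = mono, beta = beta,
    vc = list(Sigma_a = fit$Sigma_a, Sigma_e = fit$Sigma_e,
              sigma2_d = fit$sigma2_d, asycov = asycov,
              params = ai$params),
    blup = blup, responses = des$names,
    sites = vapply(des$resp, function(r) {
      if (is.na(r$site)) NA_character_ else r$site
    }, character(1)),
    traits = vapply(des$resp, `[[`, character(1), "trait"),
    near_zero = near_zero, path = fit$path,
    n = vapply(des$resp, function(r) length(r$y), integer(1))),
    class = "opqg_fit")
}

#' @export
print.opqg_fit <- function(x, ...) {
  cat(sprintf("<opqg_fit> %s path, %d iterations%s, logLik %.4f\n",
              x$path, x$iterations,
              if (x$converged) "" else " (NOT converged)",
              x$loglik[length(x$loglik)]))
  cat("Genetic (co)variances:\n"); print(round(x$vc$Sigma_a, 4))
  cat("Residual (co)variances:\n"); print(round(x$vc$Sigma_e, 4))
  if (!is.null(x$vc$sigma2_d)) {
    cat(sprintf("Replication variance: %.4f\n", x$vc$sigma2_d))
  }
  if (length(x$near_zero)) {
    cat("Near-zero components:", paste(x$near_zero, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit the univariate individual-tree mixed model by EM-REML
#'
#' Fits \eqn{y = X\beta + Z_d d + Z_a a + e} for a single trait at a
#' single site (or pooled across sites): genetic groups as fixed
#' effects, an optional random replication effect, and an additive
#' genetic effect with covariance \eqn{K \sigma^2_a} where K is the
#' pedigree A-matrix, the genomic G-matrix or a blend. Variance
#' components are estimated by EM-REML iterated to convergence, after
#' which one average-information (AI) step supplies the asymptotic
#' covariance of the estimates used for standard errors.
#'
#' @param pheno phenotype data.frame with columns `tree`, `site`,
#'   `replication`, `group` and the trait.
#' @param trait trait column name.
#' @param relmat an `opqg_relmat` covering all phenotyped trees.
#' @param site site to analyse, or `NA` to pool all sites.
#' @param fit_replication fit the random replication (design) effect;
#'   turn off when data were pre-adjusted with [design_adjust()].
#' @param control an [reml_control()].
#' @return An `opqg_fit`.
#' @export
fit_univariate <- function(pheno, trait, relmat, site = NA,
                           fit_replication = TRUE,
                           control = reml_control()) {
  des <- assemble_design(pheno, data.frame(trait = trait, site = site,
                                           stringsAsFactors = FALSE),
                         relmat, fit_replication)
  fit <- if (!fit_replication) fit_eigen_or_dense(des, control)
         else fit_dense(des, control)
  finish_fit(des, fit, control)
}

fit_eigen_or_dense <- function(des, control) {
  idsets <- lapply(des$resp, function(r) sort(r$ids))
  complete <- all(vapply(idsets, identical, logical(1), idsets[[1]]))
  if (complete && !des$fit_replication) fit_eigen(des, control)
  else fit_dense(des, control)
}

#' Fit the multivariate individual-tree mixed model by EM-REML
#'
#' Treats each (trait, site) combination as a response: genetic effects
#' have covariance `Sigma_a (x) K` (Kronecker product with the
#' relationship matrix), residuals have free covariance between
#' responses measured at the same site and structurally zero covariance
#' across sites (trees are measured at one site only). Supports both
#' traits-within-site and sites-as-traits layouts; per-response missing
#' records are allowed (row deletion per response). EM updates project
#' the genetic covariance to the nearest positive semidefinite matrix
#' each iteration; a final AI step yields the joint asymptotic
#' covariance.
#'
#' @param pheno phenotype data.frame (see [fit_univariate()]).
#' @param responses data.frame with columns `trait` and `site`
#'   (`NA` site pools across sites).
#' @param relmat an `opqg_relmat`.
#' @param control an [reml_control()].
#' @return An `opqg_fit`.
#' @export
fit_multivariate <- function(pheno, responses, relmat,
                             control = reml_control()) {
  stopifnot(is.data.frame(responses), nrow(responses) >= 2,
            all(c("trait", "site") %in% names(responses)))
  des <- assemble_design(pheno, responses, relmat, fit_replication = FALSE)
  fit <- fit_eigen_or_dense(des, control)
  finish_fit(des, fit, control)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates \eqn{-\tfrac12 [\log|V| + \log|X'V^{-1}X| + y'Py]} (up to
#' an additive constant) for the individual-tree model, with V
#' assembled directly from the supplied (co)variance components, the
#' relationship matrix and identity residual blocks.
#'
#' @inheritParams fit_multivariate
#' @param Sigma_a genetic covariance matrix over the responses (a
#'   scalar for a single response).
#' @param Sigma_e residual covariance matrix (structural zeros across
#'   sites enforced by the caller's values).
#' @param sigma2_d replication variance, or `NULL` if not fitted.
#' @param fit_replication include the replication random effect.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(pheno, responses, relmat, Sigma_a, Sigma_e,
                        sigma2_d = NULL,
                        fit_replication = !is.null(sigma2_d)) {
  des <- assemble_design(pheno, responses, relmat, fit_replication)
  t <- des$t
  Sigma_a <- matrix(Sigma_a, t, t)
  Sigma_e <- matrix(Sigma_e, t, t)
  resp <- des$resp
  nrec <- vapply(resp, function(r) length(r$y), integer(1))
  N <- sum(nrec)
  rows <- split(seq_len(N), rep(seq_len(t), nrec))
  kidx <- lapply(resp, function(r) match(r$ids, des$sub_ids))
  y <- unlist(lapply(resp, `[[`, "y"))
  X <- matrix(0, N, sum(vapply(resp, function(r) ncol(r$X), integer(1))))
  col0 <- 0L
  for (j in seq_len(t)) {
    X[rows[[j]], col0 + seq_len(ncol(resp[[j]]$X))] <- resp[[j]]$X
    col0 <- col0 + ncol(resp[[j]]$X)
  }
  V <- matrix(0, N, N)
  for (j in seq_len(t)) for (k in seq_len(t)) {
    if (Sigma_a[j, k] != 0) {
      V[rows[[j]], rows[[k]]] <- V[rows[[j]], rows[[k]]] +
        Sigma_a[j, k] * des$K[kidx[[j]], kidx[[k]], drop = FALSE]
    }
  }
  diag(V) <- diag(V) + rep(diag(Sigma_e), nrec)
  if (t > 1) {
    for (j in seq_len(t - 1)) for (k in seq(j + 1, t)) {
      if (Sigma_e[j, k] != 0) {
        shared <- intersect(resp[[j]]$ids, resp[[k]]$ids)
        if (length(shared)) {
          rj <- rows[[j]][match(shared, resp[[j]]$ids)]
          rk <- rows[[k]][match(shared, resp[[k]]$ids)]
          V[cbind(rj, rk)] <- V[cbind(rj, rk)] + Sigma_e[j, k]
          V[cbind(rk, rj)] <- V[cbind(rk, rj)] + Sigma_e[j, k]
        }
      }
    }
  }
  if (fit_replication) {
    lab <- unlist(lapply(resp, `[[`, "rep"))
    Zd <- stats::model.matrix(~ 0 + factor(lab))
    V <- V + sigma2_d * tcrossprod(Zd)
  }
  cholV <- chol(V)
  Vinv <- chol2inv(cholV)
  XtVX <- crossprod(X, Vinv) %*% X
  qrx <- qr(XtVX)
  if (qrx$rank < ncol(XtVX)) stop("singular X'V^{-1}X: aliased fixed effects")
  gamma <- solve(XtVX, crossprod(X, Vinv %*% y))
  yPy <- sum(y * (Vinv %*% (y - X %*% gamma)))
  -0.5 * (2 * sum(log(diag(cholV))) + determinant(XtVX)$modulus[1] + yPy)
}

#' Extract BLUP breeding values with accuracies
#'
#' Returns the predicted breeding values from the mixed-model solutions
#' at the final variance components, with prediction-error variances
#' and accuracy \eqn{\sqrt{1 - PEV/(K_{ii}\,\sigma^2_a)}}.
#'
#' @param fit an `opqg_fit`.
#' @return A data.frame: `id`, `response`, `ebv`, `pev`, `accuracy`.
#' @export
predict_blup <- function(fit) {
  stopifnot(inherits(fit, "opqg_fit"))
  fit$blup
}
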