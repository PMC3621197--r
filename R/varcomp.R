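#' Assemble a variance-component model
#'
#' The trait is modelled as multivariate normal with mean X beta and
#' covariance Omega = sum_k sigma2_k M_k + sigma2_e I, where the M_k are
#' user-supplied symmetric PSD structure matrices (additive relationship
#' 2*Phi, locus IBD matrix, household indicator, ...). Computation exploits
#' the block-diagonal structure induced by independent families: blocks are
#' the connected components of the combined nonzero pattern of the M_k.
#'
#' @param y numeric trait vector
#' @param components named list of n x n symmetric matrices (excluding the
#'   residual identity, which is always present)
#' @param X fixed-effect design matrix (default intercept only)
#' @param blocks optional precomputed list of block index vectors (the
#'   connected components of the combined sparsity pattern). Supplying it
#'   skips input validation and block discovery; intended for fitting many
#'   models that share one sparsity pattern, e.g. along a scan grid
#' @return a `vc_model` object
#' @export
vc_model <- function(y, components, X = NULL, blocks = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(blocks)) {
    stopifnot(nrow(X) == n, length(components) >= 1,
              !is.null(names(components)), all(nzchar(names(components))))
    for (nm in names(components)) {
      M <- components[[nm]]
      if (!isTRUE(all.equal(dim(M), c(n, n))))
        stop("component '", nm, "' has wrong dimension")
      if (max(abs(M - t(M))) > 1e-8)
        stop("component '", nm, "' is not symmetric")
    }
    if (qr(X)$rank < ncol(X)) {
      stop("design matrix is rank deficient; check columns: ",
           paste(colnames(X), collapse = ", "))
    }
    blocks <- vc_blocks(components, n)
  }
  block_data <- lapply(blocks, function(ix) {
    nb <- length(ix)
    list(idx = ix,
         y = matrix(y[ix], ncol = 1),
         X = X[ix, , drop = FALSE],
         M = lapply(components, function(M) M[ix, ix, drop = FALSE]),
         dix = seq.int(1L, nb * nb, by = nb + 1L))
  })
  structure(list(y = y, X = X, k = length(components),
                 comp_names = names(components), n = n,
                 blocks = block_data),
            class = "vc_model")
}

# connected components of the combined nonzero structure (union-find)
vc_blocks <- function(components, n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  adj <- Reduce(`+`, lapply(components, function(M) abs(M)))
  nz <- which(adj > 1e-12, arr.ind = TRUE)
  nz <- nz[nz[, 1] < nz[, 2], , drop = FALSE]
  for (r in seq_len(nrow(nz))) {
    a <- find(nz[r, 1]); b <- find(nz[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' Log-likelihood of a variance-component model
#'
#' Evaluates the multivariate normal log-likelihood
#' -1/2 [n ln 2 pi + ln|Omega| + (y - X beta)' Omega^{-1} (y - X beta)]
#' at the generalised-least-squares estimate of beta (profiling the fixed
#' effects, which is equivalent to joint ML).
#'
#' @param model a `vc_model`
#' @param sigma2 numeric vector of variances: one per component in model
#'   order, followed by the residual variance
#' @return list with `loglik`, `beta`, and `ok` (FALSE if Omega was not
#'   positive definite)
#' @export
vc_loglik <- function(model, sigma2) {
  k <- model$k
  stopifnot(length(sigma2) == k + 1)
  p <- ncol(model$X)
  XtOiX <- matrix(0, p, p)
  XtOiy <- numeric(p)
  ytOiy <- 0
  logdet <- 0
  for (b in model$blocks) {
    Omega <- sigma2[1] * b$M[[1]]
    if (k > 1) for (j in 2:k) Omega <- Omega + sigma2[j] * b$M[[j]]
    Omega[b$dix] <- Omega[b$dix] + sigma2[k + 1]
    R <- tryCatch(chol(Omega), error = function(e) NULL)
    if (is.null(R))
      return(list(loglik = -Inf, beta = rep(NA_real_, p), ok = FALSE))
    logdet <- logdet + 2 * sum(log(diag(R)))
    Ly <- backsolve(R, b$y, transpose = TRUE)
    LX <- backsolve(R, b$X, transpose = TRUE)
    XtOiX <- XtOiX + crossprod(LX)
    XtOiy <- XtOiy + crossprod(LX, Ly)[, 1]
    ytOiy <- ytOiy + sum(Ly^2)
  }
  beta <- tryCatch(solve(XtOiX, XtOiy), error = function(e) NULL)
  if (is.null(beta))
    return(list(loglik = -Inf, beta = rep(NA_real_, p), ok = FALSE))
  quad <- ytOiy - sum(beta * XtOiy)
  ll <- -0.5 * (model$n * log(2 * pi) + logdet + quad)
  list(loglik = ll, beta = as.numeric(beta), ok = TRUE)
}

#' Maximum-likelihood fit of a variance-component model
#'
#' Maximises the profiled log-likelihood over non-negative variances with
#' three deterministic starts (equal split, 90/10 and 10/90 of the
#' phenotypic variance between genetic-type and residual components).
#' Components converging to the zero boundary are pinned exactly at 0 in a
#' profile refit and flagged. Standard errors come from the numerically
#' observed information of the free variance parameters; the heritability SE
#' uses the delta method and is reported as NA when any fitted component sits
#' on the boundary.
#'
#' @param model a `vc_model`
#' @param h2_component name of the component whose variance share defines
#'   h2 (default `"additive"`; NA h2 if absent)
#' @param se compute standard errors (default TRUE)
#' @param boundary_tol variances below `boundary_tol * var(y)` are treated
#'   as boundary zeros
#' @param starts optional list of start vectors (variances, residual last)
#'   replacing the default deterministic multi-starts
#' @return a `vc_fit` list: `sigma2` (named, residual last), `beta`, `h2`,
#'   `h2_se`, `loglik`, `converged`, `boundary` (logical per component),
#'   `n`, `message`
#' @export
fit_ml <- function(model, h2_component = "additive", se = TRUE,
                   boundary_tol = 1e-5, starts = NULL) {
  k <- model$k
  vy <- stats::var(model$y)
  if (!is.finite(vy) || vy <= 0) stop("trait has no variance")

  negll <- function(par, free, fixed) {
    full <- fixed
    full[free] <- par
    r <- vc_loglik(model, full)
    if (!r$ok || !is.finite(r$loglik)) return(1e10)
    -r$loglik
  }

  if (is.null(starts))
    starts <- list(rep(vy / (k + 1), k + 1),
                   c(rep(0.9 * vy / k, k), 0.1 * vy),
                   c(rep(0.1 * vy / k, k), 0.9 * vy))
  all_idx <- seq_len(k + 1)
  lower <- c(rep(0, k), 1e-10 * vy)
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, negll, free = all_idx, fixed = numeric(k + 1),
                   method = "L-BFGS-B", lower = lower,
                   control = list(factr = 4.5e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-9) {
      best <- o
      conv <- o$convergence == 0
    }
  }
  if (is.null(best)) {
    return(structure(list(sigma2 = stats::setNames(rep(NA_real_, k + 1),
                                                   c(model$comp_names, "residual")),
                          beta = NULL, h2 = NA_real_, h2_se = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          boundary = rep(NA, k), n = model$n,
                          message = "all optimizer starts failed"),
                     class = "vc_fit"))
  }

  sig <- best$par
  boundary <- sig[seq_len(k)] < boundary_tol * vy
  if (any(boundary)) {
    fixed <- numeric(k + 1)
    free <- c(which(!boundary), k + 1L)
    o2 <- tryCatch(
      stats::optim(sig[free], negll, free = free, fixed = fixed,
                   method = "L-BFGS-B", lower = lower[free],
                   control = list(factr = 4.5e7, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o2) && o2$value <= best$value + 1e-6) {
      sig <- fixed
      sig[free] <- o2$par
      best$value <- min(best$value, o2$value)
      conv <- conv || o2$convergence == 0
    } else {
      sig[boundary] <- 0
    }
  }
  names(sig) <- c(model$comp_names, "residual")
  llr <- vc_loglik(model, sig)

  h2 <- NA_real_
  h2_se <- NA_real_
  gi <- match(h2_component, model$comp_names)
  if (!is.na(gi)) {
    h2 <- sig[gi] / sum(sig)
    if (se && !any(boundary)) {
      H <- num_hessian(function(p) negll(p, all_idx, numeric(k + 1)),
                       sig, step = pmax(1e-4 * vy, 1e-5 * sig))
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        tot <- sum(sig)
        grad <- rep(-sig[gi] / tot^2, k + 1)
        grad[gi] <- (tot - sig[gi]) / tot^2
        v <- drop(t(grad) %*% V %*% grad)
        if (is.finite(v) && v >= 0) h2_se <- sqrt(v)
      }
    }
  }

  structure(list(sigma2 = sig, beta = llr$beta,
                 h2 = unname(h2), h2_se = unname(h2_se),
                 loglik = llr$loglik, converged = conv,
                 boundary = stats::setNames(boundary, model$comp_names),
                 n = model$n, message = if (conv) "ok" else "not converged"),
            class = "vc_fit")
}

# central-difference Hessian
num_hessian <- function(f, x, step) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- step[i]; ej[j] <- step[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * step[i] * step[j])
    }
  }
  H
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Variance-component ML fit (n =", x$n, ")\n")
  print(round(x$sigma2, 5))
  cat(sprintf("h2 = %.4f (SE %s), logL = %.4f, %s\n",
              x$h2, ifelse(is.na(x$h2_se), "NA", sprintf("%.4f", x$h2_se)),
              x$loglik, x$message))
  invisible(x)
}

#' Boundary likelihood-ratio test for a single variance component
#'
#' Tests sigma2 = 0 for one component against the one-sided alternative.
#' The null distribution is the 1/2:1/2 mixture of a point mass at zero and
#' a chi-square with 1 df: p = 1/2 P(chi2_1 >= LRT) when LRT > 0, and
#' p = 1/2 when LRT = 0.
#'
#' @param fit_full fit with the component estimated
#' @param fit_null fit with the component constrained to zero (same data)
#' @param tol tolerance on a negative LRT before declaring an optimiser
#'   failure
#' @return list with `lrt`, `p_value`, `df` description
#' @export
heritability_test <- function(fit_full, fit_null, tol = 1e-6) {
  lrt <- 2 * (fit_full$loglik - fit_null$loglik)
  if (lrt < -tol)
    stop("full-model likelihood below null likelihood (",
         format(lrt), "): optimisation failure")
  lrt <- max(0, lrt)
  p <- if (lrt == 0) 0.5 else 0.5 * stats::pchisq(lrt, df = 1,
                                                  lower.tail = FALSE)
  list(lrt = lrt, p_value = p,
       df = "1/2:1/2 mixture of point mass at 0 and chi-square(1)")
}

#' LOD score from a likelihood-ratio statistic
#'
#' LOD = LRT / (2 ln 10), the log10 likelihood ratio.
#'
#' @param lrt non-negative likelihood-ratio statistic
#' @return LOD score
#' @export
lod_from_lrt <- function(lrt) {
  if (any(lrt < 0)) stop("LRT statistic must be non-negative")
  lrt / (2 * log(10))
}

#' Likelihood-ratio statistic from a LOD score
#' @param lod non-negative LOD score
#' @return LRT statistic
#' @export
lrt_from_lod <- function(lod) {
  if (any(lod < 0)) stop("LOD must be non-negative")
  lod * 2 * log(10)
}

#' Polygenic heritability fit
#'
#' Convenience wrapper: fits trait ~ additive polygenic (2*Phi) [+ household]
#' + residual by ML, plus the nested null with the additive component fixed
#' at zero, and returns estimates with the boundary-mixture LRT p-value.
#'
#' @param y trait vector (typically the inverse-normal second-stage trait)
#' @param phi kinship matrix for the same individuals (in order)
#' @param household optional household indicator matrix
#' @param X optional design matrix (default intercept)
#' @return list with `fit` (vc_fit), `null` (vc_fit), `h2`, `h2_se`,
#'   `lrt`, `p_value`
#' @export
polygenic_fit <- function(y, phi, household = NULL, X = NULL) {
  comps <- list(additive = 2 * phi)
  if (!is.null(household)) comps$household <- household
  full <- fit_ml(vc_model(y, comps, X = X))
  null_comps <- comps
  null_comps$additive <- NULL
  if (length(null_comps) == 0) {
    nfit <- iid_null_fit(y, X)
  } else {
    nfit <- fit_ml(vc_model(y, null_comps, X = X), h2_component = NA, se = FALSE)
  }
  ht <- heritability_test(full, nfit)
  list(fit = full, null = nfit, h2 = full$h2, h2_se = full$h2_se,
       lrt = ht$lrt, p_value = ht$p_value)
}

# ML fit of the iid-residual null (no genetic component): OLS beta,
# sigma2 = RSS/n, closed-form log-likelihood.
iid_null_fit <- function(y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  b <- stats::lm.fit(X, y)
  s2 <- sum(b$residuals^2) / n
  ll <- -0.5 * n * (log(2 * pi * s2) + 1)
  structure(list(sigma2 = c(residual = s2), beta = b$coefficients,
                 h2 = 0, h2_se = NA_real_, loglik = ll, converged = TRUE,
                 boundary = logical(0), n = n, message = "ok"),
            class = "vc_fit")
}

#' Region-stratified heritability
#'
#' Fits the polygenic model separately per stratum and overall. Kinship is
#' computed on the full pedigree and subset to each stratum, so relatedness
#' through individuals outside the stratum is preserved; related pairs that
#' span strata are dropped from all per-stratum fits and tallied.
#'
#' @param y named trait vector (names = individual ids)
#' @param phi full kinship matrix (dimnames = ids)
#' @param strata named character vector of stratum labels per id
#' @param household optional full household matrix
#' @return list with `overall` and one entry per stratum; strata with no
#'   related pairs are flagged not estimable. Attribute `dropped_pairs`
#'   counts related pairs spanning strata.
#' @export
stratified_heritability <- function(y, phi, strata, household = NULL) {
  ids <- names(y)
  stopifnot(!is.null(ids), all(ids %in% rownames(phi)),
            all(ids %in% names(strata)))
  phi <- phi[ids, ids]
  strata <- strata[ids]
  off <- phi
  diag(off) <- 0
  cross <- outer(strata, strata, "!=")
  dropped <- sum(off > 0 & cross & upper.tri(off))

  fit_one <- function(sel) {
    ph <- phi[sel, sel, drop = FALSE]
    offs <- ph; diag(offs) <- 0
    if (sum(sel) < 3 || all(offs == 0)) {
      return(list(estimable = FALSE, n = sum(sel),
                  reason = "no related pairs in stratum"))
    }
    hh <- if (is.null(household)) NULL else household[sel, sel, drop = FALSE]
    pf <- polygenic_fit(y[sel], ph, household = hh)
    c(list(estimable = TRUE, n = sum(sel)), pf)
  }

  out <- list(overall = fit_one(rep(TRUE, length(y))))
  for (s in sort(unique(strata))) out[[s]] <- fit_one(strata == s)
  attr(out, "dropped_pairs") <- dropped
  if (dropped > 0)
    warning(dropped, " related pair(s) span strata and are dropped from ",
            "stratified fits")
  out
}
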