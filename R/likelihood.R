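# Sufficient statistics and reference likelihood code paths.  The optimizer
# uses the compiled kernels (src/likelihood.cpp); the R implementations here
# are independent reference paths kept for validation and for the row-wise
# definition of FIML.

# split a two-trait panel into MZ/DZ matrices in the internal wave-major
# column order
ace_data <- function(panel_mz, panel_dz = NULL) {
  if (is.null(panel_dz)) {
    zyg <- attr(panel_mz, "zygosity")
    if (!all(zyg %in% c("MZ", "DZ")))
      stop("panel has records with unknown zygosity; needed for ACE models")
    full <- unclass(panel_mz)[, , drop = FALSE]
    mz <- full[zyg == "MZ", , drop = FALSE]
    dz <- full[zyg == "DZ", , drop = FALSE]
  } else {
    mz <- unclass(panel_mz)
    dz <- unclass(panel_dz)
  }
  if (ncol(mz) != 12)
    stop("ACE cross-lagged models need a two-trait (12-column) panel")
  wm <- wm_index()
  keep <- function(m) m[rowSums(!is.na(m)) > 0, wm, drop = FALSE]
  structure(list(MZ = keep(mz), DZ = keep(dz)), class = "ace_data")
}

# ML sufficient statistics (divisor n); complete data only
suff_complete <- function(X) {
  n <- nrow(X)
  if (n == 0) return(list(n = 0, xbar = rep(0, ncol(X)),
                          S = diag(ncol(X))))
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  list(n = n, xbar = xbar, S = crossprod(Xc) / n)
}

# pattern-wise sufficient statistics for FIML (0-based indices for C++)
suff_patterns <- function(X) {
  if (nrow(X) == 0) return(list())
  pat <- apply(!is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  lapply(split(seq_len(nrow(X)), pat), function(rows) {
    obs <- which(!is.na(X[rows[1], ]))
    Xs <- X[rows, obs, drop = FALSE]
    st <- suff_complete(Xs)
    list(n = st$n, idx = obs - 1L, xbar = st$xbar, S = st$S)
  })
}

has_missing <- function(ad) anyNA(ad$MZ) || anyNA(ad$DZ)

# multivariate-normal -2 log-likelihood from sufficient statistics
mvn_neg2ll_suff <- function(n, xbar, S, mu, Sigma) {
  p <- length(mu)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  logdet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  d <- xbar - mu
  n * (p * log(2 * pi) + logdet + sum(Sinv * S) +
         drop(t(d) %*% Sinv %*% d))
}

#' ACE cross-lagged log-likelihood
#'
#' Full-information maximum-likelihood log-likelihood of a parameter vector
#' for the two-group (MZ/DZ) ACE cross-lagged model.  With complete data the
#' value is computed from the group sufficient statistics; with missing
#' values each row contributes the multivariate-normal log-density of its
#' observed subset of the implied 12-variable distribution.  Both code paths
#' agree on complete data.
#'
#' @param theta full parameter vector (length 57; see the model
#'   parameterization in the package vignette).
#' @param data an object built by the fitting functions from MZ and DZ
#'   panels, or a `phenotype_panel` carrying zygosity.
#' @param rho_a_dz DZ additive-genetic cross-twin correlation.
#' @param method `"auto"` picks the sufficient-statistic path for complete
#'   data and pattern-wise FIML otherwise; `"rowwise"` forces the row-by-row
#'   reference implementation (slow; used for validation).
#' @return log-likelihood (scalar); `-Inf` if the implied covariance is not
#'   positive definite.
#' @export
ace_loglik <- function(theta, data, rho_a_dz = 0.5,
                       method = c("auto", "rowwise")) {
  method <- match.arg(method)
  if (inherits(data, "phenotype_panel")) data <- ace_data(data)
  rho <- ace_rho(rho_a_dz)
  if (method == "rowwise") return(-0.5 * ace_neg2ll_rowwise(theta, rho, data))
  n2ll <- if (has_missing(data)) {
    stats <- lapply(data[c("MZ", "DZ")], suff_patterns)
    cpp_ace_neg2ll_fiml(theta, rho, stats)
  } else {
    stats <- lapply(data[c("MZ", "DZ")], suff_complete)
    cpp_ace_neg2ll(theta, rho, stats)
  }
  if (n2ll >= 1e12) return(-Inf)
  -0.5 * n2ll
}

# slow row-wise FIML reference
ace_neg2ll_rowwise <- function(theta, rho, data) {
  mu6 <- theta[52:57]
  mu <- c(mu6, mu6)
  tot <- 0
  for (g in c("MZ", "DZ")) {
    X <- data[[g]]
    if (nrow(X) == 0) next
    Sigma <- cpp_ace_sigma(theta, rho[, g])
    for (i in seq_len(nrow(X))) {
      obs <- which(!is.na(X[i, ]))
      d <- X[i, obs] - mu[obs]
      So <- Sigma[obs, obs, drop = FALSE]
      R <- tryCatch(chol(So), error = function(e) NULL)
      if (is.null(R)) return(Inf)
      z <- backsolve(R, d, transpose = TRUE)
      tot <- tot + length(obs) * log(2 * pi) + 2 * sum(log(diag(R))) +
        sum(z^2)
    }
  }
  tot
}

#' Saturated two-group model
#'
#' Unconstrained means-and-covariances baseline fitted per zygosity group.
#' With complete data the maximum is available in closed form; with missing
#' values the saturated parameters are obtained by an EM algorithm for the
#' multivariate normal and the FIML deviance is evaluated at the EM solution.
#'
#' @param data MZ/DZ data (as passed to [fit_ace_clpm()]).
#' @param em_tol,em_max_iter EM stopping rules (missing data only).
#' @return list with `minus2ll`, `n_params`, `aic`, per-group `mu`/`sigma`.
#' @export
fit_saturated <- function(data, em_tol = 1e-8, em_max_iter = 500) {
  if (inherits(data, "phenotype_panel")) data <- ace_data(data)
  m2 <- 0
  npar <- 0
  pars <- list()
  for (g in c("MZ", "DZ")) {
    X <- data[[g]]
    if (nrow(X) == 0) next
    if (anyNA(X)) {
      em <- mvn_em(X, tol = em_tol, max_iter = em_max_iter)
      mu <- em$mu; S <- em$sigma
      m2g <- fiml_neg2ll_at(mu, S, suff_patterns(X))
    } else {
      st <- suff_complete(X)
      mu <- st$xbar; S <- st$S
      m2g <- mvn_neg2ll_suff(st$n, st$xbar, st$S, mu, S)
    }
    p <- ncol(X)
    m2 <- m2 + m2g
    npar <- npar + p + p * (p + 1) / 2
    pars[[g]] <- list(mu = mu, sigma = S)
  }
  list(minus2ll = m2, n_params = npar, aic = m2 + 2 * npar, groups = pars)
}

# FIML deviance of fixed (mu, Sigma) over missingness patterns
fiml_neg2ll_at <- function(mu, Sigma, pats) {
  tot <- 0
  for (st in pats) {
    idx <- st$idx + 1L
    tot <- tot + mvn_neg2ll_suff(st$n, st$xbar, st$S, mu[idx],
                                 Sigma[idx, idx, drop = FALSE])
  }
  tot
}

# EM for multivariate-normal mean/covariance with MCAR missing data
mvn_em <- function(X, tol = 1e-8, max_iter = 500) {
  p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  S <- stats::cov(X, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S)[diag(S) <= 0] <- 1
  ev <- eigen(S, symmetric = TRUE)
  S <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
  pats <- suff_patterns(X)
  last <- Inf
  for (it in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    n <- 0
    for (st in pats) {
      o <- st$idx + 1L
      m <- setdiff(seq_len(p), o)
      n <- n + st$n
      Soo_inv <- solve(S[o, o, drop = FALSE])
      Exx_oo <- st$n * (st$S + tcrossprod(st$xbar))
      if (length(m) == 0) {
        sum_x[o] <- sum_x[o] + st$n * st$xbar
        sum_xx[o, o] <- sum_xx[o, o] + Exx_oo
        next
      }
      B <- S[m, o, drop = FALSE] %*% Soo_inv
      mbar <- mu[m] + drop(B %*% (st$xbar - mu[o]))
      Cv <- S[m, m, drop = FALSE] - B %*% S[o, m, drop = FALSE]
      # E[sum x_m], E[sum x_m x_o'], E[sum x_m x_m']
      Exo <- st$n * tcrossprod(mu[m], st$xbar) +
        B %*% (Exx_oo - st$n * tcrossprod(mu[o], st$xbar))
      dev <- Exx_oo - st$n * (tcrossprod(st$xbar, mu[o]) +
                                tcrossprod(mu[o], st$xbar) -
                                tcrossprod(mu[o]))
      Emm <- st$n * (Cv + tcrossprod(mu[m])) +
        B %*% (st$n * (tcrossprod(st$xbar, mu[m]) -
                         tcrossprod(mu[o], mu[m]))) +
        t(B %*% (st$n * (tcrossprod(st$xbar, mu[m]) -
                           tcrossprod(mu[o], mu[m])))) +
        B %*% dev %*% t(B)
      sum_x[o] <- sum_x[o] + st$n * st$xbar
      sum_x[m] <- sum_x[m] + st$n * mbar
      sum_xx[o, o] <- sum_xx[o, o] + Exx_oo
      sum_xx[m, o] <- sum_xx[m, o] + Exo
      sum_xx[o, m] <- sum_xx[o, m] + t(Exo)
      sum_xx[m, m] <- sum_xx[m, m] + Emm
    }
    mu <- sum_x / n
    S <- sum_xx / n - tcrossprod(mu)
    S <- (S + t(S)) / 2
    ll <- fiml_neg2ll_at(mu, S, pats)
    if (abs(last - ll) < tol) break
    last <- ll
  }
  list(mu = mu, sigma = S, minus2ll = ll, iterations = it)
}
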