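#' Correlated-factors twin model
#'
#' Decomposes each of the six observed variables (two traits x three waves)
#' into A, C and E with free cross-variable correlation matrices per
#' component.  Each component's 6x6 covariance is parameterized by an
#' unconstrained lower-triangular Cholesky factor, which guarantees a valid
#' (positive semi-definite, unit-diagonal after scaling) correlation matrix.
#' Used to locate obsolete (nonsignificant) shared-environment associations
#' before fitting the structured cross-lagged model; see [reduce_model()].
#'
#' @inheritParams fit_ace_clpm
#' @param se `"none"` or `"delta"` (needed for the rC confidence intervals
#'   that drive model reduction).
#' @return A `cf_fit`: list with `correlations` (per component: 6x6 matrix,
#'   and with `se = "delta"` matching `se`/`ci_lower`/`ci_upper` matrices),
#'   `components` (per-variable h2/c2/e2), `fit`, `lambda` (component
#'   covariances).
#' @export
fit_correlated_factors <- function(data, n_starts = 3, jitter_sd = 0.1,
                                   se = c("none", "delta"), start_seed = 1L,
                                   rho_a_dz = 0.5, control = list(),
                                   conf_level = 0.95) {
  se <- match.arg(se)
  ad <- as_ace_data(data)
  traits <- attr(ad, "traits") %||% c("t1", "t2")
  rho <- ace_rho(rho_a_dz)
  missing_data <- has_missing(ad)
  stats <- if (missing_data) lapply(ad[c("MZ", "DZ")], suff_patterns)
  else lapply(ad[c("MZ", "DZ")], suff_complete)
  n_total <- nrow(ad$MZ) + nrow(ad$DZ)
  objective <- if (missing_data)
    function(p) cpp_cf_neg2ll_fiml(p, rho, stats)
  else function(p) cpp_cf_neg2ll(p, rho, stats)

  start0 <- cf_mom_start(ad, rho_a_dz)
  ctl <- modifyList(list(maxit = 3000, reltol = 1e-12), control)
  runs <- local_seed(start_seed, {
    lapply(seq_len(n_starts), function(s) {
      st <- if (s == 1) start0 else
        start0 + rnorm(length(start0), 0,
                       jitter_sd * pmax(abs(start0), 0.05))
      if (!is.finite(objective(st))) st <- start0
      r <- tryCatch(optim(st, objective, method = "BFGS", control = ctl),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      r2 <- tryCatch(optim(r$par, objective, method = "BFGS", control = ctl),
                     error = function(e) NULL)
      if (!is.null(r2) && r2$value <= r$value) r2 else r
    })
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) stop("correlated-factors model did not converge")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  g <- pracma::grad(objective, best$par)
  lam <- cpp_cf_lambda(best$par)
  names(lam) <- c("A", "C", "E")
  vn <- wm_var_names(traits)
  lam <- lapply(lam, function(L) {
    dimnames(L) <- list(vn, vn)
    L
  })
  tot <- Reduce(`+`, lam)
  comps <- data.frame(variable = vn,
                      h2 = diag(lam$A) / diag(tot),
                      c2 = diag(lam$C) / diag(tot),
                      e2 = diag(lam$E) / diag(tot))
  rownames(comps) <- NULL
  correlations <- lapply(lam, cf_safe_cor)
  out <- list(correlations = correlations, components = comps,
              lambda = lam, traits = traits, par = best$par,
              fit = list(minus2ll = best$value, n_params = length(best$par),
                         aic = best$value + 2 * length(best$par),
                         convergence = best$convergence,
                         grad_norm = max(abs(g)) / n_total,
                         converged = best$convergence == 0 &&
                           max(abs(g)) / n_total < 1e-3,
                         n_pairs = c(MZ = nrow(ad$MZ), DZ = nrow(ad$DZ))))
  if (se == "delta") {
    H <- pracma::hessian(objective, best$par)
    vc <- tryCatch(2 * solve(H), error = function(e) {
      warning("observed information is singular; using pseudo-inverse")
      2 * MASS::ginv(H)
    })
    z <- qnorm(1 - (1 - conf_level) / 2)
    corr_of <- function(p) {
      lamp <- cpp_cf_lambda(p)
      unlist(lapply(lamp, function(L) cf_safe_cor(L)[lower.tri(L)]))
    }
    J <- pracma::jacobian(corr_of, best$par)
    sds <- sqrt(pmax(diag(J %*% vc %*% t(J)), 0))
    sem <- split(sds, rep(c("A", "C", "E"), each = 15))
    for (k in c("A", "C", "E")) {
      M <- matrix(NA_real_, 6, 6, dimnames = list(vn, vn))
      M[lower.tri(M)] <- sem[[k]]
      M[upper.tri(M)] <- t(M)[upper.tri(M)]
      out$correlations[[paste0("se_", k)]] <- M
      out$correlations[[paste0("ci_lower_", k)]] <-
        out$correlations[[k]] - z * M
      out$correlations[[paste0("ci_upper_", k)]] <-
        out$correlations[[k]] + z * M
    }
    out$vcov <- vc
  }
  class(out) <- "cf_fit"
  out
}

# correlation matrix that tolerates near-zero variances
cf_safe_cor <- function(L) {
  d <- diag(L)
  s <- sqrt(pmax(d, 1e-10))
  R <- L / outer(s, s)
  diag(R) <- 1
  R[d < 1e-8, ] <- 0
  R[, d < 1e-8] <- 0
  diag(R) <- 1
  R
}

cf_mom_start <- function(ad, rho_a_dz) {
  covs <- lapply(c("MZ", "DZ"), function(g) {
    S <- stats::cov(ad[[g]], use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    list(W = (S[1:6, 1:6] + S[7:12, 7:12]) / 2,
         X = (S[1:6, 7:12] + t(S[1:6, 7:12])) / 2, n = nrow(ad[[g]]))
  })
  names(covs) <- c("MZ", "DZ")
  SW <- (covs$MZ$W * covs$MZ$n + covs$DZ$W * covs$DZ$n) /
    max(covs$MZ$n + covs$DZ$n, 1)
  A <- (covs$MZ$X - covs$DZ$X) / (1 - rho_a_dz)
  C <- covs$MZ$X - A
  E <- SW - covs$MZ$X
  mu <- colMeans(rbind(ad$MZ, ad$DZ), na.rm = TRUE)
  mu[is.na(mu)] <- 0
  chol_low <- function(M) {
    L <- t(chol(clamp_psd(M, 1e-3)))
    L[lower.tri(L, diag = TRUE)]
  }
  c(chol_low(A), chol_low(C), chol_low(E), (mu[1:6] + mu[7:12]) / 2)
}

#' @export
print.cf_fit <- function(x, digits = 2, ...) {
  cat("Correlated-factors twin model (FIML)\n")
  f <- x$fit
  cat(sprintf("  -2logL = %.2f  params = %d  converged: %s\n",
              f$minus2ll, f$n_params, f$converged))
  cat("\nVariance components:\n")
  cc <- x$components
  cc[-1] <- lapply(cc[-1], round, digits)
  print(cc, row.names = FALSE)
  for (k in c("A", "C", "E")) {
    cat("\nr", k, " correlations:\n", sep = "")
    print(round(x$correlations[[k]], digits))
  }
  invisible(x)
}

#' Drop nonsignificant shared-environment paths from a model specification
#'
#' Implements the model-reduction rule: every shared-environment (C)
#' cross-trait parameter of the cross-lagged model -- the two cross-lagged
#' transmission paths per interval and the within-wave covariances -- is
#' fixed to 0 when the corresponding shared-environment correlation (rC) in
#' the correlated-factors model has a confidence interval covering zero.
#' C variances and C stability paths are retained.
#'
#' @param spec the full [ace_model_spec()] to reduce.
#' @param cf a `cf_fit` estimated with `se = "delta"`.
#' @param alpha significance level of the rC test.
#' @return A reduced `ace_model_spec`; the decision log is attached as
#'   attribute `"reduction_log"`.
#' @export
reduce_model <- function(spec, cf, alpha = 0.05) {
  if (is.null(cf$correlations$se_C))
    stop("reduce_model needs a correlated-factors fit with se = \"delta\"")
  z <- qnorm(1 - alpha / 2)
  vn <- wm_var_names(cf$traits)
  # parameter label -> (row, col) of the rC entry it is judged by;
  # wave-major variable order is (t1w1, t2w1, t1w2, t2w2, t1w3, t2w3)
  map <- list(
    "C.W1.l21" = c(1, 2),   # within wave 1
    "C.T1.21"  = c(1, 4),   # trait1 w1 -> trait2 w2
    "C.T1.12"  = c(2, 3),   # trait2 w1 -> trait1 w2
    "C.P2.l21" = c(3, 4),   # within wave 2
    "C.T2.21"  = c(3, 6),   # trait1 w2 -> trait2 w3
    "C.T2.12"  = c(4, 5),   # trait2 w2 -> trait1 w3
    "C.P3.l21" = c(5, 6))   # within wave 3
  rC <- cf$correlations$C
  seC <- cf$correlations$se_C
  rows <- lapply(names(map), function(lbl) {
    ij <- map[[lbl]]
    est <- rC[ij[1], ij[2]]
    s <- seC[ij[1], ij[2]]
    lo <- est - z * s
    hi <- est + z * s
    data.frame(parameter = lbl,
               r_c = est, se = s, ci_lower = lo, ci_upper = hi,
               between = paste0(vn[ij[1]], " ~ ", vn[ij[2]]),
               dropped = is.na(s) | (lo <= 0 & hi >= 0))
  })
  log <- do.call(rbind, rows)
  drops <- union(spec$dropped, log$parameter[log$dropped])
  out <- ace_model_spec(drop = drops, free_means = any(spec$free[52:57]),
                        rho_a_dz = spec$rho_a_dz)
  attr(out, "reduction_log") <- log
  out
}
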