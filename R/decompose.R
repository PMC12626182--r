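#' A/C/E decomposition of every standardized path
#'
#' Expresses each stability, within-wave correlational and cross-lagged path
#' of a fitted (or generating) ACE cross-lagged model as the sum of its
#' additive-genetic, shared-environment and nonshared-environment
#' contributions, by path tracing on the standardized solution: loading into
#' the source component, latent path, loading out to the unit-variance
#' target.  By construction the three contributions sum to the total
#' standardized path, and the percentage shares sum to 100.  Shares can fall
#' outside \[0, 100\] when contributions oppose in sign; such paths are
#' flagged.  When the total path is numerically zero the shares are
#' undefined and reported as `NA`.
#'
#' @param fit an `ace_clpm_fit` (or an [ace_model()] for the generating-model
#'   decomposition).
#' @param conf_level level for the delta-method intervals (only when the fit
#'   carries a `vcov`, i.e. was estimated with `se = "delta"`).
#' @return data.frame with one row per path: total, per-component `beta_*`
#'   and `share_*` (in percent), `opposing_signs` flag, and per-component
#'   confidence bounds when available.
#' @export
decompose_paths <- function(fit, conf_level = 0.95) {
  if (inherits(fit, "ace_model")) {
    sol <- standardized_solution(fit)
    vc <- NULL
  } else {
    sol <- fit$solution
    vc <- fit$vcov
  }
  p <- sol$paths
  degenerate <- abs(p$total) < 1e-6
  p[degenerate, c("share_A", "share_C", "share_E")] <- NA_real_
  bsig <- sign(as.matrix(p[, c("beta_A", "beta_C", "beta_E")]))
  p$opposing_signs <- apply(bsig, 1, function(s) {
    s <- s[s != 0]
    length(unique(s)) > 1
  })
  if (any(p$opposing_signs))
    warning("component contributions oppose in sign for: ",
            paste(p$path[p$opposing_signs], collapse = ", "),
            "; their percentage shares are signed and may fall outside ",
            "[0, 100]")
  if (!is.null(vc)) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    spec <- fit$spec
    betas_of <- function(free) {
      m <- theta_to_model(theta_unpack(spec, free), traits = fit$traits,
                          rho_a_dz = spec$rho_a_dz)
      s <- standardized_solution(m)$paths
      as.vector(as.matrix(s[, c("beta_A", "beta_C", "beta_E")]))
    }
    J <- pracma::jacobian(betas_of, fit$par_free)
    sds <- sqrt(pmax(diag(J %*% vc %*% t(J)), 0))
    sem <- matrix(sds, nrow = nrow(p), ncol = 3)
    for (i in 1:3) {
      k <- c("A", "C", "E")[i]
      p[[paste0("beta_", k, "_lower")]] <- p[[paste0("beta_", k)]] -
        z * sem[, i]
      p[[paste0("beta_", k, "_upper")]] <- p[[paste0("beta_", k)]] +
        z * sem[, i]
    }
  }
  p
}

#' Univariate variance components implied by a fitted model
#'
#' Per observed variable and wave: the A/C/E shares of the total implied
#' variance, and for waves 2-3 also the shares of the innovation (residual)
#' variance, which is what path-diagram figures report at later assessments.
#'
#' @param fit an `ace_clpm_fit` or [ace_model()].
#' @return data.frame with columns `variable`, `wave`, `h2`, `c2`, `e2`,
#'   `h2_innovation`, `c2_innovation`, `e2_innovation`.
#' @export
variance_components <- function(fit) {
  sol <- if (inherits(fit, "ace_model")) standardized_solution(fit)
  else fit$solution
  sol$variances
}
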