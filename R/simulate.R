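#' Simulate twin-pair panels from an ACE cross-lagged generating model
#'
#' Draws MZ and DZ twin pairs from the latent A/C/E autoregressive
#' cross-lagged structure of an [ace_model()].  Per component and pair, the
#' wave-1 latent trait vectors of the two twins are drawn from one
#' multivariate normal with cross-twin correlation equal to the component's
#' zygosity coefficient (1 for A and C in MZ pairs; 0.5 for A and 1 for C in
#' DZ pairs; 0 for E); later waves are propagated through the transmission
#' matrices with cross-twin-correlated innovations.  Observed scores are the
#' sum of the three components, plus sex and age effects when covariate
#' injection is enabled; wave-level missingness is applied last.
#'
#' @param model an [ace_model()].
#' @param n_mz,n_dz number of MZ and DZ pairs.
#' @param seed integer seed; the seed fully determines the output.  `NULL`
#'   leaves the RNG state untouched.
#' @param missingness `"none"` for complete data or `"wave"` for per-twin
#'   wave-level missingness completely at random with the model's retention
#'   probabilities.
#' @param covariates if `TRUE`, inject sex and age effects (and emit the sex
#'   and age columns needed to residualize them back out).
#' @return data.frame with one row per pair: `family_id`, `zygosity`,
#'   `sex_1`, `sex_2` (0/1), `age_w1..3` (years), and the 12 score columns in
#'   panel order (twin 1: trait1 w1..w3, trait2 w1..w3; then twin 2).
#' @export
simulate_pairs <- function(model, n_mz, n_dz, seed = NULL,
                           missingness = c("none", "wave"),
                           covariates = FALSE) {
  missingness <- match.arg(missingness)
  validate_ace_model(model)
  if (!is.null(seed)) set.seed(seed)
  mz <- sim_group(model, n_mz, "MZ", missingness, covariates)
  dz <- sim_group(model, n_dz, "DZ", missingness, covariates)
  dz$family_id <- dz$family_id + n_mz
  out <- rbind(mz, dz)
  out$family_id <- sprintf("fam%05d", out$family_id)
  rownames(out) <- NULL
  out
}

sim_group <- function(model, n, zyg, missingness, covariates) {
  traits <- model$traits
  cols <- c("family_id", "zygosity", "sex_1", "sex_2",
            paste0("age_w", 1:3), panel_col_names(traits))
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$zygosity <- character(0)
    return(out)
  }
  rho <- model$rho[, zyg]
  # accumulate observed scores in wave-major pair order
  # (twin1: t1w1,t2w1,...,t2w3; twin2 likewise)
  obs <- matrix(0, n, 12)
  wave_cols <- function(w) c(2 * w - 1, 2 * w, 6 + 2 * w - 1, 6 + 2 * w)
  for (k in c("A", "C", "E")) {
    comp <- model[[k]]
    r <- rho[k]
    TT <- function(Tm) rbind(cbind(Tm, matrix(0, 2, 2)),
                             cbind(matrix(0, 2, 2), Tm))
    pairSigma <- function(P) rbind(cbind(P, r * P), cbind(r * P, P))
    x <- MASS::mvrnorm(n, rep(0, 4), pairSigma(comp$W1))
    if (is.null(dim(x))) x <- matrix(x, nrow = n)
    obs[, wave_cols(1)] <- obs[, wave_cols(1)] + x
    for (t in 1:2) {
      u <- MASS::mvrnorm(n, rep(0, 4), pairSigma(comp[[paste0("P", t + 1)]]))
      if (is.null(dim(u))) u <- matrix(u, nrow = n)
      x <- x %*% t(TT(comp[[paste0("T", t)]])) + u
      obs[, wave_cols(t + 1)] <- obs[, wave_cols(t + 1)] + x
    }
  }
  # covariates
  sex1 <- stats::rbinom(n, 1, 0.5)
  sex2 <- if (zyg == "MZ") sex1 else stats::rbinom(n, 1, 0.5)
  cv <- model$covariates
  ages <- vapply(1:3, function(w)
    cv$age_mean[w] + stats::rnorm(n, 0, cv$age_sd), numeric(n))
  if (is.null(dim(ages))) ages <- matrix(ages, nrow = n)
  if (covariates) {
    for (w in 1:3) {
      dz_age <- ages[, w] - cv$age_mean[w]
      for (j in 1:2) {  # trait index within wave
        eff1 <- cv$sex[j] * (sex1 - 0.5) + cv$age[j] * dz_age
        eff2 <- cv$sex[j] * (sex2 - 0.5) + cv$age[j] * dz_age
        obs[, 2 * (w - 1) + j] <- obs[, 2 * (w - 1) + j] + eff1
        obs[, 6 + 2 * (w - 1) + j] <- obs[, 6 + 2 * (w - 1) + j] + eff2
      }
    }
  }
  if (missingness == "wave") {
    keep <- model$retention
    for (tw in 1:2) for (w in 1:3) {
      drop <- stats::runif(n) > keep[w]
      if (any(drop)) {
        idx <- 6 * (tw - 1) + c(2 * w - 1, 2 * w)
        obs[drop, idx] <- NA_real_
      }
    }
  }
  # reorder wave-major -> panel columns
  obs <- obs[, c(.panel_of_wm, .panel_of_wm + 6L), drop = FALSE]
  out <- data.frame(family_id = seq_len(n), zygosity = zyg,
                    sex_1 = sex1, sex_2 = sex2,
                    age_w1 = ages[, 1], age_w2 = ages[, 2], age_w3 = ages[, 3])
  obs <- as.data.frame(obs)
  names(obs) <- panel_col_names(traits)
  cbind(out, obs)
}
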