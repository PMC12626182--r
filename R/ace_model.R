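#' Autoregressive ACE cross-lagged generating model
#'
#' Container for the full parameter set of a latent A/C/E autoregressive
#' cross-lagged structure for two traits measured at three waves: per variance
#' component a wave-1 2x2 trait covariance, a 2x2 transmission matrix per
#' interval (diagonal = stability paths, off-diagonal = cross-lagged paths,
#' rows index the target trait) and 2x2 innovation covariances at waves 2 and
#' 3.  Cross-twin correlations are fixed at 1 (MZ) and `rho_a_dz` (DZ) for A,
#' 1 for C and 0 for E in both groups.
#'
#' @param A,C,E per-component parameter lists with elements `W1`, `T1`, `P2`,
#'   `T2`, `P3` (all 2x2 matrices; `W1`, `P2`, `P3` symmetric positive
#'   semi-definite).
#' @param traits length-2 character vector naming the traits; the first is the
#'   cognitive measure, the second the emotional-problems measure.
#' @param rho_a_dz cross-twin correlation of the additive-genetic component in
#'   DZ pairs; 0.5 under random mating.
#' @param covariates list of covariate effects used by [simulate_pairs()] when
#'   covariate injection is enabled: `sex` and `age` (per-trait effect sizes in
#'   SD units), `age_mean` (per-wave mean ages in years) and `age_sd`.
#' @param retention per-wave probabilities that a twin contributes data at
#'   that wave, used for the wave-level missingness mode of the simulator.
#'
#' @return An object of class `ace_model`.
#' @export
ace_model <- function(A, C, E, traits = c("cog", "emo"), rho_a_dz = 0.5,
                      covariates = list(sex = c(0.10, 0.15),
                                        age = c(0.05, 0.03),
                                        age_mean = c(7, 9, 12), age_sd = 0.25),
                      retention = c(1.00, 0.62, 0.82)) {
  m <- structure(list(A = A, C = C, E = E, traits = traits,
                      rho = ace_rho(rho_a_dz), covariates = covariates,
                      retention = retention),
                 class = "ace_model")
  validate_ace_model(m)
  m
}

#' @export
print.ace_model <- function(x, ...) {
  cat("ACE autoregressive cross-lagged generating model\n")
  cat("  traits:", paste(x$traits, collapse = ", "),
      " | DZ additive-genetic correlation:", x$rho["A", "DZ"], "\n")
  v <- vapply(c("A", "C", "E"), function(k) diag(lambda_wm(x[[k]])),
              numeric(6))
  tot <- rowSums(v)
  cat("  implied total variances:", paste(round(tot, 3), collapse = " "), "\n")
  sh <- round(100 * v / tot, 1)
  rownames(sh) <- wm_var_names(x$traits)
  cat("  implied variance shares (%):\n")
  print(sh)
  invisible(x)
}

validate_ace_model <- function(m) {
  stopifnot(length(m$traits) == 2)
  for (k in c("A", "C", "E")) {
    comp <- m[[k]]
    if (!all(c("W1", "T1", "P2", "T2", "P3") %in% names(comp)))
      stop("component ", k, " must contain W1, T1, P2, T2, P3")
    for (nm in c("W1", "P2", "P3")) {
      M <- comp[[nm]]
      if (!isTRUE(all.equal(M, t(M), tolerance = 1e-10)))
        stop("block ", nm, " of component ", k, " is not symmetric")
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10)
        stop("block ", nm, " of component ", k,
             " is not positive semi-definite (min eigenvalue ",
             signif(min(ev), 3), ")")
    }
  }
  tot <- diag(phen_sigma_wm(m))
  if (any(tot <= 0)) stop("implied total variance must be positive")
  invisible(TRUE)
}

# within-twin 6x6 covariance of one component, wave-major order
lambda_wm <- function(comp) {
  B <- matrix(0, 6, 6)
  B[3:4, 1:2] <- comp$T1
  B[5:6, 3:4] <- comp$T2
  Psi <- matrix(0, 6, 6)
  Psi[1:2, 1:2] <- comp$W1
  Psi[3:4, 3:4] <- comp$P2
  Psi[5:6, 5:6] <- comp$P3
  M <- diag(6) + B + B %*% B            # (I - B)^{-1}; B is nilpotent
  M %*% Psi %*% t(M)
}

model_lambdas <- function(m) lapply(m[c("A", "C", "E")], lambda_wm)

# phenotypic (within-twin) implied covariance, wave-major
phen_sigma_wm <- function(m) Reduce(`+`, model_lambdas(m))

#' Model-implied moments for one zygosity group
#'
#' Closed-form implied 12x12 covariance matrix and mean vector of the observed
#' scores of a twin pair.  Per component the within-pair latent vector obeys a
#' recursive system with strictly lower-triangular (in time) transmission, so
#' its covariance is available in closed form; the observed covariance is the
#' sum over the A, C and E components with cross-twin blocks weighted by the
#' component's zygosity correlation.  Columns follow the fixed panel order
#' (twin 1: trait1 w1..w3, trait2 w1..w3; then twin 2).
#'
#' @param model an [ace_model()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return list with elements `sigma` (12x12), `mu` (length 12; zero for the
#'   covariate-free model).
#' @export
implied_moments <- function(model, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  lam <- model_lambdas(model)
  rho <- model$rho[, zygosity]
  SW <- Reduce(`+`, lam)
  SX <- Reduce(`+`, Map(`*`, lam, rho))
  S <- rbind(cbind(SW, SX), cbind(SX, SW))
  # reorder wave-major -> panel
  p <- c(.panel_of_wm, .panel_of_wm + 6L)
  S <- S[p, p, drop = FALSE]
  nm <- panel_col_names(model$traits)
  dimnames(S) <- list(nm, nm)
  list(sigma = S, mu = setNames(rep(0, 12), nm))
}

# Flatten a model to the canonical 57-vector (Cholesky parameterization).
model_to_theta <- function(m, means = rep(0, 6)) {
  th <- numeric(57)
  off <- 0
  for (k in c("A", "C", "E")) {
    comp <- m[[k]]
    th[off + 1:3] <- chol3(comp$W1)
    th[off + 4:7] <- as.vector(comp$T1)      # column-major
    th[off + 8:10] <- chol3(comp$P2)
    th[off + 11:14] <- as.vector(comp$T2)
    th[off + 15:17] <- chol3(comp$P3)
    off <- off + 17
  }
  th[52:57] <- means
  th
}

theta_to_model <- function(theta, traits = c("cog", "emo"), rho_a_dz = 0.5) {
  unflat <- function(off) {
    list(W1 = cov3(theta[off + 1:3]),
         T1 = matrix(theta[off + 4:7], 2, 2),
         P2 = cov3(theta[off + 8:10]),
         T2 = matrix(theta[off + 11:14], 2, 2),
         P3 = cov3(theta[off + 15:17]))
  }
  structure(list(A = unflat(0), C = unflat(17), E = unflat(34),
                 traits = traits, rho = ace_rho(rho_a_dz),
                 covariates = NULL, retention = c(1, 1, 1),
                 means = theta[52:57]),
            class = "ace_model")
}

# 2x2 symmetric PSD matrix <-> 3 Cholesky entries (l11, l21, l22)
chol3 <- function(M) {
  l11 <- sqrt(max(M[1, 1], 0))
  l21 <- if (l11 > 1e-12) M[2, 1] / l11 else 0
  l22 <- sqrt(max(M[2, 2] - l21^2, 0))
  c(l11, l21, l22)
}

cov3 <- function(l) {
  L <- matrix(c(l[1], l[2], 0, l[3]), 2, 2)
  L %*% t(L)
}

#' Model-implied phenotypic cross-lagged paths
#'
#' Computes the population-level phenotypic autoregressive cross-lagged
#' solution implied by an ACE generating model: for each interval the wave
#' t+1 variables are projected on both wave t variables (partial regressions),
#' and within-wave associations are reported as correlations (wave 1 total,
#' waves 2-3 partialled on the previous wave).
#'
#' @param model an [ace_model()] (or the standardized solution of a fit).
#' @return data.frame with columns `path`, `type`, `estimate`.
#' @export
implied_clpm_paths <- function(model) {
  S <- phen_sigma_wm(model)
  tr <- model$traits
  rows <- list()
  for (t in 1:2) {
    from <- (2 * t - 1):(2 * t)
    to <- from + 2
    G <- solve(S[from, from], S[from, to])   # rows = source, cols = target
    # standardized: data are analysed standardized; rescale by sds
    sds <- sqrt(diag(S))
    Gs <- G * outer(sds[from], 1 / sds[to])
    rows[[length(rows) + 1]] <- data.frame(
      path = c(paste0(tr[1], "_w", t, " -> ", tr[1], "_w", t + 1),
               paste0(tr[2], "_w", t, " -> ", tr[2], "_w", t + 1),
               paste0(tr[1], "_w", t, " -> ", tr[2], "_w", t + 1),
               paste0(tr[2], "_w", t, " -> ", tr[1], "_w", t + 1)),
      type = c("stability", "stability", "crosslag", "crosslag"),
      estimate = c(Gs[1, 1], Gs[2, 2], Gs[1, 2], Gs[2, 1]))
  }
  R <- stats::cov2cor(S)
  wcor <- c(R[1, 2], partial_cor(S, 3, 4, 1:2), partial_cor(S, 5, 6, 3:4))
  rows[[length(rows) + 1]] <- data.frame(
    path = paste0(tr[1], "_w", 1:3, " ~~ ", tr[2], "_w", 1:3),
    type = "correlational", estimate = wcor)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

partial_cor <- function(S, i, j, given) {
  Sc <- S[c(i, j), c(i, j)] -
    S[c(i, j), given] %*% solve(S[given, given], S[given, c(i, j)])
  Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
}

#' Standardized solution of an ACE cross-lagged model
#'
#' Expresses every model parameter on the standardized scale on which results
#' are reported: observed variables scaled to unit implied total variance,
#' path contributions by path tracing (loading in, latent path, loading out),
#' so that for every phenotypic path the A, C and E contributions sum to the
#' total.
#'
#' @param model an [ace_model()] or fitted parameter object.
#' @return list with `paths` (data.frame: one row per path x component
#'   contribution), `variances` (per variable per wave: component shares of
#'   total and of innovation variance) and `sds` (implied total SDs).
#' @keywords internal
standardized_solution <- function(model) {
  lam <- model_lambdas(model)
  tot <- Reduce(`+`, lam)
  sds <- sqrt(diag(tot))
  tr <- model$traits
  comps <- c("A", "C", "E")

  paths <- list()
  add <- function(path, type, bk) {
    tot_b <- sum(bk)
    paths[[length(paths) + 1]] <<- data.frame(
      path = path, type = type, total = tot_b,
      beta_A = bk[1], beta_C = bk[2], beta_E = bk[3],
      share_A = 100 * bk[1] / tot_b, share_C = 100 * bk[2] / tot_b,
      share_E = 100 * bk[3] / tot_b)
  }
  for (t in 1:2) {
    Tn <- paste0("T", t)
    for (src in 1:2) for (tgt in 1:2) {
      src_wm <- 2 * (t - 1) + src
      tgt_wm <- 2 * t + tgt
      bk <- vapply(comps, function(k)
        model[[k]][[Tn]][tgt, src] * lam[[k]][src_wm, src_wm] /
          (sds[src_wm] * sds[tgt_wm]), numeric(1))
      add(paste0(tr[src], "_w", t, " -> ", tr[tgt], "_w", t + 1),
          if (src == tgt) "stability" else "crosslag", bk)
    }
  }
  # within-wave contributions: wave 1 from W1, waves 2-3 from innovations
  for (w in 1:3) {
    blk <- if (w == 1) "W1" else paste0("P", w)
    i <- 2 * w - 1
    bk <- vapply(comps, function(k)
      model[[k]][[blk]][1, 2] / (sds[i] * sds[i + 1]), numeric(1))
    add(paste0(tr[1], "_w", w, " ~~ ", tr[2], "_w", w), "correlational", bk)
  }
  paths <- do.call(rbind, paths)
  rownames(paths) <- NULL

  vrows <- list()
  for (w in 1:3) for (j in 1:2) {
    i <- 2 * (w - 1) + j
    v_tot <- vapply(comps, function(k) lam[[k]][i, i], numeric(1))
    v_in <- if (w == 1) v_tot else
      vapply(comps, function(k) model[[k]][[paste0("P", w)]][j, j], numeric(1))
    vrows[[length(vrows) + 1]] <- data.frame(
      variable = tr[j], wave = w,
      h2 = v_tot[1] / sum(v_tot), c2 = v_tot[2] / sum(v_tot),
      e2 = v_tot[3] / sum(v_tot),
      h2_innovation = v_in[1] / sum(v_in), c2_innovation = v_in[2] / sum(v_in),
      e2_innovation = v_in[3] / sum(v_in))
  }
  variances <- do.call(rbind, vrows)
  list(paths = paths, variances = variances,
       sds = setNames(sds, wm_var_names(tr)))
}

# the standardized free-parameter vector used by recovery studies: all path
# contributions plus all variance shares
standardized_parameters <- function(model) {
  s <- standardized_solution(model)
  p <- s$paths
  betas <- setNames(
    as.vector(t(as.matrix(p[, c("beta_A", "beta_C", "beta_E")]))),
    as.vector(t(outer(p$path, c("A", "C", "E"), paste, sep = " | "))))
  v <- s$variances
  shares <- setNames(
    as.vector(t(as.matrix(v[, c("h2", "c2", "e2")]))),
    as.vector(t(outer(paste0(v$variable, "_w", v$wave),
                      c("h2", "c2", "e2"), paste, sep = " | "))))
  c(betas, shares)
}
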