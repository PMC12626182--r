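test_that("the compiled component algebra matches the R reference", {
  m <- twin_preset("verbal")
  th <- twinlag:::model_to_theta(m)
  lam_cpp <- twinlag:::cpp_ace_lambda(th)
  lam_r <- twinlag:::model_lambdas(m)
  for (k in 1:3)
    expect_equal(lam_cpp[[k]], unname(lam_r[[k]]), tolerance = 1e-12)
  for (z in c("MZ", "DZ")) {
    S_cpp <- twinlag:::cpp_ace_sigma(th, twinlag:::ace_rho(0.5)[, z])
    wm <- twinlag:::wm_index()
    S_r <- implied_moments(m, z)$sigma[wm, wm]
    expect_equal(S_cpp, unname(S_r), tolerance = 1e-12)
  }
})

test_that("row-wise FIML equals the sufficient-statistic likelihood on
           complete data", {
  m <- toy_model()
  pan <- sim_panel(m, 120, 120, seed = 23)
  th <- twinlag:::model_to_theta(m)
  ll_fast <- ace_loglik(th, pan)
  ll_row <- ace_loglik(th, pan, method = "rowwise")
  expect_equal(-2 * ll_fast, -2 * ll_row, tolerance = 1e-6)
})

test_that("row-wise FIML equals the pattern-wise likelihood with missing
           data", {
  m <- toy_model()
  pan <- sim_panel(m, 150, 150, seed = 24, missingness = "wave")
  th <- twinlag:::model_to_theta(m)
  expect_equal(-2 * ace_loglik(th, pan),
               -2 * ace_loglik(th, pan, method = "rowwise"),
               tolerance = 1e-6)
})

test_that("an entirely masked column equals marginalizing the implied
           normal", {
  m <- toy_model()
  pan <- sim_panel(m, 100, 100, seed = 25)
  X <- unclass(pan)
  X[, "cog_1_w2"] <- NA   # mask one column completely
  panm <- as_phenotype_panel(X, traits = c("cog", "emo"),
                             zygosity = attr(pan, "zygosity"),
                             standardize = FALSE)
  th <- twinlag:::model_to_theta(m)
  ll_mask <- -2 * ace_loglik(th, panm)
  # oracle: drop the row/column from the implied moments per group
  wm <- twinlag:::wm_index()
  drop_i <- match("cog_1_w2", colnames(pan)[wm])
  tot <- 0
  for (z in c("MZ", "DZ")) {
    S <- twinlag:::cpp_ace_sigma(th, twinlag:::ace_rho(0.5)[, z])
    mu <- rep(th[52:57], 2)
    Xg <- unclass(panm)[attr(panm, "zygosity") == z, wm][, -drop_i]
    st <- twinlag:::suff_complete(Xg)
    tot <- tot + twinlag:::mvn_neg2ll_suff(
      st$n, st$xbar, st$S, mu[-drop_i], S[-drop_i, -drop_i])
  }
  expect_equal(ll_mask, tot, tolerance = 1e-6)
})

test_that("a non-positive-definite proposal yields -Inf log-likelihood,
           not an error", {
  pan <- sim_panel(toy_model(), 30, 30, seed = 26)
  th <- twinlag:::model_to_theta(toy_model())
  th[1:3] <- 0   # kill A wave-1 variance
  th[35:37] <- 0 # kill E wave-1 variance
  th[18:20] <- 0 # kill C wave-1 variance -> singular
  expect_identical(ace_loglik(th, pan), -Inf)
})

test_that("the saturated deviance equals the closed-form plug-in maximum", {
  pan <- sim_panel(toy_model(), 80, 80, seed = 27)
  sat <- fit_saturated(pan)
  ad <- twinlag:::ace_data(pan)
  tot <- 0
  for (g in c("MZ", "DZ")) {
    st <- twinlag:::suff_complete(ad[[g]])
    R <- chol(st$S)
    tot <- tot + st$n * (12 * log(2 * pi) + 2 * sum(log(diag(R))) + 12)
  }
  expect_equal(sat$minus2ll, tot, tolerance = 1e-8)
  expect_equal(sat$n_params, 2 * (12 + 78))
})

test_that("EM reaches the saturated FIML optimum with missing data", {
  m <- toy_model()
  set.seed(28)
  X <- simulate_pairs(m, 250, 0, seed = 28, missingness = "wave")
  Xm <- as.matrix(X[, panel_col_names_for_test()])
  em <- twinlag:::mvn_em(Xm, tol = 1e-10, max_iter = 2000)
  # oracle: direct numerical maximization over (mu, Cholesky of Sigma)
  pats <- twinlag:::suff_patterns(Xm)
  p <- ncol(Xm)
  obj <- function(par) {
    mu <- par[1:p]
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- par[-(1:p)]
    twinlag:::fiml_neg2ll_at(mu, L %*% t(L), pats)
  }
  L0 <- t(chol(em$sigma))
  start <- c(em$mu, L0[lower.tri(L0, diag = TRUE)])
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lte(em$minus2ll, opt$value + 1e-3)
  # and EM beats simple-minded estimates
  naive <- twinlag:::fiml_neg2ll_at(colMeans(Xm, na.rm = TRUE),
                                    twinlag:::clamp_psd(
                                      cov(Xm, use = "pairwise.complete.obs"),
                                      1e-6), pats)
  expect_lte(em$minus2ll, naive + 1e-6)
})
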