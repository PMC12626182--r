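test_that("univariate ACE matches Falconer's closed forms and recovers a
           known heritability", {
  pan <- sim_panel(flat_ace_model(0.45, 0.25, 0.30), 6000, 6000, seed = 31)
  u <- univariate_ace(pan, "cog_w1")
  expect_lt(max(abs(u$components - u$falconer)), 0.02)
  expect_lt(abs(u$components[["h2"]] - 0.45), 0.035)
  expect_lt(abs(u$twin_correlations[["r_mz"]] - 0.70), 0.02)
  expect_lt(abs(u$twin_correlations[["r_dz"]] - 0.475), 0.025)
})

test_that("uncorrelated twins yield e2 near one", {
  pan <- sim_panel(pure_component_model("E"), 2000, 2000, seed = 32)
  u <- univariate_ace(pan, "emo_w2")
  expect_equal(unname(u$components["e2"]), 1, tolerance = 0.02)
})

test_that("the ACE cross-lagged fit recovers generating parameters", {
  m <- toy_model()
  pan <- sim_panel(m, 4000, 4000, seed = 33)
  fit <- fit_ace_clpm(pan, n_starts = 2)
  expect_true(fit$fit$converged)
  truth <- twinlag:::standardized_parameters(m)
  est <- twinlag:::standardized_parameters(fit$model)
  expect_lt(max(abs(est - truth)), 0.06)
  # the deviance at the estimate beats the deviance at the truth
  ll_true <- -2 * ace_loglik(twinlag:::model_to_theta(m), pan)
  expect_lte(fit$fit$minus2ll, ll_true)
})

test_that("an A-only generating model is recognized", {
  blk <- function(v) list(W1 = diag(v, 2), T1 = diag(0.3, 2),
                          P2 = diag(v, 2), T2 = diag(0.3, 2),
                          P3 = diag(v, 2))
  m <- ace_model(A = blk(0.7), C = blk(0), E = blk(0.3))
  pan <- sim_panel(m, 3000, 3000, seed = 34)
  fit <- fit_ace_clpm(pan, n_starts = 2)
  v <- variance_components(fit)
  expect_lt(max(v$c2[v$wave == 1]), 0.03)
  expect_equal(v$h2[v$wave == 1], rep(0.7, 2), tolerance = 0.04)
})

test_that("component contributions sum to the total and shares to 100", {
  pan <- sim_panel(toy_model(), 800, 800, seed = 35)
  fit <- fit_ace_clpm(pan, n_starts = 1)
  d <- suppressWarnings(decompose_paths(fit))
  expect_equal(d$beta_A + d$beta_C + d$beta_E, d$total, tolerance = 1e-8)
  ok <- !is.na(d$share_A)
  expect_equal(d$share_A[ok] + d$share_C[ok] + d$share_E[ok],
               rep(100, sum(ok)), tolerance = 1e-6)
  v <- variance_components(fit)
  expect_equal(v$h2 + v$c2 + v$e2, rep(1, 6), tolerance = 1e-8)
  expect_equal(v$h2_innovation + v$c2_innovation + v$e2_innovation,
               rep(1, 6), tolerance = 1e-8)
})

test_that("share arithmetic follows the component/total ratio", {
  # a single-component cross-lag carries a 100% share
  tg <- toy_targets(shares = list(c2e1 = c(1, 0, 0), c2e2 = c(.4, .4, .2),
                                  e2c1 = c(.3, .4, .3),
                                  e2c2 = c(.4, .3, .3)))
  d <- suppressWarnings(decompose_paths(calibrate_ace_model(tg)))
  row <- d[d$path == "cog_w1 -> emo_w2", ]
  expect_equal(row$share_A, 100, tolerance = 1e-8)
  expect_equal(row$share_C, 0, tolerance = 1e-8)
  expect_equal(row$share_E, 0, tolerance = 1e-8)
  # worked ratio: -0.10/-0.01/-0.005 -> 87.0/8.7/4.3
  b <- c(-0.10, -0.01, -0.005)
  expect_equal(100 * b / sum(b), c(86.95652, 8.695652, 4.347826),
               tolerance = 1e-5)
})

test_that("the likelihood is invariant to exchanging twin labels", {
  m <- toy_model()
  pan <- sim_panel(m, 200, 200, seed = 36)
  th <- twinlag:::model_to_theta(m)
  sw <- unclass(pan)[, c(7:12, 1:6)]
  pansw <- as_phenotype_panel(sw, traits = m$traits,
                              zygosity = attr(pan, "zygosity"),
                              standardize = FALSE)
  expect_equal(ace_loglik(th, pan), ace_loglik(th, pansw),
               tolerance = 1e-10)
})

test_that("likelihood-ratio bookkeeping against the saturated baseline", {
  pan <- sim_panel(toy_model(), 500, 500, seed = 37)
  fit <- fit_ace_clpm(pan, n_starts = 1)
  lrt <- lrt_vs_saturated(fit)
  expect_gte(lrt$chisq, -1e-6)
  expect_equal(lrt$df, 180 - 57)
  # mismatched rows are refused
  pan2 <- sim_panel(toy_model(), 400, 400, seed = 38)
  expect_error(lrt_vs_saturated(fit, pan2), "identical rows")
})

test_that("forcing A to zero on strong-A data inflates misfit roughly
           linearly in n", {
  blk <- function(v) list(W1 = diag(v, 2), T1 = diag(0.3, 2),
                          P2 = diag(v, 2), T2 = diag(0.3, 2),
                          P3 = diag(v, 2))
  m <- ace_model(A = blk(0.6), C = blk(0.1), E = blk(0.3))
  drop_a <- grep("^A\\.", twinlag:::ace_param_labels(), value = TRUE)
  spec0 <- ace_model_spec(drop = drop_a)
  chis <- vapply(c(500, 1000), function(n) {
    pan <- sim_panel(m, n, n, seed = 39)
    f <- fit_ace_clpm(pan, spec = spec0, n_starts = 1)
    lrt_vs_saturated(f)$chisq
  }, numeric(1))
  expect_gt(chis[1], 100)                 # gross misfit
  expect_equal(chis[2] / chis[1], 2, tolerance = 0.35)
})

test_that("equality constraints share one free parameter", {
  spec <- ace_model_spec(equal = list(c("A.T1.11", "A.T2.11")))
  expect_equal(spec$n_free, 56)
  fr <- seq_len(spec$n_free) / 100
  th <- twinlag:::theta_unpack(spec, fr)
  i <- match(c("A.T1.11", "A.T2.11"), spec$labels)
  expect_equal(th[i[1]], th[i[2]])
})

test_that("model reduction drops exactly the C parameters whose rC interval
           covers zero", {
  vn <- twinlag:::wm_var_names(c("cog", "emo"))
  mk_cf <- function(se) {
    R <- matrix(0.5, 6, 6, dimnames = list(vn, vn))
    diag(R) <- 1
    S <- matrix(se, 6, 6, dimnames = list(vn, vn))
    structure(list(correlations = list(C = R, se_C = S),
                   traits = c("cog", "emo")), class = "cf_fit")
  }
  # all rC clearly significant: nothing dropped
  spec1 <- reduce_model(ace_model_spec(), mk_cf(0.05))
  expect_equal(length(spec1$dropped), 0)
  # none significant: all seven C cross-parameters dropped,
  # C variances retained
  spec2 <- reduce_model(ace_model_spec(), mk_cf(2.0))
  expect_setequal(spec2$dropped,
                  c("C.W1.l21", "C.T1.21", "C.T1.12", "C.P2.l21",
                    "C.T2.21", "C.T2.12", "C.P3.l21"))
  expect_true(all(spec2$free[match(c("C.W1.l11", "C.W1.l22", "C.T1.11",
                                     "C.T1.22"), spec2$labels)]))
  log <- attr(spec2, "reduction_log")
  expect_equal(sum(log$dropped), 7)
})

test_that("correlated-factors model flags shared-environment structure
           correctly", {
  # diagonal C (rC = 0 cross-trait) but correlated A
  m <- toy_model()
  # zero out C cross-trait terms
  m$C$W1[1, 2] <- m$C$W1[2, 1] <- 0
  m$C$P2[1, 2] <- m$C$P2[2, 1] <- 0
  m$C$P3[1, 2] <- m$C$P3[2, 1] <- 0
  m$C$T1[1, 2] <- m$C$T1[2, 1] <- 0
  m$C$T2[1, 2] <- m$C$T2[2, 1] <- 0
  pan <- sim_panel(m, 4000, 4000, seed = 40)
  cf <- fit_correlated_factors(pan, n_starts = 1, se = "delta")
  expect_true(cf$fit$converged)
  # cross-trait rC intervals cover zero, same-trait rA is strongly positive
  for (w in 1:3) {
    i <- 2 * w - 1
    lo <- cf$correlations$ci_lower_C[i, i + 1]
    hi <- cf$correlations$ci_upper_C[i, i + 1]
    expect_true(lo <= 0 & hi >= 0)
  }
  expect_gt(cf$correlations$A["cog_w1", "cog_w2"], 0.3)
  # variance components from the correlated-factors fit track the truth
  truthv <- variance_components(m)
  expect_lt(max(abs(cf$components$h2 - truthv$h2)), 0.08)
})

test_that("the default specification is locally identified", {
  spec <- ace_model_spec()
  free <- twinlag:::theta_pack(spec,
                               twinlag:::model_to_theta(toy_model()))
  expect_true(check_identification(spec, free))
})

test_that("model-implied phenotypic cross-lags reproduce the CLPM fit", {
  m <- toy_model()
  pan <- sim_panel(m, 5000, 5000, seed = 41)
  phen <- fit_clpm(pan)
  fit <- fit_ace_clpm(pan, n_starts = 1)
  imp <- implied_clpm_paths(fit$model)
  cl <- imp[imp$type == "crosslag", ]
  for (i in seq_len(nrow(cl))) {
    got <- phen$paths$estimate[phen$paths$path == cl$path[i]]
    expect_lt(abs(got - cl$estimate[i]), 0.03)
  }
})
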