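test_that("the same seed and config reproduce the dataset exactly", {
  m <- toy_model()
  a <- simulate_pairs(m, 50, 50, seed = 17, missingness = "wave",
                      covariates = TRUE)
  b <- simulate_pairs(m, 50, 50, seed = 17, missingness = "wave",
                      covariates = TRUE)
  expect_identical(a, b)
  c2 <- simulate_pairs(m, 50, 50, seed = 18, missingness = "wave",
                       covariates = TRUE)
  expect_false(identical(a, c2))
})

test_that("zero pairs produce an empty dataset with a valid header", {
  out <- simulate_pairs(toy_model(), 0, 0)
  expect_equal(nrow(out), 0)
  expect_true(all(c("family_id", "zygosity", "cog_1_w1", "emo_2_w3")
                  %in% names(out)))
})

test_that("pure-A wave-1 data reproduce the zygosity correlations", {
  m <- pure_component_model("A")
  sim <- simulate_pairs(m, 20000, 20000, seed = 5)
  r_mz <- cor(sim$cog_1_w1[sim$zygosity == "MZ"],
              sim$cog_2_w1[sim$zygosity == "MZ"])
  r_dz <- cor(sim$cog_1_w1[sim$zygosity == "DZ"],
              sim$cog_2_w1[sim$zygosity == "DZ"])
  expect_lt(abs(r_mz - 1.0), 0.01)
  expect_lt(abs(r_dz - 0.5), 0.015)
})

test_that("flat ACE variances give cov_MZ = A + C and cov_DZ = A/2 + C", {
  sim <- simulate_pairs(flat_ace_model(0.5, 0.3, 0.2), 20000, 20000,
                        seed = 6)
  cv <- function(z) cov(sim$emo_1_w1[sim$zygosity == z],
                        sim$emo_2_w1[sim$zygosity == z])
  expect_lt(abs(cv("MZ") - 0.80), 0.02)
  expect_lt(abs(cv("DZ") - 0.55), 0.02)
})

test_that("implied moments: no transmission means block-diagonal over waves", {
  S <- implied_moments(flat_ace_model(), "MZ")$sigma
  # within twin 1, cross-wave blocks must vanish
  for (w1 in 1:2) for (w2 in (w1 + 1):3) {
    expect_equal(S[paste0("cog_1_w", w1), paste0("cog_1_w", w2)], 0)
    expect_equal(S[paste0("cog_1_w", w1), paste0("emo_1_w", w2)], 0)
  }
})

test_that("implied moments are symmetric under twin exchange", {
  for (z in c("MZ", "DZ")) {
    S <- implied_moments(twin_preset("general"), z)$sigma
    perm <- c(7:12, 1:6)
    expect_equal(unname(S[perm, perm]), unname(S), tolerance = 1e-12)
  }
})

test_that("with A set to zero the MZ and DZ implied covariances coincide", {
  m <- toy_model()
  m$A <- list(W1 = diag(0, 2), T1 = diag(0, 2), P2 = diag(0, 2),
              T2 = diag(0, 2), P3 = diag(0, 2))
  expect_equal(implied_moments(m, "MZ")$sigma,
               implied_moments(m, "DZ")$sigma, tolerance = 1e-14)
})

test_that("Monte-Carlo covariance agrees with the closed form", {
  m <- twin_preset("general")
  sim <- simulate_pairs(m, 30000, 30000, seed = 8)
  pc <- panel_col_names_for_test(m$traits)
  for (z in c("MZ", "DZ")) {
    S_emp <- cov(sim[sim$zygosity == z, pc])
    S_th <- implied_moments(m, z)$sigma
    expect_lt(max(abs(S_emp - S_th)), 0.035)
  }
})

test_that("calibrated presets reproduce their targets exactly", {
  for (p in c("general", "verbal", "nonverbal")) {
    tg <- preset_targets(p)
    m <- twin_preset(p)
    # unit implied variances
    expect_equal(unname(diag(twinlag:::phen_sigma_wm(m))), rep(1, 6),
                 tolerance = 1e-9)
    # phenotypic projection equals the target stability/cross-lagged paths
    ip <- implied_clpm_paths(m)
    expect_equal(ip$estimate[ip$type == "stability"],
                 tg$stability[c(1, 3, 2, 4)], tolerance = 1e-8)
    expect_equal(ip$estimate[ip$type == "crosslag"],
                 tg$crosslag[c(1, 3, 2, 4)], tolerance = 1e-8)
    expect_equal(ip$estimate[ip$type == "correlational"], tg$wcorr,
                 tolerance = 1e-8)
    # cross-lagged decomposition carries the target percentage shares
    d <- suppressWarnings(decompose_paths(m))
    cl <- d[d$type == "crosslag", ]
    tr <- m$traits[1]
    for (t in 1:2) {
      sh <- cl[cl$path == paste0(tr, "_w", t, " -> emo_w", t + 1),
               c("share_A", "share_C", "share_E")]
      expect_equal(unlist(sh, use.names = FALSE),
                   100 * tg$shares[[paste0("c2e", t)]], tolerance = 1e-6)
      sh <- cl[cl$path == paste0("emo_w", t, " -> ", tr, "_w", t + 1),
               c("share_A", "share_C", "share_E")]
      expect_equal(unlist(sh, use.names = FALSE),
                   100 * tg$shares[[paste0("e2c", t)]], tolerance = 1e-6)
    }
    # univariate variance shares equal the target trajectories
    v <- variance_components(m)
    cogv <- as.matrix(v[v$variable == tr, c("h2", "c2", "e2")])
    expect_equal(unname(cogv), unname(tg$v$cog), tolerance = 1e-8)
  }
})

test_that("non-positive-semidefinite blocks are rejected before sampling", {
  bad <- toy_model()
  bad$A$W1 <- matrix(c(0.3, 0.9, 0.9, 0.3), 2, 2)
  expect_error(twinlag:::validate_ace_model(bad), "positive semi-definite")
  expect_error(simulate_pairs(bad, 5, 5, seed = 1), "positive semi-definite")
})
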