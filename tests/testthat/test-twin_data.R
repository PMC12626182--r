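test_that("read_pairs parses clean rows, codes missing cells, rejects bad ones", {
  hdr <- paste(c("family_id", "zygosity", panel_col_names_for_test()),
               collapse = ",")
  rows <- c(
    paste(c("f1", "MZ", sprintf("%.2f", seq(0.1, 1.2, by = 0.1))),
          collapse = ","),
    paste(c("f2", "DZ", "0.5", "", rep("0.3", 10)), collapse = ","),
    paste(c("f3", "MZ", rep("0.2", 12)), collapse = ","),
    paste(c("f4", "XX", rep("0.2", 12)), collapse = ","))
  f <- write_fixture_csv(c(hdr, rows))
  rec <- read_pairs(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$zygosity, c("MZ", "DZ", "MZ"))
  expect_true(is.na(rec$cog_1_w2[2]))   # empty cell -> missing flag
  probs <- attr(rec, "problems")
  expect_equal(probs$row, 4)
  expect_match(probs$message, "XX")
})

test_that("write_pairs/read_pairs round-trips a simulated cohort exactly", {
  sim <- simulate_pairs(toy_model(), 25, 25, seed = 3,
                        missingness = "wave", covariates = TRUE)
  f <- tempfile(fileext = ".csv")
  write_pairs(sim, f)
  back <- read_pairs(f)
  for (cn in grep("_w", names(sim), value = TRUE))
    expect_equal(back[[cn]], sim[[cn]], tolerance = 1e-12)
  expect_equal(back$zygosity, sim$zygosity)
  expect_equal(nrow(attr(back, "problems")), 0)
})

test_that("read_pairs errors name the malformed input", {
  expect_error(read_pairs(tempfile()), "not found")
  f <- write_fixture_csv(c("a,b", "1,2"))
  expect_error(read_pairs(f), "missing required columns")
})

test_that("apply_exclusions filters on caller-supplied flags and logs reasons", {
  rec <- simulate_pairs(toy_model(), 5, 5, seed = 1)
  rec$medical <- c(TRUE, TRUE, rep(FALSE, 8))
  out <- apply_exclusions(rec, "medical")
  expect_equal(nrow(out$retained), 8)
  expect_equal(out$log$reasons$medical, 2)
  # no flags: identity
  out0 <- apply_exclusions(rec)
  expect_equal(nrow(out0$retained), nrow(rec))
  # all flagged: empty result, no crash
  rec$medical <- TRUE
  outall <- apply_exclusions(rec, "medical")
  expect_equal(nrow(outall$retained), 0)
  expect_equal(outall$log$total_excluded, 10)
})

test_that("residualization removes sex and age associations", {
  sim <- simulate_pairs(toy_model(), 400, 400, seed = 7, covariates = TRUE)
  pan <- residualize(sim, traits = c("cog", "emo"))
  ind <- twinlag:::panel_individuals(pan)
  sex <- c(sim$sex_1, sim$sex_2)
  for (j in seq_len(ncol(ind$scores))) {
    w <- as.integer(sub(".*_w", "", colnames(ind$scores)[j]))
    age <- rep(sim[[paste0("age_w", w)]], 2)
    v <- ind$scores[, j]
    expect_lt(abs(cor(v, sex)), 1e-10)
    expect_lt(abs(cor(v, age)), 1e-10)
    # two-group mean difference, checked directly
    expect_lt(abs(mean(v[sex == 1]) - mean(v[sex == 0])), 1e-10)
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-8)
  }
})

test_that("residualization is idempotent and invariant to row order", {
  sim <- simulate_pairs(toy_model(), 150, 150, seed = 9, covariates = TRUE)
  set.seed(31)
  pan1 <- residualize(sim, traits = c("cog", "emo"))
  # feed the residualized scores back through with the same covariates
  sim2 <- sim
  sim2[, panel_col_names_for_test()] <- unclass(pan1)
  pan2 <- residualize(sim2, traits = c("cog", "emo"))
  expect_equal(unclass(pan2), unclass(pan1), tolerance = 1e-10,
               ignore_attr = TRUE)
  # permutation invariance
  perm <- sample(nrow(sim))
  pan3 <- residualize(sim[perm, ], traits = c("cog", "emo"))
  ord <- match(attr(pan1, "family_id"), attr(pan3, "family_id"))
  expect_equal(unclass(pan3)[ord, ], unclass(pan1), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a missing covariate blanks that wave's scores instead of imputing", {
  sim <- simulate_pairs(toy_model(), 30, 30, seed = 2, covariates = TRUE)
  sim$sex_1[1] <- NA
  sim$age_w2[2] <- NA
  pan <- residualize(sim, traits = c("cog", "emo"))
  expect_true(all(is.na(unclass(pan)[1, c("cog_1_w1", "cog_1_w2", "cog_1_w3",
                                          "emo_1_w1", "emo_1_w2",
                                          "emo_1_w3")])))
  expect_true(all(is.na(unclass(pan)[2, c("cog_1_w2", "emo_1_w2",
                                          "cog_2_w2", "emo_2_w2")])))
  expect_false(anyNA(unclass(pan)[2, c("cog_1_w1", "emo_2_w3")]))
})

test_that("zero-variance score columns are reported by name", {
  sim <- simulate_pairs(toy_model(), 20, 20, seed = 4)
  sim$cog_1_w1 <- 1
  sim$cog_2_w1 <- 1
  expect_error(residualize(sim, traits = c("cog", "emo")), "cog_w1")
})

test_that("regress_out_trait removes the nuisance trait association per wave", {
  # three traits: verbal correlated 0.6 with nonverbal by construction
  m <- toy_model()
  set.seed(22)
  sim <- simulate_pairs(m, 500, 500, seed = 21)
  pan <- as_phenotype_panel(sim, traits = m$traits)
  ind0 <- twinlag:::panel_individuals(pan)
  # manufacture a third trait: verbal = 0.6*cog + noise, per wave
  k <- unclass(pan)
  verbal <- 0.6 * k[, c("cog_1_w1", "cog_1_w2", "cog_1_w3")] +
    matrix(rnorm(3 * nrow(k), 0, 0.8), ncol = 3)
  verbal2 <- 0.6 * k[, c("cog_2_w1", "cog_2_w2", "cog_2_w3")] +
    matrix(rnorm(3 * nrow(k), 0, 0.8), ncol = 3)
  scores <- cbind(verbal, k[, 1:6], verbal2, k[, 7:12])
  pan3 <- as_phenotype_panel(scores, traits = c("verbal", "cog", "emo"))
  attr(pan3, "zygosity") <- attr(pan, "zygosity")
  out <- regress_out_trait(pan3, target = "verbal", nuisance = "cog")
  expect_setequal(attr(out, "traits"), c("verbal", "emo"))
  ind <- twinlag:::panel_individuals(out)
  for (w in 1:3) {
    r <- cor(ind$scores[, paste0("verbal_w", w)],
             ind0$scores[, paste0("cog_w", w)], use = "complete.obs")
    expect_lt(abs(r), 1e-10)
  }
  # degenerate: target identical to nuisance
  dup <- cbind(k[, 1:3], k[, 1:3], k[, 4:6],
               k[, 7:9], k[, 7:9], k[, 10:12])
  pdup <- as_phenotype_panel(dup, traits = c("a", "cog", "emo"))
  # target 'a' is an exact copy of cog
  expect_error(regress_out_trait(pdup, "a", "cog"), "residual variance")
})
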