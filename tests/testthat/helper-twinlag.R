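# fixtures built in code: small generating models and CSV snippets

# a mid-sized, well-interior generating model used where the preset values
# (with their near-boundary C variances) would slow or destabilize small fits
toy_targets <- function(crosslag = c(-0.08, -0.06, -0.10, -0.05),
                        shares = list(c2e1 = c(.5, .3, .2),
                                      c2e2 = c(.4, .4, .2),
                                      e2c1 = c(.3, .4, .3),
                                      e2c2 = c(.4, .3, .3))) {
  list(v = list(cog = rbind(c(.40, .25, .35), c(.35, .30, .35),
                            c(.40, .20, .40)),
                emo = rbind(c(.45, .20, .35), c(.40, .25, .35),
                            c(.45, .15, .40))),
       stability = c(0.50, 0.55, 0.45, 0.50),
       crosslag = crosslag, shares = shares,
       wcorr = c(-0.15, -0.12, -0.08),
       traits = c("cog", "emo"))
}

toy_model <- function(...) calibrate_ace_model(toy_targets(...))

# single-component models for sharp closed-form checks
pure_component_model <- function(component = "A", v = 1) {
  zero <- list(W1 = diag(0, 2), T1 = diag(0, 2), P2 = diag(0, 2),
               T2 = diag(0, 2), P3 = diag(0, 2))
  act <- list(W1 = diag(v, 2), T1 = diag(0, 2), P2 = diag(v, 2),
              T2 = diag(0, 2), P3 = diag(v, 2))
  args <- list(A = zero, C = zero, E = zero)
  args[[component]] <- act
  # keep a sliver of E so the observed covariance stays invertible
  if (component != "E") {
    eps <- list(W1 = diag(1e-4, 2), T1 = diag(0, 2), P2 = diag(1e-4, 2),
                T2 = diag(0, 2), P3 = diag(1e-4, 2))
    args$E <- eps
  }
  ace_model(A = args$A, C = args$C, E = args$E)
}

# ACE wave-1 variance model with no transmission (cov_MZ = A + C etc.)
flat_ace_model <- function(a = 0.5, c = 0.3, e = 0.2) {
  blk <- function(v) list(W1 = diag(v, 2), T1 = diag(0, 2),
                          P2 = diag(v, 2), T2 = diag(0, 2),
                          P3 = diag(v, 2))
  ace_model(A = blk(a), C = blk(c), E = blk(e))
}

write_fixture_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# standardized panel straight from a simulated dataset (no covariates)
sim_panel <- function(model, n_mz, n_dz, seed, ...) {
  as_phenotype_panel(simulate_pairs(model, n_mz, n_dz, seed = seed, ...),
                     traits = model$traits)
}

expect_no_na <- function(x) expect_false(anyNA(x))

panel_col_names_for_test <- function(traits = c("cog", "emo")) {
  unlist(lapply(1:2, function(tw)
    unlist(lapply(traits, function(tr) paste0(tr, "_", tw, "_w", 1:3)))))
}
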