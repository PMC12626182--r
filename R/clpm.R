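#' Phenotypic autoregressive cross-lagged panel model
#'
#' Fits the individual-level phenotypic cross-lagged model for two traits
#' over three waves: each wave-(t+1) variable is regressed on both wave-t
#' variables (so cross-lagged paths are partial regressions adjusting for the
#' stability and within-wave association), wave-1 and residual within-wave
#' associations are estimated as correlations, and all standard errors use a
#' cluster-robust sandwich over families to account for the non-independence
#' of twins.
#'
#' @param panel a standardized `phenotype_panel` with exactly two traits.
#' @param conf_level confidence level for the normal-theory intervals.
#' @return A `clpm_fit`: list with `paths` (data.frame: path, type, estimate,
#'   se, ci_lower, ci_upper, n) and `n_clusters`.
#' @export
fit_clpm <- function(panel, conf_level = 0.95) {
  traits <- attr(panel, "traits")
  if (length(traits) != 2)
    stop("fit_clpm needs a two-trait panel; got ", length(traits))
  ind <- panel_individuals(panel)
  if (length(unique(ind$family[rowSums(!is.na(ind$scores)) > 0])) < 2)
    stop("fewer than 2 family clusters")
  z <- qnorm(1 - (1 - conf_level) / 2)
  sc <- ind$scores
  rows <- list()
  add_row <- function(path, type, est, se, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      path = path, type = type, estimate = est, se = se,
      ci_lower = est - z * se, ci_upper = est + z * se, n = n)
  }
  resids <- list()
  for (t in 1:2) {
    for (tgt in 1:2) {
      ycol <- paste0(traits[tgt], "_w", t + 1)
      xcols <- paste0(traits, "_w", t)
      d <- data.frame(y = sc[, ycol], x1 = sc[, xcols[1]],
                      x2 = sc[, xcols[2]], fam = ind$family)
      cc <- complete.cases(d)
      if (!any(cc)) stop("no complete cases for equation ", ycol)
      d <- d[cc, ]
      fit <- lm(y ~ x1 + x2, data = d)
      V <- sandwich::vcovCL(fit, cluster = d$fam)
      b <- coef(fit)
      same <- paste0("x", tgt)
      other <- paste0("x", 3 - tgt)
      add_row(paste0(traits[tgt], "_w", t, " -> ", traits[tgt], "_w", t + 1),
              "stability", b[[same]], sqrt(V[same, same]), nrow(d))
      add_row(paste0(traits[3 - tgt], "_w", t, " -> ",
                     traits[tgt], "_w", t + 1),
              "crosslag", b[[other]], sqrt(V[other, other]), nrow(d))
      resids[[ycol]] <- data.frame(fam = d$fam, idx = which(cc),
                                   r = resid(fit))
    }
  }
  # within-wave correlational paths: wave 1 total, waves 2-3 residual
  w1 <- cluster_correlation(sc[, paste0(traits, "_w1")], ind$family)
  add_row(paste0(traits[1], "_w1 ~~ ", traits[2], "_w1"), "correlational",
          w1$r, w1$se, w1$n)
  for (w in 2:3) {
    r1 <- resids[[paste0(traits[1], "_w", w)]]
    r2 <- resids[[paste0(traits[2], "_w", w)]]
    common <- intersect(r1$idx, r2$idx)
    m <- cbind(r1$r[match(common, r1$idx)], r2$r[match(common, r2$idx)])
    cc <- cluster_correlation(m, ind$family[common])
    add_row(paste0(traits[1], "_w", w, " ~~ ", traits[2], "_w", w),
            "correlational", cc$r, cc$se, cc$n)
  }
  paths <- do.call(rbind, rows)
  rownames(paths) <- NULL
  structure(list(paths = paths,
                 n_clusters = length(unique(ind$family)),
                 traits = traits, conf_level = conf_level),
            class = "clpm_fit")
}

# correlation with a family-clustered standard error, via the regression of
# one standardized variable on the other
cluster_correlation <- function(m, fam) {
  cc <- complete.cases(m)
  m <- m[cc, , drop = FALSE]
  fam <- fam[cc]
  x <- as.vector(scale(m[, 1]))
  y <- as.vector(scale(m[, 2]))
  fit <- lm(y ~ x)
  V <- sandwich::vcovCL(fit, cluster = fam)
  list(r = coef(fit)[["x"]], se = sqrt(V["x", "x"]), n = nrow(m))
}

#' @export
print.clpm_fit <- function(x, ...) {
  cat("Phenotypic cross-lagged panel model (", x$n_clusters,
      " family clusters)\n", sep = "")
  p <- x$paths
  p$estimate <- round(p$estimate, 3)
  p$se <- round(p$se, 3)
  p$ci_lower <- round(p$ci_lower, 3)
  p$ci_upper <- round(p$ci_upper, 3)
  print(p, row.names = FALSE)
  invisible(x)
}

#' Compare clustered and naive standard errors
#'
#' Diagnostic for the family-clustering requirement: refits every equation of
#' the phenotypic cross-lagged model and reports the ratio of the
#' cluster-robust to the independence (naive, HC0) standard error per path.
#'
#' @param panel a standardized `phenotype_panel` with two traits.
#' @return data.frame with columns `path`, `se_clustered`, `se_naive`,
#'   `ratio`.
#' @export
compare_clustered_vs_naive <- function(panel) {
  traits <- attr(panel, "traits")
  ind <- panel_individuals(panel)
  sc <- ind$scores
  if (nrow(sc) == 0 || all(is.na(sc))) stop("empty panel")
  rows <- list()
  for (t in 1:2) for (tgt in 1:2) {
    ycol <- paste0(traits[tgt], "_w", t + 1)
    xcols <- paste0(traits, "_w", t)
    d <- data.frame(y = sc[, ycol], x1 = sc[, xcols[1]],
                    x2 = sc[, xcols[2]], fam = ind$family)
    d <- d[complete.cases(d), ]
    if (nrow(d) == 0) stop("no complete cases for equation ", ycol)
    fit <- lm(y ~ x1 + x2, data = d)
    Vc <- sandwich::vcovCL(fit, cluster = d$fam)
    Vn <- sandwich::vcovHC(fit, type = "HC0")
    for (src in 1:2) {
      cn <- paste0("x", src)
      rows[[length(rows) + 1]] <- data.frame(
        path = paste0(traits[src], "_w", t, " -> ",
                      traits[tgt], "_w", t + 1),
        se_clustered = sqrt(Vc[cn, cn]), se_naive = sqrt(Vn[cn, cn]))
    }
  }
  out <- do.call(rbind, rows)
  out$ratio <- out$se_clustered / out$se_naive
  rownames(out) <- NULL
  out
}
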