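#' Within-pair difference scores for MZ twins
#'
#' Builds the MZ-differences panel: for every MZ pair and every trait x wave,
#' the signed difference twin1 - twin2 under the panel's twin-order
#' convention.  Because MZ co-twins share all additive-genetic and
#' shared-environment influences, these differences remove A and C by
#' construction; associations among them implicate nonshared-environment
#' pathways.  A difference is missing when either twin is missing.  DZ pairs
#' are silently excluded with their count logged.
#'
#' @param panel a `phenotype_panel` with two traits and zygosity.
#' @return An `mz_diff_panel`: matrix (MZ pairs x 6) of differences with
#'   attributes `traits`, `family_id`, `n_dz_excluded`.
#' @export
make_differences <- function(panel) {
  traits <- attr(panel, "traits")
  if (length(traits) != 2)
    stop("make_differences needs a two-trait panel")
  zyg <- attr(panel, "zygosity")
  mz <- zyg == "MZ"
  if (!any(mz)) stop("no MZ pairs in the panel")
  X <- unclass(panel)[mz, , drop = FALSE]
  d <- X[, 1:6, drop = FALSE] - X[, 7:12, drop = FALSE]
  colnames(d) <- unlist(lapply(traits, function(tr) paste0(tr, "_w", 1:3)))
  structure(d, class = "mz_diff_panel", traits = traits,
            family_id = attr(panel, "family_id")[mz],
            n_dz_excluded = sum(zyg == "DZ", na.rm = TRUE))
}

#' @export
print.mz_diff_panel <- function(x, ...) {
  cat("MZ-differences panel:", nrow(x), "pairs (",
      attr(x, "n_dz_excluded"), "DZ pairs excluded)\n")
  invisible(x)
}

#' Cross-lagged model on MZ difference scores
#'
#' Fits the same autoregressive cross-lagged path structure as [fit_clpm()]
#' to within-pair MZ difference scores: one row per family, so no clustering
#' is needed.  Intercepts are retained (difference-score means are close to
#' but not forced to zero).  Slopes are reported both on the raw difference
#' scale and standardized (difference scores scaled to unit variance); the
#' estimates are invariant to a global flip of the twin order.
#'
#' @param diffs an `mz_diff_panel` from [make_differences()].
#' @param conf_level confidence level.
#' @return An `mzdiff_fit` with a `paths` data.frame (estimate = raw-scale
#'   slope, `estimate_std` = standardized slope).
#' @export
fit_mzdiff_clpm <- function(diffs, conf_level = 0.95) {
  traits <- attr(diffs, "traits")
  X <- unclass(diffs)
  z <- qnorm(1 - (1 - conf_level) / 2)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds)) || any(sds < 1e-10))
    stop("degenerate (constant) difference-score column: ",
         paste(colnames(X)[is.na(sds) | sds < 1e-10], collapse = ", "))
  rows <- list()
  for (t in 1:2) for (tgt in 1:2) {
    ycol <- paste0(traits[tgt], "_w", t + 1)
    xcols <- paste0(traits, "_w", t)
    d <- data.frame(y = X[, ycol], x1 = X[, xcols[1]], x2 = X[, xcols[2]])
    d <- d[complete.cases(d), ]
    if (nrow(d) < 3 + 1)
      stop("fewer than 3 non-degenerate rows for equation ", ycol)
    fit <- lm(y ~ x1 + x2, data = d)
    sm <- summary(fit)$coefficients
    for (src in 1:2) {
      cn <- paste0("x", src)
      est <- sm[cn, "Estimate"]
      se <- sm[cn, "Std. Error"]
      rows[[length(rows) + 1]] <- data.frame(
        path = paste0("d_", traits[src], "_w", t, " -> d_",
                      traits[tgt], "_w", t + 1),
        type = if (src == tgt) "stability" else "crosslag",
        estimate = est, se = se,
        ci_lower = est - z * se, ci_upper = est + z * se,
        estimate_std = est * sds[xcols[src]] / sds[ycol],
        se_std = se * sds[xcols[src]] / sds[ycol],
        n = nrow(d))
    }
  }
  paths <- do.call(rbind, rows)
  rownames(paths) <- NULL
  structure(list(paths = paths, n_pairs = nrow(X), traits = traits,
                 conf_level = conf_level),
            class = "mzdiff_fit")
}

#' @export
print.mzdiff_fit <- function(x, digits = 3, ...) {
  cat("MZ-differences cross-lagged model (", x$n_pairs, " MZ pairs)\n",
      sep = "")
  p <- x$paths
  num <- vapply(p, is.numeric, logical(1))
  p[num] <- lapply(p[num], round, digits)
  print(p, row.names = FALSE)
  invisible(x)
}
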