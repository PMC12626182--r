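#' Calibration targets for the shipped generating-model presets
#'
#' Each preset describes, on the standardized reporting scale, the study
#' conditions a synthetic cohort should reproduce: per-trait A/C/E variance
#' shares at each wave, the phenotypic stability and cross-lagged paths (as
#' recovered by the phenotypic cross-lagged projection), the A/C/E percentage
#' shares of each cross-lagged path, and the total within-wave correlations.
#' [calibrate_ace_model()] turns a target set into an [ace_model()] whose
#' implied moments reproduce these quantities exactly.
#'
#' @param preset `"general"`, `"verbal"` or `"nonverbal"` (the cognitive trait
#'   paired with emotional problems in each of the three analyses).
#' @return A list of calibration targets.
#' @export
preset_targets <- function(preset = c("general", "verbal", "nonverbal")) {
  preset <- match.arg(preset)
  emo_v <- rbind(c(.49, .13, .38), c(.40, .34, .26), c(.55, .02, .43))
  tg <- switch(preset,
    general = list(
      v = list(cog = rbind(c(.38, .30, .32), c(.30, .49, .21),
                           c(.47, .11, .42)), emo = emo_v),
      stability = c(0.55, 0.58, 0.42, 0.45),
      crosslag = c(-0.07, -0.07, -0.11, -0.05),
      shares = list(c2e1 = c(.61, .27, .12), c2e2 = c(.14, .79, .07),
                    e2c1 = c(.08, .73, .19), e2c2 = c(.40, .30, .30)),
      wcorr = c(-0.12, -0.16, -0.04),
      traits = c("g", "emo")),
    verbal = list(
      v = list(cog = rbind(c(.26, .30, .44), c(.20, .45, .35),
                           c(.42, .04, .54)), emo = emo_v),
      stability = c(0.45, 0.50, 0.42, 0.45),
      crosslag = c(-0.04, -0.03, -0.04, -0.04),
      shares = list(c2e1 = c(.46, .34, .20), c2e2 = c(.38, .42, .20),
                    e2c1 = c(.22, .68, .10), e2c2 = c(.40, .30, .30)),
      wcorr = c(-0.12, -0.09, -0.06),
      traits = c("verbal", "emo")),
    nonverbal = list(
      v = list(cog = rbind(c(.15, .23, .62), c(.22, .32, .46),
                           c(.47, .01, .52)), emo = emo_v),
      stability = c(0.40, 0.45, 0.42, 0.45),
      crosslag = c(-0.04, -0.05, -0.11, -0.06),
      shares = list(c2e1 = c(.91, .05, .04), c2e2 = c(.26, .61, .13),
                    e2c1 = c(.03, .75, .22), e2c2 = c(.63, .25, .12)),
      wcorr = c(-0.10, -0.15, -0.01),
      traits = c("nonverbal", "emo")))
  tg$preset <- preset
  tg
}

geom_shares <- function(vx, vy) {
  s <- sqrt(vx * vy)
  s / sum(s)
}

#' Calibrate a generating model to standardized targets
#'
#' Constructs raw-scale A/C/E autoregressive cross-lagged parameters whose
#' implied standardized solution matches a target set exactly: observed
#' variables have unit implied variance, the phenotypic cross-lagged
#' projection equals the target stability/cross-lagged paths, the total
#' within-wave correlations equal their targets, and the A/C/E contribution of
#' every cross-lagged path carries the target percentage share.  The
#' construction is closed form given the internal path totals; a fixed-point
#' loop aligns the internal totals with the phenotypic projection (the two
#' differ slightly because the three components transmit with different
#' stabilities).
#'
#' Stability paths are allocated across components in proportion to the
#' geometric mean of the source- and target-wave component variances; when a
#' component's transmitted variance would exhaust its target variance at the
#' next wave (possible when a printed cross-lagged share loads heavily on a
#' small component), that component's stability share is reduced to leave at
#' least `innovation_floor` of the target as innovation variance, and the
#' remainder is redistributed.
#'
#' @param targets a target list as returned by [preset_targets()].
#' @param innovation_floor minimum fraction of a component's target variance
#'   left to the innovation term.
#' @param max_iter,tol fixed-point controls.
#' @param ... passed to [ace_model()] (e.g. `rho_a_dz`, `retention`).
#' @return A calibrated [ace_model()] with the targets attached as attribute
#'   `"targets"`.
#' @export
calibrate_ace_model <- function(targets, innovation_floor = 0.10,
                                max_iter = 200, tol = 1e-12, ...) {
  b_int <- c(targets$stability, targets$crosslag)
  a_int <- targets$wcorr[2:3]
  for (iter in seq_len(max_iter)) {
    m <- construct_model(targets, b_int, a_int, innovation_floor, ...)
    pr <- implied_clpm_paths(m)
    est <- pr$estimate
    # order in implied_clpm_paths: per interval (stab cog, stab emo, c2e, e2c)
    pr_b <- c(est[1], est[5], est[2], est[6], est[3], est[7], est[4], est[8])
    pr_a <- est[10:11]
    err <- unname(c(targets$stability, targets$crosslag) - pr_b)
    erra <- unname(targets$wcorr[2:3] - pr_a)
    if (max(abs(c(err, erra))) < tol) break
    b_int <- b_int + err
    a_int <- a_int + erra
  }
  if (max(abs(c(err, erra))) >= tol)
    warning("calibration fixed point did not fully converge (max err ",
            signif(max(abs(c(err, erra))), 3), ")")
  attr(m, "targets") <- targets
  attr(m, "internal_totals") <- list(paths = b_int, wcov = a_int)
  m
}

# closed-form constructor given internal standardized path totals
construct_model <- function(tg, b_int, a_int, floor_frac = 0.10, ...) {
  v <- tg$v
  stab <- list(cog = b_int[1:2], emo = b_int[3:4])
  cl <- list(c2e = b_int[5:6], e2c = b_int[7:8])
  S1 <- sum(sqrt(v$cog[1, ] * v$emo[1, ]))
  out <- list(A = list(), C = list(), E = list())
  comps <- c("A", "C", "E")
  cw <- list()
  for (k in 1:3) {
    W1 <- diag(c(v$cog[1, k], v$emo[1, k]))
    W1[1, 2] <- W1[2, 1] <- tg$wcorr[1] * sqrt(v$cog[1, k] * v$emo[1, k]) / S1
    out[[comps[k]]]$W1 <- W1
    cw[[k]] <- W1
  }
  for (t in 1:2) {
    ws <- list(cog = geom_shares(v$cog[t, ], v$cog[t + 1, ]),
               emo = geom_shares(v$emo[t, ], v$emo[t + 1, ]))
    craw <- lapply(1:3, function(k)
      c(c2e = cl$c2e[t] * tg$shares[[paste0("c2e", t)]][k] / v$cog[t, k],
        e2c = cl$e2c[t] * tg$shares[[paste0("e2c", t)]][k] / v$emo[t, k]))
    braw <- list()
    for (trn in c("cog", "emo")) {
      vtr <- v[[trn]]
      w <- ws[[trn]]
      beta_b <- stab[[trn]][t] * w
      i <- if (trn == "cog") 1 else 2
      j <- 3 - i
      for (pass in 1:3) {
        ok <- TRUE
        for (k in 1:3) {
          b <- beta_b[k] / vtr[t, k]
          cc <- craw[[k]][[if (trn == "cog") "e2c" else "c2e"]]
          cwk <- cw[[k]]
          tv <- b^2 * cwk[i, i] + 2 * b * cc * cwk[i, j] + cc^2 * cwk[j, j]
          cap <- (1 - floor_frac) * vtr[t + 1, k]
          if (tv > cap) {
            ok <- FALSE
            disc <- (2 * cc * cwk[i, j])^2 -
              4 * cwk[i, i] * (cc^2 * cwk[j, j] - cap)
            if (disc < 0)
              stop("infeasible targets: the ", comps[k], " cross-lagged ",
                   "share alone exceeds the wave-", t + 1,
                   " component variance of ", trn)
            bnew <- max((-2 * cc * cwk[i, j] + sqrt(disc)) / (2 * cwk[i, i]),
                        0)
            deficit <- beta_b[k] - bnew * vtr[t, k]
            beta_b[k] <- bnew * vtr[t, k]
            oth <- setdiff(1:3, k)
            beta_b[oth] <- beta_b[oth] + deficit * w[oth] / sum(w[oth])
          }
        }
        if (ok) break
      }
      braw[[trn]] <- beta_b / vtr[t, ]
    }
    trans <- list()
    for (k in 1:3) {
      Tm <- matrix(c(braw$cog[k], craw[[k]][["e2c"]],
                     craw[[k]][["c2e"]], braw$emo[k]), 2, 2, byrow = TRUE)
      out[[comps[k]]][[paste0("T", t)]] <- Tm
      trans[[k]] <- Tm %*% cw[[k]] %*% t(Tm)
    }
    psi <- lapply(1:3, function(k) {
      pv <- c(v$cog[t + 1, k], v$emo[t + 1, k]) - diag(trans[[k]])
      if (any(pv <= 0))
        stop("negative innovation variance for component ", comps[k],
             " at wave ", t + 1)
      pv
    })
    Spsi <- sum(sqrt(vapply(psi, function(p) p[1] * p[2], numeric(1))))
    for (k in 1:3) {
      P <- diag(psi[[k]])
      P[1, 2] <- P[2, 1] <- a_int[t] * sqrt(psi[[k]][1] * psi[[k]][2]) / Spsi
      out[[comps[k]]][[paste0("P", t + 1)]] <- P
      cw[[k]] <- trans[[k]] + P
    }
  }
  ace_model(A = out$A, C = out$C, E = out$E,
            traits = tg$traits %||% c("cog", "emo"), ...)
}

#' Shipped generating-model presets
#'
#' Returns the calibrated generating model for one of the three analyses
#' (general cognitive ability, verbal ability adjusted for nonverbal, or
#' nonverbal ability adjusted for verbal, each paired with emotional
#' problems).
#'
#' @inheritParams preset_targets
#' @param ... passed to [calibrate_ace_model()].
#' @return A calibrated [ace_model()].
#' @export
twin_preset <- function(preset = c("general", "verbal", "nonverbal"), ...) {
  calibrate_ace_model(preset_targets(match.arg(preset)), ...)
}
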