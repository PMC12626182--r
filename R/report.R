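#' Run a full genetically informed cross-lagged analysis
#'
#' Orchestrates the pipeline end to end for one trait pairing: read (or
#' simulate) twin pairs, apply caller-supplied exclusion flags, residualize
#' on sex and age, optionally regress one cognitive subdomain out of the
#' other, fit the phenotypic cross-lagged model with family clustering, fit
#' the correlated-factors twin model and drop nonsignificant
#' shared-environment cross-paths, fit the (reduced) ACE cross-lagged model
#' by FIML, decompose every path into A/C/E contributions, compute
#' univariate ACE estimates per variable, compare against the saturated
#' baseline, and corroborate with the MZ-differences design.  Each stage's
#' machine-readable result is written to `out_dir` together with a
#' consolidated path table, a provenance map and a run log; the report files
#' are re-serializations of the stage outputs, never recomputations.
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input}{path to a twin-pair CSV, or `NULL` to simulate}
#'     \item{preset, n_mz, n_dz, missingness}{simulation settings used when
#'       `input` is `NULL`}
#'     \item{traits}{length-2 character: cognitive trait and emotional trait
#'       column stems present in the input}
#'     \item{adjust}{optional list `list(target=, nuisance=)` to regress one
#'       trait out of another before modelling (the input then needs three
#'       traits)}
#'     \item{exclusion_flags}{character vector of logical columns of the
#'       input marking pairs to exclude}
#'     \item{alpha}{significance level for model reduction (default 0.05)}
#'     \item{seed}{integer; fully determines a simulated run}
#'     \item{n_starts}{optimizer starts for the SEM fits (default 4)}
#'     \item{reduce}{fit the correlated-factors model and reduce (default
#'       TRUE)}
#'     \item{out_dir}{output directory}
#'   }
#' @return Invisibly, the list of stage results.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(list(input = NULL, preset = "general", n_mz = 1000,
                         n_dz = 1000, missingness = "none", traits = NULL,
                         adjust = NULL, exclusion_flags = NULL, alpha = 0.05,
                         seed = 1L, n_starts = 4, reduce = TRUE,
                         out_dir = "twinlag-analysis"),
                    config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  cat("", file = logfile)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
  }
  artifacts <- character(0)
  save_json <- function(x, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, na = "null", pretty = TRUE)
    artifacts[name] <<- path
    path
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " start")
    r <- tryCatch(expr, error = function(e) {
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
      save_json(artifacts, "provenance")
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logmsg("stage ", name, " done")
    r
  }
  save_json(cfg[!vapply(cfg, is.null, logical(1))], "config")
  logmsg("twinlag ", as.character(utils::packageVersion("twinlag")),
         " seed=", cfg$seed)

  records <- stage("input", {
    if (is.null(cfg$input)) {
      model <- twin_preset(cfg$preset)
      cfg$traits <- cfg$traits %||% model$traits
      simulate_pairs(model, cfg$n_mz, cfg$n_dz, seed = cfg$seed,
                     missingness = cfg$missingness, covariates = TRUE)
    } else {
      all_traits <- unique(c(cfg$traits,
                             unlist(cfg$adjust, use.names = FALSE)))
      read_pairs(cfg$input, schema = twin_schema(all_traits))
    }
  })
  excl <- stage("exclusions", apply_exclusions(records,
                                               cfg$exclusion_flags))
  save_json(excl$log, "exclusions")
  records <- excl$retained

  all_traits <- unique(c(cfg$traits, unlist(cfg$adjust, use.names = FALSE)))
  panel <- stage("residualize",
                 residualize(records, traits = all_traits,
                             schema = twin_schema(all_traits)))
  if (!is.null(cfg$adjust))
    panel <- stage("adjust",
                   regress_out_trait(panel, cfg$adjust$target,
                                     cfg$adjust$nuisance))
  traits <- attr(panel, "traits")

  write_panel(panel, file.path(cfg$out_dir, "panel.csv"))
  artifacts["panel_csv"] <- file.path(cfg$out_dir, "panel.csv")

  clpm <- stage("clpm", fit_clpm(panel))
  save_json(clpm$paths, "clpm")

  spec <- ace_model_spec()
  reduction <- NULL
  if (isTRUE(cfg$reduce)) {
    cf <- stage("correlated_factors",
                fit_correlated_factors(panel, se = "delta",
                                       n_starts = max(1, cfg$n_starts - 2)))
    save_json(list(components = cf$components,
                   rA = cf$correlations$A, rC = cf$correlations$C,
                   rE = cf$correlations$E,
                   fit = cf$fit), "correlated_factors")
    spec <- stage("reduce", reduce_model(spec, cf, alpha = cfg$alpha))
    reduction <- attr(spec, "reduction_log")
    save_json(reduction, "reduction")
    logmsg("dropped C parameters: ",
           paste(reduction$parameter[reduction$dropped], collapse = ", "))
  }

  ace <- stage("ace_clpm",
               fit_ace_clpm(panel, spec = spec, n_starts = cfg$n_starts,
                            se = "delta"))
  dec <- stage("decompose", decompose_paths(ace))
  vcomp <- variance_components(ace)
  save_json(list(fit = ace$fit, theta = ace$theta,
                 paths = dec, variance_components = vcomp), "ace_clpm")
  utils::write.csv(dec, file.path(cfg$out_dir, "decomposition.csv"),
                   row.names = FALSE)
  artifacts["decomposition_csv"] <- file.path(cfg$out_dir,
                                              "decomposition.csv")

  uni <- stage("univariate", {
    vars <- unlist(lapply(traits, function(tr) paste0(tr, "_w", 1:3)))
    lapply(setNames(vars, vars), function(v) {
      u <- univariate_ace(panel, v)
      u[c("components", "twin_correlations", "se")]
    })
  })
  save_json(uni, "univariate")

  fitidx <- stage("fit_indices", lrt_vs_saturated(ace))
  save_json(fitidx, "fit_indices")

  mzd <- stage("mz_differences", fit_mzdiff_clpm(make_differences(panel)))
  save_json(mzd$paths, "mzdiff")

  # consolidated path table (byte-identical re-serialization of stage output)
  table <- stage("report_table", {
    stars <- function(lo, hi) ifelse(lo > 0 | hi < 0, "*", "")
    data.frame(path = dec$path, type = dec$type,
               beta = dec$total,
               beta_A = dec$beta_A, share_A = dec$share_A,
               beta_C = dec$beta_C, share_C = dec$share_C,
               beta_E = dec$beta_E, share_E = dec$share_E,
               sig_E = if ("beta_E_lower" %in% names(dec))
                 stars(dec$beta_E_lower, dec$beta_E_upper) else "")
  })
  utils::write.csv(table, file.path(cfg$out_dir, "table_paths.csv"),
                   row.names = FALSE)
  artifacts["table_paths_csv"] <- file.path(cfg$out_dir, "table_paths.csv")
  save_json(artifacts, "provenance")
  logmsg("analysis complete; ", length(artifacts), " artifacts")

  invisible(list(config = cfg, exclusions = excl$log, clpm = clpm,
                 reduction = reduction, ace = ace, decomposition = dec,
                 variance_components = vcomp, univariate = uni,
                 fit_indices = fitidx, mz_differences = mzd,
                 artifacts = artifacts))
}
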