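#' Column schema for twin-pair CSV files
#'
#' Describes how the columns of a wide-format twin-pair table (one row per
#' pair) map onto the fields the package needs.  Score columns follow the
#' fixed panel naming `<trait>_<twin>_w<wave>`.
#'
#' @param traits character vector of trait names present in the file.
#' @param family_id,zygosity,sex,age column names for the identifiers and
#'   covariates (`sex` length 2, `age` length 3).
#' @param zygosity_codes named character vector mapping the accepted file
#'   codes onto `"MZ"`/`"DZ"`.
#' @return A schema list used by [read_pairs()].
#' @export
twin_schema <- function(traits = c("cog", "emo"), family_id = "family_id",
                        zygosity = "zygosity",
                        sex = c("sex_1", "sex_2"),
                        age = paste0("age_w", 1:3),
                        zygosity_codes = c(MZ = "MZ", DZ = "DZ")) {
  list(traits = traits, family_id = family_id, zygosity = zygosity,
       sex = sex, age = age, zygosity_codes = zygosity_codes,
       scores = panel_col_names(traits))
}

#' Read twin-pair records from a delimited file
#'
#' Parses a wide-format CSV of twin pairs.  Rows that cannot be validated
#' (unknown zygosity code, non-numeric score) are rejected and reported in
#' the `"problems"` attribute of the result with their row index; missing
#' values are coded uniformly as `NA`.
#'
#' @param path file path.
#' @param schema a [twin_schema()].
#' @param na the missing-value token (default: empty cell).
#' @return data.frame of validated records, with attribute `"problems"`
#'   (data.frame with columns `row`, `column`, `message`; zero rows when the
#'   file is clean).
#' @export
read_pairs <- function(path, schema = twin_schema(), na = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.csv(path, na.strings = na, colClasses = "character",
             check.names = FALSE),
    error = function(e) stop("malformed file ", path, ": ",
                             conditionMessage(e)))
  needed <- c(schema$family_id, schema$zygosity, schema$scores)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  problems <- list()
  note <- function(row, col, msg)
    problems[[length(problems) + 1]] <<- data.frame(row = row, column = col,
                                                    message = msg)
  # zygosity
  zmap <- schema$zygosity_codes
  zraw <- raw[[schema$zygosity]]
  zyg <- names(zmap)[match(zraw, zmap)]
  for (i in which(is.na(zyg) | is.na(zraw)))
    note(i, schema$zygosity, paste0("unknown zygosity code '",
                                    ifelse(is.na(zraw[i]), "<NA>", zraw[i]),
                                    "'"))
  # numeric columns
  numeric_cols <- intersect(c(schema$scores, schema$sex, schema$age),
                            names(raw))
  bad <- rep(FALSE, nrow(raw))
  out <- raw
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    broken <- which(!is.na(raw[[cn]]) & is.na(v))
    for (i in broken) note(i, cn, paste0("non-numeric value '",
                                         raw[[cn]][i], "'"))
    bad[broken] <- TRUE
    out[[cn]] <- v
  }
  bad <- bad | is.na(zyg)
  out[[schema$zygosity]] <- zyg
  # a retained record needs at least one non-missing score
  sc <- as.matrix(out[, schema$scores, drop = FALSE])
  empty <- rowSums(!is.na(sc)) == 0
  for (i in which(empty & !bad))
    note(i, NA_character_, "no non-missing score for either twin")
  bad <- bad | empty
  dup <- duplicated(out[[schema$family_id]])
  for (i in which(dup & !bad))
    note(i, schema$family_id, "duplicate family_id")
  bad <- bad | dup
  res <- out[!bad, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "problems") <- if (length(problems) > 0)
    do.call(rbind, problems)
  else
    data.frame(row = integer(0), column = character(0),
               message = character(0))
  attr(res, "schema") <- schema
  res
}

#' Write twin-pair records to CSV
#'
#' Inverse of [read_pairs()]: missing values become the `na` token.
#'
#' @param records data.frame of twin-pair records.
#' @param path output file path.
#' @param na missing-value token.
#' @export
write_pairs <- function(records, path, na = "") {
  write.csv(records, path, row.names = FALSE, na = na)
  invisible(path)
}

#' Apply exclusion flags to twin-pair records
#'
#' Retains the records for which every exclusion flag is `FALSE` and returns
#' a per-reason exclusion log.  The flags are supplied by the caller (for the
#' study design this package supports they encode, e.g., severe medical
#' problems); the package does not infer them.
#'
#' @param records data.frame of twin-pair records.
#' @param flags either a logical data.frame/matrix with one column per
#'   exclusion reason (`nrow(records)` rows), or a character vector naming
#'   logical columns of `records`.
#' @return list with `retained` (records data.frame) and `log` (named counts
#'   per reason plus `total_excluded`).
#' @export
apply_exclusions <- function(records, flags = NULL) {
  if (is.null(flags) || (is.data.frame(flags) && ncol(flags) == 0)) {
    return(list(retained = records,
                log = list(total_excluded = 0L, reasons = list())))
  }
  if (is.character(flags)) {
    missing_f <- setdiff(flags, names(records))
    if (length(missing_f) > 0)
      stop("flag columns not found: ", paste(missing_f, collapse = ", "))
    fl <- records[, flags, drop = FALSE]
  } else fl <- as.data.frame(flags)
  fl[] <- lapply(fl, function(x) !is.na(x) & as.logical(x))
  if (nrow(fl) != nrow(records))
    stop("flags must have one row per record")
  drop <- Reduce(`|`, fl, accumulate = FALSE)
  drop <- if (is.null(drop)) rep(FALSE, nrow(records)) else drop
  retained <- records[!drop, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       log = list(total_excluded = sum(drop),
                  reasons = as.list(colSums(as.matrix(fl)))))
}

# individual-level long view: one row per twin, score columns trait x wave
records_to_individuals <- function(records, schema) {
  traits <- schema$traits
  n <- nrow(records)
  per_twin <- function(tw) {
    sc <- as.matrix(records[, unlist(lapply(traits, function(tr)
      paste0(tr, "_", tw, "_w", 1:3))), drop = FALSE])
    colnames(sc) <- unlist(lapply(traits, function(tr) paste0(tr, "_w", 1:3)))
    sex <- if (all(schema$sex %in% names(records)))
      records[[schema$sex[tw]]] else rep(NA_real_, n)
    list(scores = sc, sex = sex)
  }
  t1 <- per_twin(1); t2 <- per_twin(2)
  ages <- if (all(schema$age %in% names(records)))
    as.matrix(records[, schema$age, drop = FALSE])
  else matrix(NA_real_, n, 3)
  list(scores = rbind(t1$scores, t2$scores),
       sex = c(t1$sex, t2$sex),
       age = rbind(ages, ages),
       family = rep(records[[schema$family_id]], 2),
       zygosity = rep(records[[schema$zygosity]], 2),
       twin = rep(1:2, each = n))
}

#' Residualize and standardize twin scores
#'
#' Regresses every score on sex and the wave's age across individuals (both
#' twins pooled, all zygosity groups pooled), replaces scores by the
#' z-standardized residuals and returns a phenotype panel in the fixed column
#' order (twin 1: trait1 w1..w3, trait2 w1..w3; then twin 2).  An individual
#' missing sex or a wave's age is set missing for that wave's scores rather
#' than silently imputed.  When a covariate is constant over the estimation
#' sample (e.g. absent sex column) it is dropped from the regression.
#'
#' @param records data.frame of twin-pair records (from [read_pairs()] or
#'   [simulate_pairs()]).
#' @param schema a [twin_schema()]; defaults to the schema attached by
#'   `read_pairs`, or a schema built from `traits`.
#' @param traits trait names, used when no schema is attached.
#' @return A `phenotype_panel`: numeric matrix (pairs x 2*3*traits) with
#'   attributes `traits`, `family_id`, `zygosity` and `scaling` (per-column
#'   mean/sd used for standardization).
#' @export
residualize <- function(records, traits = c("cog", "emo"),
                        schema = attr(records, "schema") %||%
                          twin_schema(traits)) {
  ind <- records_to_individuals(records, schema)
  sc <- ind$scores
  k <- length(schema$traits)
  res <- matrix(NA_real_, nrow(sc), ncol(sc), dimnames = dimnames(sc))
  for (j in seq_len(ncol(sc))) {
    wave <- as.integer(sub(".*_w", "", colnames(sc)[j]))
    y <- sc[, j]
    x_sex <- ind$sex
    x_age <- ind$age[, wave]
    have_cov <- list(sex = !all(is.na(x_sex)), age = !all(is.na(x_age)))
    # individuals with a score but a missing available covariate: score -> NA
    if (have_cov$sex) y[is.na(x_sex)] <- NA
    if (have_cov$age) y[is.na(x_age)] <- NA
    use <- !is.na(y)
    if (sum(use) < 3) stop("too few observations to residualize column ",
                           colnames(sc)[j])
    if (stats::sd(y[use]) < 1e-12)
      stop("zero variance in score column ", colnames(sc)[j])
    X <- cbind(intercept = 1,
               if (have_cov$sex && stats::sd(x_sex[use]) > 0) x_sex,
               if (have_cov$age && stats::sd(x_age[use]) > 0) x_age)
    fit <- stats::lm.fit(X[use, , drop = FALSE], y[use])
    res[use, j] <- fit$residuals
  }
  standardize_panel(res, ind, schema)
}

standardize_panel <- function(res, ind, schema) {
  scaling <- data.frame(column = colnames(res),
                        mean = colMeans(res, na.rm = TRUE),
                        sd = apply(res, 2, stats::sd, na.rm = TRUE))
  for (j in seq_len(ncol(res))) {
    if (is.na(scaling$sd[j]) || scaling$sd[j] < 1e-12)
      stop("zero variance in residualized column ", scaling$column[j])
    res[, j] <- (res[, j] - scaling$mean[j]) / scaling$sd[j]
  }
  n <- nrow(res) / 2
  panel <- cbind(res[seq_len(n), , drop = FALSE],
                 res[n + seq_len(n), , drop = FALSE])
  colnames(panel) <- panel_col_names(schema$traits)
  structure(panel, class = "phenotype_panel", traits = schema$traits,
            family_id = ind$family[seq_len(n)],
            zygosity = ind$zygosity[seq_len(n)], scaling = scaling)
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat("phenotype_panel:", nrow(x), "pairs,",
      length(attr(x, "traits")), "traits x 3 waves\n")
  cat("  traits:", paste(attr(x, "traits"), collapse = ", "), "\n")
  zt <- table(attr(x, "zygosity"))
  cat("  zygosity:", paste(names(zt), zt, sep = "=", collapse = ", "), "\n")
  cat("  missingness:", round(100 * mean(is.na(unclass(x))), 1), "%\n")
  invisible(x)
}

#' Construct a phenotype panel directly from a score matrix
#'
#' For already-residualized, standardized scores (e.g. the covariate-free
#' output of [simulate_pairs()]).  Columns must follow the fixed panel order.
#'
#' @param scores numeric matrix (pairs x 2*3*traits) or a records data.frame
#'   containing the panel score columns.
#' @param traits trait names.
#' @param family_id,zygosity per-pair identifiers; taken from the records
#'   columns when `scores` is a data.frame.
#' @param standardize if `TRUE` (default), center and scale each column.
#' @return A `phenotype_panel`.
#' @export
as_phenotype_panel <- function(scores, traits = c("cog", "emo"),
                               family_id = NULL, zygosity = NULL,
                               standardize = TRUE) {
  if (is.data.frame(scores)) {
    family_id <- family_id %||% scores$family_id
    zygosity <- zygosity %||% scores$zygosity
    scores <- as.matrix(scores[, panel_col_names(traits), drop = FALSE])
  }
  stopifnot(ncol(scores) == 6 * length(traits))
  colnames(scores) <- panel_col_names(traits)
  scaling <- data.frame(column = colnames(scores),
                        mean = if (standardize)
                          colMeans(scores, na.rm = TRUE) else 0,
                        sd = if (standardize)
                          apply(scores, 2, stats::sd, na.rm = TRUE) else 1)
  if (standardize)
    for (j in seq_len(ncol(scores)))
      scores[, j] <- (scores[, j] - scaling$mean[j]) / scaling$sd[j]
  structure(scores, class = "phenotype_panel", traits = traits,
            family_id = family_id %||% seq_len(nrow(scores)),
            zygosity = zygosity %||% rep(NA_character_, nrow(scores)),
            scaling = scaling)
}

# individual-level matrix view of a panel: (2n) x (traits*3)
panel_individuals <- function(panel) {
  k <- length(attr(panel, "traits"))
  n <- nrow(panel)
  m <- rbind(unclass(panel)[, seq_len(3 * k), drop = FALSE],
             unclass(panel)[, 3 * k + seq_len(3 * k), drop = FALSE])
  colnames(m) <- unlist(lapply(attr(panel, "traits"),
                               function(tr) paste0(tr, "_w", 1:3)))
  list(scores = m, family = rep(attr(panel, "family_id"), 2),
       zygosity = rep(attr(panel, "zygosity"), 2))
}

#' Regress one trait out of another, wave by wave
#'
#' Replaces the target trait at each wave by its residual from a regression
#' on the nuisance trait at the same wave (across individuals, both twins
#' pooled), re-standardizes it, and drops the nuisance trait from the panel.
#' Used to analyse verbal ability independent of nonverbal ability and vice
#' versa.
#'
#' @param panel a `phenotype_panel` containing both traits.
#' @param target trait to adjust.
#' @param nuisance trait to regress out (dropped from the result).
#' @return A `phenotype_panel` without the nuisance trait.
#' @export
regress_out_trait <- function(panel, target, nuisance) {
  traits <- attr(panel, "traits")
  if (!all(c(target, nuisance) %in% traits))
    stop("panel does not contain traits ", target, " and ", nuisance)
  ind <- panel_individuals(panel)
  sc <- ind$scores
  adj <- sc
  for (w in 1:3) {
    ycol <- paste0(target, "_w", w)
    xcol <- paste0(nuisance, "_w", w)
    if (all(is.na(sc[, xcol])))
      stop("nuisance trait ", nuisance, " entirely missing at wave ", w)
    use <- !is.na(sc[, ycol]) & !is.na(sc[, xcol])
    if (sum(use) < 3) stop("too few complete pairs of ", ycol, ", ", xcol)
    fit <- stats::lm.fit(cbind(1, sc[use, xcol]), sc[use, ycol])
    r <- rep(NA_real_, nrow(sc))
    r[use] <- fit$residuals
    # target observed but nuisance missing: cannot adjust -> missing
    if (stats::sd(fit$residuals) < 1e-12)
      stop("zero residual variance adjusting ", ycol, " for ", xcol)
    adj[, ycol] <- r
  }
  keep_traits <- c(setdiff(traits, c(nuisance, target)), target)
  # preserve original trait order minus nuisance
  keep_traits <- traits[traits %in% keep_traits]
  keep_cols <- unlist(lapply(keep_traits, function(tr) paste0(tr, "_w", 1:3)))
  res <- adj[, keep_cols, drop = FALSE]
  standardize_panel(res, list(family = ind$family, zygosity = ind$zygosity),
                    twin_schema(keep_traits))
}

#' Write a phenotype panel to CSV
#'
#' One row per pair with `family_id`, `zygosity` and the residualized,
#' standardized score columns in the fixed panel order.
#'
#' @param panel a `phenotype_panel`.
#' @param path output file path.
#' @param na missing-value token.
#' @export
write_panel <- function(panel, path, na = "") {
  out <- data.frame(family_id = attr(panel, "family_id"),
                    zygosity = attr(panel, "zygosity"),
                    unclass(panel), check.names = FALSE)
  write.csv(out, path, row.names = FALSE, na = na)
  invisible(path)
}
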