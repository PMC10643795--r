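# Mortality contrasts, leave-one-parameter-out ablation, split robustness,
# and the predictor cross-correlation matrix.

#' Alive-vs-deceased contrast on deltaAge
#'
#' Two-sided two-sample t test (Welch by default; set `varEqual = TRUE` for
#' the pooled-variance form) on deltaAge between participants alive and
#' deceased at follow-up. Both the mean and the median per group are
#' reported.
#'
#' @param scoredTest scored data.frame with `delta_age` and `vital_status`
#'   in {"alive", "deceased"}.
#' @param varEqual use pooled variance instead of Welch.
#' @param on column to contrast (default `"delta_age"`; [score85Plus()] uses
#'   `"physiage"`).
#' @return list of class `MortalityContrast`: group sizes, means, medians,
#'   `t`, `p`.
#' @export
mortalityContrast <- function(scoredTest, varEqual = FALSE,
                              on = "delta_age") {
  stopIfMissingCols(scoredTest, c(on, "vital_status"), "scored table")
  known <- scoredTest[scoredTest$vital_status %in% c("alive", "deceased"), ]
  a <- known[[on]][known$vital_status == "alive"]
  d <- known[[on]][known$vital_status == "deceased"]
  if (length(a) == 0) stop("group empty: alive")
  if (length(d) == 0) stop("group empty: deceased")
  if (length(a) < 2 || length(d) < 2)
    stop("group too small: need >= 2 per vital-status group")
  if (sd(a) == 0 && sd(d) == 0 && mean(a) == mean(d)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(d, a, var.equal = varEqual)
  }
  structure(list(n_alive = length(a), n_deceased = length(d),
                 mean_alive = mean(a), mean_deceased = mean(d),
                 median_alive = median(a), median_deceased = median(d),
                 t = unname(tt$statistic), p = tt$p.value,
                 on = on, welch = !varEqual),
            class = "MortalityContrast")
}

#' @export
print.MortalityContrast <- function(x, ...) {
  cat(sprintf("Mortality contrast on %s (%s t test, two-tailed)\n", x$on,
              if (x$welch) "Welch" else "pooled-variance"))
  cat(sprintf("  alive    n = %4d  mean %6.2f  median %6.2f\n",
              x$n_alive, x$mean_alive, x$median_alive))
  cat(sprintf("  deceased n = %4d  mean %6.2f  median %6.2f\n",
              x$n_deceased, x$mean_deceased, x$median_deceased))
  cat(sprintf("  t = %.3f, p = %.4g\n", x$t, x$p))
  invisible(x)
}

#' Score and contrast the held 85+ participants
#'
#' Participants at the 85+ code are scored with a default age of 85 (NF
#' clamped to the table's highest tabulated age) and contrasted on the
#' PhysiAge score itself rather than deltaAge, since their exact calendar
#' age is unknown.
#'
#' @param model a \linkS4class{PhysiAgeModel}.
#' @param nf a \linkS4class{NormalizationTable}.
#' @param table85 data.frame of 85+ rows with `vital_status`.
#' @param varEqual use pooled variance instead of Welch.
#' @return a `MortalityContrast` on `physiage`.
#' @export
score85Plus <- function(model, nf, table85, varEqual = FALSE) {
  if (nrow(table85) == 0) stop("no 85+ rows supplied")
  table85$age <- 85
  scored <- physiAgeScore(model, nf, table85)
  mortalityContrast(scored, varEqual = varEqual, on = "physiage")
}

runVariant <- function(train, test, predictors, response, held85 = NULL) {
  model <- fitModel(train, predictors = predictors, response = response)
  nf <- buildNormalization(train, model)
  scored <- physiAgeScore(model, nf, test)
  mc <- if (any(scored$vital_status %in% "deceased") &&
            any(scored$vital_status %in% "alive"))
    mortalityContrast(scored) else NULL
  list(model = model, nf = nf, scored = scored,
       rmse = rmse(scored$physiage, scored$age),
       mortality_p = if (is.null(mc)) NA_real_ else mc$p,
       contrast = mc)
}

#' Leave-one-parameter-out ablation
#'
#' Refits the clock on the same train/test split with all four predictors
#' and with each predictor omitted once (five variants differing only in
#' the design matrix). Per variant: refit, rebuilt normalization table,
#' test-set RMSE vs calendar age, and the alive/deceased contrast p-value.
#'
#' @param prepared QC'd data.frame with response, predictors and
#'   `vital_status`.
#' @param seed split seed (the same split is reused across all variants).
#' @param trainFraction training proportion.
#' @param response response column (default `"phenoage"`).
#' @return data.frame of class `AblationResult` with columns `omitted`
#'   ("none" first), `rmse`, `mortality_p`; the variant models are attached
#'   as attribute `"variants"`.
#' @export
ablation <- function(prepared, seed = 1L, trainFraction = 0.8,
                     response = "phenoage") {
  sp <- splitTrainTest(prepared, trainFraction, seed)
  preds <- clockPredictors()
  variants <- c(list(none = preds),
                setNames(lapply(preds, function(p) setdiff(preds, p)), preds))
  fits <- lapply(names(variants), function(nm)
    runVariant(sp$train, sp$test, variants[[nm]], response))
  rows <- lapply(seq_along(fits), function(i)
    data.frame(omitted = names(variants)[i], rmse = fits[[i]]$rmse,
               mortality_p = fits[[i]]$mortality_p))
  out <- do.call(rbind, rows)
  class(out) <- c("AblationResult", class(out))
  attr(out, "variants") <- setNames(fits, names(variants))
  out
}

#' Split-robustness of the test RMSE
#'
#' Reruns the whole pipeline (stratified split, OLS fit, normalization,
#' test-set scoring) under each seed and summarizes the test RMSEs.
#'
#' @param prepared QC'd data.frame with response and predictors.
#' @param seeds integer vector of split seeds (>= 2).
#' @param trainFraction training proportion.
#' @param response response column.
#' @return list of class `SplitRobustnessResult`: `seeds`, `rmse` (per
#'   seed), `min`, `median`, `max`.
#' @export
splitRobustness <- function(prepared, seeds = 1:10, trainFraction = 0.8,
                            response = "phenoage") {
  if (length(seeds) < 2) stop("need at least 2 seeds")
  r <- vapply(seeds, function(s) {
    sp <- splitTrainTest(prepared, trainFraction, s)
    v <- runVariant(sp$train, sp$test, clockPredictors(), response)
    v$rmse
  }, numeric(1))
  structure(list(seeds = seeds, rmse = r, min = min(r),
                 median = median(r), max = max(r)),
            class = "SplitRobustnessResult")
}

#' @export
print.SplitRobustnessResult <- function(x, ...) {
  cat(sprintf("Split robustness over %d seeds: RMSE min %.2f / median %.2f / max %.2f years\n",
              length(x$seeds), x$min, x$median, x$max))
  invisible(x)
}

#' Pearson cross-correlation matrix of clock parameters
#'
#' Symmetric correlation matrix with unit diagonal, per-pair p-values and
#' the usual significance stars (* p < 0.05, ** p < 0.01, *** p < 0.001; no
#' multiple-testing correction). A zero-variance column is flagged and its
#' correlations reported as NA.
#'
#' @param tbl data.frame of complete rows (>= 3).
#' @param variables columns to correlate (default age + the three
#'   continuous predictors).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with matrices `r`, `p`, `stars` and the vector
#'   `zero_variance`.
#' @export
crossCorrelation <- function(tbl, variables = c("age", "glucose",
                                                "systolic_bp",
                                                "avg_daily_steps"),
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopIfMissingCols(tbl, variables, "table")
  tbl <- tbl[complete.cases(tbl[, variables, drop = FALSE]), variables,
             drop = FALSE]
  if (nrow(tbl) < 3) stop("need at least 3 complete rows")
  k <- length(variables)
  zv <- vapply(tbl, function(v) sd(v) == 0, logical(1))
  if (any(zv))
    warning("zero-variance column(s): ",
            paste(variables[zv], collapse = ", "))
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (zv[i] || zv[j]) next
    ct <- suppressWarnings(cor.test(tbl[[i]], tbl[[j]], method = method,
                                    exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix(starsFor(p), k, k, dimnames = dimnames(p))
  diag(stars) <- ""
  list(r = r, p = p, stars = stars, zero_variance = variables[zv])
}
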