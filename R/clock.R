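# The clock itself: QC, outlier fences, stratified split, OLS fit,
# normalization table, scoring, and the what-if sweeps.

clockPredictors <- function() c("sex", "glucose", "avg_daily_steps",
                                "systolic_bp")

#' The published PhysiAge model constants
#'
#' The final reported model:
#' raw = -18.5 + 1.972*Sex + 3.348*Gluc - 0.0004715*Steps + 0.3988*SysBP,
#' with Sex = 1 for men and 0 for women, glucose in mmol/L, steps per day,
#' systolic blood pressure in mmHg.
#'
#' @return a \linkS4class{PhysiAgeModel}.
#' @export
publishedPhysiAgeModel <- function() {
  new("PhysiAgeModel", intercept = -18.5,
      coefficients = c(sex = 1.972, glucose = 3.348,
                       avg_daily_steps = -0.0004715, systolic_bp = 0.3988),
      pvalues = numeric(0), note = "published constants")
}

#' QC-filter a raw participant table
#'
#' Removes rows with a missing or zero entry in any required physiological
#' column (sex and age are exempt from the zero rule: 0 is the female code),
#' drops rows younger than 20, and routes rows at the 85+ code (age >= 85 or
#' `is_85plus`) to a separate held table rather than discarding them. Every
#' exclusion reason is counted in the report.
#'
#' @param rawTable data.frame with at least `age` plus `requiredCols`.
#' @param requiredCols columns that must be present and (except sex) nonzero
#'   and non-missing; defaults to the four model predictors.
#' @return list with `retained` (ages 20-84, clean), `held_85plus`, and
#'   `report` (data.frame reason/count).
#' @export
qcFilter <- function(rawTable,
                     requiredCols = c("sex", clockPredictors()[-1])) {
  requiredCols <- unique(c("age", requiredCols))
  stopIfMissingCols(rawTable, requiredCols, "raw table")
  zeroCols <- setdiff(requiredCols, c("age", "sex"))
  n0 <- nrow(rawTable)
  hasNA <- !complete.cases(rawTable[, requiredCols, drop = FALSE])
  tbl <- rawTable[!hasNA, , drop = FALSE]
  hasZero <- rowSums(tbl[, zeroCols, drop = FALSE] == 0) > 0
  tbl <- tbl[!hasZero, , drop = FALSE]
  is85 <- tbl$age >= 85 |
    (if ("is_85plus" %in% names(tbl)) tbl$is_85plus else FALSE)
  held <- tbl[is85, , drop = FALSE]
  tbl <- tbl[!is85, , drop = FALSE]
  tooYoung <- tbl$age < 20
  tbl <- tbl[!tooYoung, , drop = FALSE]
  report <- data.frame(
    reason = c("input_rows", "missing_value", "zero_entry",
               "age_85plus_held", "age_below_20", "retained"),
    count = c(n0, sum(hasNA), sum(hasZero), nrow(held), sum(tooYoung),
              nrow(tbl)))
  list(retained = tbl, held_85plus = held, report = report)
}

#' Remove step-count outliers by Tukey fences
#'
#' Drops rows whose average daily step count lies outside
#' \[Q1 - k*IQR, Q3 + k*IQR\], quartiles taken over the whole population
#' (the box-and-whisker rule used to discard implausible accelerometer
#' totals). With fewer than 4 rows the table is returned unchanged with a
#' warning.
#'
#' @param tbl data.frame with `avg_daily_steps`.
#' @param k fence multiplier (> 0), default 1.5.
#' @return the filtered table; the removal count is reported via a message.
#' @export
removeStepOutliers <- function(tbl, k = 1.5) {
  stopIfMissingCols(tbl, "avg_daily_steps", "table")
  if (k <= 0) stop("k must be > 0")
  if (nrow(tbl) < 4) {
    warning("fewer than 4 rows; step-outlier filter skipped")
    return(tbl)
  }
  q <- quantile(tbl$avg_daily_steps, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- tbl$avg_daily_steps >= q[1] - k * iqr &
    tbl$avg_daily_steps <= q[2] + k * iqr
  message(sprintf("removeStepOutliers: removed %d of %d rows",
                  sum(!keep), nrow(tbl)))
  tbl[keep, , drop = FALSE]
}

#' Sex-stratified train/test split
#'
#' Within each sex stratum, `round(fraction * n)` rows (half-up rounding,
#' so partitions are reproducible across implementations) are sampled into
#' the training set; the split is deterministic under `seed` and the two
#' parts are disjoint with union equal to the input.
#'
#' @param tbl data.frame with a `sex` column.
#' @param trainFraction proportion in (0, 1) assigned to training.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
splitTrainTest <- function(tbl, trainFraction = 0.8, seed = 1L) {
  stopIfMissingCols(tbl, "sex", "table")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  withIsolatedSeed(seed, {
    trainIdx <- integer(0)
    for (s in sort(unique(tbl$sex))) {
      idx <- which(tbl$sex == s)
      if (length(idx) == 0) next
      nTrain <- roundHalfUp(trainFraction * length(idx))
      trainIdx <- c(trainIdx, sample(idx, nTrain))
    }
    list(train = tbl[sort(trainIdx), , drop = FALSE],
         test = tbl[setdiff(seq_len(nrow(tbl)), trainIdx), , drop = FALSE])
  })
}

#' Fit the clock by ordinary least squares
#'
#' Regresses the phenotypic-age response on the chosen predictors via
#' `stats::lm`. Rank deficiency (e.g. a single-sex training set) is an
#' explicit error rather than a silent NA coefficient.
#'
#' @param train data.frame containing `response` and `predictors`.
#' @param predictors character subset of
#'   sex / glucose / avg_daily_steps / systolic_bp.
#' @param response name of the response column (default `"phenoage"`;
#'   `"phenoage_true"` for simulation studies on the latent value).
#' @return a \linkS4class{PhysiAgeModel} with per-coefficient p-values; the
#'   `lm` fit is attached as attribute `"fit"` for diagnostics.
#' @export
fitModel <- function(train, predictors = clockPredictors(),
                     response = "phenoage") {
  bad <- setdiff(predictors, clockPredictors())
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  stopIfMissingCols(train, c(response, predictors), "training table")
  if (nrow(train) < length(predictors) + 1)
    stop("need at least ", length(predictors) + 1, " rows to fit")
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = train)
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("singular fit: coefficient(s) inestimable for ",
         paste(names(cf)[is.na(cf)], collapse = ", "),
         " (collinear or constant predictor)")
  pv <- summary(fit)$coefficients[, "Pr(>|t|)"]
  model <- new("PhysiAgeModel", intercept = unname(cf["(Intercept)"]),
               coefficients = cf[predictors],
               pvalues = pv[predictors],
               note = sprintf("OLS fit, n = %d, response = %s",
                              nrow(train), response))
  attr(model, "fit") <- fit
  model
}

#' Evaluate the raw (un-normalized) linear prediction
#'
#' Exact affine evaluation of the model over its included terms. Inputs may
#' be given as a data.frame or as named vectors; units are sex in {0, 1},
#' glucose mmol/L, steps per day, systolic BP mmHg.
#'
#' @param model a \linkS4class{PhysiAgeModel}.
#' @param data data.frame with the model's predictor columns; alternatively
#'   supply `sex`, `glucose`, `avg_daily_steps`, `systolic_bp` directly.
#' @param sex,glucose,avg_daily_steps,systolic_bp scalar/vector inputs used
#'   when `data` is NULL.
#' @return numeric vector of raw predictions in years.
#' @examples
#' rawPredict(publishedPhysiAgeModel(), sex = 0, glucose = 6,
#'            avg_daily_steps = 5000, systolic_bp = 130)  # 51.0745
#' @export
rawPredict <- function(model, data = NULL, sex = NULL, glucose = NULL,
                       avg_daily_steps = NULL, systolic_bp = NULL) {
  stopifnot(is(model, "PhysiAgeModel"))
  if (is.null(data))
    data <- data.frame(sex = sex %||% 0, glucose = glucose %||% 0,
                       avg_daily_steps = avg_daily_steps %||% 0,
                       systolic_bp = systolic_bp %||% 0)
  terms <- names(model@coefficients)
  stopIfMissingCols(data, terms, "prediction input")
  if ("avg_daily_steps" %in% terms && any(data$avg_daily_steps < 0))
    stop("negative step counts are invalid")
  if ("glucose" %in% terms && any(data$glucose <= 0))
    stop("glucose must be > 0")
  if ("sex" %in% terms && !all(data$sex %in% c(0, 1)))
    stop("sex must be coded 1 = male, 0 = female")
  pred <- rep(model@intercept, nrow(data))
  for (nm in terms) pred <- pred + model@coefficients[[nm]] * data[[nm]]
  pred
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the normalization table from scored training data
#'
#' NF(a) is the median raw model prediction among training participants of
#' integer age a (no smoothing). Ages inside the observed range with no
#' participants are filled by linear interpolation between the nearest
#' populated ages and flagged `interpolated`.
#'
#' @param train training data.frame (must include `age` and the model's
#'   predictors).
#' @param model a \linkS4class{PhysiAgeModel}.
#' @return a \linkS4class{NormalizationTable}.
#' @export
buildNormalization <- function(train, model) {
  if (nrow(train) == 0) stop("empty training set")
  stopIfMissingCols(train, "age", "training table")
  raw <- rawPredict(model, train)
  ages <- seq(min(train$age), max(train$age))
  med <- vapply(ages, function(a) {
    v <- raw[train$age == a]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  interp <- is.na(med)
  if (any(interp)) {
    filled <- approx(ages[!interp], med[!interp], xout = ages,
                     rule = 2)$y
    med[interp] <- filled[interp]
  }
  if (any(med <= 0))
    stop("non-positive median prediction; normalization undefined")
  new("NormalizationTable", age = as.integer(ages), nf = med,
      interpolated = interp)
}

#' Score participants: PhysiAge and deltaAge
#'
#' PhysiAge = raw prediction / NF(age) * age; deltaAge = PhysiAge - age.
#' Rows at the 85+ code (age >= 85 or `is_85plus`) are scored with a default
#' age of 85 and NF clamped to the table's highest tabulated age; clamping
#' is reported via [nfLookup()]'s message.
#'
#' @param model a \linkS4class{PhysiAgeModel}.
#' @param nf a \linkS4class{NormalizationTable}.
#' @param participants data.frame with `age` and the model's predictors.
#' @return the input with `raw_prediction`, `physiage` and `delta_age`
#'   columns appended.
#' @export
physiAgeScore <- function(model, nf, participants) {
  stopifnot(is(model, "PhysiAgeModel"), is(nf, "NormalizationTable"))
  stopIfMissingCols(participants, "age", "participants")
  scoreAge <- participants$age
  is85 <- scoreAge >= 85 |
    (if ("is_85plus" %in% names(participants)) participants$is_85plus
     else FALSE)
  scoreAge[is85] <- 85
  below <- scoreAge < min(nf@age)
  if (any(below & !is85))
    stop("participant age below the normalization table's range and not ",
         "clampable (85+ is the only clamped code)")
  raw <- rawPredict(model, participants)
  nfv <- nfLookup(nf, scoreAge)
  participants$raw_prediction <- raw
  participants$physiage <- raw / nfv * scoreAge
  participants$delta_age <- participants$physiage - scoreAge
  participants
}

#' What-if sweep over steps or glucose for a fixed profile
#'
#' Re-scores one hypothetical profile over a grid of the chosen variable
#' (defaults: steps 5,000-20,000 by 1,000; glucose 4-10 mmol/L by 1). Each
#' row equals a direct [physiAgeScore()] call.
#'
#' @param profile one-row data.frame or named list with `age`, `sex`,
#'   `glucose`, `avg_daily_steps`, `systolic_bp`.
#' @param variable `"avg_daily_steps"` or `"glucose"` (aliases `"steps"`,
#'   `"glucose"`).
#' @param model a \linkS4class{PhysiAgeModel}.
#' @param nf a \linkS4class{NormalizationTable}.
#' @param grid optional numeric grid overriding the default range.
#' @return data.frame with columns `value`, `physiage`, `delta_age`.
#' @export
whatIfSweep <- function(profile, variable = c("avg_daily_steps", "glucose",
                                              "steps"),
                        model = publishedPhysiAgeModel(), nf, grid = NULL) {
  variable <- match.arg(variable)
  if (variable == "steps") variable <- "avg_daily_steps"
  if (is.null(grid))
    grid <- if (variable == "avg_daily_steps") seq(5000, 20000, by = 1000)
            else seq(4, 10, by = 1)
  if (length(grid) == 0) stop("empty sweep grid")
  prof <- as.data.frame(profile)
  rows <- prof[rep(1, length(grid)), , drop = FALSE]
  rows[[variable]] <- grid
  scored <- physiAgeScore(model, nf, rows)
  data.frame(value = grid, physiage = scored$physiage,
             delta_age = scored$delta_age)
}

#' Read / write a PhysiAge model file
#'
#' Key-value YAML with `intercept`, a `coefficients` map over the model's
#' included terms, and an optional `note`. Round-trips losslessly.
#'
#' @param path file path.
#' @return `readPhysiAgeModel()` a \linkS4class{PhysiAgeModel};
#'   `writePhysiAgeModel()` the path, invisibly.
#' @export
readPhysiAgeModel <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$intercept) || is.null(raw$coefficients))
    stop("model file must contain 'intercept' and 'coefficients'")
  new("PhysiAgeModel", intercept = raw$intercept,
      coefficients = unlist(raw$coefficients),
      pvalues = if (is.null(raw$pvalues)) numeric(0) else unlist(raw$pvalues),
      note = raw$note %||% "")
}

#' @rdname readPhysiAgeModel
#' @param model a \linkS4class{PhysiAgeModel}.
#' @export
writePhysiAgeModel <- function(model, path) {
  stopifnot(is(model, "PhysiAgeModel"))
  out <- list(intercept = model@intercept,
              coefficients = as.list(model@coefficients))
  if (length(model@pvalues))  # floored: YAML readers choke near 1e-308
    out$pvalues <- as.list(pmax(model@pvalues, 1e-300))
  if (nzchar(model@note)) out$note <- model@note
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
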