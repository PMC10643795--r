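#' PhysiAgeModel: the linear physiological-age predictor
#'
#' Holds the intercept and the coefficients of the linear predictor of
#' phenotypic age. Predictor units: sex coded 1 = male / 0 = female, blood
#' glucose in mmol/L, average daily steps in steps/day, systolic blood
#' pressure in mmHg. A model variant from the ablation analysis may carry a
#' subset of the four terms; excluded terms simply do not appear in
#' \code{coefficients}.
#'
#' @slot intercept numeric(1), years.
#' @slot coefficients named numeric, a subset of
#'   \code{c("sex","glucose","avg_daily_steps","systolic_bp")}.
#' @slot pvalues named numeric, per-coefficient two-sided p-values from the
#'   OLS fit (empty for hand-specified models such as the published preset).
#' @slot note character(1), free-text provenance note.
#' @seealso [publishedPhysiAgeModel()], [fitModel()], [rawPredict()]
#' @export
setClass("PhysiAgeModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 pvalues = "numeric", note = "character"),
  prototype(intercept = 0, coefficients = numeric(0),
            pvalues = numeric(0), note = ""))

setValidity("PhysiAgeModel", function(object) {
  msg <- character(0)
  allowed <- c("sex", "glucose", "avg_daily_steps", "systolic_bp")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@coefficients)) {
    if (is.null(names(object@coefficients)) ||
        !all(names(object@coefficients) %in% allowed))
      msg <- c(msg, sprintf("coefficient names must be among: %s",
                            paste(allowed, collapse = ", ")))
    if (!all(is.finite(object@coefficients)))
      msg <- c(msg, "all coefficients must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' NormalizationTable: median raw prediction per integer calendar age
#'
#' Maps each integer calendar age in its declared range to the normalization
#' factor NF_Age (the median raw model prediction among training participants
#' of that age). Ages unpopulated in training are filled by linear
#' interpolation between the nearest populated ages (nearest value at the
#' endpoints) and flagged.
#'
#' @slot age integer vector, consecutive calendar ages covered.
#' @slot nf numeric vector, NF_Age per age; all > 0.
#' @slot interpolated logical vector, TRUE where the entry was filled rather
#'   than observed.
#' @seealso [buildNormalization()], [nfLookup()], [readNormalizationTable()]
#' @export
setClass("NormalizationTable",
  representation(age = "integer", nf = "numeric", interpolated = "logical"))

setValidity("NormalizationTable", function(object) {
  msg <- character(0)
  if (length(object@age) == 0) msg <- c(msg, "table must be non-empty")
  if (length(object@age) != length(object@nf) ||
      length(object@age) != length(object@interpolated))
    msg <- c(msg, "age, nf and interpolated must have equal length")
  else {
    if (any(diff(object@age) != 1L))
      msg <- c(msg, "ages must be consecutive integers")
    if (any(!is.finite(object@nf)) || any(object@nf <= 0))
      msg <- c(msg, "all NF values must be finite and > 0")
  }
  if (length(msg)) msg else TRUE
})

#' PhenoAgeConfig: parameterization of the phenotypic-age mapping
#'
#' Phenotypic age is computed from a linear predictor
#' \eqn{xb = intercept + \sum_j w_j x_j} over nine blood biomarkers plus
#' calendar age, mapped through a Gompertz-style mortality risk
#' \eqn{M = 1 - \exp(-e^{xb}(e^{h\gamma}-1)/\gamma)} (h = horizon in months)
#' and the outer transform \eqn{PhenoAge = a + \log(b \log(1-M))/c}.
#' Because the two transforms compose to an affine function of xb, the
#' mapping is strictly increasing in xb whenever c > 0.
#'
#' @slot intercept numeric(1), intercept of the linear predictor.
#' @slot weights named numeric over the ten inputs
#'   (albumin, creatinine, glucose, crp_ln, lymphocyte_pct, mcv, rdw, alp,
#'   wbc, age).
#' @slot gamma numeric(1), Gompertz rate per month; > 0.
#' @slot horizonMonths numeric(1), risk horizon in months; > 0.
#' @slot outerA,outerB,outerC numeric(1), constants a, b, c of the outer
#'   transform; b < 0 (log(1-M) is negative), c > 0.
#' @slot units named character, declared unit per biomarker input.
#' @seealso [computePhenoAge()], [loadPhenoAgeConfig()]
#' @export
setClass("PhenoAgeConfig",
  representation(intercept = "numeric", weights = "numeric", gamma = "numeric",
                 horizonMonths = "numeric", outerA = "numeric",
                 outerB = "numeric", outerC = "numeric", units = "character"))

#' @export
phenoAgeBiomarkers <- function() {
  c("albumin", "creatinine", "glucose", "crp_ln", "lymphocyte_pct",
    "mcv", "rdw", "alp", "wbc", "age")
}

setValidity("PhenoAgeConfig", function(object) {
  msg <- character(0)
  need <- phenoAgeBiomarkers()
  if (!setequal(names(object@weights), need))
    msg <- c(msg, sprintf("weights must cover exactly: %s",
                          paste(need, collapse = ", ")))
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0)
    msg <- c(msg, "gamma must be a single number > 0")
  if (length(object@horizonMonths) != 1L || object@horizonMonths <= 0)
    msg <- c(msg, "horizonMonths must be > 0")
  if (length(object@outerC) != 1L || !is.finite(object@outerC) ||
      object@outerC <= 0)
    msg <- c(msg, "outerC must be > 0 (mapping must increase in xb)")
  if (length(object@outerB) != 1L || !is.finite(object@outerB) ||
      object@outerB >= 0)
    msg <- c(msg, "outerB must be < 0")
  if (length(msg)) msg else TRUE
})

#' MetaboliteExperiment: plasma metabolite abundances with participant links
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"abundance"} assay
#' holds strictly positive processed abundances (rows = metabolites,
#' columns = samples). \code{colData} carries the join to scored
#' participants: \code{sample_id}, \code{group} (ordered factor
#' young < trained < normal < impaired), \code{sex}, \code{age} and
#' \code{delta_age}.
#'
#' @seealso [simulateMetabolome()], [readMetaboliteMatrix()],
#'   [correlateDelta()], [correlateGroups()]
#' @export
setClass("MetaboliteExperiment", contains = "SummarizedExperiment")

setValidity("MetaboliteExperiment", function(object) {
  msg <- character(0)
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must carry an 'abundance' assay")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (any(!is.na(a) & a <= 0))
      msg <- c(msg, "abundances must be strictly positive")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "metabolite names must be unique")
  if (!all(c("sample_id", "group") %in% names(colData(object))))
    msg <- c(msg, "colData must contain sample_id and group")
  if (length(msg)) msg else TRUE
})

healthGroupLevels <- function() c("young", "trained", "normal", "impaired")

#' Ordinal codes for the four health groups
#'
#' Maps the ordered health groups young < trained < normal < impaired to
#' ordinal codes 0-3, operationalizing the declining-health trend the group
#' screen correlates against.
#'
#' @param groups factor or character vector of group labels.
#' @return integer vector of codes 0-3.
#' @export
healthGroupCodes <- function(groups) {
  lv <- healthGroupLevels()
  g <- as.character(groups)
  bad <- setdiff(unique(g), lv)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  match(g, lv) - 1L
}

setMethod("show", "PhysiAgeModel", function(object) {
  cat("PhysiAgeModel (raw prediction, years)\n")
  cat(sprintf("  intercept: %g\n", object@intercept))
  for (nm in names(object@coefficients))
    cat(sprintf("  %-16s %+g%s\n", nm, object@coefficients[[nm]],
                if (nm %in% names(object@pvalues))
                  sprintf("  (p = %.3g)", object@pvalues[[nm]]) else ""))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "NormalizationTable", function(object) {
  cat(sprintf("NormalizationTable: ages %d-%d (%d interpolated)\n",
              min(object@age), max(object@age), sum(object@interpolated)))
  cat(sprintf("  NF range: %.2f-%.2f\n", min(object@nf), max(object@nf)))
})

setMethod("show", "PhenoAgeConfig", function(object) {
  cat("PhenoAgeConfig\n")
  cat(sprintf("  xb intercept %g; gamma %g /month; horizon %g months\n",
              object@intercept, object@gamma, object@horizonMonths))
  cat(sprintf("  outer: a = %g, b = %g, c = %g\n",
              object@outerA, object@outerB, object@outerC))
  w <- object@weights[phenoAgeBiomarkers()]
  cat("  weights:", paste(sprintf("%s=%g", names(w), w), collapse = ", "),
      "\n")
})

# --- accessors ---------------------------------------------------------------

#' @describeIn PhysiAgeModel-class coefficients including the intercept,
#'   as a named numeric vector.
#' @param object a PhysiAgeModel.
#' @export
setMethod("coef", "PhysiAgeModel", function(object) {
  c("(Intercept)" = object@intercept, object@coefficients)
})

#' Accessors for NormalizationTable
#'
#' @param x a \linkS4class{NormalizationTable}.
#' @return `nfAges()` the covered integer ages; `nfValues()` the NF_Age
#'   values; `nfInterpolated()` the fill flags.
#' @export
nfAges <- function(x) x@age

#' @rdname nfAges
#' @export
nfValues <- function(x) setNames(x@nf, x@age)

#' @rdname nfAges
#' @export
nfInterpolated <- function(x) setNames(x@interpolated, x@age)

#' Look up NF_Age for given ages, clamping outside the tabulated range
#'
#' Ages above the table's maximum (the 85+ convention) or below its minimum
#' are clamped to the nearest tabulated age; clamping is reported via a
#' message.
#'
#' @param nf a \linkS4class{NormalizationTable}.
#' @param age integer vector of calendar ages.
#' @return numeric vector of NF values.
#' @export
nfLookup <- function(nf, age) {
  lo <- min(nf@age); hi <- max(nf@age)
  clamped <- age < lo | age > hi
  if (any(clamped))
    message(sprintf("nfLookup: %d age(s) clamped to tabulated range %d-%d",
                    sum(clamped), lo, hi))
  a <- pmin(pmax(age, lo), hi)
  nf@nf[match(a, nf@age)]
}
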