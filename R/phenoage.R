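# Phenotypic age: linear predictor over nine blood biomarkers + calendar age,
# mapped through a Gompertz mortality risk and an outer log transform.

#' Construct a PhenoAgeConfig
#'
#' @param intercept intercept of the linear predictor xb.
#' @param weights named numeric over the ten inputs (see
#'   [phenoAgeBiomarkers()]); units per the `units` declaration.
#' @param gamma Gompertz rate per month (> 0).
#' @param horizonMonths risk horizon in months.
#' @param outerA,outerB,outerC outer-transform constants a, b (< 0), c (> 0).
#' @param units named character of unit declarations; defaults to the
#'   standard clinical units (albumin g/L, creatinine umol/L, glucose mmol/L,
#'   CRP on the natural-log mg/dL scale, lymphocytes %, MCV fL, RDW %,
#'   ALP U/L, WBC 10^3 cells/uL, age years).
#' @return a validated \linkS4class{PhenoAgeConfig}.
#' @export
phenoAgeConfig <- function(intercept, weights, gamma, horizonMonths = 120,
                           outerA, outerB, outerC, units = defaultPhenoAgeUnits()) {
  new("PhenoAgeConfig", intercept = as.numeric(intercept),
      weights = weights[phenoAgeBiomarkers()], gamma = as.numeric(gamma),
      horizonMonths = as.numeric(horizonMonths), outerA = as.numeric(outerA),
      outerB = as.numeric(outerB), outerC = as.numeric(outerC), units = units)
}

#' @rdname phenoAgeConfig
#' @export
defaultPhenoAgeUnits <- function() {
  c(albumin = "g/L", creatinine = "umol/L", glucose = "mmol/L",
    crp_ln = "ln mg/dL", lymphocyte_pct = "%", mcv = "fL", rdw = "%",
    alp = "U/L", wbc = "10^3 cells/uL", age = "years")
}

#' The shipped Levine phenotypic-age parameterization
#'
#' Loads the externally sourced default configuration (the published Levine
#' et al. weights, transcribed in \code{inst/extdata/phenoage_levine2018.yaml}).
#' Self-contained tests use synthetic configs; this preset is for scoring
#' real biomarker panels and for the synthetic generator's latent panel.
#'
#' @return a \linkS4class{PhenoAgeConfig}.
#' @export
levinePhenoAgeConfig <- function() {
  loadPhenoAgeConfig(system.file("extdata", "phenoage_levine2018.yaml",
                                 package = "PhysiAge", mustWork = TRUE))
}

#' Read / write a phenotypic-age configuration file
#'
#' The file is YAML with keys \code{intercept}, \code{gamma},
#' \code{horizon_months}, \code{outer: {a, b, c}}, \code{weights:} (one key
#' per biomarker plus \code{age}) and optionally \code{units:}. Unknown
#' weight keys and a missing \code{gamma} are schema errors naming the field;
#' missing \code{horizon_months} defaults to 120 and missing \code{units} to
#' [defaultPhenoAgeUnits()].
#'
#' @param path file path.
#' @return `loadPhenoAgeConfig()` a \linkS4class{PhenoAgeConfig};
#'   `writePhenoAgeConfig()` the path, invisibly. Write-then-read
#'   round-trips losslessly.
#' @export
loadPhenoAgeConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$gamma)) stop("config schema error: missing field 'gamma'")
  if (is.null(raw$weights)) stop("config schema error: missing field 'weights'")
  if (is.null(raw$intercept)) stop("config schema error: missing field 'intercept'")
  known <- phenoAgeBiomarkers()
  unknown <- setdiff(names(raw$weights), known)
  if (length(unknown))
    stop("config schema error: unknown biomarker key(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(known, names(raw$weights))
  if (length(missing))
    stop("config schema error: missing weight(s): ",
         paste(missing, collapse = ", "))
  if (is.null(raw$outer) || is.null(raw$outer$a) || is.null(raw$outer$b) ||
      is.null(raw$outer$c))
    stop("config schema error: missing field 'outer' (a, b, c)")
  units <- defaultPhenoAgeUnits()
  if (!is.null(raw$units)) {
    u <- unlist(raw$units)
    units[names(u)] <- u
  }
  phenoAgeConfig(intercept = raw$intercept,
                 weights = unlist(raw$weights)[known],
                 gamma = raw$gamma,
                 horizonMonths = if (is.null(raw$horizon_months)) 120
                                 else raw$horizon_months,
                 outerA = raw$outer$a, outerB = raw$outer$b,
                 outerC = raw$outer$c, units = units)
}

#' @rdname loadPhenoAgeConfig
#' @param config a \linkS4class{PhenoAgeConfig}.
#' @export
writePhenoAgeConfig <- function(config, path) {
  stopifnot(is(config, "PhenoAgeConfig"))
  out <- list(intercept = config@intercept,
              gamma = config@gamma,
              horizon_months = config@horizonMonths,
              outer = list(a = config@outerA, b = config@outerB,
                           c = config@outerC),
              weights = as.list(config@weights[phenoAgeBiomarkers()]),
              units = as.list(config@units[phenoAgeBiomarkers()]))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# Linear predictor xb for a panel (data.frame or coercible row-wise list).
phenoAgeXb <- function(panel, config) {
  panel <- as.data.frame(panel)
  stopIfMissingCols(panel, phenoAgeBiomarkers(), "biomarker panel")
  xb <- rep(config@intercept, nrow(panel))
  for (nm in phenoAgeBiomarkers())
    xb <- xb + config@weights[[nm]] * panel[[nm]]
  xb
}

# log(-b * K) + xb gives c * (PhenoAge - a); K = (exp(h*gamma) - 1)/gamma.
phenoAgeLogBK <- function(config) {
  K <- (exp(config@horizonMonths * config@gamma) - 1) / config@gamma
  log(-config@outerB * K)
}

#' Compute phenotypic age from a biomarker panel
#'
#' Evaluates \eqn{xb}, the Gompertz mortality risk
#' \eqn{M = 1 - \exp(-e^{xb} K)} with \eqn{K = (e^{h\gamma}-1)/\gamma}, and
#' \eqn{PhenoAge = a + \log(b \log(1-M))/c}. The composition is evaluated on
#' the log scale (\eqn{\log(b\log(1-M)) = \log(-bK) + xb}), which is exact
#' and avoids 1 - M underflowing to zero for extreme panels; M itself is
#' still computed and validated to lie in (0, 1).
#'
#' @param panel data.frame (one row per participant) or named list with the
#'   columns of [phenoAgeBiomarkers()], in the config's declared units.
#' @param config a \linkS4class{PhenoAgeConfig}.
#' @param units optional named character; if supplied it must equal the
#'   config's declaration (unit mismatch is rejected, not converted).
#' @return numeric vector of phenotypic ages in years.
#' @examples
#' cfg <- levinePhenoAgeConfig()
#' computePhenoAge(defaultBiomarkerPanel(age = 50), cfg)
#' @export
computePhenoAge <- function(panel, config, units = NULL) {
  stopifnot(is(config, "PhenoAgeConfig"))
  if (!is.null(units)) {
    shared <- intersect(names(units), names(config@units))
    bad <- shared[units[shared] != config@units[shared]]
    if (length(bad))
      stop("unit mismatch for: ", paste(bad, collapse = ", "),
           " (declared ", paste(units[bad], collapse = ", "),
           ", config expects ", paste(config@units[bad], collapse = ", "), ")")
  }
  xb <- phenoAgeXb(panel, config)
  if (any(!is.finite(xb))) stop("non-finite linear predictor")
  M <- -expm1(-exp(xb) * (exp(config@horizonMonths * config@gamma) - 1) /
                config@gamma)
  if (any(!is.finite(M) | M <= 0 | M >= 1))
    stop("mortality risk M out of domain (0,1): panel too extreme")
  # exact log-scale evaluation; equals a + log(b*log(1-M))/c
  config@outerA + (phenoAgeLogBK(config) + xb) / config@outerC
}

#' Reference biomarker panel used as inversion defaults
#'
#' Mid-normal adult clinical values; `age` and `glucose` are typically
#' overridden with the participant's own values before inversion.
#'
#' @param age calendar age in years.
#' @param glucose fasting glucose, mmol/L.
#' @return one-row data.frame over [phenoAgeBiomarkers()].
#' @export
defaultBiomarkerPanel <- function(age = 50, glucose = 5.0) {
  data.frame(albumin = 43, creatinine = 75, glucose = glucose,
             crp_ln = log(0.1), lymphocyte_pct = 30, mcv = 90, rdw = 13,
             alp = 70, wbc = 6.5, age = age)
}

#' Solve one biomarker so the panel's phenotypic age hits a target
#'
#' All fields except `freeBiomarker` are taken from `panelDefaults`; the free
#' biomarker is solved analytically. Because the outer transform composes to
#' an affine function of the linear predictor, the required predictor is
#' \eqn{xb^\* = c\,(target - a) - \log(-bK)} and the free value follows from
#' its weight. The free biomarker's weight must be nonzero. Round-trip error
#' through [computePhenoAge()] is at machine precision (well under the
#' 1e-6-year contract).
#'
#' @param targetPhenoAge target in years (vectorized; recycled against
#'   `panelDefaults` rows).
#' @param panelDefaults data.frame of default panel values.
#' @param config a \linkS4class{PhenoAgeConfig}.
#' @param freeBiomarker which field to solve; default `"crp_ln"` (log-scale,
#'   so unbounded in both directions).
#' @return data.frame panel with the free biomarker replaced.
#' @export
invertBiomarkerForPhenoAge <- function(targetPhenoAge,
                                       panelDefaults = defaultBiomarkerPanel(),
                                       config = levinePhenoAgeConfig(),
                                       freeBiomarker = "crp_ln") {
  stopifnot(is(config, "PhenoAgeConfig"))
  if (!freeBiomarker %in% phenoAgeBiomarkers())
    stop("unknown biomarker: ", freeBiomarker)
  w <- config@weights[[freeBiomarker]]
  if (!is.finite(w) || w == 0)
    stop("free biomarker '", freeBiomarker, "' has zero weight in the config")
  panel <- as.data.frame(panelDefaults)
  n <- max(nrow(panel), length(targetPhenoAge))
  panel <- panel[rep_len(seq_len(nrow(panel)), n), , drop = FALSE]
  rownames(panel) <- NULL
  target <- rep_len(targetPhenoAge, n)
  xbStar <- config@outerC * (target - config@outerA) - phenoAgeLogBK(config)
  zero <- panel
  zero[[freeBiomarker]] <- 0
  xb0 <- phenoAgeXb(zero, config)
  value <- (xbStar - xb0) / w
  if (any(!is.finite(value)))
    stop("target phenotypic age unreachable for any finite '",
         freeBiomarker, "' value")
  panel[[freeBiomarker]] <- value
  panel
}
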