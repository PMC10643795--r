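# Synthetic NHANES-like cohort generator. Every physiological variable is
# Gaussian around a linear-in-age mean; slopes are calibrated so realized
# Spearman correlations with age hit their targets.

#' Default age-trend specifications and Spearman targets
#'
#' `defaultTrendSpecs()` gives each physiological variable's value at age
#' 20 and residual SD (clinically plausible adult values); the slope is
#' left `NA`, meaning it is calibrated against the target rank correlation.
#' `defaultTargetRhos()` gives the target Spearman correlations with age
#' (glucose 0.400, systolic BP 0.474, diastolic BP -0.151, resting heart
#' rate -0.224, BMI 0.075, steps 0.029).
#'
#' @return a named list of trend specs / a named numeric of target rhos.
#' @export
defaultTrendSpecs <- function() {
  list(
    glucose         = list(intercept_at_age20 = 5.0,  slope_per_year = NA, residual_sd = 0.8),
    systolic_bp     = list(intercept_at_age20 = 112,  slope_per_year = NA, residual_sd = 12),
    diastolic_bp    = list(intercept_at_age20 = 74,   slope_per_year = NA, residual_sd = 10),
    resting_hr      = list(intercept_at_age20 = 75,   slope_per_year = NA, residual_sd = 11),
    bmi             = list(intercept_at_age20 = 27.5, slope_per_year = NA, residual_sd = 6),
    avg_daily_steps = list(intercept_at_age20 = 9500, slope_per_year = NA, residual_sd = 4000)
  )
}

#' @rdname defaultTrendSpecs
#' @export
defaultTargetRhos <- function() {
  c(glucose = 0.400, systolic_bp = 0.474, diastolic_bp = -0.151,
    resting_hr = -0.224, bmi = 0.075, avg_daily_steps = 0.029)
}

#' Parameters for the NHANES-like cohort simulator
#'
#' @param n_participants cohort size after QC (the reference analysis uses
#'   3342).
#' @param age_range inclusive integer calendar-age range, within 20-84.
#' @param male_fraction proportion of males.
#' @param trends named list of per-variable trend specs, each a list
#'   `(intercept_at_age20, slope_per_year, residual_sd)`. A slope of `NA`
#'   (the default for all six variables) means "calibrate the slope so the
#'   population Spearman correlation with age equals the target"; an explicit
#'   slope bypasses calibration.
#' @param target_rank_correlations named numeric in (-1, 1): target Spearman
#'   rho of each variable with age.
#' @param phenoage_residual_sd total SD in years of latent phenotypic age
#'   around calendar age (`age_anchored` mode).
#' @param phenoage_covariate_share fraction (0-1) of the phenoage residual
#'   variance carried by the participant's physiological deviations from
#'   their age trend (direction given by the published coefficients over
#'   glucose, steps and systolic BP), the rest being independent noise.
#'   Physiology genuinely drives phenotypic age (glucose is itself a
#'   phenotypic-age input), so a clock built on these covariates can carry
#'   mortality information beyond calendar age; 0 makes the residual pure
#'   noise and deltaAge uninformative for mortality by construction.
#' @param mode `"age_anchored"` (phenoage_true = age + noise) or
#'   `"planted_truth"` (phenoage_true generated from the published linear
#'   coefficients over the simulated covariates plus noise, for parameter
#'   recovery studies).
#' @param planted_sigma residual SD (years) in `planted_truth` mode.
#' @param n_85plus extra participants generated at the 85+ code (age
#'   recorded as 85, covariates drawn at the age-85 trend values).
#' @param seed integer RNG seed.
#' @return validated parameter list of class `CohortSimParams`.
#' @export
cohortSimParams <- function(n_participants = 3342, age_range = c(20L, 84L),
                            male_fraction = 0.5,
                            trends = defaultTrendSpecs(),
                            target_rank_correlations = defaultTargetRhos(),
                            phenoage_residual_sd = 7.4,
                            phenoage_covariate_share = 0.5,
                            mode = c("age_anchored", "planted_truth"),
                            planted_sigma = 12, n_85plus = 0L, seed = 1L) {
  mode <- match.arg(mode)
  if (phenoage_covariate_share < 0 || phenoage_covariate_share > 1)
    stop("phenoage_covariate_share must be in [0, 1]")
  stopifnot(n_participants >= 1, length(age_range) == 2)
  if (age_range[1] < 20 || age_range[2] > 84 || age_range[1] > age_range[2])
    stop("age_range must lie within [20, 84]")
  if (any(abs(target_rank_correlations) >= 1))
    stop("infeasible calibration: |target rho| must be < 1")
  for (nm in names(trends))
    if (!is.na(trends[[nm]]$residual_sd) && trends[[nm]]$residual_sd <= 0)
      stop("residual_sd must be > 0 for ", nm)
  if (phenoage_residual_sd <= 0) stop("phenoage_residual_sd must be > 0")
  structure(list(n_participants = as.integer(n_participants),
                 age_range = as.integer(age_range),
                 male_fraction = male_fraction, trends = trends,
                 target_rank_correlations = target_rank_correlations,
                 phenoage_residual_sd = phenoage_residual_sd,
                 phenoage_covariate_share = phenoage_covariate_share,
                 mode = mode,
                 planted_sigma = planted_sigma,
                 n_85plus = as.integer(n_85plus), seed = as.integer(seed)),
            class = "CohortSimParams")
}

# --- slope calibration -------------------------------------------------------

# Population Spearman of (age, k*age + e), e ~ N(0,1), is a monotone function
# of the signal-to-noise ratio k = slope/residual_sd. We solve k by
# root-finding on a large fixed reference sample (its own internal seed, so
# calibration is deterministic and independent of the cohort seed). The
# Pearson identity rho = k*sd_age/sqrt(k^2*sd_age^2 + 1) brackets the root
# but underestimates slightly once ranks are taken; root-finding removes that
# attenuation. Results are memoised per (target, age range).
.calibCache <- new.env(parent = emptyenv())

calibrateSnr <- function(targetRho, ageRange, nCal = 100000L) {
  if (targetRho == 0) return(0)
  key <- paste(format(targetRho, digits = 12), ageRange[1], ageRange[2],
               sep = "|")
  if (!is.null(.calibCache[[key]])) return(.calibCache[[key]])
  ref <- withIsolatedSeed(20260101L, {
    list(age = sample(seq(ageRange[1], ageRange[2]), nCal, replace = TRUE),
         e = rnorm(nCal))
  })
  rAge <- rank(ref$age)
  realized <- function(k) cor(rAge, rank(k * ref$age + ref$e))
  sdAge <- sqrt((diff(range(ageRange)) + 1)^2 / 12)  # discrete-uniform approx
  k0 <- abs(targetRho) / (sdAge * sqrt(1 - targetRho^2))
  f <- function(k) realized(k) - abs(targetRho)
  hi <- max(4 * k0, 1e-3)
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 4
  k <- uniroot(f, lower = 0, upper = hi, tol = 1e-7)$root
  k <- sign(targetRho) * k
  .calibCache[[key]] <- k
  k
}

# --- generator ---------------------------------------------------------------

#' Simulate an NHANES-like cohort
#'
#' Draws integer ages uniformly over the configured range, sex as Bernoulli,
#' and each physiological variable as
#' `intercept_at_age20 + slope * (age - 20) + Normal(0, residual_sd)`, with
#' slopes calibrated (see [cohortSimParams()]) so the realized Spearman
#' correlation with age matches its target within sampling error. Step
#' counts are truncated at zero; diastolic draws violating
#' `systolic > diastolic` are redrawn. Latent phenotypic age is attached
#' (`phenoage_true`) together with a nine-biomarker panel constructed by
#' [invertBiomarkerForPhenoAge()] so that the Levine mapping reproduces
#' `phenoage_true` exactly (glucose and age are shared with the participant;
#' log-CRP is the free biomarker). Reproducible under a fixed seed.
#'
#' @param params a [cohortSimParams()] object.
#' @param phenoConfig the \linkS4class{PhenoAgeConfig} used for the panel
#'   inversion.
#' @return data.frame, one row per participant: `id`, `age`, `is_85plus`,
#'   `sex` (1 = male, 0 = female), the six physiological variables, the
#'   biomarker columns, `phenoage_true`, `vital_status` (`"unknown"` until
#'   [simulateMortality()]) and `followup_years`.
#' @export
simulateNhanesCohort <- function(params = cohortSimParams(),
                                 phenoConfig = levinePhenoAgeConfig()) {
  stopifnot(inherits(params, "CohortSimParams"))
  vars <- names(params$trends)
  slopes <- vapply(vars, function(nm) {
    tr <- params$trends[[nm]]
    if (!is.na(tr$slope_per_year)) return(tr$slope_per_year)
    target <- params$target_rank_correlations[[nm]]
    if (is.null(target))
      stop("no slope and no target correlation for ", nm)
    calibrateSnr(target, params$age_range) * tr$residual_sd
  }, numeric(1))

  # one block of participants at the given ages, drawn from the current RNG
  genBlock <- function(age, is85) {
    n <- length(age)
    sex <- rbinom(n, 1, params$male_fraction)
    tbl <- data.frame(age = age, is_85plus = is85, sex = sex)
    for (nm in vars) {
      tr <- params$trends[[nm]]
      tbl[[nm]] <- tr$intercept_at_age20 + slopes[[nm]] * (age - 20) +
        rnorm(n, 0, tr$residual_sd)
    }
    tbl$avg_daily_steps <- pmax(tbl$avg_daily_steps, 0)
    tbl$glucose <- pmax(tbl$glucose, 0.1)
    bad <- which(tbl$diastolic_bp >= tbl$systolic_bp)
    tries <- 0L
    while (length(bad) && tries < 50L) {
      tr <- params$trends$diastolic_bp
      tbl$diastolic_bp[bad] <- tr$intercept_at_age20 +
        slopes[["diastolic_bp"]] * (age[bad] - 20) +
        rnorm(length(bad), 0, tr$residual_sd)
      bad <- bad[tbl$diastolic_bp[bad] >= tbl$systolic_bp[bad]]
      tries <- tries + 1L
    }
    if (length(bad))
      tbl$diastolic_bp[bad] <- tbl$systolic_bp[bad] - 5

    tbl$phenoage_true <- if (params$mode == "age_anchored") {
      share <- params$phenoage_covariate_share
      dev <- if (share > 0) {
        # deviation of each participant's physiology from their age trend,
        # combined along the published-coefficient direction
        devRaw <- 0
        w <- c(glucose = 3.348, systolic_bp = 0.3988,
               avg_daily_steps = -0.0004715)
        for (nm in names(w)) {
          tr <- params$trends[[nm]]
          expected <- tr$intercept_at_age20 + slopes[[nm]] * (age - 20)
          devRaw <- devRaw + w[[nm]] * (tbl[[nm]] - expected)
        }
        devRaw / sd(devRaw)
      } else 0
      tbl$age + sqrt(share) * params$phenoage_residual_sd * dev +
        rnorm(n, 0, sqrt(1 - share) * params$phenoage_residual_sd)
    } else {
      -18.5 + 1.972 * tbl$sex + 3.348 * tbl$glucose -
        0.0004715 * tbl$avg_daily_steps + 0.3988 * tbl$systolic_bp +
        rnorm(n, 0, params$planted_sigma)
    }
    panel <- invertBiomarkerForPhenoAge(
      tbl$phenoage_true,
      panelDefaults = defaultBiomarkerPanel(age = tbl$age,
                                            glucose = tbl$glucose),
      config = phenoConfig)
    for (nm in setdiff(phenoAgeBiomarkers(), c("glucose", "age")))
      tbl[[nm]] <- panel[[nm]]
    tbl$vital_status <- "unknown"
    tbl$followup_years <- NA_real_
    tbl
  }

  main <- withIsolatedSeed(params$seed, {
    ages <- sample(seq(params$age_range[1], params$age_range[2]),
                   params$n_participants, replace = TRUE)
    genBlock(ages, rep(FALSE, params$n_participants))
  })
  out <- main
  if (params$n_85plus > 0) {
    # the 85+ block comes from a derived substream, so the base cohort
    # realization is invariant to n_85plus
    block85 <- withIsolatedSeed(
      deriveSeed(params$seed, "misc"),
      genBlock(rep(85L, params$n_85plus), rep(TRUE, params$n_85plus)))
    out <- rbind(out, block85)
  }
  out <- cbind(id = sprintf("P%05d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Attach simulated vital status via a Gompertz-type hazard
#'
#' Each participant dies during follow-up with probability
#' \eqn{1 - \exp(-T h_0 e^{b(phenoage\_true - 50) + g(glucose - 5)})}; flags
#' are drawn independently. The optional glucose term (`glucoseLogHR`,
#' default 0) plants mortality signal that the phenotypic-age target does
#' not carry, for ablation-tradeoff studies. `h0 = 0` yields an all-alive
#' cohort; negative `h0` or `b` is rejected.
#'
#' @param cohort data.frame with `phenoage_true` (and `glucose` if
#'   `glucoseLogHR != 0`).
#' @param h0 baseline hazard per year at phenotypic age 50 (default 0.0025,
#'   giving roughly one death per ten participants over a 10-year
#'   follow-up of a 20-84 cohort).
#' @param b log-hazard slope per year of phenotypic age (default 0.09, the
#'   Gompertz rate of the phenotypic-age mortality model, ~0.0077/month).
#' @param followupYears follow-up horizon (default 10).
#' @param glucoseLogHR log-hazard per mmol/L of glucose above 5.
#' @param seed RNG seed.
#' @return the cohort with `vital_status` set to `"alive"`/`"deceased"` and
#'   `followup_years` filled; counts reported via a message.
#' @export
simulateMortality <- function(cohort, h0 = 0.0025, b = 0.09,
                              followupYears = 10, glucoseLogHR = 0,
                              seed = 1L) {
  stopIfMissingCols(cohort, "phenoage_true", "cohort")
  if (h0 < 0) stop("h0 must be >= 0")
  if (b < 0) stop("b must be >= 0")
  if (followupYears <= 0) stop("followupYears must be > 0")
  lp <- b * (cohort$phenoage_true - 50)
  if (glucoseLogHR != 0) {
    stopIfMissingCols(cohort, "glucose", "cohort")
    lp <- lp + glucoseLogHR * (cohort$glucose - 5)
  }
  H <- followupYears * h0 * exp(lp)
  p <- -expm1(-H)
  dead <- withIsolatedSeed(seed, runif(nrow(cohort)) < p)
  cohort$vital_status <- ifelse(dead, "deceased", "alive")
  cohort$followup_years <- followupYears
  message(sprintf("simulateMortality: %d alive, %d deceased over %g years",
                  sum(!dead), sum(dead), followupYears))
  cohort
}
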