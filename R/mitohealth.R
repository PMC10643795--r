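# Four-group validation cohort (young; trained / normal / impaired older
# adults) and the plasma metabolite matrix with copula-planted signal.

defaultGroupProfiles <- function() {
  # means/SDs chosen so step counts order trained > normal > impaired and
  # glucose / systolic BP order impaired > normal >= trained, which makes the
  # scored deltaAge ordering trained < normal < impaired emerge downstream.
  list(
    young    = list(age = c(20, 30), steps = c(11000, 3000),
                    glucose = c(4.8, 0.4), systolic_bp = c(115, 8)),
    trained  = list(age = c(65, 80), steps = c(13000, 3000),
                    glucose = c(5.2, 0.5), systolic_bp = c(125, 10)),
    normal   = list(age = c(65, 80), steps = c(8000, 2500),
                    glucose = c(5.6, 0.6), systolic_bp = c(135, 10)),
    impaired = list(age = c(65, 80), steps = c(4000, 1500),
                    glucose = c(6.5, 0.8), systolic_bp = c(145, 12))
  )
}

#' Parameters for the four-group validation cohort simulator
#'
#' @param group_sizes named integer vector over
#'   young/trained/normal/impaired; the defaults 17/19/17/6 sum to 59.
#' @param profiles per-group age ranges and (mean, sd) for steps, glucose
#'   and systolic BP; see `defaultGroupProfiles()`.
#' @param metabolomics_subset named integer quotas of samples with plasma
#'   metabolomics per group (defaults 12/17/16/3, summing to 48; the 36
#'   non-young samples form the "older adults" screen subset).
#' @param male_fraction proportion of males per group.
#' @param seed integer RNG seed.
#' @return validated parameter list of class `MitoHealthSimParams`.
#' @export
mitoHealthSimParams <- function(group_sizes = c(young = 17L, trained = 19L,
                                                normal = 17L, impaired = 6L),
                                profiles = defaultGroupProfiles(),
                                metabolomics_subset = c(young = 12L,
                                                        trained = 17L,
                                                        normal = 16L,
                                                        impaired = 3L),
                                male_fraction = 0.55, seed = 1L) {
  lv <- healthGroupLevels()
  if (!setequal(names(group_sizes), lv))
    stop("group_sizes must be named over: ", paste(lv, collapse = ", "))
  if (any(group_sizes < 1)) stop("every group must have size >= 1")
  if (any(metabolomics_subset > group_sizes[names(metabolomics_subset)]))
    stop("metabolomics subset cannot exceed group size")
  structure(list(group_sizes = group_sizes[lv], profiles = profiles,
                 metabolomics_subset = metabolomics_subset[lv],
                 male_fraction = male_fraction, seed = as.integer(seed)),
            class = "MitoHealthSimParams")
}

#' Simulate the four-group validation cohort
#'
#' Generates young (ages 20-30) and trained/normal/impaired older adults
#' (ages 65-80) with group-specific step counts, fasting glucose and
#' systolic blood pressure, plus a metabolomics-subset flag drawn per the
#' configured quotas.
#'
#' @param params a [mitoHealthSimParams()] object.
#' @return data.frame with `id`, `group` (ordered factor
#'   young < trained < normal < impaired), `age`, `sex`, `glucose`,
#'   `avg_daily_steps`, `systolic_bp`, `in_metabolome`.
#' @export
simulateMitoHealthCohort <- function(params = mitoHealthSimParams()) {
  stopifnot(inherits(params, "MitoHealthSimParams"))
  withIsolatedSeed(params$seed, {
    rows <- lapply(healthGroupLevels(), function(g) {
      n <- params$group_sizes[[g]]
      pr <- params$profiles[[g]]
      data.frame(group = g,
                 age = sample(seq(pr$age[1], pr$age[2]), n, replace = TRUE),
                 sex = rbinom(n, 1, params$male_fraction),
                 glucose = pmax(rnorm(n, pr$glucose[1], pr$glucose[2]), 0.5),
                 avg_daily_steps = pmax(rnorm(n, pr$steps[1], pr$steps[2]), 0),
                 systolic_bp = rnorm(n, pr$systolic_bp[1], pr$systolic_bp[2]))
    })
    tbl <- do.call(rbind, rows)
    tbl$id <- sprintf("MH%03d", seq_len(nrow(tbl)))
    tbl$group <- factor(tbl$group, levels = healthGroupLevels(),
                        ordered = TRUE)
    tbl$in_metabolome <- FALSE
    for (g in healthGroupLevels()) {
      idx <- which(tbl$group == g)
      take <- sample(idx, params$metabolomics_subset[[g]])
      tbl$in_metabolome[take] <- TRUE
    }
    tbl[, c("id", "group", "age", "sex", "glucose", "avg_daily_steps",
            "systolic_bp", "in_metabolome")]
  })
}

requiredMetaboliteNames <- function() {
  c("malate", "citrate", "isocitrate", "ribose 5-phosphate", "glucose",
    "nicotinamide")
}

#' Parameters for the plasma metabolome simulator
#'
#' @param n_metabolites number of metabolites (default 113).
#' @param names metabolite names; must include malate, citrate, isocitrate,
#'   ribose 5-phosphate, glucose and nicotinamide. Defaults to those six
#'   plus synthetic placeholders (`met_007` ...).
#' @param planted_signal named numeric in (-1, 1): target Spearman rho of
#'   each planted metabolite with deltaAge. Defaults plant the four reported
#'   deltaAge correlates (citrate -0.61, isocitrate -0.47, malate -0.35,
#'   glucose 0.36) plus ribose 5-phosphate (-0.35) and nicotinamide (-0.30).
#' @param planted_group_signal named numeric in (-1, 1): optional additional
#'   target Spearman rho with the ordinal health-group codes, so a
#'   metabolite can carry signal in both screens; defaults plant the three
#'   intersection metabolites (malate/ribose 5-phosphate negative, glucose
#'   positive).
#' @param meanlog,sdlog log-normal abundance location and scale.
#' @param seed integer RNG seed.
#' @return validated parameter list of class `MetabolomeSimParams`.
#' @export
metabolomeSimParams <- function(n_metabolites = 113L, names = NULL,
                                planted_signal = c(citrate = -0.61,
                                                   isocitrate = -0.47,
                                                   malate = -0.35,
                                                   "ribose 5-phosphate" = -0.35,
                                                   glucose = 0.36,
                                                   nicotinamide = -0.30),
                                planted_group_signal = c(malate = -0.40,
                                                         "ribose 5-phosphate" = -0.45,
                                                         glucose = 0.50),
                                meanlog = 10, sdlog = 0.6, seed = 1L) {
  if (is.null(names)) {
    req <- requiredMetaboliteNames()
    extra <- sprintf("met_%03d", seq_len(max(0, n_metabolites - length(req))) +
                       length(req))
    names <- c(req, extra)
  }
  if (length(names) != n_metabolites)
    stop("names must have length n_metabolites")
  if (anyDuplicated(names)) stop("metabolite names must be unique")
  missingReq <- setdiff(requiredMetaboliteNames(), names)
  if (length(missingReq))
    stop("names must include: ", paste(missingReq, collapse = ", "))
  if (any(abs(planted_signal) >= 1) || any(abs(planted_group_signal) >= 1))
    stop("planted rho values must lie in (-1, 1)")
  unknown <- setdiff(c(names(planted_signal), names(planted_group_signal)),
                     names)
  if (length(unknown))
    stop("planted metabolite(s) not in names: ",
         paste(unknown, collapse = ", "))
  structure(list(n_metabolites = as.integer(n_metabolites), names = names,
                 planted_signal = planted_signal,
                 planted_group_signal = planted_group_signal,
                 meanlog = meanlog, sdlog = sdlog, seed = as.integer(seed)),
            class = "MetabolomeSimParams")
}

# Latent Gaussian loadings (a, b) so that cor(z, zDelta) = r1 and
# cor(z, zGroup) = r2 given cor(zDelta, zGroup) = cc; residual variance must
# stay positive.
copulaLoadings <- function(r1, r2, cc) {
  den <- 1 - cc^2
  a <- (r1 - r2 * cc) / den
  b <- (r2 - r1 * cc) / den
  resVar <- 1 - (a^2 + b^2 + 2 * a * b * cc)
  if (resVar <= 0)
    stop("infeasible planted signal: joint targets exceed unit variance")
  list(a = a, b = b, sd = sqrt(resVar))
}

#' Simulate a plasma metabolite matrix with planted aging signal
#'
#' For the metabolomics subset of a scored cohort, builds normal scores of
#' the deltaAge ranks (and of the ordinal health-group codes), converts each
#' target Spearman rho to its latent Gaussian correlation via
#' \eqn{r = 2\sin(\pi\rho/6)}, mixes the latent scores accordingly, and
#' exponentiates into strictly positive log-normal abundances. Non-planted
#' metabolites are independent of deltaAge and group.
#'
#' @param scoredCohort data.frame with `id`, `group`, `sex`, `age`,
#'   `delta_age` and `in_metabolome` columns (see
#'   [simulateMitoHealthCohort()] and [physiAgeScore()]).
#' @param params a [metabolomeSimParams()] object.
#' @return a \linkS4class{MetaboliteExperiment}.
#' @export
simulateMetabolome <- function(scoredCohort, params = metabolomeSimParams()) {
  stopifnot(inherits(params, "MetabolomeSimParams"))
  stopIfMissingCols(scoredCohort, c("id", "group", "delta_age"),
                    "scored cohort")
  sub <- scoredCohort[scoredCohort$in_metabolome, , drop = FALSE]
  if (nrow(sub) == 0) stop("no samples flagged in_metabolome")
  if (nrow(sub) > nrow(scoredCohort))
    stop("metabolomics subset larger than cohort")
  n <- nrow(sub)
  zDelta <- qnorm((rank(sub$delta_age) - 0.5) / n)
  zGroup <- qnorm((rank(healthGroupCodes(sub$group)) - 0.5) / n)
  zDelta <- zDelta / sd(zDelta)
  zGroup <- zGroup / sd(zGroup)
  cc <- cor(zDelta, zGroup)
  withIsolatedSeed(params$seed, {
    mat <- matrix(NA_real_, nrow = params$n_metabolites, ncol = n,
                  dimnames = list(params$names, sub$id))
    for (i in seq_len(params$n_metabolites)) {
      nm <- params$names[i]
      rho1 <- if (nm %in% names(params$planted_signal))
        params$planted_signal[[nm]] else 0
      rho2 <- if (nm %in% names(params$planted_group_signal))
        params$planted_group_signal[[nm]] else 0
      if (rho1 == 0 && rho2 == 0) {
        z <- rnorm(n)
      } else {
        ld <- copulaLoadings(2 * sin(pi * rho1 / 6), 2 * sin(pi * rho2 / 6),
                             cc)
        z <- ld$a * zDelta + ld$b * zGroup + rnorm(n, 0, ld$sd)
      }
      mat[i, ] <- exp(params$meanlog + params$sdlog * z)
    }
    cd <- DataFrame(sample_id = sub$id, group = sub$group, sex = sub$sex,
                    age = sub$age, delta_age = sub$delta_age,
                    row.names = sub$id)
    se <- SummarizedExperiment(assays = list(abundance = mat), colData = cd)
    new("MetaboliteExperiment", se)
  })
}
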