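test_that("cohort generation is deterministic under a fixed seed", {
  p <- cohortSimParams(n_participants = 400, seed = 42L)
  a <- simulateNhanesCohort(p)
  b <- simulateNhanesCohort(p)
  expect_identical(a, b)
  c2 <- simulateNhanesCohort(cohortSimParams(n_participants = 400, seed = 43L))
  expect_false(identical(a$glucose, c2$glucose))
})

test_that("marginal age trends hit their Spearman targets at n = 3342", {
  co <- canonicalCohort()
  co <- co[!co$is_85plus, ]
  se2 <- 2 / sqrt(nrow(co) - 3)
  targets <- c(glucose = 0.400, systolic_bp = 0.474, resting_hr = -0.224,
               diastolic_bp = -0.151, bmi = 0.075, avg_daily_steps = 0.029)
  for (v in names(targets)) {
    rho <- cor(co[[v]], co$age, method = "spearman")
    expect_lt(abs(rho - targets[[v]]), se2, label = paste("rho for", v))
  }
})

test_that("an explicit zero slope removes the planted age trend", {
  tr <- defaultTrendSpecs()
  tr$bmi$slope_per_year <- 0
  co <- simulateNhanesCohort(cohortSimParams(trends = tr, seed = 3L))
  expect_lt(abs(cor(co$bmi, co$age, method = "spearman")),
            2 / sqrt(nrow(co) - 3))
})

test_that("calibration contract holds across 50 seeds", {
  # realized rho within 2/sqrt(n-3) of target; a 95% property checked at 50
  # draws, so we require >= 45/50 per variable (99% lower binomial bound)
  targets <- defaultTargetRhos()
  hits <- matrix(0L, nrow = 50, ncol = length(targets),
                 dimnames = list(NULL, names(targets)))
  for (s in 1:50) {
    co <- simulateNhanesCohort(cohortSimParams(seed = 1000L + s))
    se2 <- 2 / sqrt(nrow(co) - 3)
    for (v in names(targets))
      hits[s, v] <- abs(cor(co[[v]], co$age, method = "spearman") -
                          targets[[v]]) < se2
  }
  expect_true(all(colSums(hits) >= 45),
              label = paste("per-variable hits:",
                            paste(colSums(hits), collapse = " ")))
})

test_that("infeasible calibration targets are rejected", {
  expect_error(cohortSimParams(target_rank_correlations = c(glucose = 1)),
               "infeasible")
  expect_error(cohortSimParams(age_range = c(15, 84)), "age_range")
})

test_that("generated tables satisfy the participant invariants", {
  co <- canonicalCohort()
  expect_true(all(co$avg_daily_steps >= 0))
  expect_true(all(co$glucose > 0))
  expect_true(all(co$systolic_bp > co$diastolic_bp))
  expect_true(all(co$sex %in% c(0, 1)))
  # the latent phenotypic age is reproduced exactly by the attached panel
  expect_equal(computePhenoAge(co, levinePhenoAgeConfig()), co$phenoage_true,
               tolerance = 1e-9)
})

test_that("mortality simulation respects its hazard structure", {
  co <- simulateNhanesCohort(cohortSimParams(n_participants = 2000, seed = 9L))
  # zero baseline hazard: everyone alive
  allAlive <- suppressMessages(simulateMortality(co, h0 = 0, seed = 10L))
  expect_true(all(allAlive$vital_status == "alive"))
  # b = 0: death probability identical for all, so deaths are independent of
  # phenoage and the overall fraction matches 1 - exp(-T * h0)
  flat <- suppressMessages(simulateMortality(co, h0 = 0.01, b = 0,
                                             seed = 11L))
  frac <- mean(flat$vital_status == "deceased")
  expect_lt(abs(frac - (1 - exp(-10 * 0.01))), 0.02)
  tt <- t.test(phenoage_true ~ vital_status, data = flat)
  expect_gt(tt$p.value, 0.01)
  expect_error(simulateMortality(co, h0 = -1), "h0")
  expect_error(simulateMortality(co, b = -1), "b must")
})

test_that("deceased participants have higher latent phenotypic age", {
  co <- canonicalCohort()
  tt <- t.test(co$phenoage_true[co$vital_status == "deceased"],
               co$phenoage_true[co$vital_status == "alive"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("four-group cohort has the configured sizes and orderings", {
  mh <- simulateMitoHealthCohort(mitoHealthSimParams(seed = 5L))
  expect_equal(nrow(mh), 59L)
  expect_equal(as.vector(table(mh$group)), c(17L, 19L, 17L, 6L))
  m <- function(v, g) mean(mh[[v]][mh$group == g])
  expect_gt(m("avg_daily_steps", "trained"), m("avg_daily_steps", "normal"))
  expect_gt(m("avg_daily_steps", "normal"), m("avg_daily_steps", "impaired"))
  expect_gt(m("glucose", "impaired"), m("glucose", "normal"))
  expect_gte(m("glucose", "normal"), m("glucose", "trained"))
  expect_gt(m("systolic_bp", "impaired"), m("systolic_bp", "normal"))
  expect_equal(as.vector(table(mh$group[mh$in_metabolome])),
               c(12L, 17L, 16L, 3L))
})

test_that("minimal group sizes still produce a valid table", {
  p <- mitoHealthSimParams(group_sizes = c(young = 1L, trained = 1L,
                                           normal = 1L, impaired = 1L),
                           metabolomics_subset = c(young = 1L, trained = 1L,
                                                   normal = 1L,
                                                   impaired = 1L),
                           seed = 2L)
  mh <- simulateMitoHealthCohort(p)
  expect_equal(nrow(mh), 4L)
  expect_true(all(!is.na(mh$glucose)))
  expect_error(mitoHealthSimParams(group_sizes = c(young = 0L, trained = 1L,
                                                   normal = 1L,
                                                   impaired = 1L)),
               "size")
})

test_that("scored groups order trained below impaired on median deltaAge", {
  sc <- canonicalMitoHealth()
  med <- tapply(sc$delta_age, sc$group, median)
  expect_lt(med[["trained"]], med[["normal"]])
  expect_lt(med[["normal"]], med[["impaired"]])
})

test_that("metabolite matrix is positive, deterministic, and planted", {
  me <- canonicalMetabolome()
  expect_equal(dim(me), c(113L, 48L))
  expect_true(all(SummarizedExperiment::assay(me, "abundance") > 0))
  me2 <- simulateMetabolome(canonicalMitoHealth(), metabolomeSimParams(seed = 6L))
  expect_identical(SummarizedExperiment::assay(me, "abundance"),
                   SummarizedExperiment::assay(me2, "abundance"))
  # citrate is planted against deltaAge only; its realized rho among the 36
  # older adults sits inside the n = 36 sampling interval around -0.61
  older <- as.character(SummarizedExperiment::colData(me)$group) != "young"
  rho <- cor(SummarizedExperiment::assay(me, "abundance")["citrate", older],
             SummarizedExperiment::colData(me)$delta_age[older],
             method = "spearman")
  expect_lt(abs(rho - (-0.61)), 0.25)
})

test_that("copula planting converges to its target with sample size", {
  mkCohort <- function(n, seed) {
    set.seed(seed)
    data.frame(id = sprintf("X%04d", 1:n),
               group = factor(rep(c("trained", "normal"), length.out = n),
                              levels = c("young", "trained", "normal",
                                         "impaired"), ordered = TRUE),
               sex = rep(0:1, length.out = n), age = rep(70, n),
               delta_age = rnorm(n), in_metabolome = TRUE)
  }
  params <- metabolomeSimParams(
    n_metabolites = 6, planted_signal = c(citrate = -0.61),
    planted_group_signal = numeric(0), seed = 8L)
  rhoAt <- function(n) {
    me <- simulateMetabolome(mkCohort(n, n), params)
    cor(SummarizedExperiment::assay(me)["citrate", ],
        SummarizedExperiment::colData(me)$delta_age, method = "spearman")
  }
  expect_lt(abs(rhoAt(1000) - (-0.61)), 0.08)
  expect_lt(abs(rhoAt(36) - (-0.61)), 0.25)
})

test_that("metabolome parameter validation catches bad inputs", {
  expect_error(metabolomeSimParams(n_metabolites = 5), "length")
  expect_error(metabolomeSimParams(planted_signal = c(citrate = 1.2)),
               "rho")
  expect_error(metabolomeSimParams(planted_signal = c(unknown_met = 0.5)),
               "unknown_met")
})
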