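# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# A synthetic phenotypic-age configuration with hand-picked constants, so
# self-contained tests never depend on the shipped transcription.
syntheticPhenoConfig <- function() {
  phenoAgeConfig(
    intercept = -20,
    weights = c(albumin = -0.03, creatinine = 0.01, glucose = 0.2,
                crp_ln = 0.1, lymphocyte_pct = -0.012, mcv = 0.027,
                rdw = 0.33, alp = 0.002, wbc = 0.055, age = 0.08),
    gamma = 0.008, horizonMonths = 120,
    outerA = 140, outerB = -0.005, outerC = 0.09)
}

# Canonical demonstration cohort: default NHANES-like generator at n = 3342
# plus 81 participants at the 85+ code, with simulated 10-year mortality.
canonicalCohort <- function() {
  cached("cohort", {
    co <- suppressMessages(
      simulateNhanesCohort(cohortSimParams(seed = 1L, n_85plus = 81L)))
    suppressMessages(simulateMortality(co, seed = 101L))
  })
}

# Full pipeline run on the canonical cohort (split seed 1).
canonicalRun <- function() {
  cached("run", suppressMessages(runPipeline(canonicalCohort(), seed = 1L)))
}

# QC'd + phenoage-annotated table ready for split/fit, reused by the
# validation tests.
canonicalPrepared <- function() {
  cached("prepared", {
    qc <- qcFilter(canonicalCohort())
    tbl <- suppressMessages(removeStepOutliers(qc$retained))
    tbl$phenoage <- computePhenoAge(tbl, levinePhenoAgeConfig())
    tbl
  })
}

# Scored four-group cohort + metabolite matrix under the canonical NF table.
canonicalMitoHealth <- function() {
  cached("mitohealth", {
    mh <- simulateMitoHealthCohort(mitoHealthSimParams(seed = 5L))
    suppressMessages(
      physiAgeScore(publishedPhysiAgeModel(), canonicalRun()$nf, mh))
  })
}

canonicalMetabolome <- function() {
  cached("metabolome",
         simulateMetabolome(canonicalMitoHealth(), metabolomeSimParams(seed = 6L)))
}

# Build a small MetaboliteExperiment directly from an abundance matrix
# (rows = metabolites) and per-sample metadata.
makeME <- function(mat, group, delta_age = NULL, sex = NULL) {
  ids <- sprintf("S%03d", seq_len(ncol(mat)))
  colnames(mat) <- ids
  cd <- S4Vectors::DataFrame(
    sample_id = ids,
    group = factor(group, levels = c("young", "trained", "normal", "impaired"),
                   ordered = TRUE),
    row.names = ids)
  if (!is.null(delta_age)) cd$delta_age <- delta_age
  if (!is.null(sex)) cd$sex <- sex
  methods::new("MetaboliteExperiment",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(abundance = mat), colData = cd))
}
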