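# End-to-end pipeline driver: qc -> split -> phenotypic age -> fit -> NF ->
# score -> validation (-> metabolite screens when a matrix is supplied).

#' Run the full clock-building pipeline
#'
#' Stage order: QC filter, step-outlier fences, phenotypic-age computation
#' from the biomarker panel, sex-stratified split, OLS fit, normalization
#' table, test-set scoring, mortality contrast, 85+ scoring when held rows
#' exist, and the metabolite screens when a
#' \linkS4class{MetaboliteExperiment} is supplied. All randomness flows
#' from the single top-level `seed`, expanded into named per-stage streams,
#' so stage-level reruns match the full run.
#'
#' @param cohort raw participant data.frame (e.g. from
#'   [simulateNhanesCohort()] or [readCohort()]); must carry the biomarker
#'   panel columns unless `response` is already present.
#' @param metabolome optional \linkS4class{MetaboliteExperiment}.
#' @param seed top-level integer seed.
#' @param trainFraction training proportion.
#' @param fenceK Tukey fence multiplier for step outliers.
#' @param phenoConfig \linkS4class{PhenoAgeConfig} used to compute the
#'   phenotypic-age response.
#' @param outdir optional directory; when given, the model, NF table and
#'   scored test set are written there as text artifacts.
#' @return list of class `PhysiAgeRun`: `model`, `nf`, `train`, `test`
#'   (scored), `qc_report`, `rmse_train`, `rmse_test`, `rho_train`,
#'   `rho_test`, `mortality`, `contrast_85plus`, `screens` (or NULL), and
#'   `seeds` used per stage.
#' @export
runPipeline <- function(cohort, metabolome = NULL, seed = 1L,
                        trainFraction = 0.8, fenceK = 1.5,
                        phenoConfig = levinePhenoAgeConfig(),
                        outdir = NULL) {
  seeds <- c(split = deriveSeed(seed, "split"))
  qc <- qcFilter(cohort)
  tbl <- removeStepOutliers(qc$retained, k = fenceK)
  if (!"phenoage" %in% names(tbl))
    tbl$phenoage <- computePhenoAge(tbl, phenoConfig)
  sp <- splitTrainTest(tbl, trainFraction, seeds[["split"]])
  model <- fitModel(sp$train)
  nf <- buildNormalization(sp$train, model)
  trainScored <- physiAgeScore(model, nf, sp$train)
  testScored <- physiAgeScore(model, nf, sp$test)
  mort <- if (all(c("alive", "deceased") %in% testScored$vital_status))
    mortalityContrast(testScored) else NULL
  c85 <- NULL
  if (nrow(qc$held_85plus) > 0 &&
      all(c("alive", "deceased") %in% qc$held_85plus$vital_status))
    c85 <- score85Plus(model, nf, qc$held_85plus)
  screens <- NULL
  if (!is.null(metabolome)) {
    dres <- correlateDelta(metabolome)
    gres <- correlateGroups(metabolome)
    screens <- list(delta = dres, group = gres,
                    signature = selectSignature(dres, gres))
  }
  run <- structure(list(
    model = model, nf = nf, train = trainScored, test = testScored,
    qc_report = qc$report, held_85plus = qc$held_85plus,
    rmse_train = rmse(trainScored$physiage, trainScored$age),
    rmse_test = rmse(testScored$physiage, testScored$age),
    rho_train = suppressWarnings(
      cor(trainScored$physiage, trainScored$age, method = "spearman")),
    rho_test = suppressWarnings(
      cor(testScored$physiage, testScored$age, method = "spearman")),
    mortality = mort, contrast_85plus = c85, screens = screens,
    seeds = seeds), class = "PhysiAgeRun")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writePhysiAgeModel(model, file.path(outdir, "model.yaml"))
    writeNormalizationTable(nf, file.path(outdir, "nf_table.csv"))
    writeCohort(testScored, file.path(outdir, "test_scored.csv"))
  }
  run
}

#' @export
print.PhysiAgeRun <- function(x, ...) {
  cat("PhysiAge pipeline run\n")
  cat(sprintf("  train n = %d, test n = %d\n", nrow(x$train), nrow(x$test)))
  cat(sprintf("  test: Spearman rho to age %.3f, RMSE %.2f years\n",
              x$rho_test, x$rmse_test))
  if (!is.null(x$mortality))
    cat(sprintf("  mortality deltaAge: alive %.2f vs deceased %.2f (p = %.4g)\n",
                x$mortality$mean_alive, x$mortality$mean_deceased,
                x$mortality$p))
  if (!is.null(x$screens))
    cat(sprintf("  metabolite screens: %d in deltaAge set, %d in group set, %d in intersection\n",
                sum(x$screens$signature$in_delta_set),
                sum(x$screens$signature$in_group_set),
                sum(x$screens$signature$in_intersection)))
  invisible(x)
}
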