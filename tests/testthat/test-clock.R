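toyRaw <- function() {
  data.frame(
    id = sprintf("T%02d", 1:10),
    age = c(25, 40, 55, 60, 70, 84, 85, 30, 45, 17),
    sex = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    glucose = c(5, 6, 0, 5.5, 6.2, 7, 5.8, 5.1, 4.9, 5),
    avg_daily_steps = c(8000, 9000, 7000, NA, 6000, 4000, 5000, 12000,
                        10000, 9000),
    systolic_bp = c(120, 130, 125, 135, 0, 150, 140, 118, 122, 115))
}

test_that("QC removes zero/missing rows, holds 85+, and reports counts", {
  res <- qcFilter(toyRaw())
  # planted violations: glucose 0, steps NA, systolic 0; age 85 held;
  # age 17 below range
  expect_equal(nrow(res$retained), 5L)
  expect_equal(nrow(res$held_85plus), 1L)
  expect_equal(res$held_85plus$id, "T07")
  rep <- setNames(res$report$count, res$report$reason)
  expect_equal(rep[["missing_value"]] + rep[["zero_entry"]], 3)
  expect_equal(rep[["age_85plus_held"]], 1)
  expect_equal(rep[["age_below_20"]], 1)
  expect_false("T03" %in% res$retained$id)  # glucose = 0
  expect_error(qcFilter(toyRaw()[, -2]), "age")
})

test_that("Tukey fences remove the implausible step counts", {
  tbl <- data.frame(avg_daily_steps = c(5000, 6000, 7000, 8000, 3e6))
  out <- suppressMessages(removeStepOutliers(tbl))
  expect_equal(out$avg_daily_steps, c(5000, 6000, 7000, 8000))
  # IQR = 0 keeps the common value
  same <- data.frame(avg_daily_steps = rep(7000, 6))
  expect_equal(nrow(suppressMessages(removeStepOutliers(same))), 6L)
  # very large fence multiplier removes nothing
  expect_equal(nrow(suppressMessages(removeStepOutliers(tbl, k = 1e6))), 5L)
  expect_warning(removeStepOutliers(tbl[1:3, , drop = FALSE]), "fewer than 4")
})

test_that("train/test split is stratified, deterministic and complementary", {
  co <- canonicalCohort()
  co <- co[!co$is_85plus, ]
  sp <- splitTrainTest(co, 0.8, seed = 1L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(co))
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  for (s in 0:1) {
    ns <- sum(co$sex == s)
    expect_equal(sum(sp$train$sex == s), floor(0.8 * ns + 0.5))
  }
  sp2 <- splitTrainTest(co, 0.8, seed = 1L)
  expect_identical(sp$train$id, sp2$train$id)
  # complementary fractions swap the partition sizes exactly
  sp02 <- splitTrainTest(co, 0.2, seed = 7L)
  expect_equal(nrow(sp02$train), nrow(sp$test))
  expect_error(splitTrainTest(co, 1.2), "trainFraction")
})

test_that("noise-free data from the published coefficients is interpolated", {
  set.seed(4)
  train <- data.frame(sex = c(0, 1, 0, 1, 0, 1),
                      glucose = c(4, 5, 6, 7, 5.5, 6.5),
                      avg_daily_steps = c(4000, 8000, 12000, 6000, 10000,
                                          14000),
                      systolic_bp = c(118, 121, 133, 137, 124, 139))
  train$phenoage <- rawPredict(publishedPhysiAgeModel(), train)
  fit <- suppressWarnings(fitModel(train))  # "essentially perfect fit"
  expect_equal(fit@intercept, -18.5, tolerance = 1e-8)
  expect_equal(unname(fit@coefficients),
               c(1.972, 3.348, -0.0004715, 0.3988), tolerance = 1e-8)
})

test_that("single-sex training data raises an explicit singularity error", {
  train <- data.frame(sex = 0, glucose = 5 + 1:10 / 10,
                      avg_daily_steps = 8000 + 1:10 * 100,
                      systolic_bp = 120 + 1:10, phenoage = 50 + 1:10)
  expect_error(fitModel(train), "inestimable|singular")
})

test_that("raw prediction evaluates the printed equation exactly", {
  m <- publishedPhysiAgeModel()
  expect_equal(rawPredict(m, sex = 0, glucose = 6, avg_daily_steps = 5000,
                          systolic_bp = 130), 51.0745, tolerance = 1e-10)
  d <- rawPredict(m, sex = 1, glucose = 6, avg_daily_steps = 5000,
                  systolic_bp = 130) -
       rawPredict(m, sex = 0, glucose = 6, avg_daily_steps = 5000,
                  systolic_bp = 130)
  expect_equal(d, 1.972, tolerance = 1e-12)
  zero <- methods::new("PhysiAgeModel", intercept = 0,
                       coefficients = numeric(0))
  expect_equal(rawPredict(zero, data.frame(x = 1)), 0)
  expect_error(rawPredict(m, sex = 0, glucose = 6, avg_daily_steps = -5,
                          systolic_bp = 130), "step")
  expect_error(rawPredict(m, sex = 0, glucose = 0, avg_daily_steps = 5000,
                          systolic_bp = 130), "glucose")
})

test_that("normalization is the per-age median with flagged interpolation", {
  # identity-on-glucose model lets us plant raw predictions directly
  m <- methods::new("PhysiAgeModel", intercept = 0,
                    coefficients = c(glucose = 1))
  train <- data.frame(age = c(50, 50, 50), glucose = c(40, 50, 60))
  nf <- buildNormalization(train, m)
  expect_equal(unname(nfValues(nf)[["50"]]), 50)
  train2 <- data.frame(age = c(40, 40, 42, 42), glucose = c(30, 34, 40, 44))
  nf2 <- buildNormalization(train2, m)
  expect_equal(unname(nfValues(nf2)[["41"]]), (32 + 42) / 2)
  expect_true(nfInterpolated(nf2)[["41"]])
  expect_false(any(nfInterpolated(nf2)[c("40", "42")]))
  expect_error(buildNormalization(train[0, ], m), "empty")
})

test_that("training medians re-anchor exactly: median PhysiAge equals age", {
  run <- canonicalRun()
  med <- tapply(run$train$physiage, run$train$age, median)
  ages <- as.numeric(names(med))
  populated <- !nfInterpolated(run$nf)[as.character(ages)]
  expect_equal(as.numeric(med[populated]), ages[populated],
               tolerance = 1e-12)
  # equivalently, median deltaAge is 0 within every populated age
  medD <- tapply(run$train$delta_age, run$train$age, median)
  expect_equal(max(abs(medD[populated])), 0, tolerance = 1e-12)
})

test_that("scoring is the normalized prediction and deltaAge its excess", {
  m <- publishedPhysiAgeModel()
  nf <- methods::new("NormalizationTable", age = 59:61,
                     nf = c(49, 49.9587, 51), interpolated = rep(FALSE, 3))
  p <- data.frame(age = 60, sex = 0, glucose = 6, avg_daily_steps = 5000,
                  systolic_bp = 130)
  sc <- physiAgeScore(m, nf, p)
  expect_equal(sc$physiage, 51.0745 / 49.9587 * 60, tolerance = 1e-9)
  expect_equal(sc$delta_age, sc$physiage - 60, tolerance = 1e-12)
  # raw prediction equal to NF(age) is the fixed point: PhysiAge = age
  pfix <- p
  nfFix <- methods::new("NormalizationTable", age = 60L,
                        nf = 51.0745, interpolated = FALSE)
  scFix <- physiAgeScore(m, nfFix, pfix)
  expect_equal(scFix$physiage, 60, tolerance = 1e-9)
  expect_equal(scFix$delta_age, 0, tolerance = 1e-9)
})

test_that("the 12k-steps what-if reproduces the printed 57.38 score", {
  m <- publishedPhysiAgeModel()
  raw5k <- rawPredict(m, sex = 0, glucose = 6, avg_daily_steps = 5000,
                      systolic_bp = 130)
  nf60 <- raw5k * 60 / 61.34  # calibrated so the 5k profile scores 61.34
  expect_equal(nf60, 49.96, tolerance = 0.01)
  nf <- methods::new("NormalizationTable", age = 60L, nf = nf60,
                     interpolated = FALSE)
  sc <- physiAgeScore(m, nf, data.frame(age = 60, sex = 0, glucose = 6,
                                        avg_daily_steps = 12000,
                                        systolic_bp = 130))
  expect_equal(sc$physiage, 57.38, tolerance = 0.01)
})

test_that("85+ rows score at age 85 with the NF clamped to the table top", {
  m <- publishedPhysiAgeModel()
  nf <- methods::new("NormalizationTable", age = 20:84,
                     nf = seq(40, 55, length.out = 65),
                     interpolated = rep(FALSE, 65))
  p <- data.frame(age = 92, is_85plus = TRUE, sex = 1, glucose = 6,
                  avg_daily_steps = 4000, systolic_bp = 150)
  sc <- suppressMessages(physiAgeScore(m, nf, p))
  raw <- rawPredict(m, p)
  expect_equal(sc$physiage, raw / 55 * 85, tolerance = 1e-9)
  pLow <- data.frame(age = 19, sex = 1, glucose = 6, avg_daily_steps = 4000,
                     systolic_bp = 150)
  expect_error(physiAgeScore(m, nf, pLow), "clampable")
})

test_that("what-if sweeps match pointwise scoring and the printed grids", {
  run <- canonicalRun()
  prof <- data.frame(age = 60, sex = 0, glucose = 6, avg_daily_steps = 5000,
                     systolic_bp = 130)
  st <- whatIfSweep(prof, "steps", run$model, run$nf)
  expect_equal(nrow(st), 16L)
  expect_true(all(diff(st$physiage) < 0))  # negative steps coefficient
  gl <- whatIfSweep(prof, "glucose", run$model, run$nf)
  expect_equal(nrow(gl), 7L)
  expect_true(all(diff(gl$physiage) > 0))  # positive glucose coefficient
  one <- prof
  one$glucose <- 7
  expect_equal(gl$physiage[gl$value == 7],
               physiAgeScore(run$model, run$nf, one)$physiage)
  expect_error(whatIfSweep(prof, "glucose", run$model, run$nf,
                           grid = numeric(0)), "empty")
})

test_that("model and NF table serialize and reproduce identical scores", {
  run <- canonicalRun()
  mPath <- withr::local_tempfile(fileext = ".yaml")
  nfPath <- withr::local_tempfile(fileext = ".csv")
  writePhysiAgeModel(run$model, mPath)
  writeNormalizationTable(run$nf, nfPath)
  m2 <- readPhysiAgeModel(mPath)
  nf2 <- readNormalizationTable(nfPath)
  test <- canonicalRun()$test
  s1 <- physiAgeScore(run$model, run$nf, test)$physiage
  s2 <- physiAgeScore(m2, nf2, test)$physiage
  expect_equal(s1, s2, tolerance = 1e-12)
})
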