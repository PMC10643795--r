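# Readers and writers. CSV dialect is fixed: comma separator, "." decimal,
# UTF-8, one header row.

cohortRequiredCols <- function() {
  c("age", "sex", "glucose", "avg_daily_steps", "systolic_bp")
}

#' Read a participant cohort CSV
#'
#' Renames columns to the canonical names via `columnMap` (a named character
#' vector `canonical = file_column`) and applies declared unit conversions:
#' glucose declared `"mg/dL"` is divided by 18.016 into mmol/L, with the
#' conversion logged. Missing required columns are a schema error naming
#' the canonical column.
#'
#' @param path CSV path.
#' @param columnMap optional named character vector mapping canonical
#'   column names to the file's column names.
#' @param units list of unit declarations; only `glucose` (`"mmol/L"`,
#'   default, or `"mg/dL"`) triggers conversion.
#' @return data.frame with canonical columns.
#' @export
readCohort <- function(path, columnMap = NULL,
                       units = list(glucose = "mmol/L")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tbl <- read.csv(path, check.names = FALSE)
  if (!is.null(columnMap)) {
    for (canonical in names(columnMap)) {
      fileCol <- columnMap[[canonical]]
      if (!fileCol %in% names(tbl))
        stop("mapped column not in file: ", fileCol)
      names(tbl)[names(tbl) == fileCol] <- canonical
    }
  }
  stopIfMissingCols(tbl, cohortRequiredCols(), "cohort file")
  for (col in cohortRequiredCols())
    if (!is.numeric(tbl[[col]]))
      stop("unparseable numeric column: ", col)
  gl <- units$glucose %||% "mmol/L"
  if (gl == "mg/dL") {
    tbl$glucose <- tbl$glucose / 18.016
    message("readCohort: glucose converted mg/dL -> mmol/L (/18.016)")
  } else if (gl != "mmol/L") {
    stop("unsupported glucose unit: ", gl)
  }
  tbl
}

#' @rdname readCohort
#' @param tbl cohort data.frame.
#' @export
writeCohort <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a normalization-factor table CSV
#'
#' Two columns `age,nf` (plus optional `interpolated`), one row per integer
#' calendar age — the same shape as a published NF supplement, loadable
#' directly.
#'
#' @param path CSV path.
#' @return `readNormalizationTable()` a \linkS4class{NormalizationTable};
#'   `writeNormalizationTable()` the path, invisibly.
#' @export
readNormalizationTable <- function(path) {
  tbl <- read.csv(path)
  stopIfMissingCols(tbl, c("age", "nf"), "NF table")
  tbl <- tbl[order(tbl$age), ]
  new("NormalizationTable", age = as.integer(tbl$age), nf = tbl$nf,
      interpolated = if ("interpolated" %in% names(tbl))
        as.logical(tbl$interpolated) else rep(FALSE, nrow(tbl)))
}

#' @rdname readNormalizationTable
#' @param nf a \linkS4class{NormalizationTable}.
#' @export
writeNormalizationTable <- function(nf, path) {
  stopifnot(is(nf, "NormalizationTable"))
  write.csv(data.frame(age = nf@age, nf = nf@nf,
                       interpolated = nf@interpolated),
            path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a metabolite abundance CSV
#'
#' File layout: rows = samples, first column the sample id, remaining
#' columns one per metabolite (processed, strictly positive abundances).
#' Sample metadata (`group`, `sex`, `age`, `delta_age`) is joined from
#' `sampleInfo` by id; every sample id must resolve.
#'
#' @param path CSV path.
#' @param sampleInfo data.frame with `id`, `group` and (optionally) `sex`,
#'   `age`, `delta_age` for every sample in the file.
#' @return `readMetaboliteMatrix()` a \linkS4class{MetaboliteExperiment};
#'   `writeMetaboliteMatrix()` the path, invisibly.
#' @export
readMetaboliteMatrix <- function(path, sampleInfo) {
  tbl <- read.csv(path, check.names = FALSE)
  ids <- as.character(tbl[[1]])
  mat <- t(as.matrix(tbl[, -1, drop = FALSE]))
  colnames(mat) <- ids
  missing <- setdiff(ids, as.character(sampleInfo$id))
  if (length(missing))
    stop("unjoinable sample id(s): ", paste(missing, collapse = ", "))
  info <- sampleInfo[match(ids, as.character(sampleInfo$id)), ]
  cd <- DataFrame(sample_id = ids,
                  group = factor(info$group, levels = healthGroupLevels(),
                                 ordered = TRUE),
                  row.names = ids)
  for (col in c("sex", "age", "delta_age"))
    if (col %in% names(info)) cd[[col]] <- info[[col]]
  se <- SummarizedExperiment(assays = list(abundance = mat), colData = cd)
  new("MetaboliteExperiment", se)
}

#' @rdname readMetaboliteMatrix
#' @param me a \linkS4class{MetaboliteExperiment}.
#' @export
writeMetaboliteMatrix <- function(me, path) {
  stopifnot(is(me, "MetaboliteExperiment"))
  mat <- t(assay(me, "abundance"))
  out <- data.frame(sample_id = rownames(mat), check.names = FALSE)
  out <- cbind(out, as.data.frame(mat, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
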