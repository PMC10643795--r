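# Metabolite screens: per-metabolite rank correlations to deltaAge and to
# the ordered health groups, cutoff-based signature selection, group
# contrasts, and the sex-stratified screen.

olderAdultMask <- function(me) {
  as.character(colData(me)$group) != "young"
}

screenOne <- function(values, target, method) {
  keep <- is.finite(values) & is.finite(target)
  v <- values[keep]; tg <- target[keep]
  if (length(v) < 4 || sd(v) == 0 || sd(tg) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = length(v)))
  if (method == "spearman") {
    st <- spearmanTest(v, tg)
    c(rho = st$rho, p = st$p, n = st$n)
  } else {
    ct <- cor.test(v, tg, method = "pearson")
    c(rho = unname(ct$estimate), p = ct$p.value, n = length(v))
  }
}

screenMatrix <- function(me, target, mask, method) {
  a <- assay(me, "abundance")[, mask, drop = FALSE]
  res <- t(apply(a, 1, screenOne, target = target[mask], method = method))
  data.frame(metabolite = rownames(a), rho = res[, "rho"], p = res[, "p"],
             n = as.integer(res[, "n"]), row.names = NULL)
}

#' Correlate metabolites with deltaAge (older adults only)
#'
#' One row per metabolite: Spearman (default) correlation of its abundance
#' with deltaAge across the older-adult samples (all non-young groups).
#' Samples whose `colData` lacks a finite deltaAge are an error listing the
#' ids; a metabolite with a missing abundance drops that sample pairwise.
#'
#' @param me a \linkS4class{MetaboliteExperiment} whose `colData` carries
#'   `group` and `delta_age`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with `metabolite`, `rho`, `p`, `n`.
#' @export
correlateDelta <- function(me, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is(me, "MetaboliteExperiment"))
  if (!"delta_age" %in% names(colData(me)))
    stop("colData must carry delta_age (score the cohort first)")
  mask <- olderAdultMask(me)
  if (!any(mask)) stop("no older-adult samples")
  delta <- colData(me)$delta_age
  bad <- colnames(me)[mask & !is.finite(delta)]
  if (length(bad))
    stop("sample(s) without a resolvable deltaAge: ",
         paste(bad, collapse = ", "))
  screenMatrix(me, delta, mask, method)
}

#' Correlate metabolites with the ordered health groups (all samples)
#'
#' Same output schema as [correlateDelta()], but against the ordinal codes
#' young = 0 < trained = 1 < normal = 2 < impaired = 3 over all samples.
#'
#' @inheritParams correlateDelta
#' @return data.frame with `metabolite`, `rho`, `p`, `n`.
#' @export
correlateGroups <- function(me, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is(me, "MetaboliteExperiment"))
  codes <- healthGroupCodes(colData(me)$group)
  screenMatrix(me, codes, rep(TRUE, ncol(me)), method)
}

#' Select the decelerated-aging signature
#'
#' Flags metabolites below the deltaAge-screen cutoff (strict p < 0.05 by
#' default), below the group-screen cutoff (strict p < 0.01), and their
#' intersection; p-values exactly at a cutoff are excluded. A BH-FDR column
#' is emitted per screen for reference but never used in the selection.
#'
#' @param deltaResults,groupResults data.frames from [correlateDelta()] and
#'   [correlateGroups()] over the same metabolite universe.
#' @param pDeltaCut,pGroupCut strict p-value cutoffs.
#' @return data.frame with per-metabolite rho/p for both screens, FDR
#'   columns, the three flags, and attributes `cutoffs` and `intersection`
#'   (intersection metabolites sorted by decreasing |rho_delta|).
#' @export
selectSignature <- function(deltaResults, groupResults, pDeltaCut = 0.05,
                            pGroupCut = 0.01) {
  if (!setequal(deltaResults$metabolite, groupResults$metabolite))
    stop("metabolite universes differ between the two screens")
  m <- merge(deltaResults, groupResults, by = "metabolite",
             suffixes = c("_delta", "_group"), sort = FALSE)
  m$fdr_delta <- stats::p.adjust(m$p_delta, method = "BH")
  m$fdr_group <- stats::p.adjust(m$p_group, method = "BH")
  m$in_delta_set <- !is.na(m$p_delta) & m$p_delta < pDeltaCut
  m$in_group_set <- !is.na(m$p_group) & m$p_group < pGroupCut
  m$in_intersection <- m$in_delta_set & m$in_group_set
  inter <- m[m$in_intersection, ]
  inter <- inter$metabolite[order(-abs(inter$rho_delta))]
  attr(m, "cutoffs") <- c(p_delta = pDeltaCut, p_group = pGroupCut)
  attr(m, "intersection") <- inter
  m
}

#' Kruskal-Wallis contrast of one metabolite across groups
#'
#' Tie-corrected Kruskal-Wallis H with its asymptotic chi-square p-value
#' (via `stats::kruskal.test`), plus optional unadjusted pairwise Wilcoxon
#' rank-sum p-values. When every value is identical the contrast is
#' degenerate: H = 0, p = 1, flagged.
#'
#' @param values numeric abundances.
#' @param groups group labels (>= 2 groups, each with >= 1 value).
#' @param pairwise also compute pairwise rank-sum p-values.
#' @return list with `H`, `p`, `degenerate`, and `pairwise` (matrix or
#'   NULL).
#' @export
groupContrast <- function(values, groups, pairwise = TRUE) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  if (length(unique(values)) == 1)
    return(list(H = 0, p = 1, degenerate = TRUE, pairwise = NULL))
  kw <- kruskal.test(values, groups)
  pw <- NULL
  if (pairwise)
    pw <- suppressWarnings(
      pairwise.wilcox.test(values, groups, p.adjust.method = "none"))$p.value
  list(H = unname(kw$statistic), p = kw$p.value, degenerate = FALSE,
       pairwise = pw)
}

#' Sex-stratified deltaAge screen
#'
#' Repeats the deltaAge correlation separately in male and female older
#' adults (Pearson by default, matching the stratified analysis; Spearman
#' available) and classifies each metabolite at p < 0.05 per stratum as
#' `both`, `male_only`, `female_only` or `neither`. A stratum with fewer
#' than 4 samples is flagged unreliable and classifies as not significant.
#'
#' @param me a \linkS4class{MetaboliteExperiment} whose `colData` carries
#'   `group`, `sex` and `delta_age`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha per-stratum significance cutoff.
#' @return data.frame with `metabolite`, `rho_male`, `p_male`, `n_male`,
#'   `rho_female`, `p_female`, `n_female`, `class`, `unreliable`.
#' @export
sexStratifiedSignature <- function(me, method = c("pearson", "spearman"),
                                   alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is(me, "MetaboliteExperiment"))
  stopIfMissingCols(as.data.frame(colData(me)), c("sex", "delta_age"),
                    "colData")
  older <- olderAdultMask(me)
  maleMask <- older & colData(me)$sex == 1
  femaleMask <- older & colData(me)$sex == 0
  if (!any(maleMask) || !any(femaleMask))
    stop("both sex strata must be non-empty among older adults")
  delta <- colData(me)$delta_age
  unreliable <- sum(maleMask) < 4 || sum(femaleMask) < 4
  scr <- function(mask) {
    if (sum(mask) < 4) {
      data.frame(metabolite = rownames(me), rho = NA_real_, p = NA_real_,
                 n = sum(mask))
    } else screenMatrix(me, delta, mask, method)
  }
  mRes <- scr(maleMask); fRes <- scr(femaleMask)
  sigM <- !is.na(mRes$p) & mRes$p < alpha
  sigF <- !is.na(fRes$p) & fRes$p < alpha
  cls <- ifelse(sigM & sigF, "both",
         ifelse(sigM, "male_only", ifelse(sigF, "female_only", "neither")))
  data.frame(metabolite = mRes$metabolite,
             rho_male = mRes$rho, p_male = mRes$p, n_male = mRes$n,
             rho_female = fRes$rho, p_female = fRes$p, n_female = fRes$n,
             class = cls, unreliable = unreliable, row.names = NULL)
}
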