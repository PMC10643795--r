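# Internal helpers shared across modules.

# Half-up rounding of a count; R's round() is round-half-even, which would make
# stratum sizes depend on parity. Documented so partitions are reproducible.
roundHalfUp <- function(x) floor(x + 0.5)

# Run expr with an isolated RNG stream (Mersenne-Twister), restoring the
# caller's RNG state afterwards. Used wherever a function takes its own seed,
# so stage-level reruns match the full pipeline run.
withIsolatedSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(expr)
}

# Derive a named per-stage seed from one top-level seed; kept below 2^31.
deriveSeed <- function(seed, stream) {
  streams <- c(cohort = 1L, mortality = 2L, split = 3L, mitohealth = 4L,
               metabolome = 5L, robustness = 6L, misc = 7L)
  idx <- streams[[stream]]
  as.integer((as.numeric(seed) * 48271 + idx * 1000003) %% 2147483587)
}

stopIfMissingCols <- function(tbl, cols, what = "table") {
  miss <- setdiff(cols, names(tbl))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Spearman rank correlation with a documented t-approximation p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks and a two-sided
#' p-value from the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}
#' on n - 2 degrees of freedom. Ties are handled by mid-ranks. Pairs with a
#' missing value in either vector are dropped pairwise. Never returns NaN:
#' a zero-variance rank vector yields \code{rho = NA} with
#' \code{degenerate = TRUE}, and \code{|rho| = 1} yields \code{p = 0}.
#'
#' @param x,y numeric vectors of equal length (>= 4 complete pairs).
#' @return list with \code{rho}, \code{p}, \code{n} (complete pairs used) and
#'   \code{degenerate} flag.
#' @examples
#' spearmanTest(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- cor(rx, ry)
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Root-mean-squared error
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return sqrt of the mean squared difference, in the vectors' units (years
#'   for age predictions).
#' @examples
#' rmse(c(0, 2), c(0, 0))  # sqrt(2)
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) == 0) stop("empty input")
  sqrt(mean((predicted - observed)^2))
}

starsFor <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
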