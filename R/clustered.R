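#' @include itemScores.R
NULL

#' Per-respondent total score over a set of items
#'
#' Sum (default) or mean of each respondent's scores over the listed items.
#' The sum score is the quantity a fitted monotone homogeneity model
#' licenses for ordering respondents; the mean scaling is convenient for
#' reporting on the original category metric (e.g. a 1--5 Likert range).
#'
#' @param x an [ItemScores-class] object or score matrix.
#' @param items item labels or indices (default: all items).
#' @param scale `"sum"` or `"mean"`.
#' @return Numeric vector of length \eqn{N}.
#' @examples
#' x <- ItemScores(cbind(a = c(1, 2, 3), b = c(3, 4, 5)))
#' totalScore(x, scale = "mean")
#' @export
totalScore <- function(x, items = NULL, scale = c("sum", "mean")) {
  scale <- match.arg(scale)
  x <- asItemScores(x)
  if (!is.null(items)) x <- x[, items]
  if (scale == "sum") rowSums(x@scores) else rowMeans(x@scores)
}

#' One-way ANOVA intraclass correlation with F test
#'
#' Estimates the ICC(1) of a total score over groups from the one-way ANOVA
#' decomposition and tests the null hypothesis that the ICC is zero with
#' the ANOVA F test. With between- and within-group mean squares
#' \eqn{MSB} and \eqn{MSW} and the unequal-group-size correction
#' \eqn{n_0 = (N - \sum_g n_g^2 / N)/(G - 1)}, the estimator is
#' \deqn{\widehat{ICC} = \frac{MSB - MSW}{MSB + (n_0 - 1)\,MSW},}
#' and \eqn{F = MSB/MSW} on \eqn{(G-1, N-G)} degrees of freedom, with the
#' upper-tail p value. The F test assumes within-group normality of the
#' scores. A significantly positive ICC on a final scale signals
#' within-group dependency, in which case subsequent analyses should use
#' two-level (cluster-robust) methods.
#'
#' Negative ICC estimates are reported as computed (with `truncate = TRUE`
#' to clamp at zero); truncating silently would hide the F-test logic.
#'
#' @param totalScores numeric vector of length \eqn{N} (e.g. from
#'   [totalScore()]).
#' @param groups factor (or vector) of group labels, at least two nonempty
#'   groups.
#' @param truncate clamp negative ICC estimates to 0 (default `FALSE`).
#' @return An [IccResult-class] object.
#' @examples
#' g <- rep(1:3, each = 4)
#' y <- c(1, 2, 1, 2, 5, 6, 5, 6, 9, 10, 9, 10)
#' iccOneway(y, g)
#' @export
iccOneway <- function(totalScores, groups, truncate = FALSE) {
  groups <- checkGroups(groups)
  if (length(totalScores) != length(groups)) {
    stop("totalScores and groups must have the same length", call. = FALSE)
  }
  N <- length(totalScores)
  G <- nlevels(groups)
  if (N <= G) stop("within-group degrees of freedom are zero (N must exceed G)", call. = FALSE)
  fit <- suppressWarnings(stats::anova(stats::lm(totalScores ~ groups)))
  msb <- fit[["Mean Sq"]][1]
  msw <- fit[["Mean Sq"]][2]
  df1 <- as.integer(fit[["Df"]][1])
  df2 <- as.integer(fit[["Df"]][2])
  ng <- as.numeric(table(groups))
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  if (msw <= 0 || msw < 1e-12 * msb) {
    warning("zero within-group variance: F is infinite and p = 0", call. = FALSE)
    icc <- 1 - .Machine$double.eps
    f <- Inf
    p <- 0
  } else {
    icc <- (msb - msw) / (msb + (n0 - 1) * msw)
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  if (truncate && icc < 0) icc <- 0
  new("IccResult",
    icc = icc, fStat = f, df1 = df1, df2 = df2, pValue = p,
    msb = msb, msw = msw, nGroups = as.integer(G), N = as.integer(N)
  )
}

setMethod("show", "IccResult", function(object) {
  cat(sprintf(
    "IccResult: ICC = %.3f, F(%d, %d) = %.2f, p = %.3g (%d groups, N = %d)\n",
    object@icc, object@df1, object@df2, object@fStat, object@pValue,
    object@nGroups, object@N
  ))
})
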