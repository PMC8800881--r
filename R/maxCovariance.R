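#' @include utils.R
NULL

# Comonotonic cross moment E[XY] of two discrete margins given as
# (values, probabilities). This is the maximum of E[XY] over all couplings
# with these margins (sort both variables in the same order and pair
# quantile-by-quantile); equivalently the integral of the product of the
# two quantile functions. Works for arbitrary nonnegative probability
# weights, which the influence-function machinery relies on.
comonotonicEXY <- function(valsI, pI, valsJ, pJ) {
  iI <- 1L; iJ <- 1L
  remI <- pI[1L]; remJ <- pJ[1L]
  nI <- length(pI); nJ <- length(pJ)
  s <- 0
  repeat {
    t <- min(remI, remJ)
    if (t > 0) s <- s + t * valsI[iI] * valsJ[iJ]
    remI <- remI - t
    remJ <- remJ - t
    if (remI <= 1e-15) {
      iI <- iI + 1L
      if (iI > nI) break
      remI <- pI[iI]
    }
    if (remJ <= 1e-15) {
      iJ <- iJ + 1L
      if (iJ > nJ) break
      remJ <- pJ[iJ]
    }
  }
  s
}

# Maximum covariance given two weighted margins (probability scale).
maxCovarianceP <- function(valsI, pI, valsJ, pJ) {
  muI <- sum(valsI * pI)
  muJ <- sum(valsJ * pJ)
  comonotonicEXY(valsI, pI, valsJ, pJ) - muI * muJ
}

#' Maximum covariance of two items given their margins
#'
#' The largest sample covariance attainable by any joint distribution with
#' the two observed marginal category frequency distributions. It is reached
#' by the comonotonic coupling — sort both items' scores in the same order
#' and pair them rank by rank (the perfect Guttman arrangement) — and is the
#' denominator of the scalability coefficient \eqn{H_{ij}}. The covariance
#' uses the population-style \eqn{N} denominator; \eqn{H} ratios are
#' invariant to that convention.
#'
#' @param marginI,marginJ category frequency tables (as produced by
#'   [table()], or named numeric vectors: names are category scores, values
#'   are counts). Both must sum to the same total \eqn{N \ge 2}.
#' @return The maximum attainable covariance (0 if and only if either margin
#'   is degenerate).
#' @examples
#' maxCovariance(table(c(0, 0, 1, 1)), table(c(0, 0, 1, 1))) # 0.25
#' @export
maxCovariance <- function(marginI, marginJ) {
  mI <- marginAsVP(marginI)
  mJ <- marginAsVP(marginJ)
  nI <- sum(mI$n); nJ <- sum(mJ$n)
  if (abs(nI - nJ) > 1e-9) {
    stop(sprintf("margins must have equal totals (got %g and %g)", nI, nJ), call. = FALSE)
  }
  if (nI < 2) stop("margins must total N >= 2", call. = FALSE)
  maxCovarianceP(mI$vals, mI$n / nI, mJ$vals, mJ$n / nJ)
}

marginAsVP <- function(margin) {
  if (is.table(margin)) {
    vals <- as.numeric(names(margin))
    n <- as.numeric(margin)
  } else if (!is.null(names(margin))) {
    vals <- as.numeric(names(margin))
    n <- as.numeric(margin)
  } else {
    stop("margins must be tables or named vectors (names = category scores)", call. = FALSE)
  }
  if (anyNA(vals)) stop("margin names must be numeric category scores", call. = FALSE)
  o <- order(vals)
  list(vals = vals[o], n = n[o])
}

# Weighted margins of each item of a score matrix: list of (vals, p).
weightedMargins <- function(X, w) {
  lapply(seq_len(ncol(X)), function(j) {
    vals <- sort(unique(X[, j]))
    p <- vapply(vals, function(v) sum(w[X[, j] == v]), numeric(1))
    list(vals = vals, p = p)
  })
}
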