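#' @include scalability.R
NULL

makeTestResult <- function(statistic, flavor, nullValue, alpha) {
  zCrit <- stats::qnorm(1 - alpha)
  data.frame(
    statistic = statistic,
    flavor = flavor,
    nullValue = nullValue,
    alternative = "greater",
    pValue = stats::pnorm(statistic, lower.tail = FALSE),
    zCrit = zCrit,
    alpha = alpha,
    rejected = statistic >= zCrit,
    stringsAsFactors = FALSE
  )
}

#' Mokken's Delta test of marginal independence
#'
#' Mokken's normal-theory test statistics for the null hypotheses
#' \eqn{H_{ij} \le 0}, \eqn{H_i \le 0} and \eqn{H \le 0} against the
#' one-sided alternative of positive scalability:
#' \deqn{\Delta_{ij} = \frac{S_{ij}}{S_i S_j}\sqrt{N-1}, \quad
#'       \Delta_i = \frac{\sum_{j \ne i} S_{ij}}{S_i \sum_{j \ne i} S_j}\sqrt{N-1}, \quad
#'       \Delta = \frac{\sum_i \sum_{j>i} S_{ij}}{\sum_i \sum_{j>i} S_i S_j}\sqrt{N-1},}
#' where \eqn{S_{ij}} is the sample covariance of items \eqn{i,j} and
#' \eqn{S_i} the sample standard deviation of item \eqn{i} (the ratios are
#' invariant to the variance denominator convention). Asymptotically the
#' statistics are standard normal under marginal independence. The test
#' assumes a simple random sample and is only suited for nonclustered data.
#'
#' @param x an [ItemScores-class] object or score matrix.
#' @param scope `"total"`, `"item"` or `"pair"`.
#' @param i,j item labels or indices: `i` for `scope = "item"`, both for
#'   `scope = "pair"`. For `scope = "item"` the statistic uses all other
#'   items in `x`.
#' @param alpha one-sided significance level (default 0.05).
#' @return A one-row data frame: `statistic`, `flavor` (`"delta"`),
#'   `nullValue` (0), `alternative`, `pValue`, `zCrit`, `alpha`, `rejected`.
#' @examples
#' m <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
#' deltaStatistic(m, "pair", "a", "b") # sqrt(3)
#' @export
deltaStatistic <- function(x, scope = c("total", "item", "pair"), i = NULL,
                           j = NULL, alpha = 0.05) {
  scope <- match.arg(scope)
  x <- asItemScores(x)
  X <- x@scores
  N <- nrow(X)
  if (N < 2L) stop("Delta statistics require N >= 2", call. = FALSE)
  stopIfDegenerate(X, context = "Delta test")
  core <- computeHcore(X)
  S <- core$S
  sdv <- sqrt(diag(S))
  resolve <- function(k) {
    if (is.character(k)) k <- match(k, colnames(X))
    if (is.na(k) || k < 1 || k > ncol(X)) stop("unknown item", call. = FALSE)
    as.integer(k)
  }
  stat <- switch(scope,
    pair = {
      i <- resolve(i); j <- resolve(j)
      S[i, j] / (sdv[i] * sdv[j]) * sqrt(N - 1)
    },
    item = {
      i <- resolve(i)
      sum(S[i, -i]) / (sdv[i] * sum(sdv[-i])) * sqrt(N - 1)
    },
    total = {
      up <- upper.tri(S)
      sdprod <- tcrossprod(sdv)
      sum(S[up]) / sum(sdprod[up]) * sqrt(N - 1)
    }
  )
  makeTestResult(as.numeric(stat), "delta", 0, alpha)
}

#' Wald z test for a scalability coefficient
#'
#' One-sided Wald test of the null hypothesis \eqn{H \le c} against
#' \eqn{H > c} for any scalability coefficient (item-pair, item, or total):
#' \eqn{z = (\hat H - c)/SE_{\hat H}}. With two-level standard errors this
#' is the appropriate test for clustered data; the null is rejected when
#' \eqn{z \ge z_{crit}} (about 1.645 at \eqn{\alpha = 0.05}).
#'
#' @param Hhat point estimate of the coefficient.
#' @param se its standard error (strictly positive).
#' @param c null value of the coefficient (default 0).
#' @param alpha one-sided significance level.
#' @return A one-row data frame (see [deltaStatistic()] for the columns).
#' @examples
#' waldZ(0.620, 0.026, c = 0.5)
#' @export
waldZ <- function(Hhat, se, c = 0, alpha = 0.05) {
  if (!is.finite(se) || se <= 0) stop("se must be strictly positive", call. = FALSE)
  makeTestResult((Hhat - c) / se, "wald", c, alpha)
}

#' Range-preserving z test for a scalability coefficient
#'
#' A variant of the Wald test computed on the transformed scale
#' \eqn{g(H) = \log(1 - H)}, which maps the admissible range
#' \eqn{(-\infty, 1)} onto the whole real line and so respects the upper
#' bound of 1 that scalability coefficients cannot exceed. With
#' \eqn{SE_{g(\hat H)} = SE_{\hat H} / (1 - \hat H)} by the delta method,
#' the statistic for the null \eqn{H \le c} versus \eqn{H > c} is
#' \eqn{z^* = (g(c) - g(\hat H))/SE_{g(\hat H)}} (the sign is oriented so
#' that larger \eqn{\hat H} gives larger \eqn{z^*}).
#'
#' @inheritParams waldZ
#' @return A one-row data frame (see [deltaStatistic()] for the columns).
#' @examples
#' rangePreservingZ(0.620, 0.026, c = 0.5)
#' @export
rangePreservingZ <- function(Hhat, se, c = 0, alpha = 0.05) {
  if (!is.finite(se) || se <= 0) stop("se must be strictly positive", call. = FALSE)
  if (Hhat >= 1) stop("range-preserving test requires Hhat < 1", call. = FALSE)
  if (c >= 1) stop("null value c must be below 1", call. = FALSE)
  seg <- se / (1 - Hhat)
  stat <- (log(1 - c) - log(1 - Hhat)) / seg
  makeTestResult(stat, "rangePreserving", c, alpha)
}

#' Confidence interval for a scalability coefficient
#'
#' Two-sided confidence interval around a scalability coefficient, either
#' Wald (\eqn{\hat H \pm z \cdot SE}) or range-preserving. The
#' range-preserving interval is computed on the \eqn{g(H) = \log(1-H)}
#' scale and back-transformed with \eqn{g^{-1}(y) = 1 - e^y}, so its upper
#' bound never exceeds 1 — the Wald interval can spill past 1 when
#' \eqn{\hat H} is large or its standard error wide.
#'
#' @param Hhat point estimate.
#' @param se standard error (strictly positive).
#' @param level confidence level (default 0.95; the multiplier is the
#'   two-sided normal quantile, 1.96 at 95%).
#' @param flavor `"wald"` or `"rangePreserving"`.
#' @return A one-row data frame: `lower`, `upper`, `level`, `flavor`.
#' @examples
#' confidenceInterval(0.5, 0.1) # [0.304, 0.696]
#' confidenceInterval(0.9, 0.1, flavor = "rangePreserving") # upper < 1
#' @export
confidenceInterval <- function(Hhat, se, level = 0.95,
                               flavor = c("wald", "rangePreserving")) {
  flavor <- match.arg(flavor)
  if (!is.finite(se) || se <= 0) stop("se must be strictly positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (flavor == "wald") {
    lower <- Hhat - z * se
    upper <- Hhat + z * se
  } else {
    if (Hhat >= 1) stop("range-preserving interval requires Hhat < 1", call. = FALSE)
    seg <- se / (1 - Hhat)
    bounds <- 1 - exp(log(1 - Hhat) + c(1, -1) * z * seg)
    lower <- min(bounds)
    upper <- max(bounds)
  }
  data.frame(lower = lower, upper = upper, level = level, flavor = flavor,
    stringsAsFactors = FALSE
  )
}
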