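#' @include maxCovariance.R
NULL

# Core: pairwise covariances S_ij, maximum covariances given the margins,
# and all H coefficients, for a score matrix X under respondent weights w
# (w sums to 1; the empirical distribution uses w = 1/N). Population-style
# denominators throughout.
computeHcore <- function(X, w = NULL) {
  N <- nrow(X); J <- ncol(X)
  if (is.null(w)) w <- rep(1 / N, N)
  mu <- as.numeric(crossprod(w, X))
  Exy <- crossprod(X, X * w)
  S <- Exy - tcrossprod(mu)
  margins <- weightedMargins(X, w)
  Smax <- matrix(0, J, J, dimnames = dimnames(S))
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      Smax[i, j] <- Smax[j, i] <- maxCovarianceP(
        margins[[i]]$vals, margins[[i]]$p,
        margins[[j]]$vals, margins[[j]]$p
      )
    }
  }
  up <- upper.tri(S)
  Hpair <- S / Smax
  diag(Hpair) <- NA_real_
  denomItem <- rowSums(Smax) # diagonal of Smax is 0
  numItem <- rowSums(S) - diag(S)
  Hitem <- numItem / denomItem
  Htotal <- sum(S[up]) / sum(Smax[up])
  Spair <- S
  diag(Spair) <- NA_real_
  SmaxPair <- Smax
  diag(SmaxPair) <- NA_real_
  list(
    Hpair = Hpair, Hitem = Hitem, Htotal = Htotal,
    S = S, covPair = Spair, covmaxPair = SmaxPair, mu = mu,
    margins = margins
  )
}

#' Estimate Mokken scalability coefficients with standard errors
#'
#' Computes the item-pair coefficients \eqn{\hat H_{ij}} (observed covariance
#' divided by the maximum covariance given the margins), the item
#' coefficients \eqn{\hat H_i}, and the total-scale coefficient \eqn{\hat H},
#' together with delta-method standard errors under the requested sampling
#' model:
#'
#' * `level = "one"` treats respondents as an i.i.d. simple random sample
#'   (multinomial covariance of the score-pattern proportions);
#' * `level = "two"` treats the groups of the cluster design as the
#'   independent sampling units, so the standard errors absorb within-group
#'   dependency. Point estimates are identical under both levels.
#'
#' For a set of items the coefficients always satisfy the ordering
#' \eqn{\min(\hat H_{ij}) \le \min(\hat H_i) \le \hat H \le \max(\hat H_i)
#' \le \max(\hat H_{ij})}, and a Mokken scale requires \eqn{H_{ij} > 0} for
#' all pairs and \eqn{H_i \ge c} for all items (commonly \eqn{c = 0.3}).
#'
#' @param x an [ItemScores-class] object (or a bare score matrix).
#' @param level `"one"` (simple random sample) or `"two"` (clustered; requires
#'   a group design with at least two groups).
#' @param items optional subset of item labels/indices to analyse.
#' @param se compute standard errors (`TRUE` by default; point estimates only
#'   when `FALSE`).
#' @param warnLevelOne warn when one-level standard errors are requested for
#'   data that carry a cluster design (such standard errors ignore
#'   within-group dependency and are typically too small).
#' @return A [ScalabilityResults-class] object.
#' @examples
#' x <- simulateGrm(multilevelGrmSpec(nGroups = 10, groupSizes = 15, seed = 7))
#' h <- scalability(x, level = "two")
#' totalH(h)
#' totalSE(h)
#' @seealso [clusterBootstrapSE()], [waldZ()], [confidenceInterval()]
#' @export
scalability <- function(x, level = c("one", "two"), items = NULL, se = TRUE,
                        warnLevelOne = TRUE) {
  level <- match.arg(level)
  x <- asItemScores(x)
  if (!is.null(items)) x <- x[, items]
  X <- x@scores
  N <- nrow(X); J <- ncol(X)
  if (N < 2L || J < 2L) {
    stop("scalability requires at least 2 respondents and 2 items", call. = FALSE)
  }
  stopIfDegenerate(X)
  groups <- x@groups
  if (level == "two") groups <- checkGroups(groups)
  if (level == "one" && !is.null(groups) && warnLevelOne && se) {
    warning(
      "one-level standard errors requested for clustered data; they ignore ",
      "within-group dependency and are likely too small",
      call. = FALSE
    )
  }
  core <- computeHcore(X)
  sePair <- seItem <- seTotal <- NULL
  if (se) {
    if (N < 3L) stop("standard errors require N >= 3", call. = FALSE)
    IF <- influenceH(X, core)
    ses <- influenceSE(IF, level = level, groups = groups)
    sePair <- ses$sePair
    seItem <- ses$seItem
    seTotal <- ses$seTotal
  }
  new("ScalabilityResults",
    Hpair = core$Hpair, Hitem = core$Hitem, Htotal = core$Htotal,
    covPair = core$covPair, covmaxPair = core$covmaxPair,
    sePair = sePair, seItem = seItem, seTotal = seTotal,
    level = level, seMethod = if (se) "delta" else "none",
    N = as.integer(N), J = as.integer(J)
  )
}

asItemScores <- function(x) {
  if (is(x, "ItemScores")) return(x)
  ItemScores(x)
}

#' @rdname coefficient-accessors
#' @export
setMethod("pairH", "ScalabilityResults", function(x) x@Hpair)

#' @rdname coefficient-accessors
#' @export
setMethod("itemH", "ScalabilityResults", function(x) x@Hitem)

#' @rdname coefficient-accessors
#' @export
setMethod("totalH", "ScalabilityResults", function(x) x@Htotal)

#' @rdname coefficient-accessors
#' @export
setMethod("pairSE", "ScalabilityResults", function(x) x@sePair)

#' @rdname coefficient-accessors
#' @export
setMethod("itemSE", "ScalabilityResults", function(x) x@seItem)

#' @rdname coefficient-accessors
#' @export
setMethod("totalSE", "ScalabilityResults", function(x) x@seTotal)

setMethod("show", "ScalabilityResults", function(object) {
  cat(sprintf(
    "ScalabilityResults: %d items, N = %d (%s-level %s)\n",
    object@J, object@N, object@level,
    switch(object@seMethod,
      delta = "delta-method SEs",
      bootstrap = sprintf("bootstrap SEs, B = %d", object@B),
      none = "point estimates only"
    )
  ))
  df <- data.frame(Hi = round(object@Hitem, 3))
  if (!is.null(object@seItem)) df$SE <- round(object@seItem, 3)
  rownames(df) <- names(object@Hitem)
  print(df)
  if (!is.null(object@seTotal)) {
    cat(sprintf("Total H = %.3f (SE %.3f)\n", object@Htotal, object@seTotal))
  } else {
    cat(sprintf("Total H = %.3f\n", object@Htotal))
  }
})

#' Tidy per-item summary of a scalability analysis
#'
#' @param object a [ScalabilityResults-class] object.
#' @param ... unused.
#' @return A data frame with one row per item (`item`, `Hi`, and `se` when
#'   standard errors were computed) plus a final `Total` row.
#' @export
setMethod("summary", "ScalabilityResults", function(object, ...) {
  df <- data.frame(
    item = c(names(object@Hitem), "Total"),
    H = c(object@Hitem, object@Htotal),
    stringsAsFactors = FALSE
  )
  if (!is.null(object@seItem)) df$se <- c(object@seItem, object@seTotal)
  rownames(df) <- NULL
  df
})
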