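#' @import methods
NULL

setClassUnion("factorOrNULL", c("factor", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ItemScores: ordinal item-score data with an optional cluster design
#'
#' The universal input container of the package: an \eqn{N \times J} integer
#' matrix of ordinal item scores (e.g. 1--5 Likert responses), the declared
#' category range of every item, and, for data collected under a two-stage
#' cluster sampling design, a factor assigning each respondent to a group.
#'
#' @slot scores integer matrix, respondents in rows, items in columns.
#' @slot groups factor of length \code{nrow(scores)} mapping each respondent
#'   to a cluster (class, hospital, neighbourhood, ...), or \code{NULL} for a
#'   simple random sample.
#' @slot minScore,maxScore integer vectors of length \eqn{J}: the declared
#'   category range of each item. Scores must lie inside these bounds; the
#'   range is used by [recodeReversed()].
#'
#' @seealso [ItemScores()], [readItemScores()], [scalability()]
#' @export
setClass("ItemScores",
  representation(
    scores = "matrix",
    groups = "factorOrNULL",
    minScore = "integer",
    maxScore = "integer"
  )
)

setValidity("ItemScores", function(object) {
  msg <- character()
  sc <- object@scores
  if (!is.numeric(sc)) {
    msg <- c(msg, "scores must be a numeric (integer-valued) matrix")
  } else {
    if (anyNA(sc)) {
      bad <- which(is.na(sc), arr.ind = TRUE)[1, ]
      msg <- c(msg, sprintf(
        "missing score at row %d, item '%s'; remove or drop incomplete rows explicitly",
        bad[1], colnames(sc)[bad[2]]
      ))
    } else if (any(sc != round(sc))) {
      bad <- which(sc != round(sc), arr.ind = TRUE)[1, ]
      msg <- c(msg, sprintf(
        "non-integer score %g at row %d, item '%s'",
        sc[bad[1], bad[2]], bad[1], colnames(sc)[bad[2]]
      ))
    }
  }
  if (is.null(colnames(sc))) msg <- c(msg, "scores must have item labels as column names")
  if (length(object@minScore) != ncol(sc) || length(object@maxScore) != ncol(sc)) {
    msg <- c(msg, "minScore and maxScore must have one entry per item")
  } else if (!anyNA(sc) && is.numeric(sc) && ncol(sc) > 0) {
    below <- sweep(sc, 2, object@minScore, `<`)
    above <- sweep(sc, 2, object@maxScore, `>`)
    if (any(below | above)) {
      bad <- which(below | above, arr.ind = TRUE)[1, ]
      msg <- c(msg, sprintf(
        "score %g at row %d outside declared range [%d, %d] of item '%s'",
        sc[bad[1], bad[2]], bad[1], object@minScore[bad[2]],
        object@maxScore[bad[2]], colnames(sc)[bad[2]]
      ))
    }
    if (any(object@minScore > object@maxScore)) {
      msg <- c(msg, "minScore must not exceed maxScore")
    }
  }
  if (!is.null(object@groups)) {
    if (length(object@groups) != nrow(sc)) {
      msg <- c(msg, "groups must assign exactly one group per respondent row")
    }
    if (anyNA(object@groups)) msg <- c(msg, "groups must not contain missing labels")
  }
  if (length(msg)) msg else TRUE
})

#' ScalabilityResults: scalability coefficients with standard errors
#'
#' Holds the full set of Mokken scalability coefficients for an item set:
#' the item-pair coefficients \eqn{\hat H_{ij}}, item coefficients
#' \eqn{\hat H_i}, and the total-scale coefficient \eqn{\hat H}, together
#' with the pairwise covariances, the maximum covariances given the item
#' margins, and (optionally) standard errors computed under the one-level
#' (simple random sampling) or two-level (clustered sampling) method.
#'
#' Point estimates are identical under both levels; only the standard errors
#' differ. The diagonal of the pairwise tables is \code{NA}: \eqn{H_{ii}} is
#' undefined and deliberately not reported as 1.
#'
#' @slot Hpair,sePair symmetric \eqn{J \times J} matrices (diagonal \code{NA}).
#' @slot Hitem,seItem numeric vectors of length \eqn{J}.
#' @slot Htotal,seTotal scalars.
#' @slot covPair,covmaxPair observed and maximum pairwise covariances
#'   (population-style \eqn{N} denominator; the \eqn{H} ratios are
#'   denominator-invariant).
#' @slot level \code{"one"} or \code{"two"}.
#' @slot seMethod \code{"delta"}, \code{"bootstrap"}, or \code{"none"}.
#' @slot N,J sample size and number of items.
#' @slot B,seed bootstrap replicate count and seed (bootstrap SEs only).
#'
#' @seealso [scalability()], [clusterBootstrapSE()], [itemH()], [totalH()]
#' @export
setClass("ScalabilityResults",
  representation(
    Hpair = "matrix", Hitem = "numeric", Htotal = "numeric",
    covPair = "matrix", covmaxPair = "matrix",
    sePair = "matrixOrNULL", seItem = "numericOrNULL", seTotal = "numericOrNULL",
    level = "character", seMethod = "character",
    N = "integer", J = "integer",
    B = "integer", seed = "integer"
  ),
  prototype(B = NA_integer_, seed = NA_integer_, seMethod = "none")
)

setValidity("ScalabilityResults", function(object) {
  msg <- character()
  J <- object@J
  if (!identical(dim(object@Hpair), c(J, J))) msg <- c(msg, "Hpair must be J x J")
  if (length(object@Hitem) != J) msg <- c(msg, "Hitem must have length J")
  if (length(object@Htotal) != 1L) msg <- c(msg, "Htotal must be a scalar")
  if (!all(is.na(diag(object@Hpair)))) msg <- c(msg, "diagonal of Hpair must be NA (H_ii is undefined)")
  if (!object@level %in% c("one", "two")) msg <- c(msg, "level must be 'one' or 'two'")
  if (!object@seMethod %in% c("delta", "bootstrap", "none")) {
    msg <- c(msg, "seMethod must be 'delta', 'bootstrap' or 'none'")
  }
  if (!is.null(object@seTotal) && any(object@seTotal < 0, na.rm = TRUE)) {
    msg <- c(msg, "standard errors must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' ScalePartition: one AISP / T-AISP solution
#'
#' The assignment of each item to a Mokken scale produced by one run of the
#' automated item selection procedure at a single lowerbound \eqn{c}.
#' Scale indices are contiguous from 1 in order of formation; 0 marks an
#' unscalable item. The \code{trace} slot logs every criterion test the
#' greedy algorithm performed, including the running Bonferroni counter and
#' the critical value in force, so the sequential correction is auditable.
#'
#' @slot assignment named integer vector, one entry per item (0 = unscalable).
#' @slot lowerbound the scalability lowerbound \eqn{c} used.
#' @slot method \code{"classic"} (AISP) or \code{"testGuided"} (T-AISP).
#' @slot level \code{"one"} or \code{"two"} (which standard errors fed the tests).
#' @slot alpha nominal significance level before Bonferroni adjustment.
#' @slot trace data frame logging each step's tests and decisions.
#'
#' @seealso [runAisp()], [lowerboundSweep()]
#' @export
setClass("ScalePartition",
  representation(
    assignment = "integer", lowerbound = "numeric", method = "character",
    level = "character", alpha = "numeric", trace = "data.frame"
  )
)

setValidity("ScalePartition", function(object) {
  msg <- character()
  a <- object@assignment
  if (is.null(names(a))) msg <- c(msg, "assignment must be named by item")
  scales <- sort(unique(a[a > 0L]))
  if (length(scales) && !identical(scales, seq_along(scales))) {
    msg <- c(msg, "scale indices must be contiguous from 1")
  }
  if (any(tabulate(a[a > 0L]) == 1L)) msg <- c(msg, "every scale must contain at least 2 items")
  if (length(msg)) msg else TRUE
})

#' LowerboundSweep: AISP solutions across a grid of lowerbounds
#'
#' One [ScalePartition-class] per lowerbound \eqn{c}, plus the items-by-c
#' table of scale indices in which scale membership is read column-wise
#' (the standard presentation of an AISP sweep).
#'
#' @slot partitions list of [ScalePartition-class], one per lowerbound.
#' @slot table integer matrix, items in rows, lowerbounds in columns.
#' @slot lowerbounds the grid of \eqn{c} values.
#' @seealso [lowerboundSweep()]
#' @export
setClass("LowerboundSweep",
  representation(partitions = "list", table = "matrix", lowerbounds = "numeric")
)

#' IccResult: one-way ANOVA intraclass correlation with F test
#'
#' ICC(1) of a total score over groups, estimated from the one-way ANOVA
#' mean squares with the unequal-group-size correction
#' \eqn{n_0 = (N - \sum_g n_g^2/N)/(G-1)}, together with the F statistic
#' \eqn{F = MSB/MSW} on \eqn{(G-1, N-G)} degrees of freedom and its
#' upper-tail p value for the null hypothesis ICC \eqn{= 0}.
#'
#' @slot icc point estimate (may be negative; not truncated by default).
#' @slot fStat,df1,df2,pValue the F test.
#' @slot msb,msw between- and within-group mean squares.
#' @slot nGroups,N group count and total sample size.
#' @seealso [iccOneway()]
#' @export
setClass("IccResult",
  representation(
    icc = "numeric", fStat = "numeric", df1 = "integer", df2 = "integer",
    pValue = "numeric", msb = "numeric", msw = "numeric",
    nGroups = "integer", N = "integer"
  )
)

setValidity("IccResult", function(object) {
  msg <- character()
  if (object@df1 + object@df2 != object@N - 1L) msg <- c(msg, "df1 + df2 must equal N - 1")
  if (object@icc >= 1) msg <- c(msg, "icc must be below 1")
  if (length(msg)) msg else TRUE
})

#' MsaReport: result of the two-step, test-guided Mokken scale analysis
#'
#' End-to-end record of the workflow: the T-AISP lowerbound sweep (Step 1),
#' the final scales selected by the configured rule, per-scale within-group
#' dependency diagnostics (clustered designs only), and the Step-2 strength
#' evaluation (scalability coefficients, standard errors at the level the
#' ICC decision dictates, Wald confidence intervals, and Mokken's strength
#' benchmarks).
#'
#' @slot designType \code{"nonclustered"} or \code{"clustered"}.
#' @slot sweep the Step-1 [LowerboundSweep-class].
#' @slot finalScales named list of character vectors of item labels.
#' @slot selectionRule list recording how the final scales were chosen.
#' @slot icc named list of [IccResult-class] (clustered designs only).
#' @slot scaleResults named list; per scale: \code{estimates}
#'   ([ScalabilityResults-class]), \code{ci} (total-H Wald CI),
#'   \code{itemCI} (per-item Wald CIs), \code{level}, \code{strength},
#'   \code{strengthBasis} (\code{"ciLower"} or \code{"pointEstimate"}).
#' @slot alpha significance level used throughout.
#' @seealso [twoStepMSA()]
#' @export
setClass("MsaReport",
  representation(
    designType = "character", sweep = "LowerboundSweep",
    finalScales = "list", selectionRule = "list",
    icc = "list", scaleResults = "list", alpha = "numeric"
  )
)
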