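#' @include AllClasses.R
NULL

#' Accessors for ItemScores and result objects
#'
#' `scoreMatrix()` returns the raw integer score matrix; `groupLabels()` the
#' cluster factor (or `NULL`); `itemLabels()` the item names; `nRespondents()`
#' and `nItems()` the dimensions; `itemRange()` the declared per-item category
#' ranges as a two-column matrix.
#'
#' @param x an [ItemScores-class] object (or, where documented, a result object).
#' @return See each accessor's description.
#' @name accessors
#' @aliases scoreMatrix groupLabels itemLabels nRespondents nItems itemRange
#' @examples
#' x <- ItemScores(cbind(a = c(0, 1, 2, 1), b = c(1, 1, 2, 0)))
#' scoreMatrix(x)
#' nItems(x)
NULL

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("itemLabels", function(x) standardGeneric("itemLabels"))

#' @rdname accessors
#' @export
setGeneric("nRespondents", function(x) standardGeneric("nRespondents"))

#' @rdname accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname accessors
#' @export
setGeneric("itemRange", function(x) standardGeneric("itemRange"))

#' Extract scalability coefficients and their standard errors
#'
#' `pairH()`, `itemH()` and `totalH()` return the item-pair matrix
#' \eqn{\hat H_{ij}}, the item vector \eqn{\hat H_i}, and the total-scale
#' coefficient \eqn{\hat H} from a [ScalabilityResults-class] object;
#' `pairSE()`, `itemSE()` and `totalSE()` return the corresponding standard
#' errors (or `NULL` when none were computed).
#'
#' @param x a [ScalabilityResults-class] object.
#' @return A matrix, vector or scalar as described.
#' @name coefficient-accessors
NULL

#' @rdname coefficient-accessors
#' @export
setGeneric("pairH", function(x) standardGeneric("pairH"))

#' @rdname coefficient-accessors
#' @export
setGeneric("itemH", function(x) standardGeneric("itemH"))

#' @rdname coefficient-accessors
#' @export
setGeneric("totalH", function(x) standardGeneric("totalH"))

#' @rdname coefficient-accessors
#' @export
setGeneric("pairSE", function(x) standardGeneric("pairSE"))

#' @rdname coefficient-accessors
#' @export
setGeneric("itemSE", function(x) standardGeneric("itemSE"))

#' @rdname coefficient-accessors
#' @export
setGeneric("totalSE", function(x) standardGeneric("totalSE"))

#' Extract the scale assignment from a partition
#'
#' @param x a [ScalePartition-class] object.
#' @return Named integer vector of scale indices (0 = unscalable).
#' @export
setGeneric("scaleAssignment", function(x) standardGeneric("scaleAssignment"))

#' Extract the items-by-lowerbounds table from a sweep
#'
#' @param x a [LowerboundSweep-class] object.
#' @return Integer matrix, items in rows, lowerbound values as columns.
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))
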