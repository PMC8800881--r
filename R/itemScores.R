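#' @include utils.R
NULL

#' Construct an ItemScores object
#'
#' Wraps an integer matrix of ordinal item scores, an optional cluster
#' factor, and the per-item category ranges into a validated
#' [ItemScores-class] object. Missing values are rejected: if rows must be
#' dropped, do so deliberately (see `dropIncomplete` in [readItemScores()]).
#'
#' @param scores numeric matrix (or data frame) of integer-valued scores,
#'   respondents in rows, items in columns. Column names become item labels
#'   (`I1`, `I2`, ... if absent).
#' @param groups optional vector/factor of cluster labels, one per row.
#' @param minScore,maxScore optional integer vectors (or scalars, recycled)
#'   declaring each item's category range; default to the observed range.
#' @return An [ItemScores-class] object.
#' @examples
#' set.seed(1)
#' m <- matrix(sample(1:5, 40, replace = TRUE), 10, 4)
#' x <- ItemScores(m, groups = rep(c("g1", "g2"), each = 5))
#' x
#' @export
ItemScores <- function(scores, groups = NULL, minScore = NULL, maxScore = NULL) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  storage.mode(scores) <- "numeric"
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("I", seq_len(ncol(scores)))
  }
  J <- ncol(scores)
  obsMin <- suppressWarnings(apply(scores, 2, min, na.rm = TRUE))
  obsMax <- suppressWarnings(apply(scores, 2, max, na.rm = TRUE))
  if (is.null(minScore)) minScore <- obsMin
  if (is.null(maxScore)) maxScore <- obsMax
  minScore <- as.integer(rep_len(minScore, J))
  maxScore <- as.integer(rep_len(maxScore, J))
  if (!is.null(groups)) groups <- droplevels(as.factor(groups))
  new("ItemScores",
    scores = scores, groups = groups,
    minScore = minScore, maxScore = maxScore
  )
}

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "ItemScores", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("groupLabels", "ItemScores", function(x) x@groups)

#' @rdname accessors
#' @export
setMethod("itemLabels", "ItemScores", function(x) colnames(x@scores))

#' @rdname accessors
#' @export
setMethod("nRespondents", "ItemScores", function(x) nrow(x@scores))

#' @rdname accessors
#' @export
setMethod("nItems", "ItemScores", function(x) ncol(x@scores))

#' @rdname accessors
#' @export
setMethod("itemRange", "ItemScores", function(x) {
  cbind(min = x@minScore, max = x@maxScore,
    deparse.level = 0
  ) -> rg
  rownames(rg) <- colnames(x@scores)
  rg
})

#' @describeIn ItemScores-class dimensions (respondents, items).
#' @param x an \code{ItemScores} object.
#' @export
setMethod("dim", "ItemScores", function(x) dim(x@scores))

#' @describeIn ItemScores-class subset respondents (`i`) and/or items (`j`);
#'   the group factor and category ranges are subset accordingly.
#' @param i,j,...,drop row (respondent) and column (item) indices; `drop` is
#'   ignored (the result is always an `ItemScores`).
#' @export
setMethod("[", "ItemScores", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@scores))
  if (missing(j)) j <- seq_len(ncol(x@scores))
  if (is.character(j)) j <- match(j, colnames(x@scores))
  if (anyNA(j)) stop("unknown item label", call. = FALSE)
  g <- if (is.null(x@groups)) NULL else droplevels(x@groups[i])
  new("ItemScores",
    scores = x@scores[i, j, drop = FALSE], groups = g,
    minScore = x@minScore[j], maxScore = x@maxScore[j]
  )
})

setMethod("show", "ItemScores", function(object) {
  cat(sprintf(
    "ItemScores: %d respondents x %d items\n",
    nrow(object@scores), ncol(object@scores)
  ))
  rg <- range(object@minScore, object@maxScore)
  cat(sprintf("  score range: %d..%d\n", rg[1], rg[2]))
  if (is.null(object@groups)) {
    cat("  design: nonclustered (simple random sample)\n")
  } else {
    ng <- table(object@groups)
    cat(sprintf(
      "  design: clustered, %d groups (sizes %d..%d, mean %.1f)\n",
      nlevels(object@groups), min(ng), max(ng), mean(ng)
    ))
  }
  cat("  items:", paste(utils::head(colnames(object@scores), 8), collapse = ", "),
    if (ncol(object@scores) > 8) "..." else "", "\n"
  )
})

#' Read an item-score matrix from a delimited text file
#'
#' Reads a CSV/TSV file with a header row, validates that every item column
#' is integer-valued and complete, and returns an [ItemScores-class] object.
#' If `groupColumn` names a column, it is removed from the item set and used
#' as the cluster design.
#'
#' @param path file path. The delimiter is inferred from the extension
#'   (`.csv` comma, anything else tab) unless `delim` is given.
#' @param groupColumn optional name of the cluster-label column.
#' @param delim optional field delimiter overriding the extension rule.
#' @param dropIncomplete if `TRUE`, rows containing missing item scores are
#'   removed (listwise deletion) with a message; the default is to fail with
#'   an error naming the first offending cell, so that missing data are
#'   handled deliberately rather than silently.
#' @return An [ItemScores-class] object (with `groupLabels()` set when
#'   `groupColumn` was given).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(a = c(0, 1, 1, 0), b = c(1, 1, 0, 0)), f, row.names = FALSE)
#' readItemScores(f)
#' @seealso [writeItemScores()]
#' @export
readItemScores <- function(path, groupColumn = NULL, delim = NULL,
                           dropIncomplete = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path,
    header = TRUE, sep = delim, stringsAsFactors = FALSE,
    check.names = FALSE, na.strings = c("NA", "")
  )
  if (ncol(df) < 1L) stop("file has no columns", call. = FALSE)
  groups <- NULL
  if (!is.null(groupColumn)) {
    if (!groupColumn %in% names(df)) {
      stop(sprintf(
        "group column '%s' not found (columns: %s)",
        groupColumn, paste(names(df), collapse = ", ")
      ), call. = FALSE)
    }
    groups <- df[[groupColumn]]
    df <- df[, setdiff(names(df), groupColumn), drop = FALSE]
  }
  if (ncol(df) == 0L) stop("no item columns remain after removing the group column", call. = FALSE)
  for (cn in names(df)) {
    col <- df[[cn]]
    if (all(is.na(col))) stop(sprintf("item column '%s' is empty", cn), call. = FALSE)
    if (!is.numeric(col)) {
      bad <- which(!is.na(col))[1]
      stop(sprintf(
        "item column '%s' does not parse as integer (e.g. value '%s' in data row %d)",
        cn, as.character(col[bad]), bad
      ), call. = FALSE)
    }
    nonint <- which(!is.na(col) & col != round(col))
    if (length(nonint)) {
      stop(sprintf(
        "non-integer score %g in data row %d, item column '%s'",
        col[nonint[1]], nonint[1], cn
      ), call. = FALSE)
    }
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    if (dropIncomplete) {
      keep <- stats::complete.cases(m)
      message(sprintf(
        "dropIncomplete: removed %d of %d rows with missing item scores",
        sum(!keep), nrow(m)
      ))
      m <- m[keep, , drop = FALSE]
      if (!is.null(groups)) groups <- groups[keep]
    } else {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "missing score ('NA') in data row %d, item column '%s'; set dropIncomplete = TRUE to delete incomplete rows listwise",
        bad[1], colnames(m)[bad[2]]
      ), call. = FALSE)
    }
  }
  ItemScores(m, groups = groups)
}

#' Write an item-score matrix to a delimited text file
#'
#' The inverse of [readItemScores()]: writes the scores (and the group
#' column, if present, under the name given by `groupColumn`) so that a
#' read/write/read round trip reproduces the data exactly.
#'
#' @param x an [ItemScores-class] object.
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @param groupColumn column name for the cluster labels (used only when
#'   `x` carries a group design).
#' @param delim optional delimiter override.
#' @return `path`, invisibly.
#' @export
writeItemScores <- function(x, path, groupColumn = "group", delim = NULL) {
  stopifnot(is(x, "ItemScores"))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- as.data.frame(x@scores, check.names = FALSE)
  if (!is.null(x@groups)) df[[groupColumn]] <- as.character(x@groups)
  utils::write.table(df, path,
    sep = delim, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Recode reversely worded items
#'
#' Reflects each listed item about the midpoint of its declared category
#' range: a score \eqn{x} becomes \eqn{\mathrm{min} + \mathrm{max} - x}.
#' Applying the recoding twice restores the original scores. Reversely
#' worded questionnaire items must be recoded this way before any
#' scalability analysis, since their covariances with the other items would
#' otherwise be negative by construction.
#'
#' @param x an [ItemScores-class] object.
#' @param items character vector of item labels (or integer indices) to recode.
#' @return An [ItemScores-class] object with the listed items reflected.
#' @examples
#' x <- ItemScores(cbind(a = c(1, 2, 5), b = c(5, 4, 1)), minScore = 1, maxScore = 5)
#' scoreMatrix(recodeReversed(x, "b"))
#' @export
recodeReversed <- function(x, items) {
  stopifnot(is(x, "ItemScores"))
  j <- if (is.character(items)) match(items, colnames(x@scores)) else as.integer(items)
  if (anyNA(j) || any(j < 1L) || any(j > ncol(x@scores))) {
    bad <- if (is.character(items)) items[is.na(j)] else items[j < 1 | j > ncol(x@scores)]
    stop(sprintf("unknown item(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  sc <- x@scores
  for (k in j) sc[, k] <- x@minScore[k] + x@maxScore[k] - sc[, k]
  new("ItemScores",
    scores = sc, groups = x@groups,
    minScore = x@minScore, maxScore = x@maxScore
  )
}
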