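#' @include itemScores.R synthetic.R
NULL

#' Export the SWMDK questionnaire data to the package CSV layout
#'
#' The worked real-data example of the two-step, test-guided workflow is the
#' SWMDK school well-being questionnaire: 13 five-point Likert items
#' (7 on well-being with teachers, 6 with classmates) administered to 639
#' students nested in 30 classes. Those data are distributed inside the R
#' package \pkg{mokken}; this helper performs the one-time export to the
#' delimited layout this package reads (13 item columns plus a `Class`
#' group column), after which [readItemScores()] with
#' `groupColumn = "Class"` reproduces the analysis inputs. Reversely worded
#' items are already recoded in the distributed data.
#'
#' If \pkg{mokken} is not installed the export cannot run and an error
#' explains that. A purely synthetic stand-in with the same layout and
#' similar population characteristics is shipped as
#' `system.file("extdata", "swmdk_synthetic.csv", package = "ClusterMokken")`
#' (see [swmdkSynthetic()]); it is generated data, not the questionnaire
#' sample, and reproduces none of its published statistics.
#'
#' @param path output CSV path (default `"swmdk.csv"`).
#' @param dataset name of the dataset inside \pkg{mokken} (default
#'   `"SWMDK"`).
#' @return `path`, invisibly.
#' @export
exportSwmdkFixture <- function(path = "swmdk.csv", dataset = "SWMDK") {
  if (!requireNamespace("mokken", quietly = TRUE)) {
    stop(
      "the 'mokken' package (which distributes the SWMDK data) is not ",
      "installed; install it and rerun, or use the synthetic stand-in ",
      "swmdk_synthetic.csv",
      call. = FALSE
    )
  }
  env <- new.env()
  utils::data(list = dataset, package = "mokken", envir = env)
  df <- as.data.frame(get(dataset, envir = env))
  numeric <- vapply(df, is.numeric, logical(1))
  itemCols <- names(df)[numeric & vapply(df, function(v) length(unique(v)) <= 10, logical(1))]
  groupCols <- setdiff(names(df), itemCols)
  if (length(groupCols) != 1L) {
    # fall back: a column named like a class/group identifier
    groupCols <- grep("class|group", names(df), ignore.case = TRUE, value = TRUE)[1]
    itemCols <- setdiff(names(df), groupCols)
  }
  out <- df[, c(itemCols, groupCols), drop = FALSE]
  names(out)[ncol(out)] <- "Class"
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the synthetic SWMDK stand-in data set
#'
#' Reads the shipped `swmdk_synthetic.csv`: a fully synthetic data set with
#' the same layout and similar population structure as the SWMDK
#' questionnaire sample (13 five-point items in a 7 + 6 two-dimensional
#' structure, 639 respondents in 30 groups), generated from the default
#' [multilevelGrmSpec()] population. It exists so that examples, tests and
#' the command-line interface have a realistic clustered input without
#' distributing the questionnaire data, and it reproduces none of the
#' published SWMDK statistics.
#'
#' @return An [ItemScores-class] object with 639 respondents, 13 items and
#'   30 groups.
#' @examples
#' x <- swmdkSynthetic()
#' x
#' @export
swmdkSynthetic <- function() {
  f <- system.file("extdata", "swmdk_synthetic.csv",
    package = "ClusterMokken", mustWork = TRUE
  )
  readItemScores(f, groupColumn = "Class")
}
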