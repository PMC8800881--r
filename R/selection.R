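#' @include testing.R uncertainty.R
NULL

# H_i of `target` within item subset `sub` (indices into X), plus its SE at
# the requested level. Used by the greedy criterion-2 evaluations.
itemStatWithin <- function(X, groups, sub, target, level, needSE = TRUE) {
  Xs <- X[, sub, drop = FALSE]
  core <- computeHcore(Xs)
  k <- match(target, sub)
  se <- NA_real_
  if (needSE) {
    IF <- influenceH(Xs, core)
    se <- influenceSE(IF, level = level, groups = groups)$seItem[k]
  }
  list(Hi = core$Hitem[k], se = unname(se), Htotal = core$Htotal, core = core)
}

#' Run the automated item selection procedure (AISP or T-AISP)
#'
#' Greedy partitioning of items into Mokken scales at a single lowerbound
#' \eqn{c}, in the classic point-estimate-guided form (AISP) or the
#' test-guided form (T-AISP) in which both Mokken-scale criteria are
#' evaluated by Wald z tests built from one-level or two-level standard
#' errors. The algorithm:
#'
#' 1. *Start a scale* with the pair maximising \eqn{\hat H_{ij}} among all
#'    pairs of unassigned items for which both criteria are accepted; if no
#'    pair qualifies, the procedure stops.
#' 2. *Extend the scale* repeatedly with the candidate item that has both
#'    criteria accepted and yields the highest total \eqn{\hat H} of the
#'    enlarged scale.
#' 3. *Start the next scale* from the leftover items, until none remain or
#'    none qualify.
#'
#' Criterion acceptance per method: the classic AISP accepts criterion 1
#' when \eqn{\Delta_{ij} \ge z_{crit}} (null \eqn{H_{ij} \le 0}) and
#' criterion 2 when \eqn{\Delta_i \ge z_{crit}} *and* the point estimate
#' \eqn{\hat H_i \ge c}; the T-AISP replaces both by Wald tests,
#' \eqn{z_{ij} \ge z_{crit}} (null \eqn{H_{ij} \le 0}) and
#' \eqn{z_i \ge z_{crit}} (null \eqn{H_i \le c}), so that the lowerbound
#' requirement itself is tested rather than read off the point estimate.
#' For the starting pair the item coefficient equals the pair coefficient,
#' and criterion 2 is evaluated on \eqn{\hat H_{ij}} accordingly.
#'
#' The critical value is Bonferroni-adjusted sequentially: a global counter
#' accumulates the number of criterion tests performed in all previous
#' steps plus the current step, and every test in the step uses
#' \eqn{z_{crit} = \Phi^{-1}(1 - \alpha/\mathrm{counter})}. The counter,
#' the critical value and each decision are logged in the trace.
#'
#' Ties are broken deterministically: among starting pairs with equal
#' \eqn{\hat H_{ij}} the lexicographically smallest item indices win; among
#' candidate items with equal enlarged-scale \eqn{\hat H}, the smallest
#' index wins. Items with zero sample variance are excluded up front with a
#' warning and reported as unscalable.
#'
#' @param x an [ItemScores-class] object or score matrix.
#' @param lowerbound the scalability lowerbound \eqn{c} (in \eqn{[0, 1)}).
#' @param alpha nominal significance level for the criterion tests.
#' @param method `"testGuided"` (T-AISP, the default) or `"classic"`.
#' @param level `"one"` or `"two"`; defaults to `"two"` when `x` carries a
#'   cluster design, else `"one"`. One-level tests on clustered data are
#'   allowed but warn loudly, since ignoring within-group dependency makes
#'   the standard errors of high-ICC items too small.
#' @param items optional subset of items to partition.
#' @return A [ScalePartition-class] object.
#' @examples
#' x <- simulateGrm(multilevelGrmSpec(nGroups = 20, groupSizes = 15, seed = 11))
#' p <- runAisp(x, lowerbound = 0.3)
#' scaleAssignment(p)
#' @seealso [lowerboundSweep()], [twoStepMSA()]
#' @export
runAisp <- function(x, lowerbound = 0.3, alpha = 0.05,
                    method = c("testGuided", "classic"), level = NULL,
                    items = NULL) {
  method <- match.arg(method)
  x <- asItemScores(x)
  if (!is.null(items)) x <- x[, items]
  X <- x@scores
  N <- nrow(X); J <- ncol(X)
  if (J < 2L) stop("item selection requires at least 2 items", call. = FALSE)
  if (lowerbound < 0 || lowerbound >= 1) stop("lowerbound must be in [0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  groups <- x@groups
  if (is.null(level)) level <- if (is.null(groups)) "one" else "two"
  level <- match.arg(level, c("one", "two"))
  if (level == "two") groups <- checkGroups(groups)
  if (level == "one" && !is.null(groups)) {
    warning(
      "running one-level selection on clustered data: within-group dependency ",
      "is ignored and standard errors of high-ICC items are likely too small",
      call. = FALSE
    )
  }
  assignment <- rep(0L, J)
  names(assignment) <- colnames(X)
  dg <- degenerateItems(X)
  if (length(dg)) {
    warning(sprintf(
      "item(s) %s have zero variance and are marked unscalable",
      paste(sQuote(colnames(X)[dg]), collapse = ", ")
    ), call. = FALSE)
  }
  usable <- setdiff(seq_len(J), dg)

  # pairwise statistics depend only on the two items involved: compute once
  pairStats <- NULL
  if (length(usable) >= 2L) {
    Xu <- X[, usable, drop = FALSE]
    core <- computeHcore(Xu)
    Hp <- core$Hpair
    if (method == "testGuided") {
      IF <- influenceH(Xu, core)
      seP <- influenceSE(IF, level = level, groups = groups)$sePair
    } else {
      seP <- NULL
    }
    sdv <- sqrt(diag(core$S))
    DeltaP <- core$S / tcrossprod(sdv) * sqrt(N - 1)
    diag(DeltaP) <- NA_real_
    pairStats <- list(map = usable, H = Hp, se = seP, Delta = DeltaP)
  }
  pH <- function(i, j) pairStats$H[match(i, pairStats$map), match(j, pairStats$map)]
  pSE <- function(i, j) pairStats$se[match(i, pairStats$map), match(j, pairStats$map)]
  pDelta <- function(i, j) pairStats$Delta[match(i, pairStats$map), match(j, pairStats$map)]

  crit1Pair <- function(i, j, zc) {
    if (method == "classic") pDelta(i, j) >= zc else pH(i, j) / pSE(i, j) >= zc
  }

  counter <- 0L
  traceRows <- list()
  logRow <- function(scale, phase, candidate, tests, zc, c1, c2, H, selected) {
    traceRows[[length(traceRows) + 1L]] <<- data.frame(
      scale = scale, phase = phase, candidate = candidate, tests = tests,
      counter = counter, zCrit = zc, criterion1 = c1, criterion2 = c2,
      H = H, selected = selected, stringsAsFactors = FALSE
    )
  }

  remaining <- usable
  scaleIdx <- 0L
  while (length(remaining) >= 2L) {
    ## Step 1: start a new scale
    pairs <- utils::combn(remaining, 2L)
    nP <- ncol(pairs)
    counter <- counter + 2L * nP
    zc <- stats::qnorm(1 - alpha / counter)
    best <- NULL
    for (p in seq_len(nP)) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      Hij <- pH(i, j)
      c1 <- isTRUE(crit1Pair(i, j, zc))
      c2 <- if (method == "classic") {
        isTRUE(pDelta(i, j) >= zc && Hij >= lowerbound)
      } else {
        isTRUE((Hij - lowerbound) / pSE(i, j) >= zc)
      }
      ok <- c1 && c2
      logRow(scaleIdx + 1L, "start",
        paste(colnames(X)[c(i, j)], collapse = "+"),
        2L, zc, c1, c2, Hij, FALSE
      )
      if (ok && (is.null(best) || Hij > best$H + 1e-12)) best <- list(i = i, j = j, H = Hij)
    }
    if (is.null(best)) break
    scaleIdx <- scaleIdx + 1L
    scale <- c(best$i, best$j)
    # mark selection of the starting pair in the trace
    traceRows[[length(traceRows) + 1L]] <- data.frame(
      scale = scaleIdx, phase = "startSelect",
      candidate = paste(colnames(X)[scale], collapse = "+"), tests = 0L,
      counter = counter, zCrit = zc, criterion1 = TRUE, criterion2 = TRUE,
      H = best$H, selected = TRUE, stringsAsFactors = FALSE
    )
    remaining <- setdiff(remaining, scale)

    ## Step 2: extend the scale
    repeat {
      cands <- remaining
      if (!length(cands)) break
      s <- length(scale)
      counter <- counter + length(cands) * (s + 1L)
      zc <- stats::qnorm(1 - alpha / counter)
      bestCand <- NULL
      for (t in cands) {
        c1 <- all(vapply(scale, function(m) isTRUE(crit1Pair(t, m, zc)), logical(1)))
        enlarged <- c(scale, t)
        if (method == "classic") {
          st <- itemStatWithin(X, groups, enlarged, t, level, needSE = FALSE)
          coreE <- st$core
          k <- match(t, enlarged)
          Ssub <- coreE$S
          sdvE <- sqrt(diag(Ssub))
          deltaT <- sum(Ssub[k, -k]) / (sdvE[k] * sum(sdvE[-k])) * sqrt(N - 1)
          c2 <- isTRUE(deltaT >= zc && st$Hi >= lowerbound)
        } else {
          st <- itemStatWithin(X, groups, enlarged, t, level, needSE = TRUE)
          c2 <- isTRUE((st$Hi - lowerbound) / st$se >= zc)
        }
        ok <- c1 && c2
        logRow(scaleIdx, "extend", colnames(X)[t], s + 1L, zc, c1, c2, st$Htotal, FALSE)
        if (ok && (is.null(bestCand) || st$Htotal > bestCand$H + 1e-12)) {
          bestCand <- list(t = t, H = st$Htotal)
        }
      }
      if (is.null(bestCand)) break
      scale <- c(scale, bestCand$t)
      remaining <- setdiff(remaining, bestCand$t)
      traceRows[[length(traceRows) + 1L]] <- data.frame(
        scale = scaleIdx, phase = "extendSelect",
        candidate = colnames(X)[bestCand$t], tests = 0L,
        counter = counter, zCrit = zc, criterion1 = TRUE, criterion2 = TRUE,
        H = bestCand$H, selected = TRUE, stringsAsFactors = FALSE
      )
    }
    assignment[scale] <- scaleIdx
  }
  trace <- if (length(traceRows)) do.call(rbind, traceRows) else data.frame(
    scale = integer(), phase = character(), candidate = character(),
    tests = integer(), counter = integer(), zCrit = numeric(),
    criterion1 = logical(), criterion2 = logical(), H = numeric(),
    selected = logical(), stringsAsFactors = FALSE
  )
  new("ScalePartition",
    assignment = assignment, lowerbound = lowerbound,
    method = method, level = level, alpha = alpha, trace = trace
  )
}

#' @describeIn runAisp extract the named scale-index vector from a partition.
#' @export
setMethod("scaleAssignment", "ScalePartition", function(x) x@assignment)

setMethod("show", "ScalePartition", function(object) {
  a <- object@assignment
  nsc <- max(a)
  cat(sprintf(
    "ScalePartition (%s, %s-level), c = %.2f, alpha = %.3g: %d scale(s), %d unscalable\n",
    if (object@method == "classic") "AISP" else "T-AISP",
    object@level, object@lowerbound, object@alpha, nsc, sum(a == 0L)
  ))
  for (s in seq_len(nsc)) {
    cat(sprintf("  scale %d: %s\n", s, paste(names(a)[a == s], collapse = ", ")))
  }
  if (any(a == 0L)) {
    cat("  unscalable:", paste(names(a)[a == 0L], collapse = ", "), "\n")
  }
  cat(sprintf("  tests performed: %d (Bonferroni counter)\n", sum(object@trace$tests)))
})

#' Run the item selection procedure over a grid of lowerbounds
#'
#' Applies [runAisp()] at each lowerbound of an increasing grid (by default
#' \eqn{c = 0, 0.05, \ldots, 0.55}) and collects the partitions into an
#' items-by-lowerbounds table of scale indices. Reading the table
#' column-wise shows how scales form and dissolve as the scalability
#' requirement tightens, which is the standard way to judge the stability
#' of candidate scales before choosing the final ones.
#'
#' @inheritParams runAisp
#' @param lowerbounds strictly increasing vector of lowerbounds in \eqn{[0, 1)}.
#' @return A [LowerboundSweep-class] object.
#' @examples
#' x <- simulateGrm(multilevelGrmSpec(nGroups = 20, groupSizes = 15, seed = 11))
#' sw <- lowerboundSweep(x, lowerbounds = c(0.1, 0.3, 0.5))
#' sweepTable(sw)
#' @export
lowerboundSweep <- function(x, lowerbounds = seq(0, 0.55, by = 0.05),
                            alpha = 0.05, method = c("testGuided", "classic"),
                            level = NULL, items = NULL) {
  method <- match.arg(method)
  if (is.unsorted(lowerbounds, strictly = TRUE)) {
    stop("lowerbounds must be strictly increasing", call. = FALSE)
  }
  x <- asItemScores(x)
  if (!is.null(items)) x <- x[, items]
  partitions <- vector("list", length(lowerbounds))
  for (k in seq_along(lowerbounds)) {
    partitions[[k]] <- withCallingHandlers(
      runAisp(x, lowerbound = lowerbounds[k], alpha = alpha, method = method,
        level = level
      ),
      warning = function(w) {
        if (k > 1L) invokeRestart("muffleWarning") # warn once per sweep
      }
    )
  }
  tab <- vapply(partitions, scaleAssignment, integer(nItems(x)))
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = nItems(x))
  dimnames(tab) <- list(itemLabels(x), sprintf("%.2f", lowerbounds))
  new("LowerboundSweep",
    partitions = partitions, table = tab, lowerbounds = lowerbounds
  )
}

#' @describeIn lowerboundSweep extract the items-by-lowerbounds scale-index
#'   table.
#' @export
setMethod("sweepTable", "LowerboundSweep", function(x) x@table)

setMethod("show", "LowerboundSweep", function(object) {
  p1 <- object@partitions[[1]]
  cat(sprintf(
    "LowerboundSweep (%s, %s-level): %d lowerbounds\n",
    if (p1@method == "classic") "AISP" else "T-AISP", p1@level,
    length(object@lowerbounds)
  ))
  print(object@table)
})
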