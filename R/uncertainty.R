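#' @include scalability.R
NULL

# Influence functions of every H coefficient with respect to the empirical
# distribution of score patterns. For an estimator T(F_N) the influence of
# respondent r is the Gateaux derivative of T at F_N in the direction of a
# point mass at r's pattern; the delta-method variance is then assembled
# from these influences (multinomial covariance for simple random samples,
# cluster-robust aggregation for clustered samples).
#
# The covariance part has closed-form influences; the maximum-covariance
# part (a piecewise-linear functional of the two margins) is differentiated
# by a one-sided forward difference in margin space, which is exact within
# each linearity region.
influenceH <- function(X, core, eps = 1e-6) {
  N <- nrow(X); J <- ncol(X)
  mu <- core$mu
  S <- core$S
  margins <- core$margins
  Smax <- core$covmaxPair
  C <- sweep(X, 2L, mu)
  pr <- pairIndex(J)
  P <- pr$n

  catIdx <- matrix(0L, N, J)
  for (jj in seq_len(J)) catIdx[, jj] <- match(X[, jj], margins[[jj]]$vals)

  IFS <- matrix(0, N, P)
  IFM <- matrix(0, N, P)
  for (p in seq_len(P)) {
    i <- pr$i[p]; j <- pr$j[p]
    IFS[, p] <- C[, i] * C[, j] - S[i, j]
    mi <- margins[[i]]; mj <- margins[[j]]
    exy0 <- comonotonicEXY(mi$vals, mi$p, mj$vals, mj$p)
    # directional derivatives of max covariance along (delta_k - margin)
    gI <- vapply(seq_along(mi$vals), function(k) {
      pk <- (1 - eps) * mi$p
      pk[k] <- pk[k] + eps
      dEXY <- (comonotonicEXY(mi$vals, pk, mj$vals, mj$p) - exy0) / eps
      dEXY - (mi$vals[k] - mu[i]) * mu[j]
    }, numeric(1))
    gJ <- vapply(seq_along(mj$vals), function(k) {
      pk <- (1 - eps) * mj$p
      pk[k] <- pk[k] + eps
      dEXY <- (comonotonicEXY(mi$vals, mi$p, mj$vals, pk) - exy0) / eps
      dEXY - (mj$vals[k] - mu[j]) * mu[i]
    }, numeric(1))
    IFM[, p] <- gI[catIdx[, i]] + gJ[catIdx[, j]]
  }

  HpairVec <- core$Hpair[cbind(pr$i, pr$j)]
  SmaxVec <- Smax[cbind(pr$i, pr$j)]
  IFHpair <- sweep(IFS - sweep(IFM, 2L, HpairVec, `*`), 2L, SmaxVec, `/`)

  # aggregate pair influences to item level via the pair-item incidence
  A <- matrix(0, P, J)
  A[cbind(seq_len(P), pr$i)] <- 1
  A[cbind(seq_len(P), pr$j)] <- 1
  sumIFS <- IFS %*% A
  sumIFM <- IFM %*% A
  denomItem <- as.numeric(SmaxVec %*% A)
  IFHitem <- sweep(sumIFS - sweep(sumIFM, 2L, core$Hitem, `*`), 2L, denomItem, `/`)

  denomTot <- sum(SmaxVec)
  IFHtotal <- (rowSums(IFS) - core$Htotal * rowSums(IFM)) / denomTot

  list(
    pair = IFHpair, item = IFHitem, total = IFHtotal,
    pairs = pr, J = J, N = N
  )
}

# Turn influence functions into standard errors.
#  one-level: Var = (1/N^2) sum_r IF_r^2            (multinomial delta method)
#  two-level: Var = (G/(G-1)) (1/N^2) sum_g (sum_{r in g} IF_r)^2
# With singleton groups the two coincide up to the factor G/(G-1).
influenceSE <- function(IF, level, groups = NULL) {
  N <- IF$N; J <- IF$J
  seVec <- function(M) {
    if (level == "one") {
      sqrt(colSums(M^2)) / N
    } else {
      GS <- rowsum(M, groups)
      G <- nrow(GS)
      sqrt(G / (G - 1) * colSums(GS^2)) / N
    }
  }
  seP <- seVec(IF$pair)
  sePair <- matrix(NA_real_, J, J)
  sePair[cbind(IF$pairs$i, IF$pairs$j)] <- seP
  sePair[cbind(IF$pairs$j, IF$pairs$i)] <- seP
  seItem <- seVec(IF$item)
  seTotal <- seVec(matrix(IF$total, ncol = 1))
  names(seItem) <- colnames(IF$item)
  list(sePair = sePair, seItem = seItem, seTotal = as.numeric(seTotal))
}

#' Cluster-bootstrap standard errors for scalability coefficients
#'
#' Nonparametric bootstrap in which whole groups (clusters) are resampled
#' with replacement, all scalability coefficients are recomputed on each
#' replicate data set, and the standard deviations across replicates are
#' returned as standard errors. This is the model-free ground truth against
#' which the two-level delta-method standard errors of [scalability()] can
#' be validated. Replicates in which an item becomes degenerate (zero
#' variance) are redrawn, up to `10 * B` attempts in total.
#'
#' @param x an [ItemScores-class] object with a cluster design (at least two
#'   groups).
#' @param B number of bootstrap replicates (at least 200).
#' @param seed integer RNG seed; results are bit-reproducible given the seed.
#' @param items optional subset of items.
#' @return A [ScalabilityResults-class] object whose point estimates come
#'   from the original data and whose standard errors are bootstrap SDs
#'   (`seMethod == "bootstrap"`).
#' @examples
#' x <- simulateGrm(multilevelGrmSpec(nGroups = 12, groupSizes = 10, seed = 3))
#' b <- clusterBootstrapSE(x, B = 200, seed = 42)
#' totalSE(b)
#' @export
clusterBootstrapSE <- function(x, B = 1000L, seed = 1L, items = NULL) {
  x <- asItemScores(x)
  if (!is.null(items)) x <- x[, items]
  if (B < 200L) stop("B must be at least 200 for stable bootstrap SEs", call. = FALSE)
  groups <- checkGroups(x@groups)
  X <- x@scores
  stopIfDegenerate(X)
  core <- computeHcore(X)
  lev <- levels(groups)
  G <- length(lev)
  rowsByGroup <- split(seq_len(nrow(X)), groups)
  pr <- pairIndex(ncol(X))
  reps <- matrix(NA_real_, B, pr$n + ncol(X) + 1L)
  withSeed(seed, {
    b <- 1L
    attempts <- 0L
    while (b <= B) {
      attempts <- attempts + 1L
      if (attempts > 10L * B) {
        stop("too many degenerate bootstrap replicates; data are near-degenerate", call. = FALSE)
      }
      take <- sample.int(G, G, replace = TRUE)
      rows <- unlist(rowsByGroup[take], use.names = FALSE)
      Xb <- X[rows, , drop = FALSE]
      if (length(degenerateItems(Xb))) next
      cb <- computeHcore(Xb)
      reps[b, ] <- c(cb$Hpair[cbind(pr$i, pr$j)], cb$Hitem, cb$Htotal)
      b <- b + 1L
    }
  })
  sds <- apply(reps, 2L, stats::sd)
  J <- ncol(X)
  sePair <- matrix(NA_real_, J, J, dimnames = dimnames(core$Hpair))
  sePair[cbind(pr$i, pr$j)] <- sds[seq_len(pr$n)]
  sePair[cbind(pr$j, pr$i)] <- sds[seq_len(pr$n)]
  seItem <- sds[pr$n + seq_len(J)]
  names(seItem) <- colnames(X)
  new("ScalabilityResults",
    Hpair = core$Hpair, Hitem = core$Hitem, Htotal = core$Htotal,
    covPair = core$covPair, covmaxPair = core$covmaxPair,
    sePair = sePair, seItem = seItem, seTotal = sds[length(sds)],
    level = "two", seMethod = "bootstrap",
    N = nrow(X), J = as.integer(J), B = as.integer(B), seed = as.integer(seed)
  )
}
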