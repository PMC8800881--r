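#' @include itemScores.R scalability.R
NULL

#' Specify a multilevel graded response model
#'
#' Builds the population specification used by [simulateGrm()] and
#' [populationH()]: respondents nested in groups share a group-level latent
#' trait component, \eqn{\theta_{gr} = \tau_g + \varepsilon_{gr}} with
#' \eqn{\mathrm{Var}(\tau) = \rho} (the latent intraclass correlation) and
#' \eqn{\mathrm{Var}(\varepsilon) = 1 - \rho}, so the total latent variance
#' is normalised to 1. Item scores follow a graded response model: the
#' cumulative category probabilities are logistic (or probit) in
#' \eqn{a_i(\theta - b_{ik})} with per-item discrimination \eqn{a_i > 0}
#' and strictly increasing thresholds \eqn{b_{i1} < \dots < b_{im}}.
#' Two-dimensional specifications assign each item to one of two latent
#' dimensions correlated at `dimCor` (applied at both levels, so each
#' dimension keeps latent ICC \eqn{\rho}).
#'
#' The defaults emulate a typical clustered quality-of-life questionnaire
#' survey: 13 five-category Likert items split over two correlated
#' dimensions (7 + 6 items), 30 groups of 21 respondents, discriminations
#' around 2.4 (yielding within-dimension total \eqn{H} near 0.6, a strong
#' scale), and a latent ICC of 0.25, which attenuates to an observed
#' total-score ICC near 0.17 — within the 0--0.5 range commonly reported
#' for quality-of-life measures.
#'
#' @param nGroups number of groups \eqn{G}.
#' @param groupSizes group sizes (scalar or length-`nGroups` vector).
#' @param icc latent intraclass correlation \eqn{\rho \in [0, 1)}.
#' @param discrimination per-item discriminations \eqn{a_i > 0}; its length
#'   sets the number of items \eqn{J}.
#' @param thresholds list of \eqn{J} strictly increasing numeric vectors,
#'   or `NULL` for evenly spaced defaults (4 thresholds, i.e. 5 categories,
#'   item locations spread over \eqn{[-0.5, 0.5]}).
#' @param itemDim integer vector in \{1, 2\} assigning items to dimensions;
#'   the default splits the items into two blocks (first `ceiling(J/2)`
#'   items on dimension 1). Pass `itemDim = 1` for a unidimensional model.
#' @param dimCor correlation between the two latent dimensions.
#' @param link `"logistic"` or `"probit"`.
#' @param minScore lowest category score (default 1, giving 1..5 scores
#'   with the default thresholds).
#' @param seed default RNG seed used by [simulateGrm()] when no seed is
#'   passed there.
#' @return A list of class `"MultilevelGrmSpec"`.
#' @examples
#' spec <- multilevelGrmSpec(nGroups = 10, groupSizes = 20, icc = 0.3)
#' x <- simulateGrm(spec, seed = 1)
#' @export
multilevelGrmSpec <- function(nGroups = 30L, groupSizes = 21L, icc = 0.25,
                              discrimination = rep(c(2.0, 2.4, 2.8), length.out = 13L),
                              thresholds = NULL, itemDim = NULL, dimCor = 0.4,
                              link = c("logistic", "probit"), minScore = 1L,
                              seed = NULL) {
  link <- match.arg(link)
  J <- length(discrimination)
  if (J < 2L) stop("at least 2 items are required", call. = FALSE)
  if (any(discrimination <= 0)) stop("discriminations must be positive", call. = FALSE)
  if (icc < 0 || icc >= 1) stop("icc must be in [0, 1)", call. = FALSE)
  if (abs(dimCor) > 1) stop("dimCor must be in [-1, 1]", call. = FALSE)
  groupSizes <- as.integer(rep_len(groupSizes, nGroups))
  if (any(groupSizes < 1L)) stop("group sizes must be at least 1", call. = FALSE)
  if (is.null(thresholds)) {
    loc <- if (J > 1L) seq(-0.7, 0.3, length.out = J) else 0
    thresholds <- lapply(loc, function(l) l + c(-1.5, -0.5, 0.5, 1.5))
  }
  if (length(thresholds) != J) stop("thresholds must have one vector per item", call. = FALSE)
  for (b in thresholds) {
    if (is.unsorted(b, strictly = TRUE)) {
      stop("thresholds must be strictly increasing within each item", call. = FALSE)
    }
  }
  if (is.null(itemDim)) {
    itemDim <- rep(c(1L, 2L), c(ceiling(J / 2), floor(J / 2)))
  }
  itemDim <- as.integer(rep_len(itemDim, J))
  if (!all(itemDim %in% c(1L, 2L))) stop("itemDim entries must be 1 or 2", call. = FALSE)
  structure(
    list(
      nGroups = as.integer(nGroups), groupSizes = groupSizes, icc = icc,
      discrimination = discrimination, thresholds = thresholds,
      itemDim = itemDim, nDim = length(unique(itemDim)), dimCor = dimCor,
      link = link, minScore = as.integer(minScore), seed = seed
    ),
    class = "MultilevelGrmSpec"
  )
}

#' @export
print.MultilevelGrmSpec <- function(x, ...) {
  cat(sprintf(
    "MultilevelGrmSpec: %d items (%d categories), %d groups (N = %d), latent ICC = %.2f, %d dimension(s)%s, %s link\n",
    length(x$discrimination), length(x$thresholds[[1]]) + 1L, x$nGroups,
    sum(x$groupSizes), x$icc, x$nDim,
    if (x$nDim == 2L) sprintf(" (cor %.2f)", x$dimCor) else "", x$link
  ))
  invisible(x)
}

linkFun <- function(link) if (link == "logistic") stats::plogis else stats::pnorm

#' Simulate clustered polytomous item scores
#'
#' Draws one data set from a [multilevelGrmSpec()] population: group latent
#' effects \eqn{\tau_g \sim N(0, \rho)}, respondent deviations
#' \eqn{\varepsilon_{gr} \sim N(0, 1-\rho)}, and item scores from the graded
#' response model. Fully reproducible given the seed.
#'
#' @param spec a `"MultilevelGrmSpec"` object.
#' @param seed integer RNG seed; defaults to the spec's `seed`, or 1.
#' @return An [ItemScores-class] object carrying the group design.
#' @examples
#' x <- simulateGrm(multilevelGrmSpec(nGroups = 5, groupSizes = 8), seed = 2)
#' dim(x)
#' @export
simulateGrm <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "MultilevelGrmSpec"))
  if (is.null(seed)) seed <- if (is.null(spec$seed)) 1L else spec$seed
  G <- spec$nGroups
  ng <- spec$groupSizes
  N <- sum(ng)
  J <- length(spec$discrimination)
  D <- spec$nDim
  Rchol <- if (D == 2L) {
    chol(matrix(c(1, spec$dimCor, spec$dimCor, 1), 2L))
  } else {
    matrix(1, 1L, 1L)
  }
  cdf <- linkFun(spec$link)
  withSeed(seed, {
    tau <- matrix(stats::rnorm(G * D), G, D) %*% Rchol * sqrt(spec$icc)
    eps <- matrix(stats::rnorm(N * D), N, D) %*% Rchol * sqrt(1 - spec$icc)
    gidx <- rep(seq_len(G), ng)
    theta <- tau[gidx, , drop = FALSE] + eps
    X <- matrix(0L, N, J)
    for (jj in seq_len(J)) {
      th <- theta[, spec$itemDim[jj]]
      u <- stats::runif(N)
      sc <- rep(spec$minScore, N)
      for (b in spec$thresholds[[jj]]) {
        sc <- sc + (u <= cdf(spec$discrimination[jj] * (th - b)))
      }
      X[, jj] <- sc
    }
    colnames(X) <- paste0("I", seq_len(J))
    m <- length(spec$thresholds[[1]])
    ItemScores(X,
      groups = factor(paste0("g", gidx), levels = paste0("g", seq_len(G))),
      minScore = spec$minScore,
      maxScore = spec$minScore + vapply(spec$thresholds, length, integer(1))
    )
  })
}

# Category probability matrix of item jj at latent values `th` (vector):
# rows = th nodes, columns = categories minScore .. minScore + m.
grmCatProbs <- function(spec, jj, th) {
  cdf <- linkFun(spec$link)
  a <- spec$discrimination[jj]
  b <- spec$thresholds[[jj]]
  cum <- vapply(b, function(bk) cdf(a * (th - bk)), numeric(length(th)))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = length(th))
  cbind(1, cum) - cbind(cum, 0)
}

#' Population scalability coefficients of a graded response model
#'
#' Computes the model-implied joint category probabilities of every item
#' pair by numerical integration over the latent trait distribution (a
#' dense Gaussian quadrature grid; bivariate for two-dimensional
#' specifications), and from them the population covariances, maximum
#' covariances given the model-implied margins, and hence the population
#' \eqn{H_{ij}}, \eqn{H_i} and \eqn{H} values. These serve as ground truth
#' for validating sample estimates. Integration accuracy is verified by
#' recomputing on a coarser grid; a discrepancy above `tol` raises an error.
#'
#' @param spec a `"MultilevelGrmSpec"` object (the grouping part is
#'   irrelevant: the marginal latent distribution is standard normal).
#' @param gridPoints number of quadrature nodes per dimension.
#' @param tol integration-accuracy tolerance on the total coefficient.
#' @return A list with `Hpair` (\eqn{J \times J}, diagonal `NA`), `Hitem`,
#'   `Htotal`, and the underlying `covPair` and `covmaxPair` tables.
#' @examples
#' spec <- multilevelGrmSpec(discrimination = rep(1.5, 4))
#' populationH(spec)$Htotal
#' @export
populationH <- function(spec, gridPoints = 401L, tol = 1e-4) {
  stopifnot(inherits(spec, "MultilevelGrmSpec"))
  h1 <- populationHgrid(spec, gridPoints)
  h0 <- populationHgrid(spec, max(101L, gridPoints %/% 2L))
  if (abs(h1$Htotal - h0$Htotal) > tol) {
    stop(sprintf(
      "population H integration did not converge (grid %d vs %d: %.6f vs %.6f)",
      gridPoints, max(101L, gridPoints %/% 2L), h1$Htotal, h0$Htotal
    ), call. = FALSE)
  }
  h1
}

populationHgrid <- function(spec, gridPoints) {
  J <- length(spec$discrimination)
  lim <- 8
  th <- seq(-lim, lim, length.out = gridPoints)
  w <- stats::dnorm(th)
  w <- w / sum(w)
  catProbs <- lapply(seq_len(J), function(jj) grmCatProbs(spec, jj, th))
  vals <- lapply(seq_len(J), function(jj) {
    spec$minScore + 0:(length(spec$thresholds[[jj]]))
  })
  margins <- lapply(seq_len(J), function(jj) as.numeric(crossprod(w, catProbs[[jj]])))
  mu <- vapply(seq_len(J), function(jj) sum(margins[[jj]] * vals[[jj]]), numeric(1))

  twoDim <- spec$nDim == 2L
  if (twoDim) {
    r <- spec$dimCor
    # joint density weights on the product grid, w2[u, v] for (theta1, theta2)
    dth <- th[2] - th[1]
    w2 <- outer(th, th, function(x, y) {
      stats::dnorm(x) * stats::dnorm((y - r * x) / sqrt(1 - r^2)) / sqrt(1 - r^2)
    })
    w2 <- w2 / sum(w2)
  }

  S <- matrix(0, J, J)
  Smax <- matrix(0, J, J)
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      sameDim <- !twoDim || spec$itemDim[i] == spec$itemDim[j]
      if (sameDim) {
        Exy <- sum(w * (catProbs[[i]] %*% vals[[i]]) * (catProbs[[j]] %*% vals[[j]]))
      } else {
        ei <- as.numeric(catProbs[[i]] %*% vals[[i]]) # E[Xi | theta1] on grid
        ej <- as.numeric(catProbs[[j]] %*% vals[[j]]) # E[Xj | theta2] on grid
        Exy <- as.numeric(ei %*% w2 %*% ej)
      }
      S[i, j] <- S[j, i] <- Exy - mu[i] * mu[j]
      Smax[i, j] <- Smax[j, i] <- maxCovarianceP(
        vals[[i]], margins[[i]], vals[[j]], margins[[j]]
      )
    }
  }
  up <- upper.tri(S)
  Hpair <- S / Smax
  diag(Hpair) <- NA_real_
  Hitem <- (rowSums(S)) / rowSums(Smax)
  Htotal <- sum(S[up]) / sum(Smax[up])
  labs <- paste0("I", seq_len(J))
  dimnames(Hpair) <- list(labs, labs)
  names(Hitem) <- labs
  covPair <- S
  diag(covPair) <- NA_real_
  covmaxPair <- Smax
  diag(covmaxPair) <- NA_real_
  list(
    Hpair = Hpair, Hitem = Hitem, Htotal = Htotal,
    covPair = covPair, covmaxPair = covmaxPair
  )
}
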