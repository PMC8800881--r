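# Independent oracles used to validate the package implementations.
# These deliberately recompute everything from first principles with
# simple (slow) code paths that share nothing with the package internals.

# Random nondegenerate integer score matrix.
randomScores <- function(N, J, cats = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    X <- matrix(sample.int(cats, N * J, replace = TRUE) - 1L, N, J)
    if (all(apply(X, 2, function(c) length(unique(c)) > 1))) break
  }
  colnames(X) <- paste0("I", seq_len(J))
  X
}

# Population-style (N denominator) covariance.
covN <- function(x, y) mean(x * y) - mean(x) * mean(y)

# Maximum covariance by sorting both score vectors in the same order and
# pairing rank by rank (the comonotonic / perfect Guttman arrangement).
sortMaxCov <- function(x, y) covN(sort(x, decreasing = TRUE), sort(y, decreasing = TRUE))

# Maximum covariance by exhaustive search over every integer joint table
# with the observed margins. Feasible only for small N and few categories.
bruteMaxCov <- function(x, y) {
  tx <- table(x)
  ty <- table(y)
  vx <- as.numeric(names(tx))
  vy <- as.numeric(names(ty))
  rx <- as.integer(tx)
  cy <- as.integer(ty)
  N <- sum(rx)
  best <- -Inf
  K <- length(rx)
  L <- length(cy)
  cell <- matrix(0L, K, L)
  rec <- function(k, l, rowLeft, colLeft) {
    if (k > K) {
      exy <- sum(cell * outer(vx, vy)) / N
      cv <- exy - sum(rx * vx) / N * sum(cy * vy) / N
      if (cv > best) best <<- cv
      return(invisible(NULL))
    }
    if (l == L) { # last column of the row is forced
      v <- rowLeft
      if (v <= colLeft[L]) {
        cell[k, L] <<- v
        cl <- colLeft
        cl[L] <- cl[L] - v
        rec(k + 1L, 1L, rx[min(k + 1L, K)], cl)
        cell[k, L] <<- 0L
      }
      return(invisible(NULL))
    }
    for (v in 0:min(rowLeft, colLeft[l])) {
      cell[k, l] <<- v
      cl <- colLeft
      cl[l] <- cl[l] - v
      rec(k, l + 1L, rowLeft - v, cl)
      cell[k, l] <<- 0L
    }
  }
  rec(1L, 1L, rx[1], cy)
  best
}

# All H coefficients recomputed by direct tabulation.
oracleH <- function(X) {
  J <- ncol(X)
  S <- matrix(0, J, J)
  M <- matrix(0, J, J)
  for (i in 1:J) {
    for (j in 1:J) {
      if (i == j) next
      S[i, j] <- covN(X[, i], X[, j])
      M[i, j] <- sortMaxCov(X[, i], X[, j])
    }
  }
  Hpair <- S / M
  diag(Hpair) <- NA
  Hitem <- rowSums(S) / rowSums(M)
  up <- upper.tri(S)
  list(Hpair = Hpair, Hitem = Hitem, Htotal = sum(S[up]) / sum(M[up]))
}

# Nonparametric row-resampling bootstrap SE of the total H (one-level oracle).
rowBootstrapSE <- function(X, B = 600, seed = 1) {
  set.seed(seed)
  reps <- replicate(B, {
    repeat {
      Xb <- X[sample.int(nrow(X), replace = TRUE), , drop = FALSE]
      if (all(apply(Xb, 2, function(c) length(unique(c)) > 1))) break
    }
    oracleH(Xb)$Htotal
  })
  sd(reps)
}

# Independent greedy AISP trace: reimplements the selection logic with
# plain loops, reusing only low-level statistics recomputed here (classic)
# or the package's standard errors (test-guided), never its selection code.
oracleAisp <- function(X, c, alpha = 0.05, method = "classic",
                       groups = NULL, level = "one") {
  J <- ncol(X)
  N <- nrow(X)
  xobj <- ClusterMokken::ItemScores(X, groups = groups)
  seOf <- function(items, target = NULL) {
    h <- ClusterMokken::scalability(xobj,
      level = level, items = items, warnLevelOne = FALSE
    )
    h
  }
  pairH <- function(i, j) oracleH(X[, c(i, j)])$Htotal
  pairSEmat <- if (method == "testGuided") {
    ClusterMokken::pairSE(ClusterMokken::scalability(xobj,
      level = level, warnLevelOne = FALSE
    ))
  } else {
    NULL
  }
  assignment <- rep(0L, J)
  remaining <- 1:J
  counter <- 0
  sIdx <- 0L
  crit1 <- function(i, j, zc) {
    if (method == "classic") {
      cor(X[, i], X[, j]) * sqrt(N - 1) >= zc
    } else {
      pairH(i, j) / pairSEmat[i, j] >= zc
    }
  }
  while (length(remaining) >= 2) {
    prs <- combn(remaining, 2)
    counter <- counter + 2 * ncol(prs)
    zc <- qnorm(1 - alpha / counter)
    best <- NULL
    for (p in seq_len(ncol(prs))) {
      i <- prs[1, p]; j <- prs[2, p]
      Hij <- pairH(i, j)
      ok1 <- crit1(i, j, zc)
      ok2 <- if (method == "classic") {
        crit1(i, j, zc) && Hij >= c
      } else {
        (Hij - c) / pairSEmat[i, j] >= zc
      }
      if (isTRUE(ok1 && ok2) && (is.null(best) || Hij > best$H + 1e-12)) {
        best <- list(i = i, j = j, H = Hij)
      }
    }
    if (is.null(best)) break
    sIdx <- sIdx + 1L
    scale <- c(best$i, best$j)
    remaining <- setdiff(remaining, scale)
    repeat {
      if (!length(remaining)) break
      s <- length(scale)
      counter <- counter + length(remaining) * (s + 1)
      zc <- qnorm(1 - alpha / counter)
      bestC <- NULL
      for (t in remaining) {
        ok1 <- all(sapply(scale, function(m) crit1(t, m, zc)))
        enlarged <- c(scale, t)
        oh <- oracleH(X[, enlarged])
        k <- match(t, enlarged)
        Hi <- oh$Hitem[k]
        if (method == "classic") {
          # Delta_i within the enlarged scale
          sub <- X[, enlarged, drop = FALSE]
          sdv <- apply(sub, 2, function(v) sqrt(covN(v, v)))
          Sti <- sum(sapply(seq_along(enlarged)[-k], function(q) covN(sub[, k], sub[, q])))
          deltaT <- Sti / (sdv[k] * sum(sdv[-k])) * sqrt(N - 1)
          ok2 <- deltaT >= zc && Hi >= c
        } else {
          h <- ClusterMokken::scalability(xobj,
            level = level, items = enlarged, warnLevelOne = FALSE
          )
          ok2 <- (Hi - c) / ClusterMokken::itemSE(h)[k] >= zc
        }
        if (isTRUE(ok1 && ok2) && (is.null(bestC) || oh$Htotal > bestC$H + 1e-12)) {
          bestC <- list(t = t, H = oh$Htotal)
        }
      }
      if (is.null(bestC)) break
      scale <- c(scale, bestC$t)
      remaining <- setdiff(remaining, bestC$t)
    }
    assignment[scale] <- sIdx
  }
  names(assignment) <- colnames(X)
  assignment
}
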