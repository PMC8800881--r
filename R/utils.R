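#' @include AllGenerics.R
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Indices of items with zero sample variance.
degenerateItems <- function(X) {
  which(apply(X, 2, function(col) length(unique(col)) < 2L))
}

stopIfDegenerate <- function(X, context = "scalability") {
  dg <- degenerateItems(X)
  if (length(dg)) {
    stop(sprintf(
      "item(s) %s have zero sample variance; %s coefficients are undefined (maximum covariance is 0)",
      paste(sQuote(colnames(X)[dg]), collapse = ", "), context
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# Upper-triangle pair index bookkeeping for J items: pairs in column-major
# combn(J, 2) order.
pairIndex <- function(J) {
  idx <- utils::combn(J, 2L)
  list(i = idx[1L, ], j = idx[2L, ], n = ncol(idx))
}

checkGroups <- function(groups, minGroups = 2L) {
  if (is.null(groups)) {
    stop("a group design is required for two-level / clustered computations", call. = FALSE)
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < minGroups) {
    stop(sprintf("at least %d groups are required (got %d)", minGroups, nlevels(groups)),
      call. = FALSE
    )
  }
  groups
}
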