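#' @importFrom stats rnorm runif rgamma rexp var cor pt quantile hclust cutree
#'   as.dist pchisq sd
#' @importFrom methods new validObject is slot
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route their randomness through this so no call touches global state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Validate a beta-value matrix: numeric, no NAs, values in [0,1], unique
# dimnames. Returns the matrix (with dimnames filled in if absent).
checkBetaMatrix <- function(V, what = "V") {
  if (!is.matrix(V) || !is.numeric(V)) {
    stop(sprintf("'%s' must be a numeric matrix of beta values", what))
  }
  if (anyNA(V)) {
    stop(sprintf("'%s' contains missing values; impute or filter upstream", what))
  }
  if (min(V) < 0 || max(V) > 1) {
    stop(sprintf("'%s' has values outside [0,1]", what))
  }
  if (is.null(rownames(V))) {
    rownames(V) <- sprintf("probe_%d", seq_len(nrow(V)))
  }
  if (is.null(colnames(V))) {
    colnames(V) <- sprintf("sample_%d", seq_len(ncol(V)))
  }
  if (anyDuplicated(rownames(V))) stop(sprintf("duplicate probe ids in '%s'", what))
  if (anyDuplicated(colnames(V))) stop(sprintf("duplicate sample ids in '%s'", what))
  V
}

# Dirichlet draw: n vectors for one alpha parameter vector, rows sum to 1.
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Pairwise cosine distance (1 - cosine similarity) between the columns of X.
cosineDistance <- function(X) {
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) stop("zero-norm column in cosine distance computation")
  S <- crossprod(sweep(X, 2, nrm, "/"))
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

frobenius <- function(M) sqrt(sum(M^2))
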