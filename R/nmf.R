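#' Random initialization of constrained NMF factors
#'
#' Draws `W` and `H` entrywise from U(0,1) and normalizes the columns of `H`
#' to sum to 1, the starting point required by the constrained multiplicative
#' scheme.
#'
#' @param V beta-value matrix (probes x samples) being factorized; only its
#'   dimensions are used.
#' @param k number of components, `1 <= k <= min(dim(V))`.
#' @param seed integer seed; identical seeds give identical factors.
#' @return list with `W` (probes x k) and `H` (k x samples).
#' @export
initFactors <- function(V, k, seed) {
  V <- checkBetaMatrix(V)
  if (k < 1 || k > min(dim(V))) {
    stop(sprintf("k = %d out of range [1, %d]", k, min(dim(V))))
  }
  withSeed(seed, {
    W <- matrix(runif(nrow(V) * k), nrow(V), k)
    H <- matrix(runif(k * ncol(V)), k, ncol(V))
    H <- sweep(H, 2, colSums(H), "/")
    dimnames(W) <- list(rownames(V), sprintf("component_%d", seq_len(k)))
    dimnames(H) <- list(colnames(W), colnames(V))
    list(W = W, H = H)
  })
}

#' One constrained multiplicative update step
#'
#' Applies, in order: the multiplicative W-update
#' `W <- W * (V H') / (W H H')`, the corrective clip `W[W > 1] <- 1`, the
#' H-update `H <- H * (W' V) / (W' W H)` using the clipped `W`, and the
#' renormalization of the columns of `H` to sum to 1. A small `eps` guards
#' every denominator; degenerate rows or columns are absorbed, never raised.
#'
#' @param V beta matrix (probes x samples).
#' @param W current basis (probes x k), non-negative.
#' @param H current coefficients (k x samples), non-negative.
#' @param eps denominator guard, default 1e-12.
#' @return list with updated `W` (in `[0, 1]`) and `H` (columns sum to 1).
#' @export
multiplicativeStep <- function(V, W, H, eps = 1e-12) {
  if (eps <= 0) stop("eps must be > 0")
  W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
  W[W > 1] <- 1
  H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
  H <- sweep(H, 2, colSums(H) + eps, "/")
  list(W = W, H = H)
}

#' Frobenius reconstruction error
#'
#' `||V - W H||_F`, the objective monitored for convergence.
#'
#' @param V beta matrix.
#' @param W basis matrix.
#' @param H coefficient matrix.
#' @return non-negative scalar.
#' @export
reconstructionError <- function(V, W, H) {
  if (nrow(V) != nrow(W) || ncol(V) != ncol(H) || ncol(W) != nrow(H)) {
    stop("shapes of V, W, H do not conform")
  }
  frobenius(V - W %*% H)
}

#' Fit constrained NMF by multiplicative updates with corrective rules
#'
#' Factorizes a beta-value matrix as `V ~ W H` with `W` in `[0, 1]` (so its
#' columns read as methylation signatures) and the columns of `H`
#' non-negative and summing to 1 (per-sample signature contributions).
#' Iterates [multiplicativeStep()] from a [initFactors()] start until the
#' relative change of the Frobenius objective between consecutive iterations
#' falls below `tolRel` (default 1e-4, i.e. 0.01%) or `maxIter` is reached.
#' Non-convergence is reported in the returned object, not raised.
#'
#' @param V beta matrix (probes x samples), no missing values.
#' @param k number of components.
#' @param tolRel relative-change convergence tolerance (default `1e-4`).
#' @param maxIter iteration cap (default 10000).
#' @param seed integer seed for the random initialization.
#' @param eps denominator guard passed to [multiplicativeStep()].
#' @param checkConstraints when TRUE, assert after every iteration that
#'   `W` stays in `[0, 1]` and each column of `H` sums to 1 within 1e-8
#'   (debugging aid; small cost).
#' @return an [NMFFit-class] object.
#' @examples
#' refs <- makeReferenceProfiles(3, 120, 10, 0.4, seed = 1)
#' mix <- makeBulkMixtures(refs$means, 30, rep(1, 3), noiseSd = 0, seed = 11)
#' fit <- fitNMF(mix$V, k = 3, seed = 2)
#' fit
#' @export
fitNMF <- function(V, k, tolRel = 1e-4, maxIter = 10000L, seed,
                   eps = 1e-12, checkConstraints = FALSE) {
  V <- checkBetaMatrix(V)
  fac <- initFactors(V, k, seed)
  W <- fac$W
  H <- fac$H
  trace <- numeric(maxIter)
  converged <- FALSE
  iter <- 0L
  prev <- frobenius(V - W %*% H)
  while (iter < maxIter) {
    iter <- iter + 1L
    st <- multiplicativeStep(V, W, H, eps = eps)
    W <- st$W
    H <- st$H
    if (checkConstraints) {
      stopifnot(
        max(W) <= 1, min(W) >= 0,
        max(abs(colSums(H) - 1)) <= 1e-8
      )
    }
    err <- frobenius(V - W %*% H)
    trace[iter] <- err
    if (prev > 0 && abs(prev - err) / prev < tolRel) {
      converged <- TRUE
      break
    }
    if (prev == 0) {
      converged <- TRUE
      break
    }
    prev <- err
  }
  dimnames(W) <- dimnames(fac$W)
  dimnames(H) <- dimnames(fac$H)
  new("NMFFit",
    W = W, H = H, objectiveTrace = trace[seq_len(iter)],
    nIter = iter, converged = converged, tolRel = tolRel,
    seed = as.integer(seed)
  )
}
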