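#' Owen-Perry bicrossvalidation for NMF rank selection
#'
#' Selects the number of components by held-out-quadrant cross-validation.
#' Rows and columns of `V` are randomly permuted once, then split in half,
#' carving the matrix into four quadrants. Each of the four quadrants in
#' turn plays the held-out role `A`, with `B` its row-block partner, `C` its
#' column-block partner and `D` the diagonal complement. A constrained NMF
#' ([fitNMF()]) is fit on `D` alone and `A` is predicted through the
#' self-consistency identity `A ~ (B H_D^+)(W_D^+ C)`, where `Z^+` is the
#' Moore-Penrose pseudoinverse. The rank minimizing the mean of the four
#' Frobenius prediction errors wins; ties go to the smallest rank.
#'
#' @param V beta matrix (probes x samples).
#' @param kValues integer vector of candidate ranks; every value must be at
#'   most half the smaller dimension of `V` so quadrant `D` supports the fit.
#' @param seed integer seed driving the permutation and the NMF starts.
#' @param method `"rotate"` (default) rotates the four quadrant roles of one
#'   fixed partition; `"repartition"` draws four independent permutations
#'   and always holds out the top-left quadrant.
#' @param tolRel,maxIter passed to [fitNMF()].
#' @return a [BCVResult-class] object.
#' @examples
#' refs <- makeReferenceProfiles(2, 80, 8, 0.4, seed = 1)
#' mix <- makeBulkMixtures(refs$means, 24, rep(1, 2), noiseSd = 0.02, seed = 5)
#' bcv <- bicrossvalidate(mix$V, 1:3, seed = 9)
#' selectedK(bcv)
#' @export
bicrossvalidate <- function(V, kValues, seed, method = c("rotate", "repartition"),
                            tolRel = 1e-4, maxIter = 10000L) {
  V <- checkBetaMatrix(V)
  method <- match.arg(method)
  kValues <- sort(unique(as.integer(kValues)))
  kmax_ok <- floor(min(dim(V)) / 2)
  bad <- kValues[kValues > kmax_ok | kValues < 1]
  if (length(bad)) {
    stop(sprintf(
      "rank(s) %s unsupported: quadrant D is %d x %d at most",
      paste(bad, collapse = ", "), floor(nrow(V) / 2), floor(ncol(V) / 2)
    ))
  }
  n_rot <- 4L
  perms <- withSeed(seed, {
    n_perm <- if (method == "rotate") 1L else n_rot
    lapply(seq_len(n_perm), function(i) {
      list(rows = sample.int(nrow(V)), cols = sample.int(ncol(V)))
    })
  })
  half_r <- floor(nrow(V) / 2)
  half_c <- floor(ncol(V) / 2)
  fold_errors <- matrix(
    0, length(kValues), n_rot,
    dimnames = list(as.character(kValues), sprintf("fold_%d", seq_len(n_rot)))
  )
  for (rot in seq_len(n_rot)) {
    p <- perms[[if (method == "rotate") 1L else rot]]
    r1 <- p$rows[seq_len(half_r)]
    r2 <- p$rows[(half_r + 1L):nrow(V)]
    c1 <- p$cols[seq_len(half_c)]
    c2 <- p$cols[(half_c + 1L):ncol(V)]
    # which halves form the held-out block A in this rotation
    if (method == "repartition" || rot == 1L) {
      ra <- r1; rd <- r2; ca <- c1; cd <- c2
    } else if (rot == 2L) {
      ra <- r1; rd <- r2; ca <- c2; cd <- c1
    } else if (rot == 3L) {
      ra <- r2; rd <- r1; ca <- c1; cd <- c2
    } else {
      ra <- r2; rd <- r1; ca <- c2; cd <- c1
    }
    A <- V[ra, ca, drop = FALSE]
    B <- V[ra, cd, drop = FALSE]
    C <- V[rd, ca, drop = FALSE]
    D <- V[rd, cd, drop = FALSE]
    for (ki in seq_along(kValues)) {
      k <- kValues[ki]
      sub_seed <- (as.integer(seed) + 7919L * k + 104729L * rot) %% 2147483647L
      fit <- fitNMF(D, k,
        tolRel = tolRel, maxIter = maxIter, seed = sub_seed
      )
      WD <- fit@W
      HD <- fit@H
      A_hat <- (B %*% MASS::ginv(HD)) %*% (MASS::ginv(WD) %*% C)
      fold_errors[ki, rot] <- frobenius(A - A_hat)
    }
  }
  mean_errors <- rowMeans(fold_errors)
  best <- min(mean_errors)
  sel <- min(kValues[mean_errors == best])
  new("BCVResult",
    kValues = kValues, foldErrors = fold_errors, meanErrors = mean_errors,
    selectedK = as.integer(sel), seed = as.integer(seed)
  )
}
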