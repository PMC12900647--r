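#' Generate reference cell-type methylation profiles with planted markers
#'
#' Builds per-cell-type mean beta profiles on a shared random baseline, with
#' disjoint blocks of probes shifted up (hypermethylated) and down
#' (hypomethylated) by `deltaBeta` per cell type, then clipped to `[0, 1]`.
#' These stand in for purified cell-type methylomes: the planted blocks are
#' the ground truth that downstream probe selection and signature annotation
#' are tested against.
#'
#' @param nCelltypes number of cell types; the first is labelled neoplastic,
#'   the rest stromal (override via `neoplastic`).
#' @param nProbes total number of probes.
#' @param nPlantedPerType number of hyper- and of hypomethylated probes
#'   planted per cell type (so `2 * nPlantedPerType` markers per type).
#' @param deltaBeta shift applied to planted probes, in `(0, 1)`.
#' @param baselineRange length-2 vector; the shared baseline is drawn
#'   uniformly from this range.
#' @param seed integer seed; identical seeds give identical profiles.
#' @param neoplastic character vector of cell-type names to label neoplastic.
#' @return list with `means` (probes x cell types matrix), `celltypeLabels`
#'   (named `"N"`/`"S"` vector), `baseline`, `plantedHyper` and `plantedHypo`
#'   (named lists of probe ids per cell type).
#' @examples
#' refs <- makeReferenceProfiles(3, 500, 20, 0.4, seed = 1)
#' range(refs$means)
#' @export
makeReferenceProfiles <- function(nCelltypes, nProbes, nPlantedPerType,
                                  deltaBeta, baselineRange = c(0.3, 0.7),
                                  seed, neoplastic = NULL) {
  if (2 * nPlantedPerType * nCelltypes > nProbes) {
    stop("infeasible planting: 2 * nPlantedPerType * nCelltypes exceeds nProbes")
  }
  if (deltaBeta < 0 || deltaBeta >= 1) stop("deltaBeta must lie in [0, 1)")
  withSeed(seed, {
    probe_ids <- sprintf("cg%06d", seq_len(nProbes))
    ct_ids <- sprintf("celltype_%d", seq_len(nCelltypes))
    baseline <- runif(nProbes, baselineRange[1], baselineRange[2])
    names(baseline) <- probe_ids
    # one global shuffle, carved into disjoint planted blocks
    pool <- sample.int(nProbes)
    means <- matrix(baseline, nProbes, nCelltypes,
      dimnames = list(probe_ids, ct_ids)
    )
    hyper <- hypo <- vector("list", nCelltypes)
    names(hyper) <- names(hypo) <- ct_ids
    at <- 1L
    for (j in seq_len(nCelltypes)) {
      up <- pool[at:(at + nPlantedPerType - 1L)]
      at <- at + nPlantedPerType
      dn <- pool[at:(at + nPlantedPerType - 1L)]
      at <- at + nPlantedPerType
      means[up, j] <- means[up, j] + deltaBeta
      means[dn, j] <- means[dn, j] - deltaBeta
      hyper[[j]] <- probe_ids[up]
      hypo[[j]] <- probe_ids[dn]
    }
    means <- clip01(means)
    if (is.null(neoplastic)) neoplastic <- ct_ids[1]
    labels <- ifelse(ct_ids %in% neoplastic, "N", "S")
    names(labels) <- ct_ids
    list(
      means = means, celltypeLabels = labels, baseline = baseline,
      plantedHyper = hyper, plantedHypo = hypo, deltaBeta = deltaBeta,
      seed = as.integer(seed)
    )
  })
}

#' Generate an unstructured random signature basis
#'
#' Draws a probes x k basis with entries iid U(0,1). Unlike
#' [makeReferenceProfiles()], whose cell-type columns share a common
#' baseline (and are therefore strongly mutually correlated), these columns
#' are essentially uncorrelated, which makes the factorization identifiable
#' up to permutation — the fixture of choice for factor-recovery and
#' rank-selection checks.
#'
#' @param nProbes number of probes.
#' @param k number of signatures.
#' @param seed integer seed.
#' @return numeric matrix, probes x k, values in `(0, 1)`.
#' @export
makeSignatureBasis <- function(nProbes, k, seed) {
  withSeed(seed, {
    W <- matrix(runif(nProbes * k), nProbes, k)
    dimnames(W) <- list(
      sprintf("cg%06d", seq_len(nProbes)),
      sprintf("component_%d", seq_len(k))
    )
    W
  })
}

#' Generate replicate reference samples around cell-type profiles
#'
#' Draws `nPerType` replicate methylomes per cell type by adding Gaussian
#' noise to the cell-type mean profile and clipping to `[0, 1]`, yielding the
#' replicated reference matrix that one-vs-rest differential probe selection
#' needs.
#'
#' @param profiles output of [makeReferenceProfiles()].
#' @param nPerType replicates per cell type (>= 2 for downstream t-tests).
#' @param withinSd within-cell-type standard deviation on the beta scale.
#' @param seed integer seed.
#' @return list with `beta` (probes x (nCelltypes * nPerType) matrix) and
#'   `labels` (cell type per column).
#' @export
makeReferenceSamples <- function(profiles, nPerType, withinSd, seed) {
  if (withinSd < 0) stop("withinSd must be >= 0")
  withSeed(seed, {
    M <- profiles$means
    ct <- colnames(M)
    n <- nPerType * length(ct)
    beta <- matrix(0, nrow(M), n)
    labels <- character(n)
    col <- 1L
    for (j in seq_along(ct)) {
      for (r in seq_len(nPerType)) {
        beta[, col] <- clip01(M[, j] + rnorm(nrow(M), 0, withinSd))
        labels[col] <- ct[j]
        col <- col + 1L
      }
    }
    rownames(beta) <- rownames(M)
    colnames(beta) <- sprintf("%s_rep%d", labels, sequence(rep(nPerType, length(ct))))
    list(beta = beta, labels = labels)
  })
}

#' Generate bulk beta-value mixtures with known factors
#'
#' Realizes the generative model `V = clip(W H + e, 0, 1)`: bulk methylomes
#' as convex combinations of signature profiles plus truncated Gaussian
#' noise. Mixing weights are drawn per class from a class-specific Dirichlet,
#' so each column of `H` sums to 1 and a sample's class is the class whose
#' Dirichlet produced it. The pre-clip matrix is kept in the returned truth
#' so noise-level checks can be recomputed exactly.
#'
#' @param W numeric matrix (probes x k) of true signature profiles in
#'   `[0, 1]`, e.g. `means` from [makeReferenceProfiles()].
#' @param nSamples total number of bulk samples; split as evenly as possible
#'   across classes.
#' @param dirichletAlphaByClass numeric matrix, classes x k, strictly
#'   positive Dirichlet parameters (one row per class). A single class may be
#'   given as a vector.
#' @param noiseSd standard deviation of the additive Gaussian noise on the
#'   beta scale (truncated by the final clipping).
#' @param seed integer seed.
#' @return list with `V` (probes x samples beta matrix) and `truth`, a list
#'   holding `W`, `H` (k x samples, columns sum to 1), `preclip` (W H + e
#'   before clipping), `classLabels`, `rank`, `noiseSd` and `seed`.
#' @examples
#' refs <- makeReferenceProfiles(3, 200, 10, 0.4, seed = 1)
#' mix <- makeBulkMixtures(refs$means, 60, rep(1, 3), noiseSd = 0.02, seed = 11)
#' colSums(mix$truth$H)[1:5]
#' @export
makeBulkMixtures <- function(W, nSamples, dirichletAlphaByClass, noiseSd,
                             seed) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (is.vector(dirichletAlphaByClass)) {
    dirichletAlphaByClass <- matrix(dirichletAlphaByClass, nrow = 1)
  }
  if (any(dirichletAlphaByClass <= 0)) {
    stop("Dirichlet parameters must be strictly positive")
  }
  k <- ncol(W)
  if (ncol(dirichletAlphaByClass) != k) {
    stop(sprintf(
      "alpha has %d columns but W has %d components",
      ncol(dirichletAlphaByClass), k
    ))
  }
  if (min(W) < 0 || max(W) > 1) stop("W must lie in [0,1]")
  nClasses <- nrow(dirichletAlphaByClass)
  class_ids <- rownames(dirichletAlphaByClass)
  if (is.null(class_ids)) class_ids <- sprintf("class_%d", seq_len(nClasses))
  withSeed(seed, {
    sizes <- diff(round(seq(0, nSamples, length.out = nClasses + 1)))
    labels <- rep(class_ids, sizes)
    H <- matrix(0, k, nSamples)
    at <- 1L
    for (c in seq_len(nClasses)) {
      if (sizes[c] == 0) next
      H[, at:(at + sizes[c] - 1L)] <-
        t(rdirichlet(sizes[c], dirichletAlphaByClass[c, ]))
      at <- at + sizes[c]
    }
    WH <- W %*% H
    preclip <- WH + matrix(rnorm(length(WH), 0, noiseSd), nrow(WH), ncol(WH))
    V <- clip01(preclip)
    sample_ids <- sprintf("bulk_%03d", seq_len(nSamples))
    rownames(V) <- rownames(W)
    colnames(V) <- sample_ids
    comp_ids <- colnames(W)
    if (is.null(comp_ids)) comp_ids <- sprintf("component_%d", seq_len(k))
    dimnames(H) <- list(comp_ids, sample_ids)
    list(
      V = V,
      truth = list(
        W = W, H = H, preclip = preclip, classLabels = labels,
        rank = k, noiseSd = noiseSd, seed = as.integer(seed)
      )
    )
  })
}

#' Generate a two-class beta matrix for forest introspection tests
#'
#' Two classes share a random baseline profile and differ only at
#' `nInformative` planted probes, each shifted by `deltaBeta` in a randomly
#' chosen direction (class A hypo- or hypermethylated, recorded per probe).
#' Within-class variation is Gaussian with a small fixed spread so a forest
#' has something to fit.
#'
#' @param nProbes total number of probes.
#' @param nInformative number of planted class-separating probes.
#' @param nPerClass samples per class (>= 2).
#' @param deltaBeta between-class beta difference at planted probes.
#' @param seed integer seed.
#' @param withinSd within-class standard deviation (default 0.05).
#' @return list with `beta` (probes x 2*nPerClass), `labels` (factor with
#'   levels `A`, `B`) and `planted`, a data.frame of planted probe ids and
#'   the recorded direction (`"A_hypo"` or `"A_hyper"`).
#' @export
makeTwoClassForestData <- function(nProbes, nInformative, nPerClass,
                                   deltaBeta, seed, withinSd = 0.05) {
  if (nInformative > nProbes) stop("nInformative must be <= nProbes")
  if (nPerClass < 2) stop("nPerClass must be >= 2")
  withSeed(seed, {
    probe_ids <- sprintf("cg%06d", seq_len(nProbes))
    base <- runif(nProbes, 0.3, 0.7)
    meanA <- meanB <- base
    planted <- data.frame(
      probe_id = character(0), direction = character(0),
      stringsAsFactors = FALSE
    )
    if (nInformative > 0) {
      idx <- sample.int(nProbes, nInformative)
      a_hypo <- runif(nInformative) < 0.5
      half <- deltaBeta / 2
      meanA[idx] <- base[idx] + ifelse(a_hypo, -half, half)
      meanB[idx] <- base[idx] + ifelse(a_hypo, half, -half)
      planted <- data.frame(
        probe_id = probe_ids[idx],
        direction = ifelse(a_hypo, "A_hypo", "A_hyper"),
        stringsAsFactors = FALSE
      )
    }
    n <- 2L * nPerClass
    beta <- matrix(0, nProbes, n)
    for (s in seq_len(nPerClass)) {
      beta[, s] <- clip01(meanA + rnorm(nProbes, 0, withinSd))
      beta[, nPerClass + s] <- clip01(meanB + rnorm(nProbes, 0, withinSd))
    }
    labels <- factor(rep(c("A", "B"), each = nPerClass))
    rownames(beta) <- probe_ids
    colnames(beta) <- sprintf("%s_%02d", labels, sequence(c(nPerClass, nPerClass)))
    list(beta = beta, labels = labels, planted = planted)
  })
}

#' Simulate a survival cohort with immune-fraction-dependent hazard
#'
#' Exponential event times with administrative censoring: samples whose
#' immune fraction is at or below the cohort's third quartile (the
#' intermediate/low group) have their baseline hazard multiplied by
#' `hazardRatioLowVsHigh`, emulating the elevated recurrence risk of
#' immune-poor tumors. Event indicator is 1 iff the event time falls within
#' the follow-up window.
#'
#' @param n cohort size (ignored when `immuneFractions` is supplied).
#' @param immuneFractions optional numeric vector in `[0, 1]`; drawn
#'   uniformly when NULL.
#' @param hazardRatioLowVsHigh hazard multiplier for the int/low stratum
#'   (> 0).
#' @param baselineRate exponential event rate of the high-immune stratum
#'   (> 0), per follow-up time unit.
#' @param censorTime administrative censoring time (> 0; `Inf` allowed).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `time`, `event`, `immune_fraction`.
#' @export
makeSurvivalCohort <- function(n, immuneFractions = NULL,
                               hazardRatioLowVsHigh, baselineRate,
                               censorTime, seed) {
  if (hazardRatioLowVsHigh <= 0) stop("hazardRatioLowVsHigh must be > 0")
  if (baselineRate <= 0) stop("baselineRate must be > 0")
  if (censorTime <= 0) stop("censorTime must be > 0")
  withSeed(seed, {
    if (is.null(immuneFractions)) immuneFractions <- runif(n)
    n <- length(immuneFractions)
    if (any(immuneFractions < 0 | immuneFractions > 1)) {
      stop("immuneFractions must lie in [0,1]")
    }
    q3 <- unname(quantile(immuneFractions, 0.75, type = 7))
    lowish <- immuneFractions <= q3
    rate <- baselineRate * hazardRatioLowVsHigh^as.numeric(lowish)
    t_event <- rexp(n, rate = rate)
    event <- as.integer(t_event <= censorTime)
    time <- pmin(t_event, censorTime)
    data.frame(
      sample_id = sprintf("case_%04d", seq_len(n)),
      time = time, event = event, immune_fraction = immuneFractions,
      stringsAsFactors = FALSE
    )
  })
}
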