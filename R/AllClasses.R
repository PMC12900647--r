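#' Fitted constrained NMF model
#'
#' Holds the result of [fitNMF()]: the signature basis `W` (probes x k,
#' elements in `[0, 1]` like beta values), the mixture coefficients `H`
#' (k x samples, columns summing to 1), the per-iteration Frobenius objective
#' and convergence state.
#'
#' @slot W numeric matrix, probes x k, values in `[0, 1]`.
#' @slot H numeric matrix, k x samples, non-negative columns summing to 1.
#' @slot objectiveTrace numeric vector of `||V - WH||_F` per iteration.
#' @slot nIter integer, iterations performed.
#' @slot converged logical, whether the relative objective change fell below
#'   the tolerance before the iteration cap.
#' @slot tolRel numeric, relative-change convergence tolerance used.
#' @slot seed integer seed that produced the random initialization.
#'
#' @seealso [fitNMF()], [basisMatrix()], [coefMatrix()]
#' @export
setClass("NMFFit",
  representation(
    W = "matrix", H = "matrix", objectiveTrace = "numeric",
    nIter = "integer", converged = "logical", tolRel = "numeric",
    seed = "integer"
  )
)

setValidity("NMFFit", function(object) {
  msg <- character()
  if (ncol(object@W) != nrow(object@H)) {
    msg <- c(msg, "ncol(W) must equal nrow(H)")
  }
  if (min(object@W) < 0 || max(object@W) > 1) {
    msg <- c(msg, "W elements must lie in [0,1]")
  }
  if (min(object@H) < 0) msg <- c(msg, "H must be non-negative")
  if (ncol(object@H) > 0 && max(abs(colSums(object@H) - 1)) > 1e-8) {
    msg <- c(msg, "H columns must sum to 1 within 1e-8")
  }
  if (length(object@objectiveTrace) == 0) {
    msg <- c(msg, "objectiveTrace must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Bicrossvalidation rank-selection result
#'
#' Result of [bicrossvalidate()]: for each candidate rank, the four held-out
#' quadrant reconstruction errors (Frobenius norms), their mean, and the
#' selected rank (argmin of the mean, ties to the smallest rank).
#'
#' @slot kValues integer vector of candidate ranks.
#' @slot foldErrors numeric matrix, length(kValues) x 4, `||A - W_A H_A||_F`
#'   per quadrant rotation.
#' @slot meanErrors numeric vector, row means of `foldErrors`.
#' @slot selectedK integer, the selected rank.
#' @slot seed integer seed controlling the row/column permutation and fits.
#'
#' @seealso [bicrossvalidate()], [selectedK()]
#' @export
setClass("BCVResult",
  representation(
    kValues = "integer", foldErrors = "matrix", meanErrors = "numeric",
    selectedK = "integer", seed = "integer"
  )
)

setValidity("BCVResult", function(object) {
  msg <- character()
  if (nrow(object@foldErrors) != length(object@kValues)) {
    msg <- c(msg, "foldErrors must have one row per candidate k")
  }
  if (any(object@foldErrors < 0)) msg <- c(msg, "foldErrors must be >= 0")
  if (!(object@selectedK %in% object@kValues)) {
    msg <- c(msg, "selectedK must be one of kValues")
  }
  if (length(object@meanErrors)) {
    best <- min(object@meanErrors)
    k_best <- min(object@kValues[object@meanErrors == best])
    if (object@selectedK != k_best) {
      msg <- c(msg, "selectedK must minimize meanErrors (ties to smallest k)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Merged and annotated methylation signature set
#'
#' Produced by [mergeComponents()] and labelled by [annotateSignatures()].
#' Components of an NMF basis are clustered by cosine distance and merged;
#' each merged signature is later tagged neoplastic (`N`) or stromal (`S`)
#' by similarity to reference cell-type profiles and given an ordinal name
#' (`N1`, ..., `S1`, ...).
#'
#' @slot basis numeric matrix, probes x signatures; merged columns are the
#'   element-wise means of their member components (stays within `[0, 1]`).
#' @slot H numeric matrix or NULL-like empty matrix; merged mixture
#'   coefficients (sums of member rows, preserving column sums of 1).
#' @slot members named list mapping each merged signature to the original
#'   component ids it absorbed.
#' @slot labels character vector, `"N"`/`"S"` per signature (empty until
#'   annotated).
#' @slot bestReference data.frame with the most similar reference cell type
#'   and its similarity per signature (empty until annotated).
#' @slot mergeHeights numeric vector of dendrogram merge heights, so the
#'   threshold choice can be inspected.
#' @slot threshold numeric, the cosine-distance cut height used.
#'
#' @seealso [mergeComponents()], [annotateSignatures()], [deconvolveNNLS()]
#' @export
setClass("SignatureSet",
  representation(
    basis = "matrix", H = "matrix", members = "list", labels = "character",
    bestReference = "data.frame", mergeHeights = "numeric",
    threshold = "numeric"
  )
)

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (length(object@members) != ncol(object@basis)) {
    msg <- c(msg, "one members entry per merged signature required")
  }
  all_members <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    msg <- c(msg, "each original component must belong to exactly one signature")
  }
  if (length(object@labels) &&
      anyDuplicated(colnames(object@basis))) {
    msg <- c(msg, "signature names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' NNLS deconvolution result
#'
#' Per-sample non-negative least-squares projections of bulk methylomes onto
#' a signature basis: raw coefficients, per-sample normalized fractions
#' (columns summing to 1), the residual norm, and a flag for degenerate
#' samples whose raw coefficients were all zero (their fractions are `NA`,
#' never silently uniform).
#'
#' @slot raw numeric matrix, signatures x samples, raw NNLS coefficients.
#' @slot fractions numeric matrix, signatures x samples, column-normalized.
#' @slot residualNorm numeric vector, per-sample `||v - W h||_2`.
#' @slot flagged logical vector, TRUE where the raw solution was all zero.
#'
#' @seealso [deconvolveNNLS()], [fractions()], [dominantSignature()]
#' @export
setClass("DeconvolutionResult",
  representation(
    raw = "matrix", fractions = "matrix", residualNorm = "numeric",
    flagged = "logical"
  )
)

setValidity("DeconvolutionResult", function(object) {
  msg <- character()
  if (any(object@raw < 0)) msg <- c(msg, "raw coefficients must be >= 0")
  ok <- !object@flagged
  if (any(ok)) {
    cs <- colSums(object@fractions[, ok, drop = FALSE])
    if (max(abs(cs - 1)) > 1e-8) {
      msg <- c(msg, "fraction columns must sum to 1 within 1e-8")
    }
  }
  if (any(object@flagged) &&
      !all(is.na(object@fractions[, object@flagged]))) {
    msg <- c(msg, "flagged samples must have missing fractions")
  }
  if (length(msg)) msg else TRUE
})

#' Signed class-pair probe-usage tensor from a tree ensemble
#'
#' 3D array (probes x classes x classes) counting, for each probe, how often
#' it performs a split discriminating each class pair in a trained random
#' forest. Entry `[p, i, j]` is signed from class `i`'s perspective: negative
#' when class `i`'s majority routes to the low-beta (<= threshold) child at
#' those splits, i.e. the probe is hypomethylated in class `i` relative to
#' `j`. Magnitudes are symmetric (`|u[p,i,j]| == |u[p,j,i]|`) and the
#' diagonal is zero.
#'
#' @slot usage numeric 3D array of signed integer counts.
#' @slot classIds character vector of class names.
#'
#' @seealso [computeProbeUsage()], [summarizeOneVsRest()]
#' @export
setClass("ProbeUsageArray",
  representation(usage = "array", classIds = "character")
)

setValidity("ProbeUsageArray", function(object) {
  msg <- character()
  d <- dim(object@usage)
  if (length(d) != 3 || d[2] != d[3]) {
    msg <- c(msg, "usage must be a probes x classes x classes array")
  } else {
    if (d[2] != length(object@classIds)) {
      msg <- c(msg, "classIds length must match the class dimensions")
    }
    for (i in seq_len(d[2])) {
      if (any(object@usage[, i, i] != 0)) {
        msg <- c(msg, "diagonal layers must be zero")
        break
      }
    }
    au <- abs(object@usage)
    if (max(abs(au - aperm(au, c(1, 3, 2)))) > 0) {
      msg <- c(msg, "usage magnitudes must be symmetric in the class pair")
    }
    if (max(abs(object@usage - round(object@usage))) > 1e-9) {
      msg <- c(msg, "usage counts must be integer-valued")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Probe panel with per-probe provenance
#'
#' A set of probes selected for analysis, with a provenance tag per probe:
#' cell-type differential methylation (`celltype_dm`, with the cell type and
#' hyper/hypo direction), top variance (`variance`), or `both` after
#' combining panels.
#'
#' @slot table data.frame with columns `probe_id`, `provenance`, `celltype`,
#'   `direction`, `statistic`, `p_value` (NA where not applicable).
#' @slot parameters list of the selection parameters used.
#'
#' @seealso [selectCelltypeProbes()], [selectVarianceProbes()],
#'   [combinePanels()]
#' @export
setClass("ProbePanel",
  representation(table = "data.frame", parameters = "list")
)

setValidity("ProbePanel", function(object) {
  msg <- character()
  need <- c("probe_id", "provenance")
  if (!all(need %in% names(object@table))) {
    msg <- c(msg, "table must have probe_id and provenance columns")
  } else if (anyDuplicated(object@table$probe_id)) {
    msg <- c(msg, "probe ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Log-rank test result
#'
#' Observed and expected event counts per group, the chi-square statistic
#' computed from the observed-minus-expected vector and its hypergeometric
#' covariance, degrees of freedom (groups - 1), and the p-value.
#'
#' @slot chiSquare numeric, the test statistic.
#' @slot df integer, degrees of freedom.
#' @slot pValue numeric.
#' @slot observed named numeric vector of events per group.
#' @slot expected named numeric vector of expected events per group.
#'
#' @seealso [logrankTest()]
#' @export
setClass("LogRankResult",
  representation(
    chiSquare = "numeric", df = "integer", pValue = "numeric",
    observed = "numeric", expected = "numeric"
  )
)

setValidity("LogRankResult", function(object) {
  msg <- character()
  if (object@chiSquare < 0) msg <- c(msg, "chiSquare must be >= 0")
  if (object@df != length(object@observed) - 1L) {
    msg <- c(msg, "df must equal number of groups - 1")
  }
  if (abs(sum(object@observed) - sum(object@expected)) > 1e-6) {
    msg <- c(msg, "observed and expected totals must agree")
  }
  if (length(msg)) msg else TRUE
})
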