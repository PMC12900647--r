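#' Extract the signature basis matrix W
#'
#' @param object an [NMFFit-class] or [SignatureSet-class] object.
#' @return numeric matrix, probes x signatures.
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))

#' Extract the mixture-coefficient matrix H
#'
#' @param object an [NMFFit-class] or [SignatureSet-class] object.
#' @return numeric matrix, signatures x samples, columns summing to 1.
#' @export
setGeneric("coefMatrix", function(object) standardGeneric("coefMatrix"))

#' Extract normalized per-sample signature fractions
#'
#' @param object a [DeconvolutionResult-class] object.
#' @return numeric matrix, signatures x samples; `NA` columns for samples
#'   flagged as degenerate.
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' Selected rank from bicrossvalidation
#'
#' @param object a [BCVResult-class] object.
#' @return integer, the rank minimizing the mean held-out error.
#' @export
setGeneric("selectedK", function(object) standardGeneric("selectedK"))

#' Signature labels (stromal/neoplastic)
#'
#' @param object a [SignatureSet-class] object.
#' @return named character vector of `"N"`/`"S"` tags, or an empty vector if
#'   the set has not been annotated.
#' @export
setGeneric("signatureLabels", function(object) standardGeneric("signatureLabels"))

#' @describeIn basisMatrix basis of a fitted NMF model
#' @export
setMethod("basisMatrix", "NMFFit", function(object) object@W)

#' @describeIn basisMatrix merged basis of a signature set
#' @export
setMethod("basisMatrix", "SignatureSet", function(object) object@basis)

#' @describeIn coefMatrix coefficients of a fitted NMF model
#' @export
setMethod("coefMatrix", "NMFFit", function(object) object@H)

#' @describeIn coefMatrix merged coefficients of a signature set (empty
#'   matrix when no H was supplied at merge time)
#' @export
setMethod("coefMatrix", "SignatureSet", function(object) object@H)

#' @describeIn fractions normalized NNLS fractions
#' @export
setMethod("fractions", "DeconvolutionResult", function(object) object@fractions)

#' @describeIn selectedK selected rank
#' @export
setMethod("selectedK", "BCVResult", function(object) object@selectedK)

#' @describeIn signatureLabels stromal/neoplastic tags
#' @export
setMethod("signatureLabels", "SignatureSet", function(object) {
  stats::setNames(object@labels, colnames(object@basis)[seq_along(object@labels)])
})

setMethod("show", "NMFFit", function(object) {
  cat(sprintf(
    "NMFFit: %d probes x %d components, %d samples\n",
    nrow(object@W), ncol(object@W), ncol(object@H)
  ))
  cat(sprintf(
    "  %d iterations, converged: %s (tol %g)\n",
    object@nIter, object@converged, object@tolRel
  ))
  cat(sprintf(
    "  final ||V - WH||_F = %.6g\n",
    object@objectiveTrace[length(object@objectiveTrace)]
  ))
})

setMethod("show", "BCVResult", function(object) {
  cat(sprintf(
    "BCVResult over k in {%s}\n", paste(object@kValues, collapse = ", ")
  ))
  cat(sprintf("  selected k = %d\n", object@selectedK))
  cat("  mean held-out errors:\n")
  print(stats::setNames(round(object@meanErrors, 4), object@kValues))
})

setMethod("show", "SignatureSet", function(object) {
  k <- ncol(object@basis)
  cat(sprintf(
    "SignatureSet: %d signatures over %d probes\n", k, nrow(object@basis)
  ))
  if (length(object@labels)) {
    cat(sprintf(
      "  %d neoplastic (N), %d stromal (S)\n",
      sum(object@labels == "N"), sum(object@labels == "S")
    ))
  } else {
    cat("  unlabeled (run annotateSignatures())\n")
  }
  cat(sprintf("  merge threshold %.3g (cosine distance)\n", object@threshold))
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf(
    "DeconvolutionResult: %d signatures x %d samples (%d flagged)\n",
    nrow(object@raw), ncol(object@raw), sum(object@flagged)
  ))
})

setMethod("show", "ProbeUsageArray", function(object) {
  d <- dim(object@usage)
  cat(sprintf(
    "ProbeUsageArray: %d probes x %d x %d classes; %d nonzero entries\n",
    d[1], d[2], d[3], sum(object@usage != 0)
  ))
})

setMethod("show", "ProbePanel", function(object) {
  cat(sprintf("ProbePanel: %d probes\n", nrow(object@table)))
  print(table(object@table$provenance))
})

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf(
    "Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
    object@chiSquare, object@df, object@pValue
  ))
  print(data.frame(
    observed = object@observed, expected = round(object@expected, 2)
  ))
})
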