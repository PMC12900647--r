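#' Immune-cell enrichment score from deconvolved fractions
#'
#' Per sample, the sum of the normalized fractions over the named immune
#' signatures (e.g. TAM and lymphocyte signatures); a value in `[0, 1]`.
#'
#' @param deconv a [DeconvolutionResult-class].
#' @param immuneSignatureIds character vector of signature ids to sum; must
#'   all exist in the result. An empty set gives 0 for every sample.
#' @return named numeric vector, one score per sample (`NA` for flagged
#'   samples).
#' @export
immuneFraction <- function(deconv, immuneSignatureIds) {
  fr <- fractions(deconv)
  unknown <- setdiff(immuneSignatureIds, rownames(fr))
  if (length(unknown)) {
    stop(sprintf("unknown signature id(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!length(immuneSignatureIds)) {
    return(stats::setNames(
      ifelse(deconv@flagged, NA_real_, 0), colnames(fr)
    ))
  }
  colSums(fr[immuneSignatureIds, , drop = FALSE])
}

#' Quartile stratification of an immune-enrichment score
#'
#' Splits samples at the first and third quartiles (linear-interpolation
#' quantiles): `high` is strictly above Q3 (the top quartile), `low` at or
#' below Q1, `intermediate` otherwise. Samples tied exactly at Q3 fall into
#' the intermediate/low side, matching the convention of reporting Q3 as a
#' cutoff. The dichotomous grouping pools low with intermediate
#' (`int_low`) against `high`.
#'
#' @param values numeric vector (>= 4 finite values), e.g. from
#'   [immuneFraction()].
#' @return data.frame with `sample_id`, `value`, `group`
#'   (low/intermediate/high) and `dichotomous` (high/int_low); quartile
#'   cutoffs are attached as attributes `q1`, `q2`, `q3`.
#' @export
quartileStratify <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need >= 4 finite values to stratify by quartiles")
  qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  grp <- ifelse(values > qs[3], "high",
    ifelse(values <= qs[1], "low", "intermediate")
  )
  ids <- names(values)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_along(values))
  out <- data.frame(
    sample_id = ids, value = unname(values),
    group = factor(grp, levels = c("low", "intermediate", "high")),
    dichotomous = factor(
      ifelse(grp == "high", "high", "int_low"),
      levels = c("int_low", "high")
    ),
    stringsAsFactors = FALSE
  )
  attr(out, "q1") <- qs[1]
  attr(out, "q2") <- qs[2]
  attr(out, "q3") <- qs[3]
  out
}

#' Log-rank test for survival differences between groups
#'
#' Standard log-rank: at every distinct event time, the expected number of
#' events in each group is the total deaths times the group's share of the
#' at-risk set; the chi-square statistic is the quadratic form of the
#' observed-minus-expected vector in its hypergeometric covariance, on
#' `groups - 1` degrees of freedom.
#'
#' @param time non-negative follow-up times.
#' @param event binary event indicators (1 = event, 0 = censored).
#' @param groups group membership per subject (>= 2 groups, each non-empty).
#' @return a [LogRankResult-class].
#' @examples
#' coh <- makeSurvivalCohort(200,
#'   hazardRatioLowVsHigh = 3,
#'   baselineRate = 0.05, censorTime = 20, seed = 1
#' )
#' strata <- quartileStratify(
#'   stats::setNames(coh$immune_fraction, coh$sample_id)
#' )
#' logrankTest(coh$time, coh$event, strata$dichotomous)
#' @export
logrankTest <- function(time, event, groups) {
  stopifnot(length(time) == length(event), length(time) == length(groups))
  if (any(time < 0)) stop("times must be >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  groups <- factor(groups)
  groups <- droplevels(groups)
  g_ids <- levels(groups)
  G <- length(g_ids)
  if (G < 2) stop("need >= 2 non-empty groups")
  if (sum(event) == 0) stop("no events: log-rank statistic undefined")
  event_times <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(G), g_ids)
  Vmat <- matrix(0, G, G, dimnames = list(g_ids, g_ids))
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    n_g <- vapply(g_ids, function(g) sum(at_risk & groups == g), 0)
    d_g <- vapply(g_ids, function(g) sum(event == 1 & time == t & groups == g), 0)
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      const <- d * (n - d) / (n - 1)
      Vt <- const * (diag(n_g / n, G) - tcrossprod(n_g / n))
      Vmat <- Vmat + Vt
    }
  }
  z <- (O - E)[-G]
  Vsub <- Vmat[-G, -G, drop = FALSE]
  chi <- tryCatch(
    as.numeric(t(z) %*% solve(Vsub, z)),
    error = function(e) as.numeric(t(z) %*% MASS::ginv(Vsub) %*% z)
  )
  df <- G - 1L
  new("LogRankResult",
    chiSquare = chi, df = df,
    pValue = pchisq(chi, df, lower.tail = FALSE),
    observed = O, expected = E
  )
}
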