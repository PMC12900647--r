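# Row-wise Welch t statistics between two sample groups of a beta matrix.
# Returns mean difference (group1 - group2), t, df, two-sided p.
rowWelch <- function(X, idx1, idx2) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  m1 <- rowMeans(X[, idx1, drop = FALSE])
  m2 <- rowMeans(X[, idx2, drop = FALSE])
  v1 <- rowSums((X[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # zero-variance probes with zero mean difference are uninformative
  p[is.na(p)] <- 1
  list(diff = m1 - m2, t = tstat, df = df, p = p)
}

#' One-vs-rest differential methylation probe selection
#'
#' For each cell type, compares every probe between that type's replicates
#' and all remaining samples with a two-sided Welch t-test. Among probes
#' passing `pThreshold`, up to `capPerDirection` probes with the largest
#' positive mean difference (hypermethylated in the cell type) and up to
#' `capPerDirection` with the most negative (hypomethylated) are retained,
#' ranked by absolute mean difference. The panel is the union across cell
#' types, with provenance recorded per probe.
#'
#' @param refSamples beta matrix (probes x samples) of reference replicates,
#'   e.g. from [makeReferenceSamples()].
#' @param celltypeLabels cell type per column.
#' @param capPerDirection maximum probes kept per direction per cell type
#'   (default 500).
#' @param pThreshold raw p-value threshold (default 1e-5); no multiplicity
#'   correction is applied.
#' @return a [ProbePanel-class]; a probe selected for several cell types
#'   keeps the entry with the largest absolute mean difference.
#' @export
selectCelltypeProbes <- function(refSamples, celltypeLabels,
                                 capPerDirection = 500, pThreshold = 1e-5) {
  refSamples <- checkBetaMatrix(refSamples, "refSamples")
  celltypeLabels <- as.character(celltypeLabels)
  stopifnot(ncol(refSamples) == length(celltypeLabels))
  tab <- table(celltypeLabels)
  if (any(tab < 2)) {
    stop(sprintf(
      "cell type(s) with fewer than 2 replicates: %s",
      paste(names(tab)[tab < 2], collapse = ", ")
    ))
  }
  rows <- list()
  for (ct in names(tab)) {
    idx1 <- which(celltypeLabels == ct)
    idx2 <- which(celltypeLabels != ct)
    if (length(idx2) < 2) stop("need >= 2 samples outside each cell type")
    st <- rowWelch(refSamples, idx1, idx2)
    passing <- which(st$p < pThreshold)
    for (dir in c("hyper", "hypo")) {
      cand <- if (dir == "hyper") {
        passing[st$diff[passing] > 0]
      } else {
        passing[st$diff[passing] < 0]
      }
      if (!length(cand)) next
      cand <- cand[order(-abs(st$diff[cand]), rownames(refSamples)[cand])]
      cand <- cand[seq_len(min(capPerDirection, length(cand)))]
      rows[[paste(ct, dir)]] <- data.frame(
        probe_id = rownames(refSamples)[cand],
        provenance = "celltype_dm",
        celltype = ct, direction = dir,
        statistic = st$t[cand], p_value = st$p[cand],
        abs_diff = abs(st$diff[cand]),
        stringsAsFactors = FALSE
      )
    }
  }
  tbl <- if (length(rows)) do.call(rbind, rows) else data.frame(
    probe_id = character(0), provenance = character(0),
    celltype = character(0), direction = character(0),
    statistic = numeric(0), p_value = numeric(0), abs_diff = numeric(0),
    stringsAsFactors = FALSE
  )
  # unique probes: keep the strongest claim on each
  if (nrow(tbl)) {
    tbl <- tbl[order(-tbl$abs_diff), ]
    tbl <- tbl[!duplicated(tbl$probe_id), ]
    tbl <- tbl[order(tbl$probe_id), ]
  }
  tbl$abs_diff <- NULL
  rownames(tbl) <- NULL
  new("ProbePanel",
    table = tbl,
    parameters = list(
      capPerDirection = capPerDirection, pThreshold = pThreshold,
      method = "one_vs_rest_welch"
    )
  )
}

#' Top-variance probe selection
#'
#' Ranks probes by their variance across samples (descending, ties broken
#' by probe id) and keeps the top `nTop`.
#'
#' @param V beta matrix (probes x samples).
#' @param nTop number of probes to keep (`<= nrow(V)`).
#' @return a [ProbePanel-class] with provenance `"variance"`; the variance
#'   is stored in the `statistic` column.
#' @export
selectVarianceProbes <- function(V, nTop) {
  V <- checkBetaMatrix(V)
  if (nTop > nrow(V)) stop("nTop must be <= number of probes")
  v <- apply(V, 1, var)
  if (nTop > 0 && all(v == 0)) {
    warning("all probes have zero variance; selection is by probe id only")
  }
  ord <- order(-v, rownames(V))
  keep <- ord[seq_len(nTop)]
  tbl <- data.frame(
    probe_id = rownames(V)[keep], provenance = "variance",
    celltype = NA_character_, direction = NA_character_,
    statistic = v[keep], p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(tbl) <- NULL
  new("ProbePanel",
    table = tbl, parameters = list(nTop = nTop, method = "top_variance")
  )
}

#' Combine two probe panels
#'
#' Set union of the probe ids; probes present in both panels get provenance
#' `"both"`.
#'
#' @param a,b [ProbePanel-class] objects.
#' @return a [ProbePanel-class] of size `|a| + |b| - |a intersect b|`.
#' @export
combinePanels <- function(a, b) {
  ta <- a@table
  tb <- b@table
  shared <- intersect(ta$probe_id, tb$probe_id)
  ta2 <- ta
  ta2$provenance[ta2$probe_id %in% shared &
    ta2$provenance != tb$provenance[match(ta2$probe_id, tb$probe_id)]] <- "both"
  tb_only <- tb[!(tb$probe_id %in% ta$probe_id), , drop = FALSE]
  tbl <- rbind(ta2, tb_only)
  tbl <- tbl[order(tbl$probe_id), ]
  rownames(tbl) <- NULL
  new("ProbePanel",
    table = tbl,
    parameters = list(a = a@parameters, b = b@parameters, method = "union")
  )
}

#' Probe ids of a panel
#'
#' @param panel a [ProbePanel-class].
#' @return character vector of probe ids.
#' @export
panelProbes <- function(panel) panel@table$probe_id
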