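#' Merge similar NMF components into signatures
#'
#' Hierarchically clusters the columns of `W` by cosine distance (given
#' linkage), cuts the dendrogram at `distanceThreshold`, and merges each
#' cluster: the merged basis column is the element-wise mean of its members
#' (keeping values in `[0, 1]`) and, when `H` is supplied, the merged
#' coefficient row is the sum of member rows (which uniquely preserves the
#' column-sum-to-1 constraint). The dendrogram merge heights are retained so
#' the threshold choice can be inspected the way one would inspect the
#' dendrogram by eye.
#'
#' @param W basis matrix (probes x k), e.g. from [fitNMF()].
#' @param distanceThreshold cosine-distance cut height in `[0, 1]`
#'   (default 0.2).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param H optional coefficient matrix (k x samples) merged alongside.
#' @return an unlabeled [SignatureSet-class].
#' @export
mergeComponents <- function(W, distanceThreshold = 0.2, linkage = "average",
                            H = NULL) {
  if (distanceThreshold < 0 || distanceThreshold > 1) {
    stop("distanceThreshold must lie in [0, 1]")
  }
  k <- ncol(W)
  comp_ids <- colnames(W)
  if (is.null(comp_ids)) comp_ids <- sprintf("component_%d", seq_len(k))
  colnames(W) <- comp_ids
  if (k == 1) {
    groups <- stats::setNames(1L, comp_ids)
    heights <- numeric(0)
  } else {
    D <- cosineDistance(W)
    hc <- hclust(as.dist(D), method = linkage)
    groups <- cutree(hc, h = distanceThreshold)
    names(groups) <- comp_ids
    heights <- hc$height
  }
  n_sig <- max(groups)
  sig_ids <- sprintf("signature_%d", seq_len(n_sig))
  basis <- matrix(0, nrow(W), n_sig, dimnames = list(rownames(W), sig_ids))
  members <- vector("list", n_sig)
  names(members) <- sig_ids
  H_merged <- if (is.null(H)) {
    matrix(0, 0, 0)
  } else {
    matrix(0, n_sig, ncol(H), dimnames = list(sig_ids, colnames(H)))
  }
  for (g in seq_len(n_sig)) {
    idx <- which(groups == g)
    members[[g]] <- comp_ids[idx]
    basis[, g] <- rowMeans(W[, idx, drop = FALSE])
    if (!is.null(H)) H_merged[g, ] <- colSums(H[idx, , drop = FALSE])
  }
  new("SignatureSet",
    basis = basis, H = H_merged, members = members,
    labels = character(0),
    bestReference = data.frame(), mergeHeights = heights,
    threshold = distanceThreshold
  )
}

#' Annotate signatures as stromal or neoplastic
#'
#' Labels each merged signature with the class (`N` neoplastic / `S`
#' stromal) of its most similar reference cell-type profile, comparing over
#' the shared probes by Pearson correlation (or cosine similarity). Ordinal
#' names are then assigned within each class (`N1`, `N2`, ..., `S1`, ...)
#' in descending mean coefficient contribution when the set carries merged
#' `H`, otherwise in column order.
#'
#' @param set an unlabeled [SignatureSet-class] from [mergeComponents()].
#' @param refs reference profiles from [makeReferenceProfiles()], or any
#'   list with a `means` matrix (probes x cell types) and a `celltypeLabels`
#'   vector of `"N"`/`"S"` tags named by cell type.
#' @param similarity `"pearson"` (default) or `"cosine"`.
#' @return the labeled [SignatureSet-class]; columns of `basisMatrix()` are
#'   renamed to the ordinal signature names.
#' @export
annotateSignatures <- function(set, refs, similarity = c("pearson", "cosine")) {
  similarity <- match.arg(similarity)
  stopifnot(is(set, "SignatureSet"))
  M <- refs$means
  ct_labels <- refs$celltypeLabels
  if (!all(c("N", "S") %in% ct_labels)) {
    stop("references must include both a neoplastic (N) and a stromal (S) profile")
  }
  shared <- intersect(rownames(set@basis), rownames(M))
  if (length(shared) == 0) {
    stop("no probes shared between signatures and references")
  }
  Wb <- set@basis[shared, , drop = FALSE]
  Mr <- M[shared, , drop = FALSE]
  simfun <- if (similarity == "pearson") {
    function(a, b) cor(a, b)
  } else {
    function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }
  n_sig <- ncol(Wb)
  best_ct <- character(n_sig)
  best_sim <- numeric(n_sig)
  labels <- character(n_sig)
  for (s in seq_len(n_sig)) {
    sims <- vapply(seq_len(ncol(Mr)), function(j) simfun(Wb[, s], Mr[, j]),
      numeric(1)
    )
    w <- which.max(sims)
    best_ct[s] <- colnames(Mr)[w]
    best_sim[s] <- sims[w]
    labels[s] <- unname(ct_labels[colnames(Mr)[w]])
  }
  # ordinal naming: by descending mean H contribution if available
  contrib <- if (ncol(set@H) > 0) rowMeans(set@H) else rev(seq_len(n_sig))
  new_names <- character(n_sig)
  for (cls in c("N", "S")) {
    idx <- which(labels == cls)
    if (!length(idx)) next
    ord <- idx[order(-contrib[idx])]
    new_names[ord] <- sprintf("%s%d", cls, seq_along(ord))
  }
  basis <- set@basis
  old_names <- colnames(basis)
  colnames(basis) <- new_names
  H <- set@H
  if (ncol(H) > 0) rownames(H) <- new_names
  members <- set@members
  names(members) <- new_names
  new("SignatureSet",
    basis = basis, H = H, members = members, labels = labels,
    bestReference = data.frame(
      signature = new_names, merged_id = old_names, celltype = best_ct,
      similarity = best_sim, label = labels, stringsAsFactors = FALSE
    ),
    mergeHeights = set@mergeHeights, threshold = set@threshold
  )
}

#' Deconvolve bulk methylomes against a signature basis by NNLS
#'
#' For each sample, solves `min_{h >= 0} ||v - W h||_2` over the probes
#' shared between the new matrix and the basis (Lawson-Hanson NNLS), then
#' normalizes the coefficients to per-sample fractions summing to 1. Samples
#' whose raw solution is identically zero are flagged and their fractions
#' set to `NA` rather than silently made uniform.
#'
#' @param Vnew beta matrix (probes x samples) to deconvolve.
#' @param basis signature basis: a probes x k matrix or a
#'   [SignatureSet-class].
#' @return a [DeconvolutionResult-class].
#' @examples
#' refs <- makeReferenceProfiles(3, 150, 10, 0.4, seed = 1)
#' mix <- makeBulkMixtures(refs$means, 20, rep(1, 3), noiseSd = 0.02, seed = 4)
#' dec <- deconvolveNNLS(mix$V, refs$means)
#' head(t(fractions(dec)))
#' @export
deconvolveNNLS <- function(Vnew, basis) {
  if (is(basis, "SignatureSet")) basis <- basisMatrix(basis)
  Vnew <- checkBetaMatrix(Vnew, "Vnew")
  k <- ncol(basis)
  shared <- intersect(rownames(Vnew), rownames(basis))
  if (length(shared) == 0) stop("no probes shared between input and basis")
  if (length(shared) < 2 * k) {
    warning(sprintf(
      "only %d shared probes for %d signatures; estimates may be unstable",
      length(shared), k
    ))
  }
  W <- basis[shared, , drop = FALSE]
  V <- Vnew[shared, , drop = FALSE]
  n <- ncol(V)
  raw <- matrix(0, k, n, dimnames = list(colnames(basis), colnames(Vnew)))
  resid <- numeric(n)
  flagged <- logical(n)
  for (j in seq_len(n)) {
    sol <- pracma::lsqnonneg(W, V[, j])
    raw[, j] <- sol$x
    resid[j] <- sqrt(sum((V[, j] - W %*% sol$x)^2))
  }
  fr <- raw
  cs <- colSums(raw)
  flagged <- cs == 0
  fr[, flagged] <- NA_real_
  ok <- !flagged
  fr[, ok] <- sweep(raw[, ok, drop = FALSE], 2, cs[ok], "/")
  if (any(flagged)) {
    warning(sprintf(
      "%d sample(s) had all-zero NNLS coefficients and were flagged",
      sum(flagged)
    ))
  }
  new("DeconvolutionResult",
    raw = raw, fractions = fr, residualNorm = resid, flagged = flagged
  )
}

#' Dominant stromal and neoplastic signature per sample
#'
#' For every sample, the highest-fraction signature within the stromal set
#' and within the neoplastic set separately (as annotated case profiles are
#' summarized). Ties break toward the earlier signature in column order;
#' flagged samples get `NA`.
#'
#' @param result a [DeconvolutionResult-class].
#' @param labels named character vector of `"N"`/`"S"` per signature, e.g.
#'   `signatureLabels(set)`. When NULL every signature competes in a single
#'   `overall` column.
#' @return data.frame with `sample_id` and `dominant_N` / `dominant_S`
#'   columns (or `dominant` when `labels` is NULL).
#' @export
dominantSignature <- function(result, labels = NULL) {
  fr <- fractions(result)
  sig_ids <- rownames(fr)
  pick <- function(rows, col) {
    if (any(is.na(col[rows]))) return(NA_character_)
    sig_ids[rows[which.max(col[rows])]]
  }
  out <- data.frame(sample_id = colnames(fr), stringsAsFactors = FALSE)
  if (is.null(labels)) {
    out$dominant <- apply(fr, 2, function(col) pick(seq_along(sig_ids), col))
  } else {
    labels <- labels[sig_ids]
    for (cls in c("N", "S")) {
      rows <- which(labels == cls)
      if (!length(rows)) next
      out[[paste0("dominant_", cls)]] <-
        apply(fr, 2, function(col) pick(rows, col))
    }
  }
  out
}

#' Mean pairwise cosine separation within and between classes
#'
#' Quantifies how tightly samples of the same class cluster in a feature
#' space (e.g. signature fractions): `within[c]` is the mean cosine distance
#' over unordered same-class pairs, `between[i, j]` the mean over
#' cross-class pairs. Lower within-class and higher between-class distances
#' indicate tighter class structure. Zero-norm feature vectors are excluded
#' with a warning.
#'
#' @param features numeric matrix, features x samples.
#' @param classLabels class per sample (length `ncol(features)`).
#' @return list with `classIds`, `within` (named vector) and `between`
#'   (symmetric matrix whose diagonal equals `within`).
#' @export
cosineSeparation <- function(features, classLabels) {
  stopifnot(ncol(features) == length(classLabels))
  nrm <- sqrt(colSums(features^2))
  if (any(nrm == 0)) {
    warning(sprintf("excluding %d zero-norm sample(s)", sum(nrm == 0)))
    keep <- nrm > 0
    features <- features[, keep, drop = FALSE]
    classLabels <- classLabels[keep]
  }
  classLabels <- as.character(classLabels)
  class_ids <- unique(classLabels)
  tab <- table(classLabels)
  if (any(tab < 2)) {
    stop("every class needs >= 2 samples for within-class distances")
  }
  D <- cosineDistance(features)
  n_cls <- length(class_ids)
  between <- matrix(0, n_cls, n_cls, dimnames = list(class_ids, class_ids))
  for (i in seq_len(n_cls)) {
    for (j in i:n_cls) {
      si <- which(classLabels == class_ids[i])
      sj <- which(classLabels == class_ids[j])
      block <- D[si, sj, drop = FALSE]
      m <- if (i == j) {
        sum(block[upper.tri(block)]) / (length(si) * (length(si) - 1) / 2)
      } else {
        mean(block)
      }
      between[i, j] <- between[j, i] <- m
    }
  }
  list(
    classIds = class_ids,
    within = stats::setNames(diag(between), class_ids),
    between = between
  )
}
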