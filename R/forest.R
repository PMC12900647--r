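#' Train a random-forest classifier on a beta matrix
#'
#' Thin wrapper around [randomForest::randomForest()] with samples as rows
#' and probes as features, keeping the in-bag counts that
#' [computeProbeUsage()] needs to route training samples through each tree.
#' The forest is an off-the-shelf learner standing in for a production
#' methylation classifier; only its introspection is bespoke.
#'
#' @param beta beta matrix (probes x samples).
#' @param labels class per sample.
#' @param nTrees number of trees (default 200).
#' @param seed integer seed.
#' @param ... passed to [randomForest::randomForest()].
#' @return a `randomForest` object.
#' @export
trainUsageForest <- function(beta, labels, nTrees = 200, seed, ...) {
  beta <- checkBetaMatrix(beta, "beta")
  withSeed(seed, {
    randomForest::randomForest(
      x = t(beta), y = factor(labels), ntree = nTrees, keep.inbag = TRUE, ...
    )
  })
}

# Route in-bag training samples through one tree (matrix from getTree) and
# accumulate signed pair usage. `usage` is modified in the caller's frame via
# the returned increments: returns a list of (probe, i, j, sign_i) rows.
treePairSplits <- function(tree, X, weights, labels, classIds) {
  n_nodes <- nrow(tree)
  # sample index sets per node, built iteratively from the root
  node_samples <- vector("list", n_nodes)
  node_samples[[1]] <- which(weights > 0)
  out <- list()
  for (nd in seq_len(n_nodes)) {
    if (tree[nd, "status"] == -1) next # terminal
    idx <- node_samples[[nd]]
    if (is.null(idx) || !length(idx)) next
    v <- tree[nd, "split var"]
    sp <- tree[nd, "split point"]
    go_left <- X[idx, v] <= sp
    left_id <- tree[nd, "left daughter"]
    right_id <- tree[nd, "right daughter"]
    node_samples[[left_id]] <- idx[go_left]
    node_samples[[right_id]] <- idx[!go_left]
    # weighted class counts on each side
    w <- weights[idx]
    cl <- labels[idx]
    left_counts <- vapply(classIds, function(c) sum(w[go_left & cl == c]), 0)
    right_counts <- vapply(classIds, function(c) sum(w[!go_left & cl == c]), 0)
    present <- which(left_counts + right_counts > 0)
    if (length(present) < 2) next
    for (a in seq_along(present)[-length(present)]) {
      for (b in (a + 1):length(present)) {
        i <- present[a]
        j <- present[b]
        # strict majorities routed to opposite children
        i_left <- left_counts[i] > right_counts[i]
        i_right <- right_counts[i] > left_counts[i]
        j_left <- left_counts[j] > right_counts[j]
        j_right <- right_counts[j] > left_counts[j]
        if (i_left && j_right) {
          out[[length(out) + 1L]] <- c(v, i, j, -1) # i hypo at split
        } else if (i_right && j_left) {
          out[[length(out) + 1L]] <- c(v, i, j, +1) # i hyper at split
        }
      }
    }
  }
  out
}

#' Signed class-pair probe usage of a trained random forest
#'
#' Counts, for every probe and unordered class pair, the number of internal
#' nodes across the ensemble where a split on that probe discriminates the
#' pair: both classes have in-bag training samples at the node and their
#' (weighted) majorities route to opposite children. The count is stored
#' signed from each class's perspective: negative when the class's majority
#' routes to the low-beta (`<=` threshold) child, i.e. the probe is
#' hypomethylated at those splits for that class, positive when
#' hypermethylated. Entries `[p, i, j]` and `[p, j, i]` are therefore equal
#' in magnitude and opposite in sign.
#'
#' @param forest a `randomForest` trained with `keep.inbag = TRUE`, e.g.
#'   from [trainUsageForest()].
#' @param trainingData the beta matrix (probes x samples) the forest was
#'   trained on.
#' @param labels the training class labels.
#' @return a [ProbeUsageArray-class].
#' @export
computeProbeUsage <- function(forest, trainingData, labels) {
  trainingData <- checkBetaMatrix(trainingData, "trainingData")
  if (is.null(forest$inbag)) {
    stop("forest must be trained with keep.inbag = TRUE")
  }
  feat_names <- rownames(forest$importance)
  if (!identical(feat_names, rownames(trainingData))) {
    stop("forest features do not match the rows of trainingData")
  }
  labels <- as.character(labels)
  class_ids <- levels(forest$y)
  if (!all(labels %in% class_ids)) {
    stop("labels contain classes the forest was not trained on")
  }
  X <- t(trainingData)
  n_probes <- nrow(trainingData)
  n_cls <- length(class_ids)
  usage <- array(
    0,
    dim = c(n_probes, n_cls, n_cls),
    dimnames = list(rownames(trainingData), class_ids, class_ids)
  )
  for (tr in seq_len(forest$ntree)) {
    tree <- randomForest::getTree(forest, tr, labelVar = FALSE)
    incs <- treePairSplits(tree, X, forest$inbag[, tr], labels, class_ids)
    for (inc in incs) {
      p <- inc[1]; i <- inc[2]; j <- inc[3]; s <- inc[4]
      usage[p, i, j] <- usage[p, i, j] + s
      usage[p, j, i] <- usage[p, j, i] - s
    }
  }
  new("ProbeUsageArray", usage = usage, classIds = class_ids)
}

#' One-vs-rest summary of signed probe usage
#'
#' For each probe and class, the signed sum of that class's pair usage
#' against all other classes. Negative values mean the probe is
#' predominantly hypomethylated at the splits isolating that class.
#'
#' @param usage a [ProbeUsageArray-class].
#' @return numeric matrix, probes x classes, of signed sums.
#' @export
summarizeOneVsRest <- function(usage) {
  stopifnot(is(usage, "ProbeUsageArray"))
  apply(usage@usage, c(1, 2), sum)
}

#' Correlate probe methylation with a per-sample abundance covariate
#'
#' Per-probe correlation (Pearson or Spearman) between beta values and a
#' scalar covariate such as marker-positive staining abundance, with a
#' two-sided p-value from the t approximation. Zero-variance probes are
#' reported as `NA`.
#'
#' @param V beta matrix (probes x samples).
#' @param abundance numeric covariate, one value per sample.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with `probe_id`, `r`, `p_value`.
#' @export
correlateAbundance <- function(V, abundance, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  V <- checkBetaMatrix(V)
  stopifnot(length(abundance) == ncol(V))
  n <- ncol(V)
  if (n < 3) stop("need >= 3 samples for correlation")
  y <- if (method == "spearman") rank(abundance) else abundance
  X <- if (method == "spearman") t(apply(V, 1, rank)) else V
  xc <- X - rowMeans(X)
  yc <- y - mean(y)
  denom <- sqrt(rowSums(xc^2) * sum(yc^2))
  r <- as.numeric(xc %*% yc) / denom
  r[denom == 0 | !is.finite(r)] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(
    probe_id = rownames(V), r = r, p_value = p, stringsAsFactors = FALSE
  )
}
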