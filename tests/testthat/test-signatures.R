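makePairedBasis <- function() {
  # 6 columns = 3 planted pairs: within-pair cosine distance < 0.05,
  # across-pair > 0.5
  base <- stromasig:::withSeed(21, {
    list(
      a = c(runif(40, 0.6, 1), runif(80, 0, 0.05)),
      b = c(runif(40, 0, 0.05), runif(40, 0.6, 1), runif(40, 0, 0.05)),
      c = c(runif(80, 0, 0.05), runif(40, 0.6, 1))
    )
  })
  W <- cbind(
    base$a, base$a + 0.02, base$b, base$b + 0.02, base$c, base$c + 0.02
  )
  W <- stromasig:::clip01(W)
  dimnames(W) <- list(
    sprintf("cg%03d", 1:120), sprintf("component_%d", 1:6)
  )
  W
}

test_that("hierarchical merging groups the planted component pairs", {
  W <- makePairedBasis()
  # brute-force pairwise distances confirm the planted structure
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
    expect_lt(bruteCosineDist(W[, p[1]], W[, p[2]]), 0.05)
  }
  expect_gt(bruteCosineDist(W[, 1], W[, 3]), 0.5)

  set <- mergeComponents(W, distanceThreshold = 0.2)
  expect_identical(ncol(basisMatrix(set)), 3L)
  pairing <- lapply(set@members, sort)
  expect_setequal(
    vapply(pairing, paste, character(1), collapse = "+"),
    c("component_1+component_2", "component_3+component_4",
      "component_5+component_6")
  )
  # merged column = element-wise mean of members
  m1 <- set@members[[1]]
  expect_equal(
    basisMatrix(set)[, 1], rowMeans(W[, m1]),
    ignore_attr = TRUE
  )
})

test_that("identical columns collapse and orthogonal columns persist", {
  v <- c(0.2, 0.6, 0.4)
  W <- cbind(a = v, b = v)
  set <- mergeComponents(W, distanceThreshold = 0.1)
  expect_identical(ncol(basisMatrix(set)), 1L)
  expect_equal(basisMatrix(set)[, 1], v, ignore_attr = TRUE)

  Wo <- diag(3) * 0.8
  colnames(Wo) <- letters[1:3]
  expect_identical(ncol(basisMatrix(mergeComponents(Wo, 0.5))), 3L)

  expect_error(mergeComponents(W, 1.5), "distanceThreshold")
})

test_that("merged H rows are member sums, preserving the simplex", {
  W <- makePairedBasis()
  H <- stromasig:::withSeed(5, {
    h <- matrix(runif(6 * 10), 6, 10)
    sweep(h, 2, colSums(h), "/")
  })
  set <- mergeComponents(W, 0.2, H = H)
  expect_equal(max(abs(colSums(coefMatrix(set)) - 1)), 0, tolerance = 1e-12)
  expect_equal(
    coefMatrix(set)[1, ], colSums(H[match(set@members[[1]], colnames(W)), ]),
    ignore_attr = TRUE
  )
})

refFixture <- function() {
  refs <- makeReferenceProfiles(3, 150, 15, 0.4,
    seed = 31, neoplastic = "celltype_1"
  )
  names(refs$celltypeLabels) <- colnames(refs$means)
  refs
}

test_that("signatures inherit the label of their most similar reference", {
  refs <- refFixture()
  neo <- refs$means[, 1]
  imm <- refs$means[, 2]
  W <- cbind(sig_a = imm, sig_b = neo, sig_c = 0.9 * neo + 0.1 * imm)
  # threshold 0 keeps the three components separate (none are identical)
  set <- mergeComponents(W, distanceThreshold = 0)
  ann <- annotateSignatures(set, refs)
  br <- ann@bestReference
  # order of merged signatures follows component order here
  expect_identical(br$label[br$merged_id == "signature_1"], "S")
  expect_equal(br$similarity[br$merged_id == "signature_1"], 1.0)
  expect_identical(br$celltype[br$merged_id == "signature_1"], "celltype_2")
  expect_identical(br$label[br$merged_id == "signature_2"], "N")
  # brute-force correlation comparison for the 90/10 blend
  blend_cors <- apply(refs$means, 2, function(r) cor(W[, 3], r))
  expect_identical(
    br$celltype[br$merged_id == "signature_3"],
    names(which.max(blend_cors))
  )
  expect_identical(br$label[br$merged_id == "signature_3"], "N")
  # ordinal names unique, one per signature
  expect_setequal(grepl("^[NS][0-9]+$", colnames(basisMatrix(ann))), TRUE)
})

test_that("annotation is invariant to probe order and extra probes", {
  refs <- refFixture()
  W <- cbind(sig_a = refs$means[, 2], sig_b = refs$means[, 1])
  set <- mergeComponents(W, 0.01)
  lab1 <- signatureLabels(annotateSignatures(set, refs))

  shuf <- sample(nrow(W))
  W2 <- W[shuf, ]
  extra <- matrix(runif(20 * 2), 20, 2,
    dimnames = list(sprintf("extra%02d", 1:20), colnames(W))
  )
  set2 <- mergeComponents(rbind(W2, extra), 0.01)
  lab2 <- signatureLabels(annotateSignatures(set2, refs))
  expect_identical(unname(lab1), unname(lab2))

  bad <- W
  rownames(bad) <- sprintf("other%03d", seq_len(nrow(W)))
  expect_error(
    annotateSignatures(mergeComponents(bad, 0.01), refs), "shared"
  )
})

test_that("NNLS deconvolution is exact in the noiseless full-rank case", {
  W <- makeSignatureBasis(100, 4, seed = 41)
  h <- c(0.4, 0.3, 0.2, 0.1)
  v <- W %*% h
  dimnames(v) <- list(rownames(W), "s1")
  dec <- deconvolveNNLS(clip01(v), W)
  expect_equal(unname(fractions(dec)[, 1]), h, tolerance = 1e-6)
  expect_false(any(dec@flagged))
})

test_that("samples orthogonal to the basis are flagged, not uniformized", {
  W <- matrix(0, 6, 2, dimnames = list(sprintf("cg%d", 1:6), c("a", "b")))
  W[1:2, 1] <- 0.8
  W[3:4, 2] <- 0.8
  V <- matrix(0, 6, 2, dimnames = list(rownames(W), c("s1", "s2")))
  V[5:6, 1] <- 0.9 # disjoint support from every basis column
  V[1, 2] <- 0.4
  expect_warning(dec <- deconvolveNNLS(V, W), "flagged")
  expect_true(dec@flagged[1])
  expect_true(all(is.na(fractions(dec)[, 1])))
  expect_false(dec@flagged[2])
})

test_that("fractions recover the generating proportions within MAE 0.05", {
  maes <- vapply(1:3, function(s) {
    refs <- makeReferenceProfiles(3, 200, 20, 0.4, seed = s)
    mix <- makeBulkMixtures(refs$means, 50, rep(1, 3),
      noiseSd = 0.02, seed = s + 100
    )
    dec <- deconvolveNNLS(mix$V, mix$truth$W)
    mean(abs(fractions(dec) - mix$truth$H))
  }, numeric(1))
  expect_lt(max(maes), 0.05)
})

test_that("merge-then-deconvolve recovers merged ground truth", {
  # duplicate true components so merging is required before deconvolution
  W <- makeSignatureBasis(150, 3, seed = 55)
  Wdup <- cbind(W, W[, 1] + 0.01)
  colnames(Wdup) <- sprintf("component_%d", 1:4)
  mix <- makeBulkMixtures(stromasig:::clip01(Wdup), 40, rep(1, 4),
    noiseSd = 0.02, seed = 56
  )
  set <- mergeComponents(mix$truth$W, 0.2, H = mix$truth$H)
  expect_identical(ncol(basisMatrix(set)), 3L)
  dec <- deconvolveNNLS(mix$V, basisMatrix(set))
  expect_lt(mean(abs(fractions(dec) - coefMatrix(set))), 0.05)
})

test_that("dominant signatures match brute-force argmax with tie-break", {
  fr <- rbind(
    N1 = c(0.05, 0.3, 0.25),
    N2 = c(0.05, 0.3, 0.25),
    S1 = c(0.9, 0.2, 0.25),
    S2 = c(0.0, 0.2, 0.25)
  )
  colnames(fr) <- sprintf("s%d", 1:3)
  dec <- new("DeconvolutionResult",
    raw = fr, fractions = fr,
    residualNorm = rep(0, 3), flagged = rep(FALSE, 3)
  )
  labels <- c(N1 = "N", N2 = "N", S1 = "S", S2 = "S")
  dom <- dominantSignature(dec, labels)
  expect_identical(dom$dominant_S, c("S1", "S1", "S1")) # ties -> first
  expect_identical(dom$dominant_N, c("N1", "N1", "N1"))

  # random fixture vs brute force over all signatures
  fr2 <- stromasig:::withSeed(9, matrix(runif(20), 4, 5))
  fr2 <- sweep(fr2, 2, colSums(fr2), "/")
  dimnames(fr2) <- list(sprintf("sig%d", 1:4), sprintf("s%d", 1:5))
  dec2 <- new("DeconvolutionResult",
    raw = fr2, fractions = fr2,
    residualNorm = rep(0, 5), flagged = rep(FALSE, 5)
  )
  dom2 <- dominantSignature(dec2)
  expect_identical(
    dom2$dominant,
    rownames(fr2)[apply(fr2, 2, which.max)]
  )
})

test_that("cosine separation equals the brute-force double loop", {
  X <- stromasig:::withSeed(17, matrix(runif(4 * 6, 0.1, 1), 4, 6))
  colnames(X) <- sprintf("s%d", 1:6)
  cls <- c("a", "a", "a", "b", "b", "b")
  sep <- cosineSeparation(X, cls)
  # brute force
  brute <- function(idx_i, idx_j, same) {
    vals <- c()
    for (i in idx_i) {
      for (j in idx_j) {
        if (same && j <= i) next
        vals <- c(vals, bruteCosineDist(X[, i], X[, j]))
      }
    }
    mean(vals)
  }
  expect_equal(unname(sep$within["a"]), brute(1:3, 1:3, TRUE))
  expect_equal(unname(sep$within["b"]), brute(4:6, 4:6, TRUE))
  expect_equal(sep$between["a", "b"], brute(1:3, 4:6, FALSE))
  expect_equal(sep$between["a", "b"], sep$between["b", "a"])
  expect_equal(diag(sep$between), sep$within)
})

test_that("cosine separation degenerate and invariance cases", {
  X <- matrix(rep(c(0.2, 0.4), 4), 2, 4)
  colnames(X) <- sprintf("s%d", 1:4)
  sep <- cosineSeparation(X, c("a", "a", "b", "b"))
  expect_equal(unname(sep$within), c(0, 0))
  expect_equal(sep$between["a", "b"], 0)

  Y <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)) * 0.5
  colnames(Y) <- sprintf("s%d", 1:4)
  sep2 <- cosineSeparation(Y, c("a", "a", "b", "b"))
  expect_equal(unname(sep2$within), c(0, 0))
  expect_equal(sep2$between["a", "b"], 1)

  # invariance to positive rescaling of any one feature vector
  Z <- stromasig:::withSeed(3, matrix(runif(12, 0.1, 1), 3, 4))
  colnames(Z) <- sprintf("s%d", 1:4)
  Z2 <- Z
  Z2[, 2] <- Z2[, 2] * 7
  s1 <- cosineSeparation(Z, c("a", "a", "b", "b"))
  s2 <- cosineSeparation(Z2, c("a", "a", "b", "b"))
  expect_equal(s1$between, s2$between)
})
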