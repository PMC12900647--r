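test_that("reference profiles plant disjoint marker blocks within [0,1]", {
  refs <- makeReferenceProfiles(2, 100, 10, 0.4, seed = 1)
  expect_equal(dim(refs$means), c(100, 2))
  expect_true(all(refs$means >= 0 & refs$means <= 1))
  planted <- c(unlist(refs$plantedHyper), unlist(refs$plantedHypo))
  expect_length(planted, 40)
  expect_false(anyDuplicated(planted) > 0)
  expect_true(all(planted %in% rownames(refs$means)))

  # degenerate shift: sets recorded, means untouched
  refs0 <- makeReferenceProfiles(2, 100, 10, 0, seed = 1)
  expect_length(unlist(refs0$plantedHyper), 20)
  expect_equal(unname(refs0$means[, 1]), unname(refs0$baseline))

  expect_error(
    makeReferenceProfiles(4, 100, 20, 0.4, seed = 1),
    "infeasible"
  )
})

test_that("planted shifts recompute to delta before clipping", {
  refs <- makeReferenceProfiles(4, 2000, 50, 0.4,
    baselineRange = c(0.2, 0.8), seed = 7
  )
  for (ct in colnames(refs$means)) {
    hyper <- refs$plantedHyper[[ct]]
    raw_shift <- refs$baseline[hyper] + 0.4
    expect_equal(
      unname(refs$means[hyper, ct]), unname(pmin(raw_shift, 1))
    )
    shifts <- raw_shift - refs$baseline[hyper]
    expect_equal(mean(shifts), 0.4)
    hypo <- refs$plantedHypo[[ct]]
    expect_equal(
      unname(refs$means[hypo, ct]),
      unname(pmax(refs$baseline[hypo] - 0.4, 0))
    )
  }
})

test_that("reference replicates scatter around the cell-type means", {
  refs <- makeReferenceProfiles(2, 400, 10, 0.4, seed = 2)

  smp0 <- makeReferenceSamples(refs, 5, 0, seed = 3)
  expect_equal(unname(smp0$beta[, 1]), unname(refs$means[, smp0$labels[1]]))
  expect_length(smp0$labels, 10)

  smp <- makeReferenceSamples(refs, 20, 0.05, seed = 3)
  expect_length(smp$labels, 40)
  expect_true(all(smp$beta >= 0 & smp$beta <= 1))
  # empirical per-probe sd close to nominal for interior probes
  idx <- which(smp$labels == smp$labels[1])
  mu <- refs$means[, smp$labels[1]]
  interior <- mu > 0.15 & mu < 0.85
  sds <- apply(smp$beta[interior, idx], 1, sd)
  expect_gt(mean(sds >= 0.03 & sds <= 0.07), 0.9)

  expect_error(makeReferenceSamples(refs, 5, -0.1, seed = 1), "withinSd")
})

test_that("bulk mixtures realize V = clip(WH + noise) with simplex H", {
  W <- makeSignatureBasis(200, 3, seed = 11)
  mix <- makeBulkMixtures(W, 60, rep(1, 3), noiseSd = 0.02, seed = 11)
  H <- mix$truth$H
  expect_equal(max(abs(colSums(H) - 1)), 0, tolerance = 1e-9)
  expect_true(all(mix$V >= 0 & mix$V <= 1))
  expect_identical(dim(mix$V), c(200L, 60L))
  # class labels align with the Dirichlet that produced each column
  expect_length(mix$truth$classLabels, 60)

  # truncated-Gaussian mean absolute deviation, recomputed from the truth
  mad_emp <- mean(abs(mix$V - W %*% H))
  expect_gt(mad_emp, 0.012)
  expect_lt(mad_emp, 0.020)

  # zero noise, no clipping: exact factorization at the true rank
  mix0 <- makeBulkMixtures(W, 60, rep(1, 3), noiseSd = 0, seed = 11)
  expect_equal(mix0$V, W %*% mix0$truth$H, ignore_attr = TRUE)
  expect_identical(qr(mix0$V)$rank, 3L)

  expect_error(makeBulkMixtures(W, 10, rep(1, 4), 0, seed = 1), "components")
  expect_error(makeBulkMixtures(W, 10, c(1, 0, 1), 0, seed = 1), "positive")
})

test_that("class-conditional Dirichlet mixing yields dominant signatures", {
  W <- makeSignatureBasis(120, 3, seed = 4)
  alpha <- rbind(c(8, 1, 1), c(1, 8, 1), c(1, 1, 8))
  mix <- makeBulkMixtures(W, 60, alpha, noiseSd = 0, seed = 5)
  cls <- mix$truth$classLabels
  for (c in unique(cls)) {
    idx <- which(cls == c)
    dom <- apply(mix$truth$H[, idx], 2, which.max)
    expect_gt(mean(dom == match(c, unique(cls))), 0.7)
  }
})

test_that("generators are seed-deterministic and leave global RNG alone", {
  a <- makeBulkMixtures(makeSignatureBasis(50, 2, 1), 10, c(1, 1), 0.02, seed = 9)
  b <- makeBulkMixtures(makeSignatureBasis(50, 2, 1), 10, c(1, 1), 0.02, seed = 9)
  expect_identical(a, b)
  c <- makeBulkMixtures(makeSignatureBasis(50, 2, 1), 10, c(1, 1), 0.02, seed = 10)
  expect_false(identical(a$V, c$V))

  set.seed(123)
  before <- .Random.seed
  invisible(makeReferenceProfiles(2, 50, 5, 0.3, seed = 77))
  expect_identical(before, .Random.seed)
})

test_that("two-class forest data differs only at planted probes", {
  dat0 <- makeTwoClassForestData(50, 0, 10, 0.6, seed = 1)
  expect_identical(nrow(dat0$planted), 0L)

  dat <- makeTwoClassForestData(100, 2, 50, 0.6, seed = 5)
  expect_identical(nrow(dat$planted), 2L)
  expect_true(all(dat$planted$direction %in% c("A_hypo", "A_hyper")))
  mA <- rowMeans(dat$beta[, dat$labels == "A"])
  mB <- rowMeans(dat$beta[, dat$labels == "B"])
  d <- mA - mB
  planted_idx <- match(dat$planted$probe_id, rownames(dat$beta))
  expect_true(all(abs(d[planted_idx]) > 0.5))
  expect_true(all(abs(d[-planted_idx]) < 0.1))
  # recorded direction matches the sign of the recomputed difference
  expect_equal(
    dat$planted$direction,
    unname(ifelse(d[planted_idx] < 0, "A_hypo", "A_hyper"))
  )

  expect_error(makeTwoClassForestData(10, 20, 5, 0.5, seed = 1), "nInformative")
  expect_error(makeTwoClassForestData(10, 2, 1, 0.5, seed = 1), "nPerClass")
})

test_that("survival cohort hazard tracks the immune stratum", {
  coh <- makeSurvivalCohort(400,
    hazardRatioLowVsHigh = 3, baselineRate = 0.1,
    censorTime = 20, seed = 2
  )
  expect_true(all(coh$time >= 0))
  expect_true(all(coh$event %in% c(0, 1)))
  q3 <- unname(quantile(coh$immune_fraction, 0.75))
  lo <- coh$immune_fraction <= q3
  rate_ratio <- (sum(coh$event[lo]) / sum(coh$time[lo])) /
    (sum(coh$event[!lo]) / sum(coh$time[!lo]))
  expect_gt(rate_ratio, 2)
  expect_lt(rate_ratio, 4.5)

  # infinite follow-up: every subject has an event
  coh_inf <- makeSurvivalCohort(50,
    hazardRatioLowVsHigh = 2, baselineRate = 0.1,
    censorTime = Inf, seed = 3
  )
  expect_true(all(coh_inf$event == 1))

  expect_error(
    makeSurvivalCohort(10, NULL, 1, 0.1, censorTime = 0, seed = 1),
    "censorTime"
  )
})
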