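test_that("global medians: per-sample then per-group, order invariant", {
  sh <- studySheet(c("p1", "p2"))
  b <- matrix(0.7, 5, 6, dimnames = list(paste0("cg", 1:5), sh$sample_id))
  gm <- globalMedian(BetaSet(b, sh))
  expect_true(all(gm$sampleMedians == 0.7))
  expect_true(all(gm$groupMedians == 0.7))

  b2 <- matrix(stats::runif(30), 5, 6,
               dimnames = list(paste0("cg", 1:5), sh$sample_id))
  bs <- BetaSet(b2, sh)
  perm <- BetaSet(b2[sample(5), sample(6)], sh)
  g1 <- globalMedian(bs)
  g2 <- globalMedian(perm)
  expect_equal(g1$sampleMedians[names(g2$sampleMedians)], g2$sampleMedians)
  expect_equal(g1$groupMedians, g2$groupMedians)

  odd <- matrix(c(0.1, 0.2, 0.9), 3, 6,
                dimnames = list(paste0("cg", 1:3), sh$sample_id))
  expect_true(all(globalMedian(BetaSet(odd, sh))$sampleMedians == 0.2))
})

test_that("group medians order baseline below post-diet and healthy on planted data", {
  sim <- simulateCohort(simulationConfig(n_probes = 300L,
    n_planted_hyper = 150L, n_planted_hypo = 5L, seed = 12L))
  gm <- globalMedian(sim$betas)$groupMedians
  expect_lt(gm[["T1"]], gm[["T2"]])
  expect_lt(gm[["T1"]], gm[["T3"]])
  expect_lte(gm[["T1"]], gm[["healthy_blood"]])
})

test_that("PCA is sign-deterministic, bounded and reconstructs the data", {
  set.seed(30)
  b <- matrix(stats::runif(200), 20, 10,
              dimnames = list(paste0("cg", 1:20), paste0("s", 1:10)))
  pc <- pcaProfiles(b, nComponents = 10)
  expect_true(all(pc$varianceExplained >= 0 & pc$varianceExplained <= 1))
  expect_true(all(diff(pc$varianceExplained) <= 1e-12))
  expect_lte(sum(pc$varianceExplained), 1 + 1e-12)
  for (j in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  x <- t(b)
  centred <- sweep(x, 2, colMeans(x))
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(unname(recon), unname(centred), tolerance = 1e-8)

  ident <- matrix(0.4, 5, 3, dimnames = list(paste0("cg", 1:5),
                                             paste0("s", 1:3)))
  expect_true(all(pcaProfiles(ident, 2)$varianceExplained == 0))
  expect_error(pcaProfiles(b, nComponents = 11), "fewer samples")
})

test_that("PC1 separates baseline from post-diet samples under a strong shift", {
  sim <- simulateCohort(simulationConfig(n_probes = 400L,
    n_planted_hyper = 80L, n_planted_hypo = 5L, delta_effect = 0.3,
    noise_sd = 0.02, seed = 14L))
  pan <- plantedProbes(sim$truth)
  bs <- sim$betas
  pc <- pcaProfiles(betaValues(bs)[pan, ], nComponents = 2)
  expect_gt(pc$varianceExplained[1], 0.8)
  strata <- ifelse(sampleSheet(bs)$group == "study",
                   sampleSheet(bs)$timepoint, "healthy")
  t1Scores <- pc$scores[strata == "T1", 1]
  otherScores <- pc$scores[strata != "T1", 1]
  expect_true(max(t1Scores) < min(otherScores) ||
              min(t1Scores) > max(otherScores))
})

test_that("clinical correlations report exact r and Bonferroni-adjusted p", {
  x <- stats::setNames(seq(0.4, 0.6, length.out = 10), paste0("s", 1:10))
  clin <- data.frame(a = unname(x), b = -unname(x),
                     row.names = paste0("s", 1:10))
  r <- correlateGlobals(x, clin)
  expect_equal(r$r[r$parameter == "a"], 1)
  expect_equal(r$r[r$parameter == "b"], -1)
  expect_true(all(r$p_adjusted == pmin(1, 2 * r$p)))

  clin$c <- 5  # zero variance
  expect_warning(r2 <- correlateGlobals(x, clin), "zero variance")
  expect_true(is.na(r2$r[r2$parameter == "c"]))
})

test_that("independent parameters rarely survive Bonferroni at the study size", {
  set.seed(99)
  nSig <- 0L
  nSigAdj <- 0L
  for (rep in 1:40) {
    x <- stats::setNames(stats::rnorm(18), paste0("s", 1:18))
    clin <- as.data.frame(matrix(stats::rnorm(18 * 20), 18, 20))
    rownames(clin) <- names(x)
    r <- correlateGlobals(x, clin)
    nSig <- nSig + sum(r$p < 0.05)
    nSigAdj <- nSigAdj + sum(r$p_adjusted < 0.05)
  }
  expect_gt(nSig / 40, 0.3)     # ~1 raw hit per 20 parameters
  expect_lt(nSigAdj / 40, 0.3)  # essentially none after adjustment
})
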