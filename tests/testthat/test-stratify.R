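liverFixture <- function(seed = 1L, ...) {
  cfg <- simulationConfig(n_probes = 400L, n_planted_hyper = 30L,
                          n_planted_hypo = 5L, seed = seed, ...)
  sim <- simulateCohort(cfg)
  list(lv = simulateLiverPanel(cfg, sim$truth),
       panel = plantedProbes(sim$truth))
}

test_that("disjoint constant profiles give the closed-form 2x2 chi-square", {
  bs <- disjointLiver()
  r <- clusterAndTest(bs, paste0("cg", 1:8), k = 2)
  expect_equal(r@chi2, 20)
  expect_equal(r@df, 1)
  expect_true(all(sort(as.vector(r@contingency)) == c(0, 0, 10, 10)))
})

test_that("the chi-square statistic matches an explicit O/E loop", {
  f <- liverFixture(seed = 2L)
  r <- clusterAndTest(f$lv, f$panel)
  expect_equal(r@chi2, oracleChi2(r@contingency))
  set.seed(17)
  for (rep in 1:10) {
    tab <- matrix(stats::rpois(12, 20) + 1, 3, 4)
    expect_equal(
      unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic),
      oracleChi2(tab))
  }
})

test_that("clustering recovers simulated grades and warns on sparse cells", {
  f <- liverFixture(seed = 3L)
  r <- clusterAndTest(f$lv, f$panel)
  expect_lt(r@p, 1e-10)
  expect_equal(sum(r@contingency), 160)
  expect_warning(clusterAndTest(disjointLiver(4, 10), paste0("cg", 1:8),
                                k = 2), "expected cell")
  expect_error(clusterAndTest(f$lv, f$panel, k = 1000), "exceeds")
})

test_that("classifier is byte-reproducible under a fixed seed", {
  f <- liverFixture(seed = 4L)
  a <- classifyGrades(f$lv, f$panel, seed = 11)
  b <- classifyGrades(f$lv, f$panel, seed = 11)
  expect_identical(a@foldAUC, b@foldAUC)
  expect_identical(a@scores, b@scores)
  c <- classifyGrades(f$lv, f$panel, seed = 12)
  expect_false(identical(a@scores, c@scores))
})

test_that("held-out AUC flips exactly under label inversion and matches the rank formula", {
  f <- liverFixture(seed = 5L)
  r <- classifyGrades(f$lv, f$panel, seed = 2)
  pooled <- as.numeric(pROC::auc(pROC::roc(
    response = r@truthLabels, predictor = r@scores,
    levels = c(0, 1), direction = "<", quiet = TRUE)))
  expect_equal(pooled, oracleAUC(r@scores, r@truthLabels))
  anti <- as.numeric(pROC::auc(pROC::roc(
    response = 1L - r@truthLabels, predictor = r@scores,
    levels = c(0, 1), direction = "<", quiet = TRUE)))
  expect_equal(anti, 1 - pooled)
  expect_equal(oracleAUC(r@scores, 1L - r@truthLabels), 1 - pooled)
})

test_that("identical feature rows carry no class information", {
  probes <- paste0("cg", 1:5)
  ids <- sprintf("L%02d", 1:24)
  b <- matrix(rep(stats::runif(5, 0.3, 0.7), 24), 5, 24,
              dimnames = list(probes, ids))
  sh <- data.frame(sample_id = ids, patient_id = paste0("pt", 1:24),
                   timepoint = NA_character_, group = "nafld_liver",
                   tissue = "liver",
                   fibrosis_grade = rep(c(0L, 3L), each = 12))
  r <- classifyGrades(BetaSet(b, sh), probes, nFolds = 4, seed = 1)
  expect_equal(r@meanAUC, 0.5, tolerance = 0.2)
  expect_error(classifyGrades(BetaSet(b, sh), probes, nFolds = 13),
               "fewer samples than folds")
})

test_that("heatmap leaf order is invariant to input sample permutation", {
  f <- liverFixture(seed = 6L)
  ord1 <- crossTissueHeatmapOrder(f$lv, f$panel)
  set.seed(2)
  b <- betaValues(f$lv)
  perm <- BetaSet(b[sample(nrow(b)), sample(ncol(b))], sampleSheet(f$lv))
  ord2 <- crossTissueHeatmapOrder(perm, f$panel)
  expect_identical(ord1$sampleOrder, ord2$sampleOrder)
  expect_identical(ord1$probeOrder, ord2$probeOrder)

  single <- BetaSet(b[f$panel, 1, drop = FALSE],
                    sampleSheet(f$lv)[1, , drop = FALSE])
  o <- crossTissueHeatmapOrder(single, f$panel)
  expect_identical(o$sampleOrder, colnames(b)[1])
  expect_error(crossTissueHeatmapOrder(f$lv, character()), "empty")
})

test_that("baseline blood samples split from post-diet and healthy in the 2-cut", {
  sim <- simulateCohort(simulationConfig(n_probes = 400L,
    n_planted_hyper = 40L, n_planted_hypo = 4L, seed = 8L))
  pan <- plantedProbes(sim$truth)
  ord <- crossTissueHeatmapOrder(sim$betas, pan)
  cl <- stats::cutree(ord$sampleHclust, k = 2)
  sh <- sampleSheet(sim$betas)
  strata <- ifelse(sh$group == "study", sh$timepoint, "healthy")
  names(strata) <- sh$sample_id
  t1Cl <- cl[names(cl) %in% sh$sample_id[strata == "T1"]]
  restCl <- cl[names(cl) %in% sh$sample_id[strata != "T1"]]
  expect_equal(length(unique(t1Cl)), 1)
  expect_equal(length(unique(restCl)), 1)
  expect_false(unique(t1Cl) == unique(restCl))
})
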