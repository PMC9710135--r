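test_that("delta-beta is mean(post-diet) minus baseline, per patient", {
  sh <- studySheet("p1")
  b <- matrix(c(0.2, 0.5, 0.7), nrow = 1,
              dimnames = list("cg1", sh$sample_id))
  expect_equal(computeDelta(BetaSet(b, sh))["cg1", "p1"], 0.4)
  b[] <- 0.5
  expect_equal(computeDelta(BetaSet(b, sh))["cg1", "p1"], 0)
})

test_that("a patient missing one post-diet timepoint falls back to the other", {
  sh <- studySheet("p1", c("T1", "T2"))
  b <- matrix(c(0.9, 0.6), nrow = 1, dimnames = list("cg1", sh$sample_id))
  expect_equal(computeDelta(BetaSet(b, sh))["cg1", "p1"], -0.3)
})

test_that("missing baseline or missing both post-diet timepoints is an error", {
  sh <- studySheet("p1", c("T2", "T3"))
  b <- tinyBeta(1, 2)
  colnames(b) <- sh$sample_id
  expect_error(computeDelta(BetaSet(b, sh)), "exactly one T1")
  sh2 <- studySheet("p1", "T1")
  b2 <- tinyBeta(1, 1)
  colnames(b2) <- sh2$sample_id
  expect_error(computeDelta(BetaSet(b2, sh2)), "neither")
})

test_that("per-probe missing values exclude that patient from the consensus denominator", {
  sh <- studySheet(c("p1", "p2", "p3"))
  b <- matrix(0.5, nrow = 1, ncol = 9, dimnames = list("cg1", sh$sample_id))
  b[1, sh$timepoint != "T1" & sh$patient_id == "p1"] <- 0.7
  b[1, sh$timepoint != "T1" & sh$patient_id == "p2"] <- 0.7
  b[1, "p3_T1"] <- NA  # p3 not evaluable at this probe
  d <- computeDelta(BetaSet(b, sh))
  expect_true(is.na(d["cg1", "p3"]))
  res <- callSites(d, delta_threshold = 0.1, consensus_fraction = 0.77)
  # 2 of 2 evaluable patients reach the bar (ceil(0.77 * 2) = 2)
  expect_identical(as.character(res@call[["cg1"]]), "hyper")
  expect_identical(res@nEval, 2L)
})

test_that("minimum consensus count is the ceiling of fraction times n", {
  expect_identical(minPatients(18, 0.77), 14L)
  expect_identical(minPatients(4, 0.77), 4L)
  expect_identical(minPatients(1, 0.77), 1L)
  expect_identical(minPatients(4, 0.75), 3L)  # exact product stays exact
  for (n in 1:40)
    for (f in c(0.5, 0.6, 2/3, 0.75, 0.77, 0.9, 1))
      expect_identical(minPatients(n, f), as.integer(ceiling(f * n - 1e-9)))
})

test_that("consensus calls follow the counting rule at the threshold boundary", {
  mk <- function(v) matrix(v, nrow = 1,
                           dimnames = list("cg1", sprintf("P%02d", seq_along(v))))
  r <- callSites(mk(c(rep(0.15, 14), rep(0, 4))))
  expect_identical(as.character(r@call[[1]]), "hyper")  # 14 >= 14
  r <- callSites(mk(c(rep(0.15, 13), rep(0, 5))))
  expect_identical(as.character(r@call[[1]]), "none")   # 13 < 14
  r <- callSites(mk(rep(-0.2, 18)))
  expect_identical(as.character(r@call[[1]]), "hypo")
})

test_that("vectorised caller agrees with a brute-force loop in both modes", {
  set.seed(11)
  for (rep in 1:25) {
    np <- sample(1:50, 1)
    npat <- sample(2:20, 1)
    d <- matrix(stats::rnorm(np * npat, sd = 0.12), np, npat,
                dimnames = list(paste0("cg", seq_len(np)),
                                paste0("P", seq_len(npat))))
    d[sample(length(d), length(d) %/% 10)] <- NA
    thr <- stats::runif(1, 0.05, 0.2)
    frac <- stats::runif(1, 0.55, 1)  # majority: directions are exclusive
    for (mode in c(TRUE, FALSE)) {
      got <- callSites(d, thr, frac, require_direction_consistency = mode)
      expect_identical(as.character(got@call),
                       oracleCallSites(d, thr, frac, directional = mode))
    }
  }
})

test_that("raising threshold or consensus fraction never adds calls", {
  set.seed(4)
  d <- matrix(stats::rnorm(600, sd = 0.12), 60, 10,
              dimnames = list(paste0("cg", 1:60), paste0("P", 1:10)))
  prev <- Inf
  for (thr in c(0.05, 0.1, 0.15, 0.2)) {
    n <- length(calledProbes(callSites(d, thr, 0.6)))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (frac in c(0.5, 0.6, 0.77, 0.9, 1)) {
    n <- length(calledProbes(callSites(d, 0.1, frac)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("negating the delta matrix swaps hyper and hypo counts exactly", {
  set.seed(8)
  d <- matrix(stats::rnorm(300, sd = 0.15), 30, 10,
              dimnames = list(paste0("cg", 1:30), paste0("P", 1:10)))
  a <- callSites(d)
  b <- callSites(-d)
  expect_identical(a@hyperCount, b@hypoCount)
  expect_identical(a@hypoCount, b@hyperCount)
  swapped <- c(hyper = "hypo", hypo = "hyper", none = "none")
  expect_identical(unname(swapped[as.character(a@call)]),
                   as.character(b@call))
})

test_that("with direction consistency and majority consensus no probe is called twice", {
  set.seed(13)
  for (rep in 1:20) {
    d <- matrix(stats::rnorm(200, sd = 0.2), 20, 10,
                dimnames = list(paste0("cg", 1:20), paste0("P", 1:10)))
    r <- callSites(d, 0.1, 0.6)
    expect_true(all(!(r@hyperCount >= ceiling(0.6 * r@nEval) &
                      r@hypoCount >= ceiling(0.6 * r@nEval))))
  }
})

test_that("subset medians behave on constants and on the planted cohort", {
  sh <- studySheet("p1")
  b <- matrix(0.5, 3, 3, dimnames = list(paste0("cg", 1:3), sh$sample_id))
  prof <- subsetMedianProfile(BetaSet(b, sh), paste0("cg", 1:3))
  expect_true(all(prof == 0.5))
  b2 <- matrix(c(0.2, 0.4), 2, 3,
               dimnames = list(c("cg1", "cg2"), sh$sample_id))
  expect_equal(unname(subsetMedianProfile(BetaSet(b2, sh), c("cg1", "cg2"))["T1"]),
               0.3)
  expect_error(subsetMedianProfile(BetaSet(b, sh), character()), "empty")

  sim <- simulateCohort(simulationConfig(n_probes = 500L,
    n_planted_hyper = 30L, n_planted_hypo = 3L, seed = 6L))
  prof <- subsetMedianProfile(sim$betas, plantedProbes(sim$truth))
  # post-diet and healthy medians are mutually closer than either is to T1
  expect_lt(abs(prof["T2"] - prof["healthy_blood"]),
            abs(prof["T1"] - prof["healthy_blood"]))
  expect_lt(abs(prof["T3"] - prof["T2"]), abs(prof["T1"] - prof["T2"]))
})

test_that("dispersion test flags a 10x spread and not identical groups", {
  sh <- rbind(studySheet(sprintf("a%02d", 1:20), "T1"),
              studySheet(sprintf("b%02d", 1:20), "T2"))
  set.seed(21)
  vals <- c(stats::rnorm(20, 0.5, 0.1), stats::rnorm(20, 0.5, 0.01))
  b <- matrix(rep(vals, each = 1), nrow = 1,
              dimnames = list("cg1", sh$sample_id))
  b <- pmin(pmax(b, 0), 1)
  r <- subsetVarianceTest(BetaSet(b, sh), "cg1")
  expect_lt(r$tests$p[r$tests$stratum == "T2"], 0.05)
  expect_gt(r$variances[["T1"]], r$variances[["T2"]])

  bEq <- matrix(rep(c(0.3, 0.5, 0.7, 0.4, 0.6), 8), nrow = 1,
                dimnames = list("cg1", sh$sample_id))
  rEq <- subsetVarianceTest(BetaSet(bEq, sh), "cg1")
  expect_gt(rEq$tests$p[1], 0.9)
  expect_equal(rEq$variances[["T1"]], rEq$variances[["T2"]])
})
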