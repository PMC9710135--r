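#' SimulationConfig: parameters of the synthetic methylation cohort
#'
#' Defaults emulate the study design this package targets: 18 patients
#' profiled in blood at three timepoints (baseline T1 and two post-diet
#' timepoints T2/T3), 60 healthy-blood controls, and liver panels of 40
#' profiles per fibrosis grade 0-3. A planted subset of CpGs carries a
#' 0.20 beta shift at T1 relative to the common post-diet mean (mostly
#' hypomethylated at baseline, i.e. hypermethylation calls), carried by
#' 90% of patients; per-observation noise is Beta-distributed with sd 0.03.
#'
#' @slot n_patients,n_probes,n_planted_hyper,n_planted_hypo counts.
#' @slot delta_effect planted beta-scale shift (fraction).
#' @slot consensus_carrier_fraction probability a patient carries the shift.
#' @slot noise_sd sd of the Beta-distributed per-observation noise.
#' @slot n_healthy_blood healthy blood control count.
#' @slot n_liver_per_grade liver profiles per fibrosis grade 0..3.
#' @slot grade_drift per-grade beta shift of liver profiles toward the
#'   diseased (T1-like) mean at planted sites.
#' @slot planted_feature_bias if TRUE, planted probes are biased toward
#'   OpenSea/GeneBody annotations; default FALSE (unbiased).
#' @slot seed master RNG seed; all draws flow from it in a fixed order.
#' @export
setClass("SimulationConfig", representation(
  n_patients = "integer", n_probes = "integer",
  n_planted_hyper = "integer", n_planted_hypo = "integer",
  delta_effect = "numeric", consensus_carrier_fraction = "numeric",
  noise_sd = "numeric", n_healthy_blood = "integer",
  n_liver_per_grade = "integer", grade_drift = "numeric",
  planted_feature_bias = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n_planted_hyper + object@n_planted_hypo > object@n_probes)
    msg <- c(msg, "planted probes exceed n_probes")
  if (object@delta_effect < 0 || object@delta_effect >= 1)
    msg <- c(msg, "delta_effect must be in [0, 1)")
  if (object@consensus_carrier_fraction <= 0 ||
      object@consensus_carrier_fraction > 1)
    msg <- c(msg, "consensus_carrier_fraction must be in (0, 1]")
  if (object@noise_sd <= 0 || object@noise_sd >= 0.5)
    msg <- c(msg, "noise_sd must be in (0, 0.5)")
  if (length(object@n_liver_per_grade) != 4)
    msg <- c(msg, "n_liver_per_grade must have one count per grade 0..3")
  if (length(msg) == 0) TRUE else msg
})

#' @describeIn SimulationConfig constructor with study-design defaults
#' @param n_patients,n_probes,n_planted_hyper,n_planted_hypo,delta_effect,consensus_carrier_fraction,noise_sd,n_healthy_blood,n_liver_per_grade,grade_drift,planted_feature_bias,seed see slots.
#' @export
simulationConfig <- function(n_patients = 18L, n_probes = 5000L,
                             n_planted_hyper = 100L, n_planted_hypo = 10L,
                             delta_effect = 0.20,
                             consensus_carrier_fraction = 0.9,
                             noise_sd = 0.03, n_healthy_blood = 60L,
                             n_liver_per_grade = c(40L, 40L, 40L, 40L),
                             grade_drift = 0.15,
                             planted_feature_bias = FALSE, seed = 1L) {
  new("SimulationConfig",
      n_patients = as.integer(n_patients), n_probes = as.integer(n_probes),
      n_planted_hyper = as.integer(n_planted_hyper),
      n_planted_hypo = as.integer(n_planted_hypo),
      delta_effect = delta_effect,
      consensus_carrier_fraction = consensus_carrier_fraction,
      noise_sd = noise_sd, n_healthy_blood = as.integer(n_healthy_blood),
      n_liver_per_grade = as.integer(n_liver_per_grade),
      grade_drift = grade_drift,
      planted_feature_bias = isTRUE(planted_feature_bias),
      seed = as.integer(seed))
}

#' GroundTruth: ledger of planted diet-responsive CpGs
#'
#' @slot plantedHyper,plantedHypo probe IDs planted for hypermethylation
#'   (T1 lowered) and hypomethylation (T1 raised) respectively.
#' @slot carriers logical matrix (planted probe x patient): which patients
#'   carry the shift.
#' @slot muPre,muPost per-probe baseline (T1, diseased-like) and post-diet
#'   (healthy-like) mean beta; equal for non-planted probes. Used to place
#'   liver-panel grades on the diseased-healthy axis.
#' @export
setClass("GroundTruth", representation(
  plantedHyper = "character", plantedHypo = "character",
  carriers = "matrix", muPre = "numeric", muPost = "numeric"))

setValidity("GroundTruth", function(object) {
  if (length(intersect(object@plantedHyper, object@plantedHypo)) > 0)
    "plantedHyper and plantedHypo overlap"
  else TRUE
})

#' @describeIn GroundTruth all planted probe IDs
#' @param x a `GroundTruth`
#' @export
plantedProbes <- function(x) c(x@plantedHyper, x@plantedHypo)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d hyper + %d hypo planted probes, %d patients\n",
              length(object@plantedHyper), length(object@plantedHypo),
              ncol(object@carriers)))
})

## Beta draws with given mean and sd via moment matching; sd is capped just
## under the Beta-feasible bound sqrt(m(1-m)) and values clamped to
## [0.01, 0.99] so downstream arithmetic never sees the boundaries.
.rbetaMeanSd <- function(n, mean, sd) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  vmax <- mean * (1 - mean)
  v <- pmin(sd^2, 0.9 * vmax)
  k <- vmax / v - 1
  x <- stats::rbeta(n, mean * k, (1 - mean) * k)
  pmin(pmax(x, 0.01), 0.99)
}

#' Simulate a longitudinal blood methylation cohort
#'
#' Generates blood beta profiles for each patient at T1/T2/T3 plus a
#' healthy-blood control group, a probe manifest, and a ground-truth
#' ledger. At planted hypermethylation probes, carrier patients' T1 values
#' are drawn around a mean lowered by `delta_effect` relative to the
#' common post-diet mean shared by T2, T3 and healthy blood (so the
#' per-patient delta-beta is about `+delta_effect`); hypomethylation
#' probes are symmetric. Non-planted probes share one mean across all
#' timepoints and groups. Baseline means follow a bimodal mixture
#' (components near 0.1 and 0.9 plus an intermediate one) to mimic array
#' beta distributions. Identical config (including seed) gives identical
#' output.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `betas` (a [BetaSet-class] of blood
#'   samples), `manifest` (a [ProbeManifest-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' sim <- simulateCohort(simulationConfig(n_probes = 200L,
#'   n_planted_hyper = 10L, n_planted_hypo = 2L, seed = 7L))
#' sim$betas
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  np <- config@n_probes
  npat <- config@n_patients
  probes <- sprintf("cg%08d", seq_len(np))
  patients <- sprintf("P%02d", seq_len(npat))

  ## draw order is fixed: baseline means, planted assignment/means,
  ## carriers, blood betas, healthy betas, manifest
  comp <- sample.int(3L, np, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu <- numeric(np)
  mu[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 18)   # low mode ~0.1
  mu[comp == 2L] <- stats::rbeta(sum(comp == 2L), 18, 2)   # high mode ~0.9
  mu[comp == 3L] <- stats::runif(sum(comp == 3L), 0.25, 0.75)

  nHyper <- config@n_planted_hyper
  nHypo <- config@n_planted_hypo
  plantedIdx <- sample.int(np, nHyper + nHypo)
  hyperIdx <- plantedIdx[seq_len(nHyper)]
  hypoIdx <- setdiff(plantedIdx, hyperIdx)

  muPost <- mu
  muPre <- mu
  ## planted means are placed so that both pre and post stay inside (0,1)
  muPost[hyperIdx] <- stats::runif(nHyper, 0.35, 0.75)
  muPre[hyperIdx] <- muPost[hyperIdx] - config@delta_effect
  muPost[hypoIdx] <- stats::runif(nHypo, 0.25, 0.65)
  muPre[hypoIdx] <- muPost[hypoIdx] + config@delta_effect
  names(muPre) <- names(muPost) <- probes

  ## each planted probe is carried by an exact fraction of patients
  ## (rounded), randomly chosen per probe; with the 0.9 default and 18
  ## patients that is 16 carriers, deterministically above the 77% bar
  nCarriers <- max(1L, round(config@consensus_carrier_fraction * npat))
  carriers <- matrix(FALSE, nrow = length(plantedIdx), ncol = npat,
                     dimnames = list(probes[plantedIdx], patients))
  for (i in seq_along(plantedIdx))
    carriers[i, sample.int(npat, nCarriers)] <- TRUE

  ## mean matrix for study samples: T1 uses muPre for carrier patients at
  ## planted probes; T2/T3 (and healthy blood) use muPost everywhere
  meanT1 <- matrix(muPost, nrow = np, ncol = npat)
  for (j in seq_len(npat)) {
    carr <- plantedIdx[carriers[, j]]
    meanT1[carr, j] <- muPre[carr]
  }

  sampleIds <- c(paste0(patients, "_T1"), paste0(patients, "_T2"),
                 paste0(patients, "_T3"),
                 sprintf("HB%03d", seq_len(config@n_healthy_blood)))
  beta <- matrix(NA_real_, nrow = np, ncol = length(sampleIds),
                 dimnames = list(probes, sampleIds))
  beta[, seq_len(npat)] <-
    .rbetaMeanSd(np * npat, as.vector(meanT1), config@noise_sd)
  for (tp in 1:2)  # T2 then T3 around the common post-diet mean
    beta[, npat * tp + seq_len(npat)] <-
      .rbetaMeanSd(np * npat, rep(muPost, npat), config@noise_sd)
  beta[, 3 * npat + seq_len(config@n_healthy_blood)] <-
    .rbetaMeanSd(np * config@n_healthy_blood,
                 rep(muPost, config@n_healthy_blood), config@noise_sd)

  sheet <- data.frame(
    sample_id = sampleIds,
    patient_id = c(rep(patients, 3),
                   sprintf("HBP%03d", seq_len(config@n_healthy_blood))),
    timepoint = c(rep(c("T1", "T2", "T3"), each = npat),
                  rep(NA_character_, config@n_healthy_blood)),
    group = c(rep("study", 3 * npat),
              rep("healthy_blood", config@n_healthy_blood)),
    tissue = "blood", fibrosis_grade = NA_integer_,
    stringsAsFactors = FALSE)

  manifest <- .simulateManifest(probes, plantedIdx, config)

  truth <- new("GroundTruth",
               plantedHyper = probes[hyperIdx], plantedHypo = probes[hypoIdx],
               carriers = carriers, muPre = muPre, muPost = muPost)
  list(betas = BetaSet(beta, sheet), manifest = manifest, truth = truth)
}

## category probabilities loosely mirroring EPIC-array composition
.GENE_REGION_P <- c(TSS1500 = 0.09, TSS200 = 0.05, "5'UTR" = 0.09,
                    "1stExon" = 0.04, ExonBoundary = 0.03, GeneBody = 0.30,
                    "3'UTR" = 0.04, intergenic = 0.36)
.CGI_P <- c(Island = 0.20, NorthShore = 0.09, SouthShore = 0.08,
            NorthShelf = 0.05, SouthShelf = 0.05, OpenSea = 0.53)
.REG_P <- c(Promoter = 0.12, PromoterFlanking = 0.08, Enhancer = 0.10,
            CTCF = 0.05, OpenChromatin = 0.05, TFBS = 0.05, none = 0.55)

.simulateManifest <- function(probes, plantedIdx, config) {
  np <- length(probes)
  gr <- sample(names(.GENE_REGION_P), np, TRUE, prob = .GENE_REGION_P)
  cgi <- sample(names(.CGI_P), np, TRUE, prob = .CGI_P)
  reg <- sample(names(.REG_P), np, TRUE, prob = .REG_P)
  if (config@planted_feature_bias && length(plantedIdx) > 0) {
    grB <- .GENE_REGION_P; grB["GeneBody"] <- 4 * grB["GeneBody"]
    cgiB <- .CGI_P; cgiB["OpenSea"] <- 4 * cgiB["OpenSea"]
    gr[plantedIdx] <- sample(names(grB), length(plantedIdx), TRUE, prob = grB)
    cgi[plantedIdx] <- sample(names(cgiB), length(plantedIdx), TRUE, prob = cgiB)
  }
  genePool <- sprintf("GENE%05d", seq_len(max(1L, np %/% 3L)))
  gene <- sample(genePool, np, replace = TRUE)
  gene[gr == "intergenic"] <- NA_character_
  ProbeManifest(data.frame(
    probe_id = probes,
    chromosome = paste0("chr", sample.int(22L, np, replace = TRUE)),
    gene_id = gene, gene_region = gr, cgi_relation = cgi,
    regulatory_feature = reg, stringsAsFactors = FALSE))
}

#' Simulate a fibrosis-graded liver methylation panel
#'
#' Grade-0 liver profiles are drawn around the healthy (post-diet-like)
#' mean at planted sites; grade-g profiles are shifted by
#' `g * grade_drift` toward the diseased (T1-like) mean, so hypermethylation
#' probes (baseline-low) decrease in mean beta with grade. Non-planted
#' probes are identically distributed across grades. Deterministic: seeded
#' from the master seed (offset by 1 so the blood cohort is unchanged).
#'
#' @param config the [SimulationConfig-class] used for [simulateCohort()].
#' @param truth the matching [GroundTruth-class].
#' @return a [BetaSet-class] of liver samples with fibrosis grades 0-3.
#' @export
simulateLiverPanel <- function(config, truth) {
  validObject(config)
  if (!is(truth, "GroundTruth"))
    stop("truth must be the GroundTruth from simulateCohort()")
  set.seed(config@seed + 1L)
  probes <- names(truth@muPost)
  np <- length(probes)
  dirn <- sign(truth@muPre - truth@muPost)  # -1 at hyper, +1 at hypo, 0 else
  grades <- rep(0:3, times = config@n_liver_per_grade)
  n <- length(grades)
  sampleIds <- sprintf("LV%03d_g%d", seq_len(n), grades)
  beta <- matrix(NA_real_, nrow = np, ncol = n,
                 dimnames = list(probes, sampleIds))
  for (i in seq_len(n)) {
    mu <- truth@muPost + grades[i] * config@grade_drift * dirn
    beta[, i] <- .rbetaMeanSd(np, mu, config@noise_sd)
  }
  sheet <- data.frame(
    sample_id = sampleIds, patient_id = sprintf("LVP%03d", seq_len(n)),
    timepoint = NA_character_, group = "nafld_liver", tissue = "liver",
    fibrosis_grade = grades, stringsAsFactors = FALSE)
  BetaSet(beta, sheet)
}
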