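## Core procedure: per-patient delta-beta and consensus-threshold calling
## of diet-responsive CpG sites.

#' Per-patient delta-beta matrix
#'
#' For each study patient, delta-beta at a probe is the mean beta over the
#' available post-diet timepoints (T2, T3) minus the baseline (T1) beta:
#' positive values are gains of methylation after the diet change. A
#' patient missing T1 is an error; a patient with only one of T2/T3 falls
#' back to that single post-diet value. If a patient's value is missing at
#' a probe (baseline, or both post-diet timepoints), the delta is `NA`
#' there and the patient is excluded from that probe's consensus count.
#'
#' @param bs a [BetaSet-class]; only `group == "study"` samples are used.
#' @return numeric matrix (probes x patients) of delta-beta values.
#' @examples
#' sim <- simulateCohort(simulationConfig(n_probes = 100L,
#'   n_planted_hyper = 5L, n_planted_hypo = 1L, seed = 3L))
#' d <- computeDelta(sim$betas)
#' dim(d)
#' @export
computeDelta <- function(bs) {
  stopifnot(is(bs, "BetaSet"))
  cd <- colData(bs)
  study <- which(cd$group == "study")
  if (length(study) == 0) stop("no study samples in BetaSet")
  b <- betaValues(bs)[, study, drop = FALSE]
  pid <- cd$patient_id[study]
  tp <- cd$timepoint[study]
  patients <- unique(pid)
  delta <- matrix(NA_real_, nrow = nrow(b), ncol = length(patients),
                  dimnames = list(rownames(b), patients))
  for (k in seq_along(patients)) {
    t1 <- which(pid == patients[k] & tp == "T1")
    post <- which(pid == patients[k] & tp %in% c("T2", "T3"))
    if (length(t1) != 1)
      stop("patient ", patients[k], " must have exactly one T1 sample")
    if (length(post) == 0)
      stop("patient ", patients[k], " has neither a T2 nor a T3 sample")
    postMean <- rowMeans(b[, post, drop = FALSE], na.rm = TRUE)
    postMean[is.nan(postMean)] <- NA_real_
    delta[, k] <- postMean - b[, t1]
  }
  delta
}

#' Minimum number of patients for consensus
#'
#' `ceiling(consensus_fraction * n_patients)`, the smallest patient count
#' meeting the configured consensus fraction (e.g. 14 of 18 at 0.77). A
#' 1e-9 tolerance inside the ceiling guards against IEEE round-up of exact
#' products.
#'
#' @param n_patients number of evaluable patients.
#' @param consensus_fraction required fraction in (0, 1].
#' @return integer count.
#' @export
minPatients <- function(n_patients, consensus_fraction = 0.77) {
  stopifnot(n_patients >= 1, consensus_fraction > 0, consensus_fraction <= 1)
  as.integer(ceiling(consensus_fraction * n_patients - 1e-9))
}

#' Consensus delta-beta site calling
#'
#' A probe is called hypermethylated when at least
#' `minPatients(n_eval, consensus_fraction)` patients show
#' `delta >= delta_threshold` (hypomethylated symmetrically with
#' `delta <= -delta_threshold`), where `n_eval` is the number of patients
#' with a non-missing delta at that probe. With
#' `require_direction_consistency = FALSE`, a probe instead qualifies when
#' enough patients show `|delta| >= delta_threshold`; its direction is then
#' the majority sign among qualifying patients, ties giving no call.
#'
#' @param delta probe x patient delta-beta matrix from [computeDelta()].
#' @param delta_threshold minimum absolute beta difference (default 0.10).
#' @param consensus_fraction minimum fraction of patients (default 0.77).
#' @param require_direction_consistency logical, default TRUE.
#' @return a [DeltaCallResult-class].
#' @examples
#' d <- matrix(c(rep(0.15, 14), rep(0, 4)), nrow = 1,
#'             dimnames = list("cg1", sprintf("P%02d", 1:18)))
#' callSites(d)  # hyper: 14 of 18 >= 0.10, consensus 14 needed
#' @export
callSites <- function(delta, delta_threshold = 0.10,
                      consensus_fraction = 0.77,
                      require_direction_consistency = TRUE) {
  stopifnot(is.matrix(delta), ncol(delta) >= 1,
            delta_threshold > 0, delta_threshold < 1)
  hyperCount <- as.integer(rowSums(delta >= delta_threshold, na.rm = TRUE))
  hypoCount <- as.integer(rowSums(delta <= -delta_threshold, na.rm = TRUE))
  nEval <- as.integer(rowSums(!is.na(delta)))
  minp <- ifelse(nEval >= 1,
                 ceiling(consensus_fraction * nEval - 1e-9), Inf)
  call <- rep("none", nrow(delta))
  if (require_direction_consistency) {
    hy <- hyperCount >= minp
    ho <- hypoCount >= minp
    if (any(hy & ho))
      stop("internal error: probe reached consensus in both directions")
    call[hy] <- "hyper"
    call[ho] <- "hypo"
  } else {
    qual <- hyperCount + hypoCount  # |delta| >= threshold counts
    hit <- qual >= minp & nEval >= 1
    dirn <- sign(hyperCount - hypoCount)
    call[hit & dirn > 0] <- "hyper"
    call[hit & dirn < 0] <- "hypo"
    ## ties (dirn == 0) stay "none"
  }
  call <- factor(call, levels = c("hyper", "hypo", "none"))
  names(call) <- rownames(delta)
  new("DeltaCallResult", delta = delta, hyperCount = hyperCount,
      hypoCount = hypoCount, nEval = nEval, call = call,
      params = list(delta_threshold = delta_threshold,
                    consensus_fraction = consensus_fraction,
                    require_direction_consistency = require_direction_consistency))
}

## strata used by subset summaries: study samples by timepoint, other
## groups as themselves
.sampleStrata <- function(bs) {
  cd <- colData(bs)
  ifelse(cd$group == "study", as.character(cd$timepoint),
         as.character(cd$group))
}

#' Median methylation of a probe subset, per group/timepoint
#'
#' For each stratum (study timepoints T1/T2/T3 and each non-study group),
#' the median of all beta values at the subset probes across that
#' stratum's samples.
#'
#' @param bs a [BetaSet-class].
#' @param subset non-empty character vector of probe IDs present in `bs`.
#' @return named numeric vector of per-stratum medians.
#' @export
subsetMedianProfile <- function(bs, subset) {
  stopifnot(is(bs, "BetaSet"))
  if (length(subset) == 0) stop("empty probe subset")
  if (!all(subset %in% rownames(bs)))
    stop("subset probes absent from BetaSet")
  b <- betaValues(bs)[subset, , drop = FALSE]
  strata <- .sampleStrata(bs)
  vapply(split(seq_len(ncol(b)), strata), function(cols)
    stats::median(b[, cols], na.rm = TRUE), numeric(1))
}

#' Group dispersion of subset methylation, with Brown-Forsythe tests
#'
#' Computes, per stratum, the variance of per-sample mean methylation over
#' the subset probes, and tests each stratum against the baseline (T1)
#' stratum for unequal dispersion with the Brown-Forsythe test (Levene's
#' test centred at the median).
#'
#' @param bs a [BetaSet-class].
#' @param subset probe IDs.
#' @param reference stratum used as comparison baseline (default "T1").
#' @param pooled if TRUE, variances (but not the tests) are computed over
#'   pooled beta values rather than per-sample means.
#' @return list with `variances` (named numeric) and `tests` (data.frame
#'   of stratum, F statistic and p vs the reference).
#' @importFrom car leveneTest
#' @export
subsetVarianceTest <- function(bs, subset, reference = "T1",
                               pooled = FALSE) {
  stopifnot(is(bs, "BetaSet"))
  if (length(subset) == 0) stop("empty probe subset")
  b <- betaValues(bs)[subset, , drop = FALSE]
  strata <- .sampleStrata(bs)
  means <- colMeans(b, na.rm = TRUE)
  bySt <- split(means, strata)
  if (length(bySt) < 2 || any(lengths(bySt) < 2))
    stop("need >= 2 strata with >= 2 samples each")
  if (!reference %in% names(bySt))
    stop("reference stratum '", reference, "' not present")
  variances <- if (pooled)
    vapply(split(seq_len(ncol(b)), strata),
           function(cols) stats::var(as.vector(b[, cols])), numeric(1))
  else vapply(bySt, stats::var, numeric(1))
  others <- setdiff(names(bySt), reference)
  tests <- do.call(rbind, lapply(others, function(g) {
    y <- c(bySt[[reference]], bySt[[g]])
    grp <- factor(rep(c(reference, g), c(length(bySt[[reference]]),
                                         length(bySt[[g]]))))
    lt <- car::leveneTest(y, grp, center = "median")
    data.frame(stratum = g, statistic = lt[1, "F value"],
               p = lt[1, "Pr(>F)"], stringsAsFactors = FALSE)
  }))
  list(variances = variances, tests = tests)
}
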