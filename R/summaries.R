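## Global methylation summaries: per-sample medians, PCA, correlation of
## methylation summaries with clinical parameters.

#' Median global methylation per sample and per group
#'
#' Per-sample median over all probes (missing values excluded), then a
#' per-stratum median of the sample medians (study timepoints T1/T2/T3 and
#' each non-study group form the strata).
#'
#' @param bs a [BetaSet-class].
#' @return list with `sampleMedians` (named numeric per sample) and
#'   `groupMedians` (named numeric per stratum).
#' @export
globalMedian <- function(bs) {
  stopifnot(is(bs, "BetaSet"), nrow(bs) > 0)
  b <- betaValues(bs)
  allMissing <- colSums(!is.na(b)) == 0
  if (any(allMissing))
    stop("sample(s) with no observed beta values: ",
         paste(colnames(b)[allMissing], collapse = ", "))
  sampleMedians <- apply(b, 2, stats::median, na.rm = TRUE)
  strata <- .sampleStrata(bs)
  groupMedians <- vapply(split(sampleMedians, strata), stats::median,
                         numeric(1))
  list(sampleMedians = sampleMedians, groupMedians = groupMedians)
}

#' PCA of methylation profiles
#'
#' Probes with any missing value are dropped listwise, samples are centred
#' per probe, and the decomposition is made sign-deterministic by flipping
#' each component so its largest-magnitude probe loading is positive.
#'
#' @param bs a [BetaSet-class] (or bare beta matrix).
#' @param nComponents number of components to return.
#' @return list with `scores` (samples x components),
#'   `varianceExplained` (fraction per returned component, non-increasing)
#'   and `loadings` (probes x components).
#' @export
pcaProfiles <- function(bs, nComponents = 2) {
  b <- if (is(bs, "BetaSet")) betaValues(bs) else bs
  if (ncol(b) < 2) stop("need >= 2 samples for PCA")
  if (nComponents > ncol(b))
    stop("fewer samples than requested components")
  keep <- rowSums(is.na(b)) == 0
  b <- b[keep, , drop = FALSE]
  if (nrow(b) == 0) stop("no complete probes for PCA")
  pc <- stats::prcomp(t(b), center = TRUE, scale. = FALSE)
  totVar <- sum(pc$sdev^2)
  ve <- if (totVar > 0) pc$sdev^2 / totVar else rep(0, length(pc$sdev))
  k <- min(nComponents, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # fix sign: largest |loading| positive
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, varianceExplained = ve[seq_len(k)],
       loadings = loadings)
}

#' Correlate per-sample methylation summaries with clinical parameters
#'
#' Pearson correlation of a methylation summary (e.g. per-sample median
#' global methylation) against each clinical parameter, with Bonferroni
#' adjustment across parameters. Parameters with zero variance yield
#' `NA` with a warning.
#'
#' @param summary named numeric vector (one value per sample or patient).
#' @param clinical data.frame of numeric parameters whose rownames match
#'   `names(summary)` (rows are matched by name).
#' @return data.frame with parameter, n, r, p and Bonferroni-adjusted p.
#' @export
correlateGlobals <- function(summary, clinical) {
  stopifnot(!is.null(names(summary)), !is.null(rownames(clinical)))
  common <- intersect(names(summary), rownames(clinical))
  if (length(common) < 3) stop("need >= 3 paired observations")
  x <- summary[common]
  m <- ncol(clinical)
  res <- do.call(rbind, lapply(colnames(clinical), function(param) {
    y <- clinical[common, param]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3)
      stop("parameter '", param, "' has < 3 paired observations")
    if (stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      warning("zero variance for parameter '", param, "'; r undefined")
      return(data.frame(parameter = param, n = sum(ok), r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(parameter = param, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- pmin(1, m * res$p)
  res
}
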