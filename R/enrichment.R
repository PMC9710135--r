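## Feature-category enrichment of a called CpG subset: fold change against
## the array background and a size-matched resampling null.

.axisVocab <- function(axis) {
  switch(axis,
         gene_region = .GENE_REGIONS,
         cgi_relation = .CGI_RELATIONS,
         regulatory_feature = .REG_FEATURES,
         stop("unknown feature axis: ", axis))
}

.countByCategory <- function(values, vocab) {
  tab <- table(factor(values, levels = vocab))
  as.integer(tab)
}

#' Feature-category fold change of a CpG subset
#'
#' For each category of the chosen annotation axis, the fold change is the
#' category's frequency in the subset divided by its frequency in the
#' background: `FC = (observed/subset_size) / (background/background_size)`.
#' Categories absent from the subset report FC = 0; categories absent from
#' the background are omitted with a warning. FC > 1 marks enrichment,
#' FC < 1 depletion.
#'
#' @param subset non-empty character vector of probe IDs, all present in
#'   the manifest.
#' @param manifest a [ProbeManifest-class].
#' @param featureAxis one of `"gene_region"`, `"cgi_relation"`,
#'   `"regulatory_feature"`.
#' @param background probe IDs to use as background (default: the whole
#'   manifest).
#' @return an [EnrichmentTable-class].
#' @examples
#' sim <- simulateCohort(simulationConfig(n_probes = 500L,
#'   n_planted_hyper = 20L, n_planted_hypo = 5L, seed = 11L))
#' featureFoldChange(plantedProbes(sim$truth), sim$manifest, "cgi_relation")
#' @export
featureFoldChange <- function(subset, manifest, featureAxis,
                              background = manifest$probe_id) {
  vocab <- .axisVocab(featureAxis)
  if (length(subset) == 0) stop("empty probe subset")
  idx <- match(subset, manifest$probe_id)
  if (anyNA(idx)) stop("subset probes absent from manifest")
  bgIdx <- match(background, manifest$probe_id)
  if (anyNA(bgIdx)) stop("background probes absent from manifest")
  vals <- manifest[[featureAxis]]
  obs <- .countByCategory(vals[idx], vocab)
  bg <- .countByCategory(vals[bgIdx], vocab)
  present <- bg > 0
  if (any(!present))
    warning("category(ies) absent from background omitted: ",
            paste(vocab[!present], collapse = ", "))
  subsetSize <- length(subset)
  bgSize <- length(background)
  fc <- (obs[present] / subsetSize) / (bg[present] / bgSize)
  tab <- DataFrame(category = vocab[present], observed = obs[present],
                   subset_size = subsetSize, background = bg[present],
                   background_size = bgSize, fold_change = fc)
  new("EnrichmentTable", axis = featureAxis, table = tab)
}

#' Empirical enrichment p-values by size-matched resampling
#'
#' Operationalizes "expected by chance" as uniform resampling of
#' size-matched probe subsets from the background. The two-sided empirical
#' p per category is the fraction of random subsets whose `|log FC|` is at
#' least the observed `|log FC|`, with a +1 pseudo-count in numerator and
#' denominator; FC = 0 is treated as infinitely extreme (the comparison
#' stays on the count scale, no log of zero is taken).
#'
#' @inheritParams featureFoldChange
#' @param nDraws number of random subsets (>= 100).
#' @param seed RNG seed.
#' @return the [EnrichmentTable-class] with an `empirical_p` column added.
#' @export
enrichmentResampleP <- function(subset, manifest, featureAxis,
                                nDraws = 1000, seed = 1,
                                background = manifest$probe_id) {
  stopifnot(nDraws >= 100)
  if (length(subset) > length(background))
    stop("subset larger than background")
  et <- featureFoldChange(subset, manifest, featureAxis,
                          background = background)
  tab <- et@table
  vocabP <- tab$category
  bgVals <- factor(manifest[[featureAxis]][match(background,
                                                 manifest$probe_id)],
                   levels = vocabP)
  subsetSize <- length(subset)
  bgFreq <- tab$background / tab$background_size
  ## statistic: |log FC|; zero counts are floored at half a count so the
  ## comparison stays on the count scale and no log of zero is taken
  statOf <- function(counts) {
    fc <- (pmax(counts, 0.5) / subsetSize) / bgFreq
    abs(log(fc))
  }
  obsStat <- statOf(tab$observed)
  set.seed(seed)
  exceed <- integer(length(vocabP))
  for (d in seq_len(nDraws)) {
    draw <- sample.int(length(background), subsetSize)
    counts <- tabulate(bgVals[draw], nbins = length(vocabP))
    exceed <- exceed + as.integer(statOf(counts) >= obsStat)
  }
  tab$empirical_p <- (1 + exceed) / (nDraws + 1)
  new("EnrichmentTable", axis = featureAxis, table = tab)
}
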