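## Fibrosis-grade stratification of liver methylomes: Ward clustering with
## a chi-squared cluster-by-grade test, and a seeded gradient-boosted tree
## classifier with cross-validated ROC.

## Canonical sample order (sorted IDs) before clustering makes leaf orders
## invariant to the input permutation.
.gradedLiver <- function(bs, panel) {
  cd <- colData(bs)
  keep <- which(!is.na(cd$fibrosis_grade))
  if (length(keep) == 0) stop("no fibrosis-graded samples in BetaSet")
  if (!all(panel %in% rownames(bs)))
    stop("panel probes absent from BetaSet")
  b <- betaValues(bs)[panel, keep, drop = FALSE]
  list(beta = b, grade = cd$fibrosis_grade[keep])
}

#' Unsupervised clustering of graded liver profiles with a chi-squared test
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances between
#' beta profiles restricted to the panel) cut into `k` clusters (`"auto"`:
#' the number of distinct fibrosis grades), followed by a Pearson
#' chi-squared test of independence (no continuity correction) on the
#' cluster-by-grade contingency table. A warning is emitted when any
#' expected cell count is below 5.
#'
#' @param bs a [BetaSet-class] containing fibrosis-graded liver samples.
#' @param panel character vector of probe IDs (the called CpG subset).
#' @param k number of clusters, or `"auto"`.
#' @param linkage hclust method (default `"ward.D2"`, Ward on Euclidean
#'   distances).
#' @return a [ClusterGradeResult-class].
#' @export
clusterAndTest <- function(bs, panel, k = "auto", linkage = "ward.D2") {
  g <- .gradedLiver(bs, panel)
  grades <- g$grade
  if (length(unique(grades)) < 2) stop("need >= 2 fibrosis grades")
  ord <- order(colnames(g$beta))
  b <- g$beta[, ord, drop = FALSE]
  grades <- grades[ord]
  if (identical(k, "auto")) k <- length(unique(grades))
  if (k > ncol(b)) stop("k exceeds number of samples")
  hc <- stats::hclust(stats::dist(t(b), method = "euclidean"),
                      method = linkage)
  cl <- stats::cutree(hc, k = k)
  tab <- table(cluster = cl, grade = grades)
  contingency <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  expected <- outer(rowSums(contingency), colSums(contingency)) /
    sum(contingency)
  if (any(expected < 5))
    warning("expected cell count < 5; chi-squared approximation may be poor")
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  new("ClusterGradeResult", linkage = linkage, clusters = cl,
      contingency = contingency, chi2 = unname(ct$statistic),
      df = unname(ct$parameter), p = unname(ct$p.value))
}

## fixed gradient-boosted tree settings; the contribution under test is
## the CpG panel, so the model is deliberately unsearched and fully
## seeded. Column subsampling (0.5 per tree) decorrelates the trees so
## the score draws on the whole panel rather than one maximally
## separating probe.
.XGB_PARAMS <- list(objective = "binary:logistic", eta = 0.1,
                    max_depth = 3, subsample = 1, colsample_bytree = 0.5,
                    nthread = 1)
.XGB_NROUNDS <- 100

## stratified fold assignment, seeded
.stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(nFolds), length.out = length(idx)))
  }
  fold
}

## mid-rank (Mann-Whitney) AUC of scores for the positive class
.rankAUC <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated fibrosis-grade classification from a CpG panel
#'
#' Trains a gradient-boosted tree ensemble (fixed hyperparameters: 100
#' rounds, learning rate 0.1, depth 3, no subsampling, single thread)
#' under seeded stratified k-fold cross-validation to separate two grade
#' groups (default grade 3+ vs grade 0), reporting per-fold held-out ROC
#' AUC, their mean, and pooled accuracy at a 0.5 score threshold. Fully
#' reproducible under a fixed seed.
#'
#' @param bs a [BetaSet-class] containing fibrosis-graded liver samples.
#' @param panel probe IDs to use as features.
#' @param positive,negative fibrosis grades forming the positive and
#'   negative class (defaults 3 and 0; intermediate grades are excluded).
#' @param nFolds number of cross-validation folds (default 5).
#' @param seed RNG seed controlling fold assignment and the learner.
#' @return a [ClassifierReport-class].
#' @importFrom xgboost xgb.train xgb.DMatrix
#' @importFrom pROC roc auc
#' @export
classifyGrades <- function(bs, panel, positive = 3, negative = 0,
                           nFolds = 5, seed = 1) {
  g <- .gradedLiver(bs, panel)
  y <- ifelse(g$grade %in% positive, 1L,
              ifelse(g$grade %in% negative, 0L, NA_integer_))
  keep <- !is.na(y)
  x <- t(g$beta[, keep, drop = FALSE])
  y <- y[keep]
  if (min(table(y)) < nFolds)
    stop("a class has fewer samples than folds; reduce nFolds")
  set.seed(seed)
  fold <- .stratifiedFolds(y, nFolds)
  scores <- numeric(length(y))
  foldAUC <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
    model <- xgboost::xgb.train(params = c(.XGB_PARAMS, seed = seed),
                                data = dtrain, nrounds = .XGB_NROUNDS,
                                verbose = 0)
    scores[!tr] <- stats::predict(
      model, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
    r <- pROC::roc(response = y[!tr], predictor = scores[!tr],
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    foldAUC[f] <- as.numeric(pROC::auc(r))
  }
  accuracy <- mean((scores > 0.5) == (y == 1L))
  names(scores) <- rownames(x)
  new("ClassifierReport", foldAUC = foldAUC, meanAUC = mean(foldAUC),
      accuracy = accuracy, nFolds = as.integer(nFolds),
      seed = as.integer(seed),
      labels = c(paste0("grade", paste(positive, collapse = "+")),
                 paste0("grade", paste(negative, collapse = "+"))),
      scores = scores, truthLabels = y)
}

#' Deterministic two-way clustering order for a cross-tissue heatmap
#'
#' Ward clustering of samples and of probes on the panel-restricted beta
#' matrix, returning leaf orders suitable for heatmap rendering. Sample
#' and probe IDs are sorted before clustering, so the result is invariant
#' to the input ordering.
#'
#' @param bs a [BetaSet-class] (e.g. combined blood + liver samples).
#' @param panel non-empty probe IDs.
#' @return list with `sampleOrder`, `probeOrder` (IDs in dendrogram leaf
#'   order) and the two `hclust` objects (`NULL` for a single sample or
#'   probe).
#' @export
crossTissueHeatmapOrder <- function(bs, panel) {
  if (length(panel) == 0) stop("empty panel")
  if (!all(panel %in% rownames(bs)))
    stop("panel probes absent from BetaSet")
  b <- betaValues(bs)[sort(panel), sort(colnames(bs)), drop = FALSE]
  clusterDim <- function(m) {
    if (ncol(m) < 2) return(list(order = colnames(m), hclust = NULL))
    hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                        method = "ward.D2")
    list(order = colnames(m)[hc$order], hclust = hc)
  }
  s <- clusterDim(b)
  p <- clusterDim(t(b))
  list(sampleOrder = s$order, probeOrder = p$order,
       sampleHclust = s$hclust, probeHclust = p$hclust)
}
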