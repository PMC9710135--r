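#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## Closed vocabularies for sample metadata and probe annotation ------------

.TIMEPOINTS <- c("T1", "T2", "T3")
.GROUPS     <- c("study", "healthy_blood", "healthy_liver", "nafld_liver")
.TISSUES    <- c("blood", "liver")
.GRADES     <- 0:3

.GENE_REGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "ExonBoundary",
                   "GeneBody", "3'UTR", "intergenic")
.CGI_RELATIONS <- c("Island", "NorthShore", "SouthShore", "NorthShelf",
                    "SouthShelf", "OpenSea")
.REG_FEATURES <- c("Promoter", "PromoterFlanking", "Enhancer", "CTCF",
                   "OpenChromatin", "TFBS", "none")

.SHEET_COLS <- c("sample_id", "patient_id", "timepoint", "group",
                 "tissue", "fibrosis_grade")
.MANIFEST_COLS <- c("probe_id", "chromosome", "gene_id", "gene_region",
                    "cgi_relation", "regulatory_feature")

#' BetaSet: a methylation beta-value experiment
#'
#' `BetaSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay named `"beta"` holding methylation fractions in \[0, 1\]
#' (CpG probes in rows, samples in columns; `NA` marks missing values) and
#' a column annotation carrying the sample sheet (patient, timepoint,
#' group, tissue, fibrosis grade).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

.validBetaSet <- function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- assay(object, "beta")
  if (is.null(rownames(b)) || is.null(colnames(b)))
    msg <- c(msg, "beta matrix must have probe rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(b)))
      msg <- c(msg, "duplicate probe IDs")
    if (anyDuplicated(colnames(b)))
      msg <- c(msg, "duplicate sample IDs")
  }
  bad <- which(!is.na(b) & (b < 0 | b > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    msg <- c(msg, sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (%.4g)",
      rownames(b)[i[1]], colnames(b)[i[2]], b[i[1], i[2]]))
  }
  cd <- colData(object)
  miss <- setdiff(setdiff(.SHEET_COLS, "sample_id"), colnames(cd))
  if (length(miss) > 0)
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    msg <- c(msg, .validateSheetContent(
      data.frame(sample_id = colnames(b),
                 patient_id = cd$patient_id,
                 timepoint = cd$timepoint, group = cd$group,
                 tissue = cd$tissue, fibrosis_grade = cd$fibrosis_grade,
                 stringsAsFactors = FALSE)))
  }
  if (length(msg) == 0) TRUE else msg
}
setValidity("BetaSet", .validBetaSet)

## shared sample-sheet content checks (used by readSampleSheet and BetaSet)
.validateSheetContent <- function(sheet) {
  msg <- character()
  badTp <- !is.na(sheet$timepoint) & !(sheet$timepoint %in% .TIMEPOINTS)
  if (any(badTp))
    msg <- c(msg, paste0("invalid timepoint value(s): ",
                         paste(unique(sheet$timepoint[badTp]), collapse = ", ")))
  badGr <- !(sheet$group %in% .GROUPS)
  if (any(badGr))
    msg <- c(msg, paste0("invalid group value(s): ",
                         paste(unique(sheet$group[badGr]), collapse = ", ")))
  badTs <- !(sheet$tissue %in% .TISSUES)
  if (any(badTs))
    msg <- c(msg, paste0("invalid tissue value(s): ",
                         paste(unique(sheet$tissue[badTs]), collapse = ", ")))
  badFg <- !is.na(sheet$fibrosis_grade) & !(sheet$fibrosis_grade %in% .GRADES)
  if (any(badFg))
    msg <- c(msg, "fibrosis_grade must be 0..3 or NA")
  offside <- !is.na(sheet$fibrosis_grade) &
    !(sheet$tissue == "liver" & sheet$group == "nafld_liver")
  if (any(offside))
    msg <- c(msg, "fibrosis_grade allowed only for nafld_liver liver samples")
  st <- sheet[sheet$group == "study", , drop = FALSE]
  if (nrow(st) > 0 &&
      anyDuplicated(paste(st$patient_id, st$timepoint)))
    msg <- c(msg, "duplicate (patient_id, timepoint) within group 'study'")
  msg
}

#' Construct a BetaSet from a beta matrix and a sample sheet
#'
#' @param beta numeric matrix of methylation fractions (probes x samples)
#'   with unique probe rownames and sample colnames; `NA` allowed.
#' @param sheet data.frame with columns `sample_id`, `patient_id`,
#'   `timepoint`, `group`, `tissue`, `fibrosis_grade`, one row per sample
#'   of `beta` (matched by `sample_id`).
#' @return a validated [BetaSet-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' sh <- data.frame(sample_id = c("s1", "s2"), patient_id = c("p1", "p1"),
#'                  timepoint = c("T1", "T2"), group = "study",
#'                  tissue = "blood", fibrosis_grade = NA)
#' bs <- BetaSet(b, sh)
#' @export
BetaSet <- function(beta, sheet) {
  stopifnot(is.matrix(beta))
  sheet <- as.data.frame(sheet)
  miss <- setdiff(.SHEET_COLS, colnames(sheet))
  if (length(miss) > 0)
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!setequal(sheet$sample_id, colnames(beta)))
    stop("sample sheet sample_ids do not match beta matrix columns")
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  cd <- DataFrame(sheet[setdiff(.SHEET_COLS, "sample_id")],
                  row.names = sheet$sample_id)
  new("BetaSet", SummarizedExperiment(
    assays = SimpleList(beta = beta), colData = cd))
}

#' @describeIn BetaSet the beta-value matrix (probes x samples)
#' @param object,x a `BetaSet`
#' @export
betaValues <- function(x) assay(x, "beta")

#' @describeIn BetaSet the sample sheet as a data.frame (with `sample_id`)
#' @export
sampleSheet <- function(x) {
  cd <- colData(x)
  data.frame(sample_id = rownames(cd), as.data.frame(cd),
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "BetaSet", function(object) {
  cat(sprintf("BetaSet: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  tab <- table(colData(object)$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab),
                         collapse = ", "), "\n")
  b <- assay(object, "beta")
  cat(sprintf("  beta range: [%.3f, %.3f], %d missing\n",
              suppressWarnings(min(b, na.rm = TRUE)),
              suppressWarnings(max(b, na.rm = TRUE)), sum(is.na(b))))
})

#' ProbeManifest: per-CpG probe annotation
#'
#' A [S4Vectors::DataFrame] subclass with one row per probe and columns
#' `probe_id`, `chromosome`, `gene_id` (NA for intergenic probes),
#' `gene_region`, `cgi_relation` and `regulatory_feature`, each annotation
#' drawn from a closed vocabulary mirroring EPIC-array manifest categories.
#'
#' @export
setClass("ProbeManifest", contains = "DFrame")

.validProbeManifest <- function(object) {
  msg <- character()
  miss <- setdiff(.MANIFEST_COLS, colnames(object))
  if (length(miss) > 0)
    return(paste0("manifest lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$probe_id))
    msg <- c(msg, "duplicate probe_id in manifest")
  chk <- function(col, vocab) {
    bad <- !(object[[col]] %in% vocab)
    if (any(bad))
      sprintf("invalid %s value(s): %s", col,
              paste(unique(object[[col]][bad]), collapse = ", "))
    else character()
  }
  msg <- c(msg,
           chk("gene_region", .GENE_REGIONS),
           chk("cgi_relation", .CGI_RELATIONS),
           chk("regulatory_feature", .REG_FEATURES))
  if (length(msg) == 0) TRUE else msg
}
setValidity("ProbeManifest", .validProbeManifest)

#' Construct a ProbeManifest
#'
#' @param df data.frame (or DataFrame) with the manifest columns.
#' @return a validated [ProbeManifest-class].
#' @export
ProbeManifest <- function(df) {
  d <- DataFrame(df)
  rownames(d) <- d$probe_id
  new("ProbeManifest", d)
}

setMethod("show", "ProbeManifest", function(object) {
  cat(sprintf("ProbeManifest: %d probes, %d with gene annotation\n",
              nrow(object), sum(!is.na(object$gene_id))))
  cat("  cgi_relation:",
      paste(names(table(object$cgi_relation)), collapse = ", "), "\n")
})

#' DeltaCallResult: per-probe delta-beta consensus calls
#'
#' Holds the per-probe, per-patient delta-beta matrix (mean of post-diet
#' timepoints minus baseline), per-probe counts of patients crossing the
#' threshold in each direction, the per-probe evaluable patient count, and
#' the consensus call (`hyper`, `hypo` or `none`).
#'
#' @slot delta numeric matrix (probes x patients) of delta-beta values.
#' @slot hyperCount,hypoCount,nEval integer vectors, one entry per probe.
#' @slot call factor per probe with levels hyper/hypo/none.
#' @slot params the `DeltaCallParams` list used (delta_threshold,
#'   consensus_fraction, require_direction_consistency).
#' @export
setClass("DeltaCallResult", representation(
  delta = "matrix", hyperCount = "integer", hypoCount = "integer",
  nEval = "integer", call = "factor", params = "list"))

setValidity("DeltaCallResult", function(object) {
  msg <- character()
  n <- nrow(object@delta)
  if (length(object@call) != n || length(object@hyperCount) != n ||
      length(object@hypoCount) != n || length(object@nEval) != n)
    msg <- c(msg, "per-probe slots must match delta row count")
  if (any(object@hyperCount + object@hypoCount > ncol(object@delta)))
    msg <- c(msg, "hyperCount + hypoCount exceeds patient count")
  if (length(msg) == 0) TRUE else msg
})

#' @describeIn DeltaCallResult probe IDs with a non-`none` call
#' @param x a `DeltaCallResult`
#' @export
calledProbes <- function(x) names(x@call)[x@call != "none"]

#' @describeIn DeltaCallResult per-probe call summary as a data.frame with
#'   columns probe_id, mean_delta, hyper_count, hypo_count, n_eval, call
#' @export
callTable <- function(x) {
  data.frame(probe_id = rownames(x@delta),
             mean_delta = rowMeans(x@delta, na.rm = TRUE),
             hyper_count = x@hyperCount, hypo_count = x@hypoCount,
             n_eval = x@nEval, call = as.character(x@call),
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "DeltaCallResult", function(object) {
  tab <- table(object@call)
  cat(sprintf(
    "DeltaCallResult: %d probes x %d patients; threshold %.2f, consensus %.2f\n",
    nrow(object@delta), ncol(object@delta),
    object@params$delta_threshold, object@params$consensus_fraction))
  cat(sprintf("  calls: %d hyper, %d hypo, %d none\n",
              tab[["hyper"]], tab[["hypo"]], tab[["none"]]))
})

#' EnrichmentTable: feature-category enrichment of a CpG subset
#'
#' @slot axis the feature axis used (gene_region, cgi_relation or
#'   regulatory_feature).
#' @slot table DataFrame with per-category observed counts, background
#'   counts, fold change and (after resampling) empirical p.
#' @export
setClass("EnrichmentTable", representation(axis = "character",
                                           table = "DFrame"))

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable (axis: %s)\n", object@axis))
  print(as.data.frame(object@table))
})

#' @describeIn EnrichmentTable the per-category table as a data.frame
#' @param x an `EnrichmentTable`
#' @export
enrichmentTable <- function(x) as.data.frame(x@table)

#' ClusterGradeResult: unsupervised clustering vs fibrosis grade
#'
#' @slot linkage linkage method label.
#' @slot clusters named integer vector of cluster assignments per sample.
#' @slot contingency cluster x grade count matrix.
#' @slot chi2,df,p Pearson chi-squared statistic (no continuity
#'   correction), degrees of freedom and p-value of independence.
#' @export
setClass("ClusterGradeResult", representation(
  linkage = "character", clusters = "integer", contingency = "matrix",
  chi2 = "numeric", df = "numeric", p = "numeric"))

setMethod("show", "ClusterGradeResult", function(object) {
  cat(sprintf("ClusterGradeResult (%s linkage): chi2 = %.4g, df = %d, p = %.3g\n",
              object@linkage, object@chi2, object@df, object@p))
  print(object@contingency)
})

#' ClassifierReport: cross-validated fibrosis-grade classifier metrics
#'
#' @slot foldAUC per-fold held-out ROC AUC.
#' @slot meanAUC mean of fold AUCs.
#' @slot accuracy pooled held-out accuracy at a 0.5 score threshold.
#' @slot nFolds,seed cross-validation settings.
#' @slot labels the positive/negative grade labels.
#' @slot scores pooled held-out classifier scores, one per sample.
#' @slot truthLabels 0/1 class membership matching `scores`.
#' @export
setClass("ClassifierReport", representation(
  foldAUC = "numeric", meanAUC = "numeric", accuracy = "numeric",
  nFolds = "integer", seed = "integer", labels = "character",
  scores = "numeric", truthLabels = "integer"))

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(
    "ClassifierReport (%s vs %s, %d-fold, seed %d): mean AUC %.4f, accuracy %.4f\n",
    object@labels[1], object@labels[2], object@nFolds, object@seed,
    object@meanAUC, object@accuracy))
})
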