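## Readers/writers for the TSV dialect used throughout: tab-separated,
## UTF-8, "." decimal point, literal "NA" for missing values.

#' Read a beta-value matrix from a delimited text file
#'
#' The file must have a header row `probe_id<delim>sample1<delim>...` and
#' one row per probe with the probe ID in the first column. Values must be
#' methylation fractions in \[0, 1\] or `NA`; out-of-range values are an
#' error, never clipped.
#'
#' @param path path to the file.
#' @param delimiter field delimiter (default tab).
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
readBetaMatrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA", quote = "", comment.char = "")
  if (ncol(df) < 2)
    stop("malformed beta matrix: need a probe_id column plus >= 1 sample")
  if (nrow(df) == 0)
    stop("malformed beta matrix: empty data section")
  if (colnames(df)[1] != "probe_id")
    stop("malformed beta matrix header: first column must be 'probe_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("malformed beta matrix: non-numeric values")
  rownames(m) <- as.character(df[[1]])
  validateBetaMatrix(m)
  m
}

#' Validate a beta matrix in place
#'
#' Checks unique probe/sample identifiers and that all non-missing values
#' lie in \[0, 1\]; errors name the offending probe and sample.
#'
#' @param m numeric matrix with dimnames.
#' @return invisibly, `m`.
#' @export
validateBetaMatrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("beta matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %g",
                 rownames(m)[i[1]], colnames(m)[i[2]], m[i[1], i[2]]))
  }
  invisible(m)
}

#' Write a beta-value matrix to tab-separated text
#'
#' Values are written with 6 decimal places so a write/read round trip
#' reproduces the matrix to that precision; `NA` is written literally.
#'
#' @param m numeric matrix (or a [BetaSet-class], whose beta assay is
#'   written) with dimnames.
#' @param path output path.
#' @export
writeBetaMatrix <- function(m, path) {
  if (is(m, "BetaSet")) m <- betaValues(m)
  if (ncol(m) == 0) stop("refusing to write a 0-sample beta matrix")
  validateBetaMatrix(m)
  out <- cbind(probe_id = rownames(m),
               as.data.frame(formatC(m, digits = 6, format = "f")))
  for (j in seq_len(ncol(m)))  # formatC stringifies NA; restore real NA
    out[[j + 1]][is.na(m[, j])] <- NA
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id, patient_id, timepoint, group,
#'   tissue, fibrosis_grade`.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "NA",
                             quote = "", comment.char = "")
  miss <- setdiff(.SHEET_COLS, colnames(sheet))
  if (length(miss) > 0)
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  ## all-NA columns come back logical; pin the declared types
  sheet$timepoint <- as.character(sheet$timepoint)
  sheet$fibrosis_grade <- as.integer(sheet$fibrosis_grade)
  msg <- .validateSheetContent(sheet)
  if (length(msg) > 0) stop(paste(msg, collapse = "; "))
  sheet
}

#' Write a sample sheet
#' @param sheet data.frame as returned by [readSampleSheet()].
#' @param path output path.
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet[.SHEET_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Read a probe-annotation manifest
#'
#' @param path TSV with columns `probe_id, chromosome, gene_id,
#'   gene_region, cgi_relation, regulatory_feature`.
#' @return a validated [ProbeManifest-class].
#' @export
readProbeManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          quote = "", comment.char = "")
  ProbeManifest(df)
}

#' Write a probe-annotation manifest
#' @param manifest a [ProbeManifest-class].
#' @param path output path.
#' @export
writeProbeManifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest)[.MANIFEST_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Map a CpG probe set to its annotated genes
#'
#' Returns the deduplicated set of non-missing gene IDs over the probes;
#' each probe carries at most one gene in the manifest (the first listed
#' gene of the array annotation), so intergenic probes contribute nothing.
#'
#' @param probes character vector of probe IDs, all present in `manifest`.
#' @param manifest a [ProbeManifest-class].
#' @return character vector of unique gene IDs (possibly empty).
#' @examples
#' m <- ProbeManifest(data.frame(
#'   probe_id = c("cg1", "cg2", "cg3"), chromosome = "chr1",
#'   gene_id = c("A", "A", "B"), gene_region = "GeneBody",
#'   cgi_relation = "OpenSea", regulatory_feature = "none"))
#' mapProbesToGenes(c("cg1", "cg2", "cg3"), m)  # "A" "B"
#' @export
mapProbesToGenes <- function(probes, manifest) {
  idx <- match(probes, manifest$probe_id)
  if (anyNA(idx))
    stop("probe(s) absent from manifest: ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  genes <- manifest$gene_id[idx]
  unique(genes[!is.na(genes)])
}
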