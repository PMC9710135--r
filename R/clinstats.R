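## Longitudinal clinical-parameter testing: normality-gated dispatch to
## repeated-measures ANOVA or Friedman, with paired post hoc tests and
## per-parameter Bonferroni correction over the three timepoint pairs.

.PAIRS <- list(c("T1", "T2"), c("T1", "T3"), c("T2", "T3"))

#' Impute missing clinical values with the parameter mean
#'
#' Missing values of each parameter are replaced by the mean of that
#' parameter's observed values, pooled over patients and timepoints;
#' observed values are untouched, so the parameter mean is preserved
#' exactly.
#'
#' @param table long-format data.frame with columns `patient_id`,
#'   `parameter`, `timepoint`, `value`.
#' @return the table with `value` imputed.
#' @export
imputeMissing <- function(table) {
  stopifnot(all(c("patient_id", "parameter", "timepoint", "value")
                %in% colnames(table)))
  for (param in unique(table$parameter)) {
    idx <- table$parameter == param
    v <- table$value[idx]
    if (all(is.na(v)))
      stop("parameter '", param, "' is fully missing; cannot impute")
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    table$value[idx] <- v
  }
  table
}

## Shapiro-Wilk gate; constant vectors (inadmissible for the test) are
## routed to the nonparametric branch
.isNormal <- function(x, alpha) {
  if (length(unique(x)) < 3) return(FALSE)
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p >= alpha
}

#' Test a clinical parameter across three timepoints
#'
#' Per-timepoint Shapiro-Wilk normality at `normalityAlpha` gates the
#' branch: all timepoints normal gives repeated-measures ANOVA with paired
#' t post hoc tests; any failure gives the Friedman test with Wilcoxon
#' signed-rank post hoc tests. The three pairwise p-values (T1-T2, T1-T3,
#' T2-T3) are Bonferroni-adjusted (`min(1, 3 * p)`); post hoc tests run
#' only when the omnibus p is below `alpha`.
#'
#' @param table long-format data.frame (see [imputeMissing()]); should be
#'   imputation-complete.
#' @param parameter the parameter to test.
#' @param alpha omnibus significance level gating the post hoc tests
#'   (default 0.05).
#' @param normalityAlpha level of the Shapiro-Wilk gate (default 0.05).
#' @return list with `parameter`, `omnibus_test` ("rm_anova" or
#'   "friedman"), `omnibus_statistic`, `omnibus_p`, `posthoc_test`
#'   ("paired_t" or "wilcoxon") and `pairwise` (data.frame of pair, raw
#'   and adjusted p; `NULL` when the omnibus is not significant).
#' @export
testParameter <- function(table, parameter, alpha = 0.05,
                          normalityAlpha = 0.05) {
  sub <- table[table$parameter == parameter, , drop = FALSE]
  if (nrow(sub) == 0) stop("parameter '", parameter, "' not in table")
  wide <- stats::reshape(
    sub[c("patient_id", "timepoint", "value")],
    idvar = "patient_id", timevar = "timepoint", direction = "wide")
  cols <- paste0("value.", c("T1", "T2", "T3"))
  if (!all(cols %in% colnames(wide)))
    stop("parameter '", parameter, "' lacks one of timepoints T1/T2/T3")
  m <- as.matrix(wide[cols])
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3) stop("need >= 3 patients with complete triplets")
  colnames(m) <- c("T1", "T2", "T3")

  normal <- all(vapply(1:3, function(j) .isNormal(m[, j], normalityAlpha),
                       logical(1)))
  if (normal) {
    long <- data.frame(
      patient = factor(rep(rownames(m) %||% seq_len(nrow(m)), 3)),
      timepoint = factor(rep(colnames(m), each = nrow(m))),
      value = as.vector(m))
    fit <- stats::aov(value ~ timepoint + Error(patient), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    stat <- tab[1, "F value"]  # row 1 is the timepoint effect
    p <- tab[1, "Pr(>F)"]
    omnibus <- "rm_anova"
    posthoc <- "paired_t"
  } else {
    ft <- stats::friedman.test(m)
    stat <- unname(ft$statistic)
    p <- unname(ft$p.value)
    if (is.nan(stat) && all(m == m[, 1])) {
      stat <- 0  # fully tied data carry no evidence
      p <- 1
    }
    omnibus <- "friedman"
    posthoc <- "wilcoxon"
  }

  pairwise <- NULL
  if (!is.na(p) && p < alpha) {
    raw <- vapply(.PAIRS, function(pr) {
      a <- m[, pr[1]]
      b <- m[, pr[2]]
      if (all(a == b)) return(1)  # identical pair: no evidence
      if (posthoc == "paired_t")
        stats::t.test(a, b, paired = TRUE)$p.value
      else
        suppressWarnings(stats::wilcox.test(
          a, b, paired = TRUE, exact = nrow(m) <= 25)$p.value)
    }, numeric(1))
    pairwise <- data.frame(
      pair = vapply(.PAIRS, paste, character(1), collapse = "-"),
      p = raw, p_adjusted = pmin(1, 3 * raw), stringsAsFactors = FALSE)
  }
  list(parameter = parameter, omnibus_test = omnibus,
       omnibus_statistic = unname(stat), omnibus_p = unname(p),
       posthoc_test = posthoc, pairwise = pairwise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare a study-group vector against healthy controls
#'
#' Normality-gated dispatch: both groups Shapiro-Wilk-normal gives the
#' independent two-sample t test (Welch), otherwise the Mann-Whitney
#' (Wilcoxon rank-sum) test; two-sided. Fully degenerate input (both
#' groups constant and equal) returns p = 1 with a note.
#'
#' @param values study-group numeric vector (>= 3 values).
#' @param controls control-group numeric vector (>= 3 values).
#' @param normalityAlpha level of the Shapiro-Wilk gate (default 0.05).
#' @return list with `test` ("t" or "mann_whitney"), `statistic`, `p`,
#'   and `note` (NA unless degenerate).
#' @export
compareToControls <- function(values, controls, normalityAlpha = 0.05) {
  stopifnot(length(values) >= 3, length(controls) >= 3)
  if (stats::sd(values) == 0 && stats::sd(controls) == 0 &&
      values[1] == controls[1])
    return(list(test = "degenerate", statistic = NA_real_, p = 1,
                note = "all values identical in both groups"))
  normal <- .isNormal(values, normalityAlpha) &&
    .isNormal(controls, normalityAlpha)
  if (normal) {
    tt <- stats::t.test(values, controls)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         note = NA_character_)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values, controls))
    list(test = "mann_whitney", statistic = unname(wt$statistic),
         p = wt$p.value, note = NA_character_)
  }
}
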