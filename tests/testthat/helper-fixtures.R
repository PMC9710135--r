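# Fixtures built in code; no data files.

tinyBeta <- function(nProbes = 3, nSamples = 2, values = NULL) {
  m <- matrix(if (is.null(values)) seq(0.1, 0.9, length.out = nProbes * nSamples)
              else values,
              nrow = nProbes, ncol = nSamples,
              dimnames = list(paste0("cg", seq_len(nProbes)),
                              paste0("s", seq_len(nSamples))))
  m
}

tinyManifest <- function(n = 10, gene_region = "GeneBody",
                         cgi_relation = "OpenSea",
                         regulatory_feature = "none", gene_id = NULL) {
  ProbeManifest(data.frame(
    probe_id = paste0("cg", seq_len(n)), chromosome = "chr1",
    gene_id = if (is.null(gene_id)) paste0("G", seq_len(n)) else gene_id,
    gene_region = gene_region, cgi_relation = cgi_relation,
    regulatory_feature = regulatory_feature, stringsAsFactors = FALSE))
}

# Study-design sheet for a blood cohort: one row per patient x timepoint.
studySheet <- function(patients, timepoints = c("T1", "T2", "T3")) {
  grid <- expand.grid(patient_id = patients, timepoint = timepoints,
                      stringsAsFactors = FALSE)
  data.frame(sample_id = paste0(grid$patient_id, "_", grid$timepoint),
             patient_id = grid$patient_id, timepoint = grid$timepoint,
             group = "study", tissue = "blood", fibrosis_grade = NA_integer_,
             stringsAsFactors = FALSE)
}

# Two disjoint constant-profile liver groups (grades 0 and 3).
disjointLiver <- function(n0 = 10, n3 = 10) {
  probes <- paste0("cg", 1:8)
  n <- n0 + n3
  ids <- sprintf("L%02d", seq_len(n))
  b <- cbind(matrix(0.1, 8, n0), matrix(0.9, 8, n3))
  dimnames(b) <- list(probes, ids)
  sh <- data.frame(sample_id = ids, patient_id = paste0("pt", seq_len(n)),
                   timepoint = NA_character_, group = "nafld_liver",
                   tissue = "liver",
                   fibrosis_grade = rep(c(0L, 3L), c(n0, n3)))
  BetaSet(b, sh)
}

# Independent brute-force consensus caller: plain per-probe loops, no
# vectorised logic shared with the implementation.
oracleCallSites <- function(delta, thr, frac, directional = TRUE) {
  out <- character(nrow(delta))
  for (i in seq_len(nrow(delta))) {
    hyper <- 0L; hypo <- 0L; n <- 0L
    for (j in seq_len(ncol(delta))) {
      v <- delta[i, j]
      if (is.na(v)) next
      n <- n + 1L
      if (v >= thr) hyper <- hyper + 1L
      if (v <= -thr) hypo <- hypo + 1L
    }
    need <- if (n >= 1) ceiling(frac * n - 1e-9) else Inf
    if (directional) {
      out[i] <- if (hyper >= need) "hyper" else if (hypo >= need) "hypo"
                else "none"
    } else {
      if (hyper + hypo >= need && n >= 1) {
        out[i] <- if (hyper > hypo) "hyper" else if (hypo > hyper) "hypo"
                  else "none"
      } else out[i] <- "none"
    }
  }
  out
}

# Independent Pearson chi-square: explicit O/E loop.
oracleChi2 <- function(tab) {
  tot <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / tot
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  stat
}

# Independent mid-rank AUC (Mann-Whitney U / n1 n0).
oracleAUC <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
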