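#' Transcripts-per-million normalisation
#'
#' Converts a counts matrix with per-gene transcript lengths to TPM:
#' per sample, `TPM_i = (count_i / length_i) / sum_j (count_j / length_j) * 1e6`.
#' Every non-zero sample column sums to exactly one million; an all-zero
#' column stays all-zero with a warning.
#'
#' @param em An [expression_matrix()] with `units = "counts"` and
#'   `lengths` present.
#' @return An `expr_matrix` with `units = "TPM"`.
#' @export
compute_tpm <- function(em) {
  if (is.null(em$lengths)) {
    stop_pivotnet("TPM requires per-gene transcript lengths")
  }
  if (any(em$values < 0)) stop_pivotnet("counts must be non-negative")
  rate <- em$values / em$lengths
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(em$values)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  em$values <- sweep(rate, 2, totals, "/") * 1e6
  em$units <- "TPM"
  em
}

#' Expressed-gene filter on stage-wise TPM
#'
#' A gene is kept iff there is at least one stage in which it has
#' TPM strictly greater than `threshold` in strictly more than
#' `replicate_fraction` of that stage's replicates.  Both inequalities
#' are strict (a gene at exactly the threshold everywhere is dropped),
#' matching a literal reading of "TPMs higher than one in more than 50%
#' replicates in at least one stage".
#'
#' @param em An [expression_matrix()] of TPM values.
#' @param threshold TPM threshold (default 1).
#' @param replicate_fraction Fraction of a stage's replicates that must
#'   exceed the threshold (default 0.5).
#' @return Character vector of retained gene ids (matrix row order).
#' @export
filter_expressed <- function(em, threshold = 1, replicate_fraction = 0.5) {
  if (!identical(em$units, "TPM")) {
    stop_pivotnet("`filter_expressed()` expects a TPM matrix (units tag)")
  }
  stages <- unique(em$samples$stage)
  keep <- rep(FALSE, nrow(em$values))
  for (s in stages) {
    cols <- which(em$samples$stage == s)
    n_above <- rowSums(em$values[, cols, drop = FALSE] > threshold)
    keep <- keep | (n_above / length(cols) > replicate_fraction)
  }
  rownames(em$values)[keep]
}

#' Collapse multi-probe genes to their most expressed probe
#'
#' When a gene is represented by several probes, the probe with the
#' highest mean expression across all samples is selected; ties are
#' broken by the lexicographically smallest probe id.
#'
#' @param em An [expression_matrix()] whose rows are probes.
#' @param map A data.frame with columns `probe`, `gene` (many probes to
#'   one gene).  Every probe row of `em` must appear.
#' @return An `expr_matrix` with one row per gene (rows named by gene).
#' @export
collapse_probes <- function(em, map) {
  probes <- rownames(em$values)
  missing <- setdiff(probes, map$probe)
  if (length(missing)) {
    stop_pivotnet("unmapped probe(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(map$probe)) {
    stop_pivotnet("`map` must map every probe to exactly one gene")
  }
  gene_of <- stats::setNames(map$gene, map$probe)[probes]
  means <- rowMeans(em$values)
  ord <- order(gene_of, -means, probes)
  chosen <- ord[!duplicated(gene_of[ord])]
  chosen <- chosen[order(gene_of[chosen])]
  values <- em$values[chosen, , drop = FALSE]
  rownames(values) <- unname(gene_of[chosen])
  expression_matrix(values, stage = em$samples$stage,
                    replicate = em$samples$replicate, units = em$units,
                    lengths = NULL)
}

#' Detection p-value filter for array probes
#'
#' With `keep_detected = TRUE` (the conventional Illumina rule) a probe
#' is retained iff it is detected (detection p < `alpha`) in at least
#' `min_samples` samples.  `keep_detected = FALSE` applies the opposite
#' polarity (retain probes NOT detected in at least `min_samples`
#' samples), reproducing the literal wording of some QC descriptions;
#' the conventional polarity is the default.
#'
#' @param em An [expression_matrix()] of probe intensities.
#' @param detection_p Numeric matrix of detection p-values, same
#'   dimensions and dimnames as `em$values`.
#' @param alpha Detection significance level (default 0.05).
#' @param min_samples Minimum number of qualifying samples (default 1).
#' @param keep_detected Filter polarity, see above.
#' @return An `expr_matrix` restricted to the retained probes.
#' @export
detection_filter <- function(em, detection_p, alpha = 0.05, min_samples = 1,
                             keep_detected = TRUE) {
  if (!identical(dim(detection_p), dim(em$values))) {
    stop_pivotnet("`detection_p` must match the expression matrix shape")
  }
  n_detected <- rowSums(detection_p < alpha)
  keep <- if (keep_detected) {
    n_detected >= min_samples
  } else {
    rowSums(detection_p <= alpha) < min_samples
  }
  em$values <- em$values[keep, , drop = FALSE]
  if (!is.null(em$lengths)) em$lengths <- em$lengths[keep]
  em
}

#' Quantile normalisation
#'
#' Forces every sample column onto the common reference distribution
#' (the row-wise mean of the column-sorted input); ties within a column
#' receive the mean of the corresponding reference values.  Column means
#' are equal after normalisation.
#'
#' @param em An [expression_matrix()] with at least two samples.
#' @return An `expr_matrix` with `units = "normalized"`.
#' @export
quantile_normalize <- function(em) {
  if (ncol(em$values) < 2) {
    stop_pivotnet("quantile normalisation needs >= 2 samples")
  }
  values <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(values) <- dimnames(em$values)
  em$values <- values
  em$units <- "normalized"
  em
}
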