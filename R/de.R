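#' Two-sample t-test with explicit degenerate-variance behaviour
#'
#' Standard two-sample t-test (Welch by default, Student's pooled
#' variance optionally), two-sided.  When both samples are constant:
#' equal means give `t = 0, p = 1`; unequal means give an infinite
#' statistic and `p = 0` with a warning.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param variant `"welch"` (unequal variances, default) or
#'   `"student"` (pooled variance).
#' @return A list with elements `t`, `p`, `df`.
#' @export
two_sample_ttest <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) {
    stop_pivotnet("each sample needs >= 2 values")
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    warning("zero variance with unequal means: p = 0")
    return(list(t = sign(mean(b) - mean(a)) * Inf, p = 0, df = NA_real_))
  }
  ht <- stats::t.test(b, a, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Stage-contrast differential expression
#'
#' Per-gene two-sample t-test between two stage/condition groups with
#' the MAQC-style dual threshold: a gene is significant iff its
#' BH-adjusted p-value is strictly below `q_cutoff` AND its linear
#' fold change is strictly above `fc_cutoff`.  The t-test runs on
#' `log2(x + 1)`-transformed values (configurable); fold changes are
#' ratios of linear group means, `max(mean) / min(mean)`, with the
#' direction ("up" = higher in `group_b`) tracked separately.  A zero
#' mean in one group with a non-zero mean in the other yields an
#' infinite fold change unless a `pseudo` count is supplied.
#'
#' @param em An [expression_matrix()].
#' @param group_a,group_b Stage/condition labels (each with >= 2
#'   replicates); `group_a` is the reference.
#' @param q_cutoff BH-adjusted p cutoff (default 0.05, strict `<`).
#' @param fc_cutoff Linear fold-change cutoff (default 1.4, strict `>`).
#' @param variant t-test variant, see [two_sample_ttest()].
#' @param log_transform Run the t-test on `log2(x + 1)` (default TRUE).
#' @param pseudo Pseudo-count added to both means for the fold change
#'   (default 0 = off).
#' @return A data.frame of class `de_result`, one row per gene:
#'   `gene`, `mean_a`, `mean_b`, `fold_change`, `direction`, `t`, `p`,
#'   `q`, `significant`.
#' @export
stage_de <- function(em, group_a, group_b, q_cutoff = 0.05, fc_cutoff = 1.4,
                     variant = c("welch", "student"), log_transform = TRUE,
                     pseudo = 0) {
  variant <- match.arg(variant)
  cols_a <- which(em$samples$stage == group_a)
  cols_b <- which(em$samples$stage == group_b)
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop_pivotnet("both groups need >= 2 replicates")
  }
  xa <- em$values[, cols_a, drop = FALSE]
  xb <- em$values[, cols_b, drop = FALSE]
  ta <- if (log_transform) log2(xa + 1) else xa
  tb <- if (log_transform) log2(xb + 1) else xb

  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  hi <- pmax(mean_a, mean_b) + pseudo
  lo <- pmin(mean_a, mean_b) + pseudo
  fold_change <- ifelse(hi == lo, 1, ifelse(lo == 0, Inf, hi / lo))
  direction <- ifelse(mean_b > mean_a, "up",
                      ifelse(mean_b < mean_a, "down", "none"))

  stat <- vapply(seq_len(nrow(em$values)), function(i) {
    res <- suppressWarnings(two_sample_ttest(ta[i, ], tb[i, ], variant))
    c(res$t, res$p)
  }, numeric(2))
  p <- stat[2, ]
  q <- bh_adjust(p)

  out <- data.frame(
    gene = rownames(em$values),
    mean_a = mean_a, mean_b = mean_b,
    fold_change = fold_change, direction = direction,
    t = stat[1, ], p = p, q = q,
    significant = q < q_cutoff & fold_change > fc_cutoff,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  attr(out, "contrast") <- c(group_a, group_b)
  out
}

#' Overlap of significant genes between two DE analyses
#'
#' Intersects the significant genes of two [stage_de()] tables (for
#' instance one per dataset) and orders the shared genes by the chosen
#' criterion: `"min_q"` ranks by the larger (worse) of the two adjusted
#' p-values, ascending, so the top genes are strongly significant in
#' BOTH analyses; `"max_fc"` ranks by the smaller of the two fold
#' changes, descending.  Ties break by gene id.
#'
#' @param de_a,de_b Two `de_result` tables sharing a gene namespace.
#' @param rank_by `"min_q"` (default) or `"max_fc"`.
#' @return Character vector of shared significant genes, best first.
#' @export
cross_dataset_overlap <- function(de_a, de_b, rank_by = c("min_q", "max_fc")) {
  rank_by <- match.arg(rank_by)
  if (!length(intersect(de_a$gene, de_b$gene))) {
    stop_pivotnet("the two DE tables share no gene identifiers")
  }
  shared <- intersect(de_a$gene[de_a$significant], de_b$gene[de_b$significant])
  if (!length(shared)) return(character(0))
  ia <- match(shared, de_a$gene); ib <- match(shared, de_b$gene)
  key <- if (rank_by == "min_q") {
    pmax(de_a$q[ia], de_b$q[ib])
  } else {
    -pmin(de_a$fold_change[ia], de_b$fold_change[ib])
  }
  shared[order(key, shared)]
}

#' Write a DE table as tab-separated text
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_de <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
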