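#' Two-group chi-square test of abnormal-centrosome proportions
#'
#' Pearson chi-square on the 2x2 table (abnormal/normal x
#' control/treated), df = 1, continuity correction off by default.
#' When a margin of the table is zero (no abnormal cells anywhere, or
#' all cells abnormal) the test is defined as `chi_square = 0, p = 1`
#' with a warning.
#'
#' @param control,treated Length-2 numeric vectors `c(n, k)`: cells
#'   counted and cells with more than two centrosomes.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @param alpha Significance level for the flag (default 0.05,
#'   `p <= alpha`).
#' @return An object of class `proportion_test`: list with
#'   `chi_square`, `degrees_of_freedom`, `p`, `proportions` (named
#'   control/treated), `significant`.
#' @export
centrosome_chisq <- function(control, treated, correct = FALSE,
                             alpha = 0.05) {
  n1 <- control[1]; k1 <- control[2]
  n2 <- treated[1]; k2 <- treated[2]
  if (n1 <= 0 || n2 <= 0) stop_pivotnet("cell counts must be positive")
  if (k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    stop_pivotnet("abnormal counts must satisfy 0 <= k <= n")
  }
  tbl <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                dimnames = list(c("abnormal", "normal"),
                                c("control", "treated")))
  if (any(rowSums(tbl) == 0)) {
    warning("zero margin in the 2x2 table: chi-square defined as 0, p = 1")
    stat <- 0; p <- 1
  } else {
    ht <- suppressWarnings(stats::chisq.test(tbl, correct = correct))
    stat <- unname(ht$statistic); p <- unname(ht$p.value)
  }
  structure(
    list(chi_square = stat, degrees_of_freedom = 1L, p = p,
         proportions = c(control = k1 / n1, treated = k2 / n2),
         significant = p <= alpha),
    class = "proportion_test"
  )
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf(
    "<proportion_test> chi-square = %.4g (df = %d), p = %.4g%s; proportions: control %.3f, treated %.3f\n",
    x$chi_square, x$degrees_of_freedom, x$p,
    if (x$significant) " *" else "", x$proportions["control"],
    x$proportions["treated"]
  ))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Dose-response summary of centrosome-abnormality counts
#'
#' Tests every non-control condition against the control row with
#' [centrosome_chisq()] and reports per-dose proportions, chi-square
#' statistics, p-values, significance flags and asterisk codes, plus a
#' descriptive monotone-trend indicator (are the proportions
#' non-decreasing in the table's row order?).
#'
#' @param counts A data.frame with columns `condition`,
#'   `n_cells_counted`, `n_cells_gt2_centrosomes` (see
#'   [generate_centrosome_counts()]), doses in increasing order.
#' @param control_label The control row's condition label.
#' @param correct,alpha Passed to [centrosome_chisq()].
#' @return A data.frame, one row per non-control condition, with
#'   attribute `monotone_trend`.
#' @export
dose_response_table <- function(counts, control_label, correct = FALSE,
                                alpha = 0.05) {
  if (!control_label %in% counts$condition) {
    stop_pivotnet("control label `", control_label, "` not in the table")
  }
  ctrl <- counts[counts$condition == control_label, ][1, ]
  rest <- counts[counts$condition != control_label, , drop = FALSE]
  rows <- lapply(seq_len(nrow(rest)), function(i) {
    r <- rest[i, ]
    ht <- centrosome_chisq(
      c(ctrl$n_cells_counted, ctrl$n_cells_gt2_centrosomes),
      c(r$n_cells_counted, r$n_cells_gt2_centrosomes),
      correct = correct, alpha = alpha
    )
    data.frame(
      condition = r$condition,
      n = r$n_cells_counted, k = r$n_cells_gt2_centrosomes,
      proportion = unname(ht$proportions["treated"]),
      chi_square = ht$chi_square, p = ht$p,
      significant = ht$significant,
      stars = significance_stars(ht$p),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(0), n = integer(0), k = integer(0),
               proportion = numeric(0), chi_square = numeric(0),
               p = numeric(0), significant = logical(0),
               stars = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  props <- counts$n_cells_gt2_centrosomes / counts$n_cells_counted
  attr(out, "monotone_trend") <- !is.unsorted(props)
  out
}
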