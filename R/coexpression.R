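#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment
#' (`q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1), returned in the
#' input order.  Input values must lie in `[0, 1]`.
#'
#' @param p Numeric vector of raw p-values.
#' @return Numeric vector of adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_pivotnet("p-values must lie in [0, 1] and contain no NA")
  }
  stats::p.adjust(p, method = "BH")
}

#' Overlay expression correlation on a PPI scaffold
#'
#' For every PPI edge whose two genes are present in the expression
#' matrix and have non-zero variance, computes the Pearson correlation r
#' across all samples (stages pooled), the exact two-sided p-value via
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (|r| = 1 maps to p = 0), and BH-adjusts across all tested edges.
#' Edges with `q <= q_cutoff` are retained and annotated with their
#' correlation sign; edges skipped for missing genes or a constant
#' profile are counted, not errors.
#'
#' @param ppi A [load_ppi()] network (or a data.frame with `gene_a`,
#'   `gene_b` and optionally `interaction_type`).
#' @param em An [expression_matrix()] with at least 3 samples.
#' @param q_cutoff BH-adjusted significance cutoff (default 0.01,
#'   retained when `q <= q_cutoff`).
#' @return An object of class `coexpr_network`: a list with `edges`
#'   (retained edges with columns gene_a, gene_b, interaction_type, r,
#'   p, q, sign), `tested` (all tested edges), `nodes` (genes incident
#'   to a retained edge), skip counters and the cutoff.
#' @export
edge_correlation <- function(ppi, em, q_cutoff = 0.01) {
  n <- ncol(em$values)
  if (n < 3) stop_pivotnet("correlation p-values need >= 3 samples")
  genes <- rownames(em$values)
  if (!any(c(ppi$gene_a, ppi$gene_b) %in% genes)) {
    stop_pivotnet("PPI and expression matrix share no gene identifiers")
  }

  present <- ppi$gene_a %in% genes & ppi$gene_b %in% genes
  n_missing <- sum(!present)
  e <- ppi[present, , drop = FALSE]
  if (is.null(e$interaction_type)) e$interaction_type <- "unknown"

  sds <- apply(em$values, 1, stats::sd)
  ok <- sds[e$gene_a] > 0 & sds[e$gene_b] > 0
  n_constant <- sum(!ok)
  e <- e[ok, , drop = FALSE]

  if (nrow(e)) {
    z <- t(scale(t(em$values[unique(c(e$gene_a, e$gene_b)), , drop = FALSE])))
    r <- rowSums(z[e$gene_a, , drop = FALSE] * z[e$gene_b, , drop = FALSE]) /
      (n - 1)
    r <- pmin(1, pmax(-1, r))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tt), df = n - 2))
    q <- bh_adjust(p)
  } else {
    r <- p <- q <- numeric(0)
  }

  tested <- data.frame(
    gene_a = e$gene_a, gene_b = e$gene_b,
    interaction_type = e$interaction_type,
    r = unname(r), p = unname(p), q = unname(q),
    sign = ifelse(r < 0, "anti-correlated", "correlated"),
    stringsAsFactors = FALSE
  )
  retained <- tested[tested$q <= q_cutoff, , drop = FALSE]
  rownames(retained) <- NULL

  structure(
    list(
      edges = retained,
      tested = tested,
      nodes = sort(unique(c(retained$gene_a, retained$gene_b))),
      n_tested = nrow(tested),
      n_skipped_missing = n_missing,
      n_skipped_constant = n_constant,
      q_cutoff = q_cutoff
    ),
    class = "coexpr_network"
  )
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf(
    "<coexpr_network> %d/%d edges retained at q <= %g; %d nodes (skipped: %d missing, %d constant)\n",
    nrow(x$edges), x$n_tested, x$q_cutoff, length(x$nodes),
    x$n_skipped_missing, x$n_skipped_constant
  ))
  invisible(x)
}

# degree of every network node over the retained edges
network_degree <- function(net) {
  tab <- table(c(net$edges$gene_a, net$edges$gene_b))
  stats::setNames(as.integer(tab), names(tab))
}

# neighbours of one gene over the retained edges
network_neighbors <- function(net, gene) {
  e <- net$edges
  c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene])
}

#' Write a co-expression network as tab-separated edge list
#'
#' @param net A `coexpr_network`.
#' @param path Output path (columns gene_a, gene_b, interaction_type,
#'   r, p, q, sign).
#' @return The path, invisibly.
#' @export
write_coexpression <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
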