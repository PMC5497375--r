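#' Hypergeometric GO-term enrichment of a gene set
#'
#' For every annotation term with at least one annotated gene inside
#' `gene_set`, computes the one-sided upper-tail hypergeometric p-value
#' `P(X >= k)` with `X ~ Hypergeom(N = |universe|, K = term genes in
#' universe, n = |gene_set|)`, then BH-adjusts across the terms tested
#' for this gene set.  Annotations outside the universe are ignored;
#' terms with `k = 0` are not reported.
#'
#' @param gene_set Character vector of genes (must lie in `universe`).
#' @param annotations A data.frame with columns `gene`, `term`.
#' @param universe Character vector: the gene universe.
#' @return A data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, sorted by `p`.
#' @export
go_enrichment <- function(gene_set, annotations, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_pivotnet("empty universe")
  if (!all(gene_set %in% universe)) {
    stop_pivotnet("`gene_set` must be a subset of `universe`")
  }
  gene_set <- unique(gene_set)
  ann <- unique(annotations[annotations$gene %in% universe, c("gene", "term")])
  N <- length(universe)
  n <- length(gene_set)

  K_by_term <- table(ann$term)
  in_set <- ann[ann$gene %in% gene_set, , drop = FALSE]
  k_by_term <- table(in_set$term)
  terms <- names(k_by_term)
  if (length(terms) == 0) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  k <- as.integer(k_by_term[terms])
  K <- as.integer(K_by_term[terms])
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select GO-enriched functional modules from an MCL partition
#'
#' A cluster is flagged *functional* iff it has at least `min_size`
#' genes AND at least one GO term enriched at BH `q <= q_cutoff`
#' (enrichment computed against `universe`, by default the clustered
#' nodes).
#'
#' @param clusters An `mcl_partition` or a plain list of character
#'   vectors partitioning the network nodes.
#' @param annotations A data.frame with columns `gene`, `term`.
#' @param universe Gene universe for the hypergeometric tests; defaults
#'   to the union of the clusters.
#' @param min_size Minimum functional-module size (default 10).
#' @param q_cutoff Enrichment significance cutoff (default 0.05).
#' @return An object of class `module_set`: a list with `clusters`
#'   (named M1, M2, ...), `enrichment` (one data.frame per cluster),
#'   `functional` (named logical), and the two thresholds.
#' @export
select_functional_modules <- function(clusters, annotations, universe = NULL,
                                      min_size = 10, q_cutoff = 0.05) {
  if (inherits(clusters, "mcl_partition")) clusters <- clusters$clusters
  if (is.null(universe)) universe <- unlist(clusters, use.names = FALSE)
  names(clusters) <- paste0("M", seq_along(clusters))

  enrichment <- lapply(clusters, function(cl) {
    go_enrichment(intersect(cl, universe), annotations, universe)
  })
  functional <- vapply(seq_along(clusters), function(i) {
    length(clusters[[i]]) >= min_size &&
      nrow(enrichment[[i]]) > 0 &&
      any(enrichment[[i]]$q <= q_cutoff)
  }, logical(1))
  names(functional) <- names(clusters)

  structure(
    list(clusters = clusters, enrichment = enrichment,
         functional = functional, min_size = min_size,
         q_cutoff = q_cutoff),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d clusters, %d functional (min size %d, enrichment q <= %g)\n",
              length(x$clusters), sum(x$functional), x$min_size, x$q_cutoff))
  for (m in names(x$clusters)[x$functional]) {
    top <- utils::head(x$enrichment[[m]], 1)
    cat(sprintf("  %s: %d genes, top term %s (q = %.3g)\n", m,
                length(x$clusters[[m]]), top$term, top$q))
  }
  invisible(x)
}

# genes belonging to any functional module
functional_module_genes <- function(modules) {
  unlist(modules$clusters[modules$functional], use.names = FALSE)
}

#' Write cluster assignments and enrichment tables
#'
#' @param modules A `module_set`.
#' @param prefix Path prefix; writes `<prefix>_clusters.tsv` (gene,
#'   cluster, functional) and `<prefix>_enrichment.tsv` (cluster, term,
#'   k, K, n, N, p, q).
#' @return The two paths, invisibly.
#' @export
write_modules <- function(modules, prefix) {
  cl_path <- paste0(prefix, "_clusters.tsv")
  en_path <- paste0(prefix, "_enrichment.tsv")
  cl <- data.frame(
    gene = unlist(modules$clusters, use.names = FALSE),
    cluster = rep(names(modules$clusters), lengths(modules$clusters)),
    functional = rep(unname(modules$functional), lengths(modules$clusters)),
    stringsAsFactors = FALSE
  )
  utils::write.table(cl, cl_path, sep = "\t", quote = FALSE, row.names = FALSE)
  en <- do.call(rbind, lapply(names(modules$enrichment), function(m) {
    e <- modules$enrichment[[m]]
    if (nrow(e)) cbind(cluster = m, e) else NULL
  }))
  if (is.null(en)) {
    en <- data.frame(cluster = character(0), term = character(0))
  }
  utils::write.table(en, en_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(clusters = cl_path, enrichment = en_path))
}
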