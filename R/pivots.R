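#' Inter-modular hubs of a co-expression network
#'
#' Inter-modular hubs are the genes that sit *between* the functional
#' modules: nodes of the co-expression network that are NOT members of
#' any functional module and interact with at least `min_degree` genes.
#' (Cluster membership is exclusive because MCL partitions the network,
#' so "between the modules" is operationalised as non-membership.)
#'
#' @param network A `coexpr_network`.
#' @param modules A `module_set` computed on the same network.
#' @param min_degree Minimum degree (default 10, "at least ten genes").
#' @return Character vector of hub gene ids, by decreasing degree.
#' @export
find_intermodular_hubs <- function(network, modules, min_degree = 10) {
  deg <- network_degree(network)
  inside <- functional_module_genes(modules)
  hubs <- deg[!(names(deg) %in% inside) & deg >= min_degree]
  names(sort(hubs, decreasing = TRUE))
}

#' Pivot genes: hubs enriched for interactions with a functional module
#'
#' For every hub and every functional module, tests whether the hub has
#' significantly MORE co-expression neighbours inside the module than
#' expected under neighbour sampling without replacement:
#' `p = P(X >= k)` with `X ~ Hypergeom(N = network nodes minus the hub,
#' K = module size, n = hub degree)` and `k` the hub's neighbours inside
#' the module.  A hub is a pivot iff at least one module reaches
#' `p <= p_cutoff` (raw p by default; set `adjust = "BH"` to adjust
#' across all hub-module tests of the call).
#'
#' @param hubs Character vector from [find_intermodular_hubs()].
#' @param network The same `coexpr_network`.
#' @param modules The same `module_set`.
#' @param p_cutoff Significance cutoff (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame of class `pivot_records`, one row per
#'   hub-module pair: `gene`, `degree`, `module`, `module_size`, `k`,
#'   `p` (and `q` if adjusted), `flagged`; attribute `pivots` holds the
#'   pivot gene ids.
#' @export
identify_pivots <- function(hubs, network, modules, p_cutoff = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  fmods <- modules$clusters[modules$functional]
  rows <- list()
  n_nodes <- length(network$nodes)
  for (h in hubs) {
    nb <- network_neighbors(network, h)
    for (m in names(fmods)) {
      members <- setdiff(fmods[[m]], h)
      k <- sum(nb %in% members)
      K <- length(members)
      p <- stats::phyper(k - 1, K, (n_nodes - 1) - K, length(nb),
                         lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        gene = h, degree = length(nb), module = m, module_size = K,
        k = k, p = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), degree = integer(0),
               module = character(0), module_size = integer(0),
               k = integer(0), p = numeric(0), stringsAsFactors = FALSE)
  if (adjust == "BH" && nrow(out)) {
    out$q <- bh_adjust(out$p)
    out$flagged <- out$q <= p_cutoff
  } else {
    out$flagged <- out$p <= p_cutoff
  }
  if (!nrow(out)) out$flagged <- logical(0)
  rownames(out) <- NULL
  class(out) <- c("pivot_records", "data.frame")
  attr(out, "pivots") <- unique(out$gene[out$flagged])
  out
}

#' Pivot gene ids from a `pivot_records` table
#'
#' @param records Output of [identify_pivots()].
#' @return Character vector of pivot gene ids.
#' @export
pivot_genes <- function(records) attr(records, "pivots") %||% character(0)

#' Per-pivot crosstalk report
#'
#' For every pivot and each functional module it is enriched against,
#' reports the module's top GO labels and the correlated /
#' anti-correlated breakdown of the pivot's co-expression edges into
#' the module.
#'
#' @param records Output of [identify_pivots()].
#' @param modules The `module_set` used to compute them.
#' @param network The `coexpr_network` used to compute them.
#' @param n_terms Number of top GO terms to list per module (default 3).
#' @return A data.frame, one row per pivot-module enrichment: `gene`,
#'   `module`, `k`, `p`, `top_terms`, `n_correlated`,
#'   `n_anticorrelated`.
#' @export
pivot_module_report <- function(records, modules, network, n_terms = 3) {
  sel <- records[records$flagged, , drop = FALSE]
  e <- network$edges
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    g <- sel$gene[i]; m <- sel$module[i]
    members <- modules$clusters[[m]]
    into <- e[(e$gene_a == g & e$gene_b %in% members) |
                (e$gene_b == g & e$gene_a %in% members), , drop = FALSE]
    enr <- modules$enrichment[[m]]
    data.frame(
      gene = g, module = m, k = sel$k[i], p = sel$p[i],
      top_terms = paste(utils::head(enr$term, n_terms), collapse = ";"),
      n_correlated = sum(into$sign == "correlated"),
      n_anticorrelated = sum(into$sign == "anti-correlated"),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), module = character(0), k = integer(0),
               p = numeric(0), top_terms = character(0),
               n_correlated = integer(0), n_anticorrelated = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
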