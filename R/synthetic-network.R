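#' Simulate a protein-protein interaction edge list around planted truth
#'
#' Wires a BioGrid-like undirected edge list over the genes of a
#' [generate_stage_expression()] ground truth: pairs inside the same
#' planted module are connected with probability `p_within`; every
#' planted pivot is wired as a hub of degree exactly `hub_min_degree`,
#' with `round(p_hub_to_module * hub_min_degree)` of those edges going
#' into its target module (a majority when `p_hub_to_module > 0.5`) and
#' the rest to random genes outside it; all remaining pairs not inside a
#' common module are connected with probability `p_background`.
#' Self-edges and duplicates (in either orientation) never occur; when a
#' background draw would duplicate a hub or module edge the earlier edge
#' wins.
#'
#' @param truth A `synthetic_truth` object.
#' @param p_within Within-module edge probability (must exceed
#'   `p_background`).
#' @param p_hub_to_module Fraction of each pivot's edges wired into its
#'   target module.
#' @param p_background Background edge probability.
#' @param hub_min_degree Degree given to every planted pivot.
#' @param seed Integer RNG seed.
#'
#' @return A data.frame with columns `gene_a`, `gene_b`,
#'   `interaction_type` (`"physical"`/`"genetic"`).
#' @export
generate_ppi <- function(truth, p_within = 0.9, p_hub_to_module = 10 / 12,
                         p_background = 0.01, hub_min_degree = 12, seed = 1) {
  probs <- c(p_within, p_hub_to_module, p_background)
  if (any(probs < 0) || any(probs > 1)) {
    stop_pivotnet("probabilities must lie in [0, 1]")
  }
  if (p_within <= p_background && p_within > 0) {
    stop_pivotnet("`p_within` must exceed `p_background`")
  }
  if (p_hub_to_module <= 0.5 && nrow(truth$pivot_genes) > 0) {
    warning("p_hub_to_module <= 0.5: pivots will not have a majority of edges in their target module")
  }
  genes <- names(truth$module_assignments)
  n <- length(genes)

  with_seed(seed, {
    a <- character(0); b <- character(0)

    # intra-module edges
    for (members in truth$modules) {
      if (length(members) >= 2 && p_within > 0) {
        pairs <- utils::combn(members, 2)
        keep <- stats::runif(ncol(pairs)) < p_within
        a <- c(a, pairs[1, keep]); b <- c(b, pairs[2, keep])
      }
    }

    # pivot hub wiring
    pv <- truth$pivot_genes
    for (i in seq_len(nrow(pv))) {
      hub <- pv$gene[i]
      members <- truth$modules[[pv$target_module[i]]]
      n_in <- min(length(members), max(1L, round(p_hub_to_module * hub_min_degree)))
      nb_in <- sample(members, n_in)
      n_out <- hub_min_degree - n_in
      pool <- setdiff(genes, c(hub, members))
      nb_out <- if (n_out > 0) sample(pool, n_out) else character(0)
      nb <- c(nb_in, nb_out)
      a <- c(a, rep(hub, length(nb))); b <- c(b, nb)
    }

    # background edges over pairs not sharing a module
    if (p_background > 0) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      ga <- genes[idx[, 1]]; gb <- genes[idx[, 2]]
      same_mod <- truth$module_assignments[ga] != "background" &
        truth$module_assignments[ga] == truth$module_assignments[gb]
      keep <- !same_mod & stats::runif(length(ga)) < p_background
      a <- c(a, ga[keep]); b <- c(b, gb[keep])
    }

    if (length(a) == 0) {
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        interaction_type = character(0),
                        stringsAsFactors = FALSE))
    }
    dup <- duplicated(edge_key(a, b))
    a <- a[!dup]; b <- b[!dup]
    data.frame(
      gene_a = a, gene_b = b,
      interaction_type = sample(c("physical", "genetic"), length(a),
                                replace = TRUE, prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate flat GO biological-process annotations for planted modules
#'
#' Emits `terms_per_module` synthetic GO terms per planted module.  At
#' `annotation_noise = 0` a module's terms annotate exactly its members;
#' at `annotation_noise = 1` every gene is annotated independently with
#' the module's base rate (term membership carries no module signal).
#' Intermediate noise linearly interpolates the two regimes:
#' `P(gene annotated) = (1 - noise) * 1[gene in module] + noise * |module| / n_genes`.
#'
#' @param truth A `synthetic_truth` object.
#' @param terms_per_module Number of terms per planted module (>= 1).
#' @param annotation_noise Mixing weight in `[0, 1]` (see above).
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `gene`, `term`.
#' @export
generate_go_annotations <- function(truth, terms_per_module = 3,
                                    annotation_noise = 0.05, seed = 1) {
  if (terms_per_module < 1) stop_pivotnet("`terms_per_module` must be >= 1")
  if (annotation_noise < 0 || annotation_noise > 1) {
    stop_pivotnet("`annotation_noise` must lie in [0, 1]")
  }
  genes <- names(truth$module_assignments)
  n <- length(genes)
  with_seed(seed, {
    gene_col <- character(0); term_col <- character(0)
    for (j in seq_along(truth$modules)) {
      members <- truth$modules[[j]]
      p_base <- length(members) / n
      prob <- (1 - annotation_noise) * (genes %in% members) +
        annotation_noise * p_base
      for (t in seq_len(terms_per_module)) {
        annotated <- genes[stats::runif(n) < prob]
        gene_col <- c(gene_col, annotated)
        term_col <- c(term_col, rep(sprintf("GO:SYN%02d%02d", j, t),
                                    length(annotated)))
      }
    }
    data.frame(gene = gene_col, term = term_col, stringsAsFactors = FALSE)
  })
}
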