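#' Markov cluster algorithm (MCL)
#'
#' Native implementation of the Markov cluster algorithm: the graph's
#' adjacency matrix (with self-loops of weight `loop_weight`) is column
#' normalised to a stochastic matrix, then alternately *expanded*
#' (raised to the matrix power `expansion`) and *inflated* (entry-wise
#' power `inflation`, entries below `prune_threshold` set to zero,
#' columns renormalised) until the matrix changes by less than
#' `tolerance` in max-norm or `max_iterations` is reached
#' (non-convergence is a warning, not an error).  Clusters are read off
#' the attractor rows of the limit matrix: attractors (positive
#' diagonal) that flow into one another form one attractor system, and
#' every node joins the system its column mass flows to.  The result is
#' always a partition of the node set; a node claimed by several systems
#' is assigned to the one receiving the most of its mass, ties broken
#' towards the cluster containing the lexicographically smallest node.
#'
#' Defaults (`inflation = 2`, `expansion = 2`, `loop_weight = 1`,
#' `prune_threshold = 1e-5`) are the canonical defaults of the original
#' MCL formulation.
#'
#' @param network A `coexpr_network` from [edge_correlation()], or any
#'   data.frame with columns `gene_a`, `gene_b` (optionally `r` when
#'   `use_weights = TRUE`).
#' @param inflation Entry-wise inflation exponent (> 0).
#' @param expansion Matrix-power expansion exponent (integer >= 2).
#' @param loop_weight Self-loop weight added to every node (> 0).
#' @param prune_threshold Entries below this are zeroed after inflation.
#' @param max_iterations Iteration cap.
#' @param tolerance Max-norm convergence tolerance.
#' @param nodes Optional extra node ids to include even if isolated
#'   (isolated nodes come out as singleton clusters).
#' @param use_weights If `TRUE`, edges are weighted by |r| instead of 1.
#'
#' @return An object of class `mcl_partition`: a list with `clusters`
#'   (list of character vectors, sorted by decreasing size), `iterations`
#'   and `converged`.
#' @export
mcl_cluster <- function(network, inflation = 2, expansion = 2,
                        loop_weight = 1, prune_threshold = 1e-5,
                        max_iterations = 100, tolerance = 1e-6,
                        nodes = NULL, use_weights = FALSE) {
  if (inflation <= 0 || loop_weight <= 0) {
    stop_pivotnet("`inflation` and `loop_weight` must be positive")
  }
  if (expansion < 2) stop_pivotnet("`expansion` must be an integer >= 2")

  edges <- if (inherits(network, "coexpr_network")) network$edges else
    as.data.frame(network)
  ids <- sort(unique(c(edges$gene_a, edges$gene_b, nodes)))
  n <- length(ids)
  if (n == 0) stop_pivotnet("network is empty")

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    w <- if (use_weights && !is.null(edges$r)) abs(edges$r) else
      rep(1, nrow(edges))
    ia <- match(edges$gene_a, ids)
    ib <- match(edges$gene_b, ids)
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
  }
  diag(A) <- loop_weight

  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0
  while (iter < max_iterations) {
    iter <- iter + 1
    Me <- M
    for (k in seq_len(expansion - 1)) Me <- Me %*% M
    Mi <- Me^inflation
    Mi[Mi < prune_threshold] <- 0
    cs <- colSums(Mi)
    dead <- cs == 0
    if (any(dead)) {            # fully pruned column: park mass on self
      Mi[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Mi <- sweep(Mi, 2, cs, "/")
    delta <- max(abs(Mi - M))
    M <- Mi
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("MCL did not converge within %d iterations (last delta above tolerance)",
                    max_iterations))
  }

  clusters <- read_mcl_clusters(M, ids)

  # partition assertion: disjoint cover of the node set
  flat <- unlist(clusters, use.names = FALSE)
  stopifnot(!anyDuplicated(flat), setequal(flat, ids))

  sizes <- lengths(clusters)
  firsts <- vapply(clusters, function(cl) cl[1], character(1))
  clusters <- clusters[order(-sizes, firsts)]

  structure(list(clusters = clusters, iterations = iter,
                 converged = converged),
            class = "mcl_partition")
}

# Interpret the MCL limit matrix: attractor systems and their basins.
read_mcl_clusters <- function(M, ids) {
  n <- length(ids)
  eps <- .Machine$double.eps^0.5
  att <- which(diag(M) > eps)
  if (length(att) == 0) att <- seq_len(n)   # degenerate; treat all as attractors

  # attractor systems: connected components of the attractor-attractor flow
  sys <- rep(NA_integer_, n)
  n_sys <- 0
  for (a in att) {
    if (!is.na(sys[a])) next
    n_sys <- n_sys + 1
    queue <- a
    sys[a] <- n_sys
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      linked <- att[(M[x, att] > eps | M[att, x] > eps) & is.na(sys[att])]
      sys[linked] <- n_sys
      queue <- c(queue, linked)
    }
  }

  # each node joins the system receiving the most of its column mass
  mass <- matrix(0, n_sys, n)
  for (a in att) {
    mass[sys[a], ] <- mass[sys[a], ] + M[a, ]
  }
  member <- sys                      # attractors stay in their own system
  free <- which(is.na(member))
  for (j in free) {
    m <- mass[, j]
    if (max(m) <= eps) {             # no attractor claims it: singleton
      member[j] <- n_sys <- n_sys + 1
    } else {
      best <- which(m == max(m))
      if (length(best) > 1) {
        # tie: cluster containing the lexicographically smallest node id
        leads <- vapply(best, function(s) min(ids[which(member == s)]),
                        character(1))
        best <- best[order(leads)][1]
      }
      member[j] <- best
    }
  }
  lapply(split(ids, member), sort)
}

#' @export
print.mcl_partition <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("<mcl_partition> %d clusters over %d nodes (sizes: %s)%s\n",
              length(sz), sum(sz),
              paste(utils::head(sz, 10), collapse = ", "),
              if (x$converged) sprintf("; converged in %d iterations", x$iterations)
              else "; NOT converged"))
  invisible(x)
}

#' Flatten an MCL partition to a membership vector
#'
#' @param partition An `mcl_partition`.
#' @return Named integer vector mapping node id to cluster index.
#' @export
mcl_membership <- function(partition) {
  idx <- rep(seq_along(partition$clusters), lengths(partition$clusters))
  stats::setNames(idx, unlist(partition$clusters, use.names = FALSE))
}
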