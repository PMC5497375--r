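#' Construct three gene sets with exactly specified Venn cardinalities
#'
#' Builds three sets A, B, C whose sizes, pairwise intersections
#' (INCLUSIVE of the triple region, matching the usual three-way Venn
#' arithmetic `|A u B u C| = sum singles - sum pairwise + triple`) and
#' triple intersection match the request exactly.  Infeasible requests
#' (any of the seven exclusive regions would be negative) raise an error
#' naming the violated region.
#'
#' @param set_sizes Integer vector of length 3: |A|, |B|, |C|.
#' @param pairwise_intersections Integer vector of length 3 in the order
#'   |A n B|, |A n C|, |B n C| (each inclusive of the triple).
#' @param triple_intersection |A n B n C|.
#' @param universe_prefix Prefix for the synthetic member identifiers.
#' @return A named list of three character vectors `A`, `B`, `C`.
#' @export
generate_venn_fixture <- function(set_sizes, pairwise_intersections,
                                  triple_intersection,
                                  universe_prefix = "G") {
  stopifnot(length(set_sizes) == 3, length(pairwise_intersections) == 3,
            length(triple_intersection) == 1)
  sa <- set_sizes[1]; sb <- set_sizes[2]; sc <- set_sizes[3]
  ab <- pairwise_intersections[1]; ac <- pairwise_intersections[2]
  bc <- pairwise_intersections[3]; t3 <- triple_intersection

  regions <- c(
    "A&B&C" = t3,
    "A&B"   = ab - t3,
    "A&C"   = ac - t3,
    "B&C"   = bc - t3,
    "A"     = sa - ab - ac + t3,
    "B"     = sb - ab - bc + t3,
    "C"     = sc - ac - bc + t3
  )
  bad <- names(regions)[regions < 0]
  if (length(bad)) {
    stop_pivotnet(
      "infeasible Venn specification: exclusive region(s) ",
      paste(bad, collapse = ", "), " would be negative"
    )
  }
  total <- sum(regions)
  ids <- sprintf("%s%05d", universe_prefix, seq_len(total))
  pool <- split(ids, rep(names(regions), times = regions))
  member <- function(set) {
    in_regions <- names(regions)[vapply(
      strsplit(names(regions), "&", fixed = TRUE),
      function(p) set %in% p, logical(1)
    )]
    sort(unlist(pool[in_regions], use.names = FALSE))
  }
  list(A = member("A"), B = member("B"), C = member("C"))
}

#' Simulate centrosome-abnormality count tables
#'
#' For each condition draws the number of cells counted uniformly in
#' `n_range` (default 250-270, the per-condition counting effort of the
#' immunofluorescence quantification this emulates) and the number of
#' cells with more than two centrosomes binomially at the condition's
#' true abnormality proportion.
#'
#' @param conditions Character vector of condition labels.
#' @param true_proportions Numeric vector in `[0, 1]`, one per condition.
#' @param n_range Integer vector `c(min, max)` for cells counted.
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `condition`, `n_cells_counted`,
#'   `n_cells_gt2_centrosomes`.
#' @export
generate_centrosome_counts <- function(conditions, true_proportions,
                                       n_range = c(250, 270), seed = 1) {
  if (length(conditions) != length(true_proportions)) {
    stop_pivotnet("`conditions` and `true_proportions` must have equal length")
  }
  if (any(true_proportions < 0) || any(true_proportions > 1)) {
    stop_pivotnet("`true_proportions` must lie in [0, 1]")
  }
  if (n_range[1] < 1 || n_range[2] < n_range[1]) {
    stop_pivotnet("`n_range` must be a positive, non-decreasing pair")
  }
  with_seed(seed, {
    n <- sample(seq(n_range[1], n_range[2]), length(conditions),
                replace = TRUE)
    k <- stats::rbinom(length(conditions), n, true_proportions)
    data.frame(
      condition = as.character(conditions),
      n_cells_counted = n,
      n_cells_gt2_centrosomes = k,
      stringsAsFactors = FALSE
    )
  })
}
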