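#' Set-algebra summary of DE gene lists across conditions
#'
#' Computes, by exact set algebra over the membership patterns, all
#' Venn regions of two or more gene sets: per-set sizes, all pairwise
#' intersections (inclusive of higher-order overlaps), the full
#' intersection, the exclusive region sizes, and the union.  For three
#' sets the union is additionally recomputed by inclusion-exclusion
#' (`|A u B u C| = sum singles - sum pairwise + triple`) and asserted
#' equal to the direct count.
#'
#' @param sets A named list of two or more character vectors, or an
#'   unnamed list plus `labels`.
#' @param labels Optional labels (must be unique).
#' @return An object of class `venn_summary`: list with `labels`,
#'   `sizes`, `pairwise` (data.frame set1/set2/size, inclusive),
#'   `full_intersection`, `exclusive` (named by membership pattern),
#'   `union`.
#' @export
venn_overlap <- function(sets, labels = names(sets)) {
  if (length(sets) < 2) stop_pivotnet("need at least two sets")
  if (is.null(labels)) labels <- LETTERS[seq_along(sets)]
  if (anyDuplicated(labels)) stop_pivotnet("duplicate set labels")
  sets <- lapply(sets, unique)
  names(sets) <- labels

  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)

  pattern <- apply(memb, 1, function(row) paste(labels[row], collapse = "&"))
  exclusive <- table(pattern)

  pairs <- utils::combn(labels, 2)
  pairwise <- data.frame(
    set1 = pairs[1, ], set2 = pairs[2, ],
    size = apply(pairs, 2, function(pr) {
      length(intersect(sets[[pr[1]]], sets[[pr[2]]]))
    }),
    stringsAsFactors = FALSE
  )
  sizes <- vapply(sets, length, integer(1))
  full <- length(Reduce(intersect, sets))
  union_size <- length(universe)

  if (length(sets) == 3) {
    ie <- sum(sizes) - sum(pairwise$size) + full
    stopifnot(ie == union_size)  # inclusion-exclusion identity
  }

  structure(
    list(labels = labels, sizes = sizes, pairwise = pairwise,
         full_intersection = full,
         exclusive = stats::setNames(as.integer(exclusive), names(exclusive)),
         union = union_size),
    class = "venn_summary"
  )
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> %d sets, union %d\n", length(x$labels), x$union))
  cat("  sizes:", paste(sprintf("%s=%d", x$labels, x$sizes), collapse = ", "), "\n")
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  |%s n %s| = %d\n", x$pairwise$set1[i], x$pairwise$set2[i],
                x$pairwise$size[i]))
  }
  cat(sprintf("  |%s| = %d\n", paste(x$labels, collapse = " n "),
              x$full_intersection))
  invisible(x)
}

#' Write a Venn summary as JSON
#'
#' @param vs A `venn_summary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_venn <- function(vs, path) {
  jsonlite::write_json(
    list(labels = vs$labels, sizes = as.list(vs$sizes),
         pairwise = vs$pairwise, full_intersection = vs$full_intersection,
         exclusive = as.list(vs$exclusive), union = vs$union),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
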