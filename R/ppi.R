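#' Load and clean a protein-protein interaction edge table
#'
#' Reads a BioGrid-TAB-like tab-separated table (or takes a data.frame)
#' of undirected interactions, drops self-interactions, and merges
#' redundant records: `(A,B)` and `(B,A)` are the same edge, and the
#' first record of a duplicated edge keeps its interaction type.  The
#' numbers of dropped records are reported via `message()` and stored as
#' attributes `n_self_dropped` / `n_duplicates_dropped`.
#'
#' @param x A file path or a data.frame.
#' @param col_a,col_b Names of the two interactor columns.
#' @param col_type Optional name of the interaction-type column; absent
#'   or unrecognised types become `"unknown"`.
#' @return A data.frame of class `ppi_network` with columns `gene_a`,
#'   `gene_b`, `interaction_type`.
#' @export
load_ppi <- function(x, col_a = "gene_a", col_b = "gene_b",
                     col_type = "interaction_type") {
  df <- if (is.character(x) && length(x) == 1) {
    utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (!all(c(col_a, col_b) %in% names(df))) {
    stop_pivotnet("interactor columns `", col_a, "`/`", col_b, "` not found")
  }
  a <- as.character(df[[col_a]])
  b <- as.character(df[[col_b]])
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad)) {
    stop_pivotnet("malformed interaction row(s) at line(s): ",
                  paste(utils::head(bad, 10), collapse = ", "))
  }
  type <- if (col_type %in% names(df)) {
    t <- as.character(df[[col_type]])
    ifelse(t %in% c("physical", "genetic"), t, "unknown")
  } else {
    rep("unknown", length(a))
  }

  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; type <- type[!self]
  dup <- duplicated(edge_key(a, b))
  n_dup <- sum(dup)

  out <- data.frame(gene_a = a[!dup], gene_b = b[!dup],
                    interaction_type = type[!dup],
                    stringsAsFactors = FALSE)
  message(sprintf("load_ppi: kept %d edges (dropped %d self-interactions, %d redundant records)",
                  nrow(out), n_self, n_dup))
  attr(out, "n_self_dropped") <- n_self
  attr(out, "n_duplicates_dropped") <- n_dup
  class(out) <- c("ppi_network", "data.frame")
  out
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d edges, %d genes\n", nrow(x),
              length(unique(c(x$gene_a, x$gene_b)))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
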