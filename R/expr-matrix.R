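#' Gene-by-sample expression matrix with stage annotations
#'
#' The central data container of the package: a numeric gene x sample
#' matrix of non-negative abundances (counts or TPM) together with a
#' per-sample annotation table giving the developmental stage (or
#' treatment condition) and replicate index of every column, and an
#' optional per-gene transcript length (base pairs) needed for TPM
#' normalisation.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).  Values must be finite
#'   and non-negative.
#' @param stage Character vector, one stage/condition label per column.
#' @param replicate Integer vector, one replicate index per column.
#'   Defaults to a per-stage running index.
#' @param units One of `"counts"`, `"TPM"` or `"normalized"`; a tag
#'   carried along so downstream stages can refuse the wrong scale.
#' @param lengths Optional named numeric vector of transcript lengths in
#'   base pairs (names = gene ids, strictly positive).
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `samples` (data.frame with columns sample, stage,
#'   replicate), `units` and `lengths`.
#' @export
expression_matrix <- function(values, stage, replicate = NULL,
                              units = c("counts", "TPM", "normalized"),
                              lengths = NULL) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_pivotnet("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_pivotnet("`values` must have gene rownames and sample colnames")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_pivotnet("`values` must be finite (no NA/NaN/Inf)")
  }
  if (any(values < 0)) stop_pivotnet("expression values must be non-negative")
  if (anyDuplicated(rownames(values))) {
    stop_pivotnet("duplicate gene ids in `values`")
  }
  if (length(stage) != ncol(values)) {
    stop_pivotnet("`stage` must annotate every sample column")
  }
  stage <- as.character(stage)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(stage), stage, FUN = seq_along)
  }
  if (length(replicate) != ncol(values)) {
    stop_pivotnet("`replicate` must annotate every sample column")
  }
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(values)]
    if (anyNA(lengths) || any(lengths <= 0)) {
      stop_pivotnet("`lengths` must be positive and cover every gene")
    }
    names(lengths) <- rownames(values)
  }
  structure(
    list(
      values = values,
      samples = data.frame(
        sample = colnames(values),
        stage = stage,
        replicate = as.integer(replicate),
        stringsAsFactors = FALSE
      ),
      units = units,
      lengths = lengths
    ),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples [%s]\n",
    nrow(x$values), ncol(x$values), x$units
  ))
  tab <- table(x$samples$stage)
  cat("  stages:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# Keep only the given genes (order preserved as given).
subset_genes <- function(em, genes) {
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing)) {
    stop_pivotnet(
      "genes not present in matrix: ",
      paste(utils::head(missing, 5), collapse = ", ")
    )
  }
  em$values <- em$values[genes, , drop = FALSE]
  if (!is.null(em$lengths)) em$lengths <- em$lengths[genes]
  em
}

#' Write / read an expression matrix as tab-separated text
#'
#' `write_expression()` writes two files: `<prefix>_matrix.tsv` (genes in
#' rows, header = sample ids, first column `gene`) and
#' `<prefix>_samples.tsv` (columns sample, stage, replicate).
#' `read_expression()` reads them back.
#'
#' @param em An [expression_matrix()].
#' @param prefix Path prefix for the two output files.
#' @return `write_expression()` returns the two paths invisibly;
#'   `read_expression()` returns an `expr_matrix`.
#' @export
write_expression <- function(em, prefix) {
  mat_path <- paste0(prefix, "_matrix.tsv")
  ann_path <- paste0(prefix, "_samples.tsv")
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$samples, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mat_path, samples = ann_path))
}

#' @rdname write_expression
#' @param units Units tag to stamp on the matrix being read.
#' @export
read_expression <- function(prefix, units = "TPM") {
  df <- utils::read.delim(paste0(prefix, "_matrix.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  ann <- utils::read.delim(paste0(prefix, "_samples.tsv"),
                           stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  values <- values[, ann$sample, drop = FALSE]
  expression_matrix(values, stage = ann$stage, replicate = ann$replicate,
                    units = units)
}
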