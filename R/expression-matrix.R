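#' Expression matrix container
#'
#' A light container for a probeset-by-sample grid of log2 intensities plus
#' optional per-sample annotations (phenotype, condition, learning index).
#' Values are stored as a plain numeric matrix with probeset IDs as row names
#' and sample IDs as column names, in the style of limma's workflows.
#'
#' @param values numeric matrix, probesets in rows, samples in columns; must
#'   carry unique, non-missing dimnames.
#' @param samples optional data.frame of per-sample annotations with a
#'   `sample_id` column matching `colnames(values)`; extra samples are an
#'   error, missing samples are an error once annotations are attached.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `samples` (the annotation data.frame or NULL).
#' @export
expression_matrix <- function(values, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probeset row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probeset IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  x <- structure(list(values = values, samples = NULL), class = "expr_matrix")
  if (!is.null(samples)) x <- attach_samples(x, samples)
  x
}

attach_samples <- function(x, samples) {
  if (!is.data.frame(samples) || is.null(samples$sample_id))
    stop("sample sheet must be a data.frame with a 'sample_id' column")
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample IDs in sample sheet")
  missing <- setdiff(colnames(x$values), samples$sample_id)
  if (length(missing))
    stop("sample sheet is missing samples: ", paste(missing, collapse = ", "))
  extra <- setdiff(samples$sample_id, colnames(x$values))
  if (length(extra))
    stop("sample sheet has samples absent from the matrix: ",
         paste(extra, collapse = ", "))
  # keyed join: annotation order follows the matrix, not the sheet
  x$samples <- samples[match(colnames(x$values), samples$sample_id), , drop = FALSE]
  rownames(x$samples) <- NULL
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probesets x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$samples)) {
    ann <- setdiff(names(x$samples), "sample_id")
    cat("annotations:", paste(ann, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects a header line, a first column named `probeset_id`, and one numeric
#' column of log2 intensities per sample.
#'
#' @param path file path.
#' @return an [expression_matrix()] without sample annotations.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probeset_id")
    stop("first column must be named 'probeset_id', found '", names(df)[1], "'")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric values in sample column(s): ", paste(bad, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m)
}

#' Write an expression matrix as tab-delimited text
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(probeset_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet and attach it to a matrix
#'
#' The sheet is tab-delimited with columns `sample_id`, `phenotype`,
#' `condition` and optionally a numeric `learning_index`. Rows are matched to
#' matrix columns by `sample_id`, so sheet order is irrelevant.
#'
#' @param path file path.
#' @param x the `expr_matrix` to annotate.
#' @return `x` with `$samples` populated.
#' @export
read_sample_sheet <- function(path, x) {
  if (!file.exists(path)) stop("no such file: ", path)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  attach_samples(x, sheet)
}

#' Write the sample sheet of an annotated matrix
#' @param x an annotated `expr_matrix`.
#' @param path output path.
#' @export
write_sample_sheet <- function(x, path) {
  if (is.null(x$samples)) stop("matrix carries no sample annotations")
  utils::write.table(x$samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset an expression matrix by probesets and/or samples
#' @param x an `expr_matrix`.
#' @param probesets,samples logical, integer or character index vectors.
#' @return the subsetted `expr_matrix`.
#' @export
subset_matrix <- function(x, probesets = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(probesets)) v <- v[probesets, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  out <- expression_matrix(v)
  if (!is.null(x$samples))
    out$samples <- x$samples[match(colnames(v), x$samples$sample_id), , drop = FALSE]
  out
}
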