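#' Construct an expression matrix
#'
#' A thin validated wrapper around a numeric matrix of non-negative abundance
#' values (FPKM semantics) with unique gene identifiers as row names and an
#' ordered set of condition labels as column names.
#'
#' @param values numeric matrix, genes x conditions, non-negative.
#' @param gene_ids character vector of unique gene identifiers
#'   (default: existing row names).
#' @param conditions character vector of ordered condition labels
#'   (default: existing column names).
#' @return a numeric matrix of class \code{expression_matrix}.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3), c("g1", "g2"), c("SP", "SD", "SD_12h"))
expression_matrix <- function(values, gene_ids = rownames(values),
                              conditions = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stop_if_not(!is.null(gene_ids) && !is.null(conditions),
              "gene ids and condition labels are required")
  stop_if_not(ncol(values) >= 2, "an expression matrix needs at least 2 conditions")
  stop_if_not(!anyDuplicated(gene_ids), "duplicate gene ids")
  stop_if_not(all(is.finite(values)) && all(values >= 0),
              "expression values must be finite and non-negative")
  dimnames(values) <- list(as.character(gene_ids), as.character(conditions))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d conditions (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more genes\n", nrow(x) - 5L))
  invisible(x)
}

#' Write / read an expression matrix as TSV
#'
#' The TSV layout is a header row of condition labels with the first column
#' holding gene ids. Values are serialized with 17 significant digits so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param x an \code{expression_matrix} (or coercible matrix).
#' @param path file path.
#' @return \code{write_expression_tsv} returns \code{path} invisibly;
#'   \code{read_expression_tsv} returns an \code{expression_matrix}.
#' @export
write_expression_tsv <- function(x, path) {
  stop_if_not(is.matrix(x), "x must be a matrix")
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character", sep = "\t")
  stop_if_not(ncol(df) >= 3, "expression TSV needs a gene_id column and >= 2 conditions")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene ids in %s (first duplicate at line %d)",
                 path, which(duplicated(ids))[1] + 1L), call. = FALSE)
  }
  vals <- vapply(df[-1], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      stop(sprintf("malformed numeric value in %s at line %d",
                   path, which(is.na(v))[1] + 1L), call. = FALSE)
    }
    v
  }, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1]))
  expression_matrix(vals)
}
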