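#' Filter genes by abundance
#'
#' A gene is retained when its maximum abundance across conditions is at
#' least \code{threshold} (inclusive). Using the per-gene maximum rather
#' than a per-sample rule keeps genes that are silent before elicitation but
#' induced afterwards -- exactly the genes a temporal screen targets.
#'
#' @param matrix an \code{\link{expression_matrix}}.
#' @param threshold abundance threshold (FPKM, default 30).
#' @return the filtered \code{expression_matrix}, row order preserved.
#' @export
filter_by_abundance <- function(matrix, threshold = 30) {
  stop_if_not(threshold >= 0, "threshold must be non-negative")
  keep <- apply(matrix, 1, max) >= threshold
  if (!any(keep)) warning("abundance filter removed every gene")
  out <- unclass(matrix)[keep, , drop = FALSE]
  hgo_log("abundance filter: ", sum(keep), " of ", nrow(matrix),
          " genes retained at threshold ", threshold)
  if (nrow(out)) expression_matrix(out) else out
}

#' Standardize expression rows
#'
#' Centers and scales each row to mean 0 and standard deviation 1, using the
#' population (n-denominator) standard deviation -- the convention of the
#' fuzzy c-means clustering workflow this feeds. Constant rows cannot be
#' standardized; they are dropped with a warning and recorded in the
#' \code{excluded} attribute.
#'
#' @param matrix numeric matrix (genes x conditions).
#' @return standardized matrix with attribute \code{excluded} holding the
#'   ids of dropped constant rows.
#' @export
standardize_rows <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  const <- sd_pop == 0 | !is.finite(sd_pop)
  if (any(const)) {
    warning(sprintf("excluded %d constant row(s) from standardization",
                    sum(const)))
  }
  out <- (m[!const, , drop = FALSE] - mu[!const]) / sd_pop[!const]
  attr(out, "excluded") <- rownames(m)[const] %||% which(const)
  out
}
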