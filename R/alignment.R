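## local protein alignment used by the homology stage of the screen
##
## Exact affine-gap Smith-Waterman (Gotoh) via Biostrings'
## pairwiseAlignment(type = "local"), replacing the heuristic BLAST step
## with a deterministic, dependency-free equivalent. Default scoring mirrors
## protein BLAST: BLOSUM62, gap open 11, gap extend 1 (a gap of length L
## costs 11 + L).

# BLOSUM62 with the unknown residue X scoring 0 against anything
.hgonet_env <- new.env(parent = emptyenv())

.blosum62_x0 <- function() {
  if (is.null(.hgonet_env$blosum62_x0)) {
    mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()), envir = environment())
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .hgonet_env$blosum62_x0 <- mat
  }
  .hgonet_env$blosum62_x0
}

.clean_protein <- function(s) {
  s <- toupper(as.character(s))
  known <- rownames(.blosum62_x0())
  chartr_from <- paste(setdiff(unique(strsplit(s, "")[[1]]), known),
                       collapse = "")
  if (nzchar(chartr_from)) {
    s <- chartr(chartr_from, strrep("X", nchar(chartr_from)), s)
  }
  s
}

#' Smith-Waterman local alignment score
#'
#' Exact affine-gap local alignment between two protein sequences. Unknown
#' letters are mapped to X, which scores 0 against anything. Empty
#' sequences score 0. The score is symmetric in its arguments and never
#' below 0 (the empty alignment).
#'
#' @param query,target protein sequences (character or Biostrings objects).
#' @param substitution scoring matrix (default: BLOSUM62 with X = 0).
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend gap extension penalty per residue (positive).
#' @param score_only if TRUE return just the numeric score.
#' @return list with \code{score}, \code{query_span} and \code{target_span}
#'   (start/end of the aligned region), or a number when
#'   \code{score_only = TRUE}.
#' @export
#' @examples
#' smith_waterman("ACDE", "ACDE", score_only = TRUE) # 24
smith_waterman <- function(query, target, substitution = .blosum62_x0(),
                           gap_open = 11, gap_extend = 1,
                           score_only = FALSE) {
  q <- .clean_protein(query)
  t <- .clean_protein(target)
  if (!nzchar(q) || !nzchar(t)) {
    if (score_only) return(0)
    return(list(score = 0, query_span = NULL, target_span = NULL))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t),
    type = "local", substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend,
    scoreOnly = score_only)
  if (score_only) return(max(0, aln))
  sc <- max(0, Biostrings::score(aln))
  list(score = sc,
       query_span = c(Biostrings::start(Biostrings::pattern(aln)),
                      Biostrings::end(Biostrings::pattern(aln))),
       target_span = c(Biostrings::start(Biostrings::subject(aln)),
                       Biostrings::end(Biostrings::subject(aln))))
}

## best local-alignment score of each sequence against a set of queries
.best_query_scores <- function(seqs, queries, gap_open = 11, gap_extend = 1) {
  qnames <- names(queries) %||% sprintf("query_%d", seq_along(queries))
  scores <- sapply(seq_along(queries), function(j) {
    vapply(seq_along(seqs), function(i) {
      smith_waterman(seqs[[i]], queries[[j]], gap_open = gap_open,
                     gap_extend = gap_extend, score_only = TRUE)
    }, numeric(1))
  })
  scores <- matrix(scores, nrow = length(seqs),
                   dimnames = list(names(seqs), qnames))
  data.frame(best_score = apply(scores, 1, max),
             best_query = qnames[apply(scores, 1, which.max)],
             row.names = names(seqs), stringsAsFactors = FALSE)
}
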