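#' Built-in ADH-like seed protein sequence
#'
#' A fixed 350-residue sequence used as the ancestor for planted candidate
#' sequences and as the default homology query. Its residue content is
#' arbitrary (a fixed pseudo-random draw from typical globular-protein
#' composition, committed once); only its length and fixed identity matter
#' to the generator contracts.
#'
#' @return an [Biostrings::AAStringSet] of length 1 named \code{ADH_seed}.
#' @export
adh_seed_sequence <- function() {
  path <- system.file("extdata", "adh_seed.fasta", package = "hgonet",
                      mustWork = TRUE)
  read_protein_fasta(path)
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate candidate and decoy protein sequences
#'
#' Candidates are derived from a seed sequence by substituting a fixed
#' number of positions (chosen without replacement) with different residues,
#' so each candidate has exactly the requested identity (up to rounding of
#' \code{identity_to_seed * length}). Decoys are random sequences of the
#' seed's length drawn from the seed's residue composition.
#'
#' @param n_decoys number of decoy sequences.
#' @param n_candidates number of planted ADH-like candidate sequences.
#' @param identity_to_seed target fractional identity of candidates to the
#'   seed, in (0, 1].
#' @param seed integer RNG seed.
#' @param seed_sequence seed protein as a length-1 [Biostrings::AAStringSet]
#'   or character string (default: the built-in ADH-like seed).
#' @return an [Biostrings::AAStringSet] named \code{candidate_1...},
#'   \code{decoy_1...}, with a \code{labels} attribute
#'   (\code{"candidate"}/\code{"decoy"}).
#' @export
#' @examples
#' seqs <- generate_sequences(3, 2, identity_to_seed = 0.9, seed = 1)
#' names(seqs)
generate_sequences <- function(n_decoys, n_candidates, identity_to_seed,
                               seed = 1L, seed_sequence = adh_seed_sequence()) {
  stop_if_not(identity_to_seed > 0 && identity_to_seed <= 1,
              "identity_to_seed must be in (0, 1]")
  stop_if_not(n_decoys >= 0 && n_candidates >= 0, "counts must be non-negative")
  seed_chr <- if (is.character(seed_sequence)) seed_sequence[1] else
    as.character(seed_sequence)[1]
  res <- strsplit(seed_chr, "")[[1]]
  L <- length(res)
  with_seed(seed, {
    cands <- lapply(seq_len(n_candidates), function(j) {
      n_sub <- round((1 - identity_to_seed) * L)
      s <- res
      if (n_sub > 0) {
        pos <- sample.int(L, n_sub)
        s[pos] <- vapply(s[pos], function(a)
          sample(setdiff(.aa_alphabet, a), 1L), character(1))
      }
      paste(s, collapse = "")
    })
    decoys <- lapply(seq_len(n_decoys), function(j)
      paste(sample(res, L, replace = TRUE), collapse = ""))
    out <- Biostrings::AAStringSet(c(unlist(cands) %||% character(0),
                                     unlist(decoys) %||% character(0)))
    names(out) <- c(sprintf("candidate_%d", seq_len(n_candidates)),
                    sprintf("decoy_%d", seq_len(n_decoys)))
    attr(out, "labels") <- rep(c("candidate", "decoy"),
                               c(n_candidates, n_decoys))
    out
  })
}

#' Fractional identity between two equal-length sequences
#'
#' @param a,b character strings of equal length.
#' @return fraction of identical positions.
#' @export
sequence_identity <- function(a, b) {
  x <- strsplit(as.character(a), "")[[1]]
  y <- strsplit(as.character(b), "")[[1]]
  stop_if_not(length(x) == length(y), "sequences must have equal length")
  mean(x == y)
}
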