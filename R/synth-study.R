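#' Assemble the default planted screening study
#'
#' Builds every input of the candidate screen with known ground truth: an
#' expression matrix with the two informative temporal templates plus
#' background and low-abundance genes, ADH-like candidate proteins planted
#' on template genes, decoy proteins scattered over other genes, and the
#' two marker sets (shared-pathway markers on the MeJA-inducible template,
#' competing-branch markers on the constitutive template).
#'
#' The default study plants 10 candidates (6 on the inducible template, 4 on
#' the constitutive one) at 85 percent identity to the seed query, 8 + 6
#' marker genes disjoint from the candidates, and 40 decoy sequences; all
#' counts scale down safely for smaller \code{n_genes}.
#'
#' @param n_genes total genes (default 5000).
#' @param noise_cv expression noise CV (default 0.2).
#' @param seed integer seed driving every random choice.
#' @param candidate_identity identity of planted candidates to the seed.
#' @param n_candidates integer vector of length 2: candidates planted on
#'   the inducible / constitutive templates.
#' @param n_markers integer vector of length 2: marker genes per template.
#' @param n_decoys decoy sequences attached to random non-candidate genes.
#' @return list with \code{matrix}, \code{truth} (gene table with planted
#'   labels and roles), \code{candidate_ids}, \code{sequences} (named by
#'   gene id), \code{marker_sets}, and \code{queries}.
#' @export
synth_screen_study <- function(n_genes = 5000, noise_cv = 0.2, seed = 1L,
                               candidate_identity = 0.85,
                               n_candidates = c(6L, 4L),
                               n_markers = c(8L, 6L), n_decoys = 40L) {
  cfg <- synth_expression_config(n_genes = n_genes, noise_cv = noise_cv,
                                 seed = seed)
  gen <- generate_expression_matrix(cfg)
  truth <- gen$truth
  tmpl_labels <- vapply(cfg$templates, `[[`, character(1), "label")
  tmpl_genes <- lapply(tmpl_labels, function(lb) truth$gene_id[truth$label == lb])
  stop_if_not(all(lengths(tmpl_genes) >= n_candidates + n_markers),
              "templates too small for the requested candidates and markers")

  # deterministic role assignment inside each template block
  candidate_ids <- unlist(lapply(seq_along(tmpl_genes), function(j)
    utils::head(tmpl_genes[[j]], n_candidates[j])))
  marker_sets <- lapply(seq_along(tmpl_genes), function(j)
    tmpl_genes[[j]][n_candidates[j] + seq_len(n_markers[j])])
  names(marker_sets) <- c("common", "downstream")[seq_along(marker_sets)]

  seqs <- generate_sequences(n_decoys = n_decoys,
                             n_candidates = length(candidate_ids),
                             identity_to_seed = candidate_identity,
                             seed = seed + 1L)
  labels <- attr(seqs, "labels")
  decoy_seqs <- seqs[labels == "decoy"]
  cand_seqs <- seqs[labels == "candidate"]

  # decoys go to random genes that are neither candidates nor markers
  pool <- setdiff(truth$gene_id, c(candidate_ids, unlist(marker_sets)))
  decoy_genes <- with_seed(seed + 2L, sample(pool, length(decoy_seqs)))
  sequences <- c(cand_seqs, decoy_seqs)
  names(sequences) <- c(candidate_ids, decoy_genes)

  truth$role <- "none"
  truth$role[truth$gene_id %in% candidate_ids] <- "candidate"
  truth$role[truth$gene_id %in% unlist(marker_sets)] <- "marker"
  truth$role[truth$gene_id %in% decoy_genes] <- "decoy_sequence"

  list(matrix = gen$matrix, truth = truth, candidate_ids = candidate_ids,
       sequences = sequences, marker_sets = marker_sets,
       queries = adh_seed_sequence())
}

#' Precision and recall of a screen result against planted truth
#'
#' @param table a \code{candidate_table} from \code{\link{run_screen}}.
#' @param candidate_ids character vector of planted candidate gene ids.
#' @return list with \code{precision}, \code{recall}, \code{n_called},
#'   \code{n_true}.
#' @export
screen_precision_recall <- function(table, candidate_ids) {
  called <- table$gene_id[table$candidate]
  tp <- length(intersect(called, candidate_ids))
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = tp / length(candidate_ids),
       n_called = length(called), n_true = length(candidate_ids))
}
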