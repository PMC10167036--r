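#' Screen configuration
#'
#' Bundles the tunable parameters of the three-step candidate screen.
#'
#' @param abundance_threshold FPKM threshold of the abundance filter
#'   (default 30).
#' @param n_clusters number of fuzzy c-means clusters (default 12).
#' @param fuzzifier fuzzifier m (> 1) or \code{"auto"} for the empirical
#'   estimate of \code{\link{estimate_fuzzifier}}. The default is a fixed
#'   1.5: for matrices with only a handful of conditions the empirical
#'   formula returns about 2.0, at which softness a membership core of 0.7
#'   admits only the very tightest members of a realistically noisy module;
#'   1.5 makes core assignment behave as intended on short profiles while
#'   the estimator remains available.
#' @param acore minimum core membership for cluster assignment (default 0.7).
#' @param tol,max_iter,restarts fuzzy c-means convergence controls.
#' @param seed integer RNG seed for clustering initialization.
#' @param sw_score_threshold minimum local-alignment score against any
#'   query for the homology criterion (default 50).
#' @param gap_open,gap_extend affine gap penalties of the homology stage.
#' @return list of class \code{screen_config}.
#' @export
screen_config <- function(abundance_threshold = 30, n_clusters = 12,
                          fuzzifier = 1.5, acore = 0.7, tol = 1e-6,
                          max_iter = 200, restarts = 5L, seed = 1L,
                          sw_score_threshold = 50, gap_open = 11,
                          gap_extend = 1) {
  stop_if_not(n_clusters >= 2, "n_clusters must be >= 2")
  stop_if_not(acore > 0 && acore <= 1, "acore must be in (0, 1]")
  stop_if_not(identical(fuzzifier, "auto") ||
                (is.numeric(fuzzifier) && fuzzifier > 1),
              "fuzzifier must be 'auto' or numeric > 1")
  structure(list(abundance_threshold = abundance_threshold,
                 n_clusters = n_clusters, fuzzifier = fuzzifier,
                 acore = acore, tol = tol, max_iter = max_iter,
                 restarts = restarts, seed = as.integer(seed),
                 sw_score_threshold = sw_score_threshold,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "screen_config")
}

#' Select pathway clusters from marker genes
#'
#' For each marker set, returns the cluster containing the plurality of its
#' assigned members. Plurality ties return all tied clusters and raise a
#' flag; a marker set with no assigned member selects nothing and is
#' flagged. Markers missing from the assignment map are logged.
#'
#' @param assignments named cluster vector from
#'   \code{\link{core_assignments}}.
#' @param marker_sets named list of character vectors of marker gene ids
#'   (conventionally \code{common} for the shared upstream pathway and
#'   \code{downstream} for the competing branch).
#' @return list per marker set: \code{clusters} (integer vector, possibly
#'   empty), \code{tied}, \code{empty}, and the marker tally.
#' @export
select_pathway_clusters <- function(assignments, marker_sets) {
  stop_if_not(is.list(marker_sets) && length(marker_sets) >= 1,
              "marker_sets must be a non-empty named list")
  lapply(marker_sets, function(markers) {
    missing <- setdiff(markers, names(assignments))
    if (length(missing)) {
      hgo_log("markers absent from assignments: ",
              paste(missing, collapse = ", "))
    }
    present <- assignments[intersect(markers, names(assignments))]
    present <- present[!is.na(present)]
    if (!length(present)) {
      return(list(clusters = integer(0), tied = FALSE, empty = TRUE,
                  tally = table(integer(0))))
    }
    tally <- table(present)
    top <- as.integer(names(tally)[tally == max(tally)])
    list(clusters = top, tied = length(top) > 1L, empty = FALSE,
         tally = tally)
  })
}

#' Run the three-step candidate-gene screen
#'
#' Composes the screen: (1) abundance filter, (2) row standardization and
#' fuzzy c-means temporal clustering with membership-core assignment, with
#' the pathway clusters picked by marker plurality, (3) exact local
#' alignment of the surviving genes' proteins against the query set. A
#' candidate passes all three criteria.
#'
#' @param matrix an \code{\link{expression_matrix}}.
#' @param sequences named [Biostrings::AAStringSet] (or named character
#'   vector) of protein sequences for (a subset of) the genes.
#' @param marker_sets named list of marker id vectors, see
#'   \code{\link{select_pathway_clusters}}.
#' @param config a \code{\link{screen_config}}.
#' @param queries query proteins ([Biostrings::AAStringSet] or named
#'   character vector); defaults to the built-in ADH-like seed.
#' @return a \code{candidate_table}: data frame with one row per input gene
#'   (id, cluster, membership, best alignment score/query, per-criterion
#'   pass flags and the final \code{candidate} flag), with stage counts and
#'   the selected clusters in attributes.
#' @export
run_screen <- function(matrix, sequences, marker_sets, config = screen_config(),
                       queries = adh_seed_sequence()) {
  stop_if_not(inherits(config, "screen_config"),
              "config must come from screen_config()")
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  if (is.character(queries)) queries <- Biostrings::AAStringSet(queries)

  out <- data.frame(gene_id = rownames(matrix), cluster = NA_integer_,
                    membership = NA_real_, best_score = NA_real_,
                    best_query = NA_character_, passes_abundance = FALSE,
                    passes_cluster = FALSE, passes_homology = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$gene_id

  ## criterion 1: abundance
  kept <- filter_by_abundance(matrix, config$abundance_threshold)
  out[rownames(kept), "passes_abundance"] <- TRUE
  counts <- c(input = nrow(matrix), abundance = nrow(kept))

  selected <- list()
  if (nrow(kept) > 0 && length(marker_sets) &&
      any(lengths(marker_sets) > 0)) {
    ## criterion 2: temporal coexpression with the pathway markers
    std <- standardize_rows(kept)
    fit <- fuzzy_cmeans(std, c = config$n_clusters, m = config$fuzzifier,
                        tol = config$tol, max_iter = config$max_iter,
                        seed = config$seed, restarts = config$restarts)
    assign <- core_assignments(fit, config$acore)
    out[names(assign), "cluster"] <- assign
    out[rownames(fit$membership), "membership"] <-
      apply(fit$membership, 1, max)
    selected <- select_pathway_clusters(assign, marker_sets)
    sel_clusters <- unique(unlist(lapply(selected, `[[`, "clusters")))
    for (s in names(selected)) {
      if (selected[[s]]$empty) {
        warning(sprintf("marker set '%s' has no assigned member; no cluster selected", s))
      }
      if (selected[[s]]$tied) {
        hgo_log("marker set '", s, "' plurality tie; returning all tied clusters")
      }
    }
    out$passes_cluster <- out$passes_abundance &
      !is.na(out$cluster) & out$cluster %in% sel_clusters
    attr(out, "fcm_fit") <- fit
  } else {
    if (!length(marker_sets) || all(lengths(marker_sets) == 0)) {
      warning("no marker genes supplied; no cluster can be selected")
    }
    sel_clusters <- integer(0)
  }
  counts <- c(counts, cluster = sum(out$passes_cluster))

  ## criterion 3: homology to the query proteins
  cand_ids <- out$gene_id[out$passes_cluster]
  with_seqs <- intersect(cand_ids, names(sequences))
  if (length(with_seqs)) {
    sc <- .best_query_scores(sequences[with_seqs], queries,
                             gap_open = config$gap_open,
                             gap_extend = config$gap_extend)
    out[with_seqs, "best_score"] <- sc$best_score
    out[with_seqs, "best_query"] <- sc$best_query
    out[with_seqs, "passes_homology"] <-
      sc$best_score >= config$sw_score_threshold
  }
  out$candidate <- out$passes_abundance & out$passes_cluster &
    out$passes_homology
  counts <- c(counts, homology = sum(out$candidate))
  hgo_log("screen counts: ", paste(names(counts), counts, sep = "=",
                                   collapse = ", "))

  attr(out, "stage_counts") <- counts
  attr(out, "selected_clusters") <- selected
  attr(out, "config") <- config
  class(out) <- c("candidate_table", class(out))
  out
}

#' @export
print.candidate_table <- function(x, ...) {
  counts <- attr(x, "stage_counts")
  cat("candidate screen result\n")
  cat(sprintf("  genes: %d -> abundance %d -> cluster %d -> candidates %d\n",
              counts["input"], counts["abundance"], counts["cluster"],
              counts["homology"]))
  cand <- x[x$candidate, , drop = FALSE]
  if (nrow(cand)) {
    cat("  candidates:\n")
    print.data.frame(cand[, c("gene_id", "cluster", "membership",
                              "best_score", "best_query")], row.names = FALSE)
  }
  invisible(x)
}
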