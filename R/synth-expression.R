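#' Configuration for the synthetic expression-matrix generator
#'
#' The generator emulates the temporal design of a methyl-jasmonate (MeJA)
#' elicitation experiment over two cell lines: a shikonin-proficient line
#' (SP), a shikonin-deficient line before elicitation (SD) and the deficient
#' line 12/24/36 h after MeJA treatment. Planted templates mimic the two
#' informative temporal patterns: an elicitation-inducible profile that is
#' low in SD, rises after MeJA and peaks at 12-24 h ("cluster-6-like"), and
#' a constitutively SP-high profile insensitive to MeJA ("cluster-3-like").
#'
#' @param n_genes total number of genes.
#' @param condition_labels ordered condition labels (default the five-
#'   condition MeJA design).
#' @param templates list of templates, each a list with \code{profile}
#'   (numeric, one value per condition), \code{n} (gene count) and
#'   \code{label}.
#' @param abundance_scale baseline FPKM multiplier for template profiles.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   expression noise (FPKM is positive and right-skewed).
#' @param low_abundance_fraction fraction of genes forced below the
#'   abundance-filter threshold.
#' @param filter_threshold the abundance threshold the low-abundance genes
#'   are forced under (FPKM).
#' @param seed integer seed; fixes every generated value.
#' @return a list of class \code{synth_expression_config}.
#' @export
synth_expression_config <- function(n_genes = 5000,
                                    condition_labels = c("SP", "SD", "SD_12h",
                                                         "SD_24h", "SD_36h"),
                                    templates = default_templates(condition_labels),
                                    abundance_scale = 50,
                                    noise_cv = 0.2,
                                    low_abundance_fraction = 0.3,
                                    filter_threshold = 30,
                                    seed = 1L) {
  stop_if_not(n_genes >= 1, "n_genes must be positive")
  stop_if_not(length(condition_labels) >= 2, "need at least 2 conditions")
  stop_if_not(noise_cv >= 0, "noise_cv must be non-negative")
  stop_if_not(low_abundance_fraction >= 0 && low_abundance_fraction <= 1,
              "low_abundance_fraction must be in [0, 1]")
  stop_if_not(abundance_scale > 0, "abundance_scale must be positive")
  for (tp in templates) {
    stop_if_not(length(tp$profile) == length(condition_labels),
                "template profile length must match the number of conditions")
    stop_if_not(all(tp$profile >= 0), "template profiles must be non-negative")
  }
  n_template <- sum(vapply(templates, `[[`, numeric(1), "n"))
  n_low <- round(low_abundance_fraction * n_genes)
  if (n_template + n_low > n_genes) {
    stop(sprintf("templates (%d genes) plus low-abundance genes (%d) exceed n_genes (%d)",
                 n_template, n_low, n_genes), call. = FALSE)
  }
  structure(list(n_genes = n_genes, condition_labels = condition_labels,
                 templates = templates, abundance_scale = abundance_scale,
                 noise_cv = noise_cv,
                 low_abundance_fraction = low_abundance_fraction,
                 filter_threshold = filter_threshold, seed = as.integer(seed)),
            class = "synth_expression_config")
}

#' Default planted templates
#'
#' @param conditions ordered condition labels (length 5 for the defaults).
#' @return list of template descriptions: a cluster-6-like MeJA-inducible
#'   profile (290 genes) and a cluster-3-like constitutively SP-high profile
#'   (500 genes); the sizes mirror the relative sizes of the two informative
#'   clusters in a real post-filter transcriptome (639 and 1106 of 7637).
#' @export
default_templates <- function(conditions = c("SP", "SD", "SD_12h", "SD_24h",
                                             "SD_36h")) {
  stop_if_not(length(conditions) == 5, "default templates assume 5 conditions")
  list(
    list(profile = c(2, 1, 4, 6, 3), n = 290L, label = "cluster6_like"),
    list(profile = c(8, 2, 2, 2, 2), n = 500L, label = "cluster3_like")
  )
}

#' Background expression archetypes
#'
#' Temporal transcriptomes are low-rank: most genes follow a few smooth
#' trends rather than independent white profiles. Background genes are
#' drawn from these archetypes (drifts, line contrasts, off-peak bumps)
#' with per-gene shape jitter, which is what gives a fuzzy clustering of
#' real data its distinct non-elicitation clusters. For condition counts
#' other than 5 the archetypes are smooth random walks drawn from the
#' active RNG.
#'
#' @param k number of conditions.
#' @return matrix of archetype profiles (rows) on an arbitrary scale.
#' @export
background_archetypes <- function(k = 5) {
  if (k == 5) {
    return(rbind(
      c(5, 4, 3, 2, 1), c(4, 5, 4, 3, 2), c(1, 1, 2, 3, 4),
      c(3, 1, 1, 1, 3), c(1, 5, 3, 2, 1), c(4, 1, 2, 3, 4),
      c(1, 2, 5, 2, 1), c(2, 3, 1, 4, 2), c(5, 2, 4, 1, 3),
      c(1, 4, 4, 1, 4)))
  }
  t(vapply(seq_len(2 * k), function(i) {
    p <- abs(cumsum(rnorm(k))) + 0.5
    p / mean(p) * 3
  }, numeric(k)))
}

## mean-one multiplicative lognormal noise with a given CV
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic expression matrix with planted ground truth
#'
#' Rows carrying a template have expectation profile * abundance_scale under
#' mean-one multiplicative lognormal noise; background rows get independent
#' random smooth profiles; a configured fraction of genes is rescaled to lie
#' entirely below the abundance-filter threshold (and every other gene is
#' guaranteed at least one value at or above it, so the below-threshold gene
#' count is exact).
#'
#' @param config a \code{\link{synth_expression_config}}.
#' @return list with \code{matrix} (an \code{\link{expression_matrix}}) and
#'   \code{truth} (data frame \code{gene_id}, \code{label}).
#' @export
#' @examples
#' cfg <- synth_expression_config(n_genes = 50, noise_cv = 0, seed = 7)
#' out <- generate_expression_matrix(cfg)
#' table(out$truth$label)
generate_expression_matrix <- function(config) {
  stop_if_not(inherits(config, "synth_expression_config"),
              "config must come from synth_expression_config()")
  with_seed(config$seed, {
    n <- config$n_genes
    k <- length(config$condition_labels)
    thr <- config$filter_threshold
    ids <- sprintf("gene%05d", seq_len(n))
    mat <- matrix(0, n, k, dimnames = list(ids, config$condition_labels))
    label <- rep("background", n)

    i <- 0L
    for (tp in config$templates) {
      idx <- i + seq_len(tp$n)
      mu <- tp$profile * config$abundance_scale
      noise <- matrix(.lognormal_noise(tp$n * k, config$noise_cv), tp$n, k)
      mat[idx, ] <- rep(mu, each = tp$n) * noise
      label[idx] <- tp$label
      i <- i + tp$n
    }

    n_low <- round(config$low_abundance_fraction * n)
    bg_idx <- seq.int(i + 1L, length.out = n - i)
    low_idx <- utils::head(bg_idx, n_low)
    arch <- background_archetypes(k)
    for (idx in bg_idx) {
      # background profile: a smooth archetype with per-gene shape jitter
      # and a right-skewed per-gene amplitude
      profile <- arch[sample.int(nrow(arch), 1L), ] * rlnorm(k, 0, 0.35)
      mat[idx, ] <- profile * config$abundance_scale * rlnorm(1, 0, 0.6) *
        .lognormal_noise(k, config$noise_cv)
    }
    if (length(low_idx)) {
      targets <- thr * runif(length(low_idx), 0.1, 0.97)
      mat[low_idx, ] <- mat[low_idx, , drop = FALSE] *
        (targets / apply(mat[low_idx, , drop = FALSE], 1, max))
      label[low_idx] <- "low_abundance"
    }
    # guarantee every non-low gene clears the filter, keeping row shapes
    keep_idx <- setdiff(seq_len(n), low_idx)
    row_max <- apply(mat[keep_idx, , drop = FALSE], 1, max)
    short <- row_max < thr
    if (any(short)) {
      mat[keep_idx[short], ] <- mat[keep_idx[short], , drop = FALSE] *
        (thr * 1.5 / row_max[short])
      hgo_log("rescaled ", sum(short), " gene(s) up to clear the filter threshold")
    }

    list(matrix = expression_matrix(mat),
         truth = data.frame(gene_id = ids, label = label,
                            stringsAsFactors = FALSE))
  })
}
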