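## exact-mass arithmetic for the compound identity evidence

# monoisotopic atomic masses (Da); the registry is restricted to CHNOP
.monoisotopic <- c(C = 12.000000, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151)
.proton_mass <- 1.0072765

#' Parse a molecular formula
#'
#' @param formula a formula string such as \code{"C16H20O3"}, or a named
#'   integer vector of element counts.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stop_if_not(is.character(formula) && length(formula) == 1L,
                "formula must be a single string or a named count vector")
    if (!nzchar(formula)) return(setNames(integer(0), character(0)))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    stop_if_not(sum(attr(m, "match.length")) == nchar(formula),
                sprintf("cannot parse formula '%s'", formula))
    el <- sub("[0-9]*$", "", parts)
    n <- sub("^[A-Za-z]+", "", parts)
    counts <- setNames(ifelse(nzchar(n), as.integer(n), 1L), el)
    counts <- tapply(counts, names(counts), sum)[unique(el)]
  }
  stop_if_not(all(counts > 0) && all(counts == round(counts)),
              "element counts must be positive integers")
  unknown <- setdiff(names(counts), names(.monoisotopic))
  if (length(unknown)) {
    stop(sprintf("unknown element(s): %s (registry covers C,H,N,O,P)",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' @inheritParams parse_formula
#' @return mass in Da; 0 for an empty formula.
#' @export
#' @examples
#' monoisotopic_mass("H2O")      # 18.0106
#' monoisotopic_mass("C16H20O3") # 260.1412, the branch-point aldehyde
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) return(0)
  sum(.monoisotopic[names(counts)] * counts)
}

#' m/z of the deprotonated ion [M-H]-
#'
#' Singly charged negative-mode ion: monoisotopic mass minus one proton.
#'
#' @inheritParams parse_formula
#' @return m/z value.
#' @export
#' @examples
#' deprotonated_mz("C16H20O3") # 259.1 at one decimal
deprotonated_mz <- function(formula) {
  counts <- parse_formula(formula)
  stop_if_not("H" %in% names(counts),
              "cannot deprotonate a formula without hydrogen")
  monoisotopic_mass(counts) - .proton_mass
}

#' Compound registry
#'
#' The small registry of compounds in the oxidoreductase reaction network,
#' shipped as a plain-text fixture. Formulas follow from the structures:
#' the geranylhydroquinone (GHQ) core is C16H22O2, 3''-hydroxylation gives
#' C16H22O3 for the two alcohol isomers, and alcohol-to-aldehyde oxidation
#' (loss of 2 H) gives C16H20O3 for the shared aldehyde.
#'
#' @return data frame with columns \code{name}, \code{role}, \code{formula},
#'   plus derived \code{monoisotopic_mass} and \code{mz_deprotonated}.
#' @export
compound_registry <- function() {
  path <- system.file("extdata", "compounds.tsv", package = "hgonet",
                      mustWork = TRUE)
  df <- read.delim(path, sep = "\t", colClasses = "character")
  df$monoisotopic_mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  df$mz_deprotonated <- vapply(df$formula, deprotonated_mz, numeric(1))
  df
}
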