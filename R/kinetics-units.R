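## unit arithmetic connecting Vmax, kcat and catalytic efficiency
##
## Units are fixed package-wide: concentrations in uM, time in s for kcat,
## specific activities in pkat per ug protein. The single conversion used
## everywhere is 1 pkat/ug = 1e-6 mol s^-1 g^-1, so
## kcat [1/s] = Vmax [pkat/ug] * M [g/mol] * 1e-6.

#' Turnover number from specific activity
#'
#' @param Vmax limiting specific activity, pkat per ug protein.
#' @param molar_mass enzyme subunit molar mass, g/mol.
#' @return kcat in 1/s.
#' @export
#' @examples
#' kcat_from_vmax(63.47, 40680) # about 2.58
kcat_from_vmax <- function(Vmax, molar_mass) {
  stop_if_not(all(Vmax >= 0) && all(molar_mass > 0),
              "Vmax must be non-negative and molar_mass positive")
  Vmax * molar_mass * 1e-6
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat turnover number, 1/s.
#' @param Km Michaelis constant, uM.
#' @param digits if non-NULL, round half-away-from-zero to this many
#'   decimals (the presentation convention for reported efficiencies).
#' @return efficiency in 1/uM/s.
#' @export
#' @examples
#' catalytic_efficiency(2.58, 24.68, digits = 2) # 0.10
catalytic_efficiency <- function(kcat, Km, digits = NULL) {
  stop_if_not(all(Km > 0), "Km must be positive")
  eff <- kcat / Km
  if (!is.null(digits)) eff <- round_half_away(eff, digits)
  eff
}

#' Infer the enzyme molar mass from (Vmax, kcat) pairs
#'
#' Given rows of jointly reported specific activity and turnover number,
#' returns the least-squares molar mass M minimizing
#' sum((Vmax_i * M * 1e-6 - kcat_i)^2), i.e.
#' M = sum(kcat_i * Vmax_i) / sum(Vmax_i^2) * 1e6. A reported kinetic table
#' is internally consistent when one M reproduces every kcat from its Vmax.
#'
#' @param Vmax numeric vector, pkat per ug protein.
#' @param kcat numeric vector, 1/s (same length).
#' @return molar mass in g/mol.
#' @export
#' @examples
#' k <- aehgo_kinetic_constants()
#' infer_molar_mass(k$Vmax, k$kcat) # about 4.07e4 g/mol
infer_molar_mass <- function(Vmax, kcat) {
  stop_if_not(length(Vmax) >= 1 && length(Vmax) == length(kcat),
              "need matching non-empty Vmax and kcat vectors")
  stop_if_not(all(Vmax > 0) && all(kcat > 0), "values must be positive")
  sum(kcat * Vmax) / sum(Vmax^2) * 1e6
}

#' Published kinetic constants of AeHGO
#'
#' The apparent kinetic constants reported for the recombinant enzyme:
#' oxidation of the (Z)- and (E)-alcohols (at saturating NADP+), the NADP+
#' cofactor itself (with the (Z)-alcohol as substrate), and the reduction of
#' the aldehyde (with NADPH). Used as reference inputs by the simulation
#' presets and the worked examples.
#'
#' @return data frame with columns \code{species}, \code{role}, \code{Km}
#'   (uM), \code{Km_se}, \code{Vmax} (pkat/ug), \code{Vmax_se}, \code{kcat}
#'   (1/s), \code{kcat_se} and \code{efficiency} (1/uM/s, as reported).
#' @export
aehgo_kinetic_constants <- function() {
  data.frame(
    species = c("(Z)-3''-OH-GHQ", "(E)-3''-OH-GHQ", "NADP+", "(E)-3''-oxo-GHQ"),
    role = c("oxidation substrate", "oxidation substrate", "cofactor",
             "reduction substrate"),
    Km = c(24.68, 18.70, 17.81, 9.96),
    Km_se = c(5.18, 5.39, 5.62, 2.87),
    Vmax = c(63.47, 33.95, 56.01, 69.79),
    Vmax_se = c(3.79, 2.28, 3.99, 9.33),
    kcat = c(2.58, 1.38, 2.28, 2.84),
    kcat_se = c(0.15, 0.09, 0.16, 0.38),
    efficiency = c(0.10, 0.07, 0.13, 0.28),
    stringsAsFactors = FALSE
  )
}

#' Optimum of a condition-activity table
#'
#' Rescales a relative-activity table to a maximum of 100 percent and
#' returns the condition value at the maximum. Exact ties are resolved to
#' the midpoint of the tied condition values and flagged.
#'
#' @param table data frame with columns \code{value} (condition, e.g. pH or
#'   temperature) and \code{activity} (>= 3 rows).
#' @return list with \code{optimum}, \code{tied} (logical flag) and
#'   \code{table} (activity normalized to max 100).
#' @export
condition_optimum <- function(table) {
  stop_if_not(is.data.frame(table) &&
                all(c("value", "activity") %in% names(table)) &&
                nrow(table) >= 3,
              "table needs columns value, activity and >= 3 rows")
  act <- table$activity / max(table$activity) * 100
  at_max <- which(abs(act - 100) < 1e-9)
  tied <- length(at_max) > 1L
  if (tied) hgo_log("condition optimum tied across ", length(at_max),
                    " values; reporting midpoint")
  out <- table
  out$activity <- act
  list(optimum = mean(range(table$value[at_max])), tied = tied, table = out)
}
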