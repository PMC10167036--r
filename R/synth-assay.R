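#' Generate noisy initial-rate data
#'
#' Rates are the rate-law value (Michaelis-Menten, or substrate inhibition
#' when \code{params$Ki} is present and finite) perturbed by multiplicative
#' Gaussian noise with coefficient of variation \code{noise_cv}, truncated
#' at zero.
#'
#' @param params list with \code{Km}, \code{Vmax} and optionally \code{Ki}
#'   (all uM / pkat per ug).
#' @param concentrations positive substrate concentrations, uM.
#' @param noise_cv coefficient of variation of the assay noise.
#' @param seed integer RNG seed.
#' @param replicates technical replicates per concentration (default 1).
#' @return data frame with columns \code{concentration_uM},
#'   \code{rate_pkat_per_ug}, \code{rate} (alias) and \code{replicate}.
#' @export
#' @examples
#' generate_initial_rates(list(Km = 24.68, Vmax = 63.47),
#'                        c(3, 5, 10, 25, 50, 100, 200), noise_cv = 0, seed = 1)
generate_initial_rates <- function(params, concentrations, noise_cv = 0,
                                   seed = 1L, replicates = 1L) {
  stop_if_not(all(concentrations > 0), "concentrations must be positive")
  stop_if_not(noise_cv >= 0, "noise_cv must be non-negative")
  stop_if_not(all(c("Km", "Vmax") %in% names(params)),
              "params needs Km and Vmax")
  S <- rep(concentrations, each = replicates)
  v <- if (!is.null(params$Ki) && is.finite(params$Ki)) {
    si_rate(S, params$Km, params$Vmax, params$Ki)
  } else {
    mm_rate(S, params$Km, params$Vmax)
  }
  with_seed(seed, {
    obs <- pmax(0, v * (1 + rnorm(length(v), 0, noise_cv)))
    data.frame(concentration_uM = S, rate_pkat_per_ug = obs, rate = obs,
               replicate = rep(seq_len(replicates), length(concentrations)))
  })
}

#' Generate synthetic pH / temperature / ion condition profiles
#'
#' Emulates the biochemical-property assays: a Gaussian bell in pH around
#' the optimum, a skewed bell in temperature (slow rise, fast fall above the
#' optimum, as enzymes denature), and an ion table applying relative
#' activity multipliers (Cu2+ fully abolishes activity by default). All
#' tables are normalized to a maximum of 100 percent after noise.
#'
#' @param optimum_pH pH of maximal activity (default 7.5).
#' @param optimum_T temperature of maximal activity, Celsius (default 37).
#' @param widths list with \code{pH} (Gaussian sd in pH units), \code{T_left}
#'   and \code{T_right} (sd below/above the optimum, Celsius).
#' @param ion_effects named multipliers of relative activity per added ion.
#' @param noise_cv multiplicative Gaussian noise on activities before
#'   normalization.
#' @param seed integer RNG seed.
#' @return list of data frames \code{pH}, \code{temperature} (columns
#'   \code{value}, \code{activity}) and \code{ions} (columns \code{ion},
#'   \code{activity}).
#' @export
generate_condition_profiles <- function(optimum_pH = 7.5, optimum_T = 37,
                                        widths = list(pH = 1.0, T_left = 12,
                                                      T_right = 4),
                                        ion_effects = default_ion_effects(),
                                        noise_cv = 0, seed = 1L) {
  stop_if_not(all(unlist(widths) > 0), "widths must be positive")
  stop_if_not(noise_cv >= 0, "noise_cv must be non-negative")
  with_seed(seed, {
    noisy <- function(x) pmax(0, x * (1 + rnorm(length(x), 0, noise_cv)))
    norm100 <- function(x) x / max(x) * 100

    pH_grid <- seq(5.5, 9.5, by = 0.5)
    pH_act <- exp(-(pH_grid - optimum_pH)^2 / (2 * widths$pH^2))
    pH <- data.frame(value = pH_grid, activity = norm100(noisy(pH_act)))

    T_grid <- seq(15, 59, by = 2)
    sdT <- ifelse(T_grid <= optimum_T, widths$T_left, widths$T_right)
    T_act <- exp(-(T_grid - optimum_T)^2 / (2 * sdT^2))
    temperature <- data.frame(value = T_grid,
                              activity = norm100(noisy(T_act)))

    ions <- data.frame(ion = names(ion_effects),
                       activity = 100 * unname(unlist(ion_effects)),
                       stringsAsFactors = FALSE)
    list(pH = pH, temperature = temperature, ions = ions)
  })
}

#' Default relative ion effects on activity
#'
#' Qualitative pattern of the divalent-cation sensitivity assays: no effect
#' of Mg2+/Ca2+/EDTA, slight reduction by Fe2+/Ni2+, severe reduction by
#' Mn2+/Co2+/Zn2+, complete termination by Cu2+.
#'
#' @return named list of multipliers relative to the no-ion control.
#' @export
default_ion_effects <- function() {
  list(none = 1, `Mg2+` = 1, `Ca2+` = 1, EDTA = 1,
       `Fe2+` = 0.85, `Ni2+` = 0.85,
       `Mn2+` = 0.3, `Co2+` = 0.3, `Zn2+` = 0.25, `Cu2+` = 0)
}
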