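#' Michaelis-Menten rate law
#'
#' v = Vmax * S / (Km + S).
#'
#' @param S substrate concentration, uM (scalar or vector, >= 0).
#' @param Km Michaelis constant, uM (> 0).
#' @param Vmax limiting rate, pkat per ug protein (> 0).
#' @return rate(s) in the units of \code{Vmax}.
#' @export
#' @examples
#' mm_rate(24.68, Km = 24.68, Vmax = 63.47) # half-saturation: Vmax/2
mm_rate <- function(S, Km, Vmax) {
  stop_if_not(all(S >= 0), "substrate concentrations must be non-negative")
  stop_if_not(Km > 0 && Vmax > 0, "Km and Vmax must be positive")
  Vmax * S / (Km + S)
}

#' Substrate-inhibition rate law
#'
#' v = Vmax * S / (Km + S + S^2/Ki). Reduces to the Michaelis-Menten law as
#' Ki -> Inf; the rate is maximal at S = sqrt(Km * Ki).
#'
#' @inheritParams mm_rate
#' @param Ki substrate-inhibition constant, uM (> 0; \code{Inf} allowed).
#' @return rate(s) in the units of \code{Vmax}.
#' @export
si_rate <- function(S, Km, Vmax, Ki) {
  stop_if_not(all(S >= 0), "substrate concentrations must be non-negative")
  stop_if_not(Km > 0 && Vmax > 0 && Ki > 0, "Km, Vmax and Ki must be positive")
  Vmax * S / (Km + S + S^2 / Ki)
}

#' Initial rate from a progress curve
#'
#' Estimates the initial velocity as the ordinary least-squares slope of
#' product concentration against time, restricted to the early window where
#' the reaction is below a completion cap (by default 10 percent of the
#' total substrate), with a free intercept.
#'
#' @param progress data frame with columns \code{time} and \code{product}
#'   (product concentration, same units as \code{substrate_total}).
#' @param substrate_total total substrate concentration defining completion.
#' @param completion_cap fraction of completion delimiting the linear window.
#' @return list with \code{rate} (slope), \code{intercept}, \code{n_points},
#'   and the fitted window.
#' @export
initial_rate <- function(progress, substrate_total, completion_cap = 0.10) {
  stop_if_not(is.data.frame(progress) &&
                all(c("time", "product") %in% names(progress)),
              "progress must have columns 'time' and 'product'")
  stop_if_not(substrate_total > 0, "substrate_total must be positive")
  stop_if_not(completion_cap >= 0, "completion_cap must be non-negative")
  win <- progress[progress$product <= completion_cap * substrate_total, ,
                  drop = FALSE]
  if (nrow(win) < 3L) {
    stop(sprintf(paste0("only %d points below %.0f%% completion; ",
                        "sample the progress curve earlier/shorter"),
                 nrow(win), 100 * completion_cap), call. = FALSE)
  }
  if (is.unsorted(win$product[order(win$time)], strictly = FALSE)) {
    warning("product is not monotone non-decreasing inside the linear window")
  }
  fit <- lm(product ~ time, data = win)
  list(rate = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_points = nrow(win), window = win)
}
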