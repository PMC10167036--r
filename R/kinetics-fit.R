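## nonlinear least-squares fitting of initial-rate data
##
## Both fitters use derivative-based Levenberg-Marquardt least squares
## (minpack.lm) with box constraints Km, Ki in (0, 1e6] uM, a data-driven
## initialization (Vmax0 = max observed rate; Km0 = concentration whose rate
## is nearest Vmax0/2), and a deterministic multi-start over inits jittered
## by factors of 3, keeping the best residual sum of squares.

.kin_starts <- function(S, rate) {
  Vmax0 <- max(rate)
  Km0 <- S[which.min(abs(rate - Vmax0 / 2))]
  if (Km0 <= 0) Km0 <- stats::median(S)
  jit <- list(c(1, 1), c(3, 1), c(1 / 3, 1), c(1, 3), c(1, 1 / 3))
  lapply(jit, function(j) c(Km = Km0 * j[1], Vmax = Vmax0 * j[2]))
}

## Gauss-Newton covariance (J'J)^-1 * RSS/(n-p) from the converged nls.lm
## object; singular information matrices yield NA standard errors
.kin_identifiability <- function(fit, n_obs) {
  est <- coef(fit)
  p <- length(est)
  sigma2 <- sum(fit$fvec^2) / max(n_obs - p, 1)
  vc <- tryCatch(sigma2 * chol2inv(chol(fit$hessian)),
                 error = function(e) NULL)
  if (!is.null(vc)) {
    se <- sqrt(pmax(diag(vc), 0))
    d <- se
    d[d == 0] <- 1  # exact fits: zero variance, define corr as 0
    corr <- vc / outer(d, d)
    dimnames(corr) <- list(names(est), names(est))
  } else {
    se <- rep(NA_real_, p)
    corr <- NULL
  }
  names(se) <- names(est)
  rel_se <- abs(se / est)
  list(se = se, rel_se = rel_se, corr = corr)
}

.kin_fit_result <- function(fit, data, model, converged, molar_mass = NULL) {
  if (is.null(fit)) {
    res <- list(params = NULL, se = NULL, rss = NA_real_, converged = FALSE,
                identifiability = NULL, flags = "no start converged",
                data = data, model = model)
    class(res) <- "kinetic_fit"
    return(res)
  }
  est <- coef(fit)
  idf <- .kin_identifiability(fit, nrow(data))
  flags <- character(0)
  if (est[["Km"]] <= 1e-6 || est[["Km"]] >= 1e6 - 1e-6) {
    flags <- c(flags, "Km at boundary")
  }
  params <- as.list(est)
  if (!is.null(molar_mass)) {
    params$kcat <- kcat_from_vmax(est[["Vmax"]], molar_mass)
    params$efficiency <- catalytic_efficiency(params$kcat, est[["Km"]])
  }
  if (model == "si") {
    ki_rel_se <- idf$rel_se[["Ki"]]
    ki_km_corr <- if (!is.null(idf$corr)) idf$corr["Ki", "Km"] else NA_real_
    ki_bad <- is.na(ki_rel_se) || ki_rel_se > 0.5 ||
      is.na(ki_km_corr) || abs(ki_km_corr) > 0.95 ||
      est[["Ki"]] >= 1e6 - 1e-6
    if (ki_bad) flags <- c(flags, "Ki unidentifiable")
    idf$ki_rel_se <- ki_rel_se
    idf$ki_km_corr <- ki_km_corr
  }
  res <- list(params = params, se = idf$se, rss = sum(fit$fvec^2),
              converged = converged, identifiability = idf, flags = flags,
              data = data, model = model, fit = fit)
  class(res) <- "kinetic_fit"
  res
}

.fit_rate_model <- function(data, model_fn, jac_fn, make_start, lower, upper,
                            model, molar_mass = NULL) {
  stop_if_not(is.data.frame(data) && "concentration_uM" %in% names(data) &&
                any(c("rate", "rate_pkat_per_ug") %in% names(data)),
              "data needs columns concentration_uM and rate(_pkat_per_ug)")
  if (!"rate" %in% names(data)) data$rate <- data$rate_pkat_per_ug
  stop_if_not(length(unique(data$concentration_uM)) >= 4,
              "need at least 4 distinct concentrations")
  S <- data$concentration_uM
  y <- data$rate
  best <- NULL
  for (st in make_start(S, y)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(p) y - model_fn(S, p),
        jac = function(p) -jac_fn(S, p),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    # info codes 1-4 signal convergence of the Levenberg-Marquardt iteration
    if (!is.null(fit) && fit$info %in% 1:4) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  .kin_fit_result(best$fit, data, model, converged = !is.null(best),
                  molar_mass = molar_mass)
}

#' Fit the Michaelis-Menten law to initial-rate data
#'
#' @param data data frame with columns \code{concentration_uM} and
#'   \code{rate} (or \code{rate_pkat_per_ug}); at least 4 distinct
#'   concentrations.
#' @param molar_mass optional enzyme molar mass (g/mol); when given, kcat
#'   (1/s) and catalytic efficiency (1/uM/s) are derived from the fitted
#'   Vmax (pkat/ug).
#' @return an object of class \code{kinetic_fit}: estimated parameters,
#'   standard errors (Gauss-Newton approximation), residual sum of squares,
#'   a convergence flag and an identifiability report.
#' @seealso [fit_substrate_inhibition()], [mm_rate()]
#' @export
#' @examples
#' d <- generate_initial_rates(list(Km = 24.68, Vmax = 63.47),
#'                             c(3, 5, 10, 25, 50, 100, 200),
#'                             noise_cv = 0, seed = 1)
#' coef(fit_michaelis_menten(d))
fit_michaelis_menten <- function(data, molar_mass = NULL) {
  model_fn <- function(S, p) p[["Vmax"]] * S / (p[["Km"]] + S)
  jac_fn <- function(S, p) {
    den <- p[["Km"]] + S
    cbind(Km = -p[["Vmax"]] * S / den^2, Vmax = S / den)
  }
  .fit_rate_model(
    data, model_fn, jac_fn, .kin_starts,
    lower = c(Km = 1e-9, Vmax = 1e-12),
    upper = c(Km = 1e6, Vmax = Inf), model = "mm", molar_mass = molar_mass)
}

#' Fit the substrate-inhibition law to initial-rate data
#'
#' Fits v = Vmax*S/(Km + S + S^2/Ki). The identifiability report flags Ki as
#' unidentifiable when its relative standard error exceeds 0.5 or when the
#' estimate correlation |corr(Ki, Km)| exceeds 0.95 -- the situation arising
#' when the assayed concentration range does not bracket the rate optimum at
#' sqrt(Km*Ki).
#'
#' @inheritParams fit_michaelis_menten
#' @return an object of class \code{kinetic_fit}; \code{$flags} contains
#'   \code{"Ki unidentifiable"} when the diagnostic fires.
#' @export
fit_substrate_inhibition <- function(data, molar_mass = NULL) {
  make_start <- function(S, rate) {
    base <- .kin_starts(S, rate)
    Ki0 <- max(S)
    lapply(base, function(st) c(st, Ki = Ki0))
  }
  model_fn <- function(S, p) {
    p[["Vmax"]] * S / (p[["Km"]] + S + S^2 / p[["Ki"]])
  }
  jac_fn <- function(S, p) {
    den <- p[["Km"]] + S + S^2 / p[["Ki"]]
    cbind(Km = -p[["Vmax"]] * S / den^2,
          Vmax = S / den,
          Ki = p[["Vmax"]] * S^3 / (p[["Ki"]]^2 * den^2))
  }
  .fit_rate_model(
    data, model_fn, jac_fn, make_start,
    lower = c(Km = 1e-9, Vmax = 1e-12, Ki = 1e-9),
    upper = c(Km = 1e6, Vmax = Inf, Ki = 1e6), model = "si",
    molar_mass = molar_mass)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  if (is.null(object$params)) return(NULL)
  unlist(object$params)
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  stop_if_not(object$converged, "cannot predict from a non-converged fit")
  S <- if (is.null(newdata)) object$data$concentration_uM else
    if (is.data.frame(newdata)) newdata$concentration_uM else newdata
  p <- object$params
  if (object$model == "mm") mm_rate(S, p$Km, p$Vmax)
  else si_rate(S, p$Km, p$Vmax, p$Ki)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  lab <- c(mm = "Michaelis-Menten", si = "substrate-inhibition")[x$model]
  cat(sprintf("%s fit (%d points)\n", lab, nrow(x$data)))
  if (!x$converged) {
    cat("  NOT CONVERGED - parameters unusable\n")
    return(invisible(x))
  }
  p <- x$params
  se <- x$se
  fmt <- function(nm, unit) {
    s <- if (!is.null(se) && nm %in% names(se) && is.finite(se[[nm]]))
      sprintf(" +/- %.3g", se[[nm]]) else ""
    sprintf("  %-5s %.4g%s %s\n", nm, p[[nm]], s, unit)
  }
  cat(fmt("Km", "uM"))
  cat(fmt("Vmax", "pkat/ug"))
  if (!is.null(p$Ki)) cat(fmt("Ki", "uM"))
  if (!is.null(p$kcat)) cat(sprintf("  kcat  %.4g 1/s (kcat/Km %.4g 1/uM/s)\n",
                                    p$kcat, p$efficiency))
  cat(sprintf("  RSS %.4g\n", x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$identifiability$corr)) {
    cat("parameter correlation:\n")
    print(round(object$identifiability$corr, 3))
  }
  invisible(object)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  stop_if_not(x$converged, "cannot plot a non-converged fit")
  S <- x$data$concentration_uM
  plot(S, x$data$rate, xlab = "substrate (uM)", ylab = "rate (pkat/ug)",
       pch = 19, ...)
  grid_S <- seq(0, max(S), length.out = 200)
  graphics::lines(grid_S, predict(x, grid_S), col = "steelblue", lwd = 2)
  invisible(x)
}
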