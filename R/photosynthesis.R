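# Light-response and CO2-response models of leaf photosynthesis, with bounded
# nonlinear least-squares fitting and derived quantities.

#' Light-response (non-rectangular hyperbola) parameter set
#'
#' Parameters of the non-rectangular hyperbola describing net photosynthesis
#' as a function of photosynthetic photon flux density (PPFD):
#' \deqn{P_n(Q) = \frac{\alpha Q + P_{max} - \sqrt{(\alpha Q + P_{max})^2 -
#'   4\kappa\alpha Q P_{max}}}{2\kappa} - R_d}
#' The convexity \eqn{\kappa \in [0, 1]} interpolates between a rectangular
#' hyperbola (\eqn{\kappa = 0}) and a Blackman two-line response
#' (\eqn{\kappa = 1}).
#'
#' @param alpha Maximum apparent quantum yield of CO2
#'   (mol CO2 mol^-1 photons); initial slope of the curve. Must be > 0.
#' @param pn_max Irradiance-saturated rate of gross photosynthesis
#'   (umol CO2 m^-2 s^-1). Must be > 0.
#' @param kappa Dimensionless convexity, in \[0, 1\].
#' @param rd Dark respiration rate (umol CO2 m^-2 s^-1). Must be >= 0.
#' @return An object of class `light_response_params`.
#' @export
#' @examples
#' p <- light_response_params(alpha = 0.052, pn_max = 19.9,
#'                            kappa = 0.53, rd = 2.07)
#' eval_light_response(p, q = c(0, 200, 2000))
light_response_params <- function(alpha, pn_max, kappa, rd) {
  stop_if_not_number(alpha, "alpha", positive = TRUE)
  stop_if_not_number(pn_max, "pn_max", positive = TRUE)
  stop_if_not_number(kappa, "kappa")
  stop_if_not_number(rd, "rd", nonneg = TRUE)
  if (kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, pn_max = pn_max, kappa = kappa, rd = rd),
            class = "light_response_params")
}

#' CO2-response parameter set
#'
#' Parameters of the CO2-response (A–Ci) model
#' \deqn{P_n(C_i) = \frac{\varepsilon P_{sat} C_i}{\varepsilon C_i + P_{sat}}
#'   - R_p,}
#' a rectangular hyperbola in intercellular CO2 offset by photorespiration.
#'
#' @param epsilon Carboxylation efficiency (mol m^-2 s^-1); initial slope of
#'   the A–Ci curve. Must be > 0.
#' @param pn_sat Photosynthetic capacity (umol CO2 m^-2 s^-1). Must be > 0.
#' @param rp Photorespiration rate (umol CO2 m^-2 s^-1). Must be >= 0.
#' @return An object of class `co2_response_params`.
#' @export
co2_response_params <- function(epsilon, pn_sat, rp) {
  stop_if_not_number(epsilon, "epsilon", positive = TRUE)
  stop_if_not_number(pn_sat, "pn_sat", positive = TRUE)
  stop_if_not_number(rp, "rp", nonneg = TRUE)
  structure(list(epsilon = epsilon, pn_sat = pn_sat, rp = rp),
            class = "co2_response_params")
}

# Gross non-rectangular hyperbola in the algebraically conjugate form
#   2 a Q P / [(aQ + P) + sqrt((aQ + P)^2 - 4 k a Q P)],
# which avoids both the subtractive cancellation of the printed root form and
# the division by 2*kappa, so it is continuous through kappa -> 0.
nrh_gross <- function(alpha, pn_max, kappa, q) {
  s <- alpha * q + pn_max
  disc <- pmax(s^2 - 4 * kappa * alpha * q * pn_max, 0)
  2 * alpha * q * pn_max / (s + sqrt(disc))
}

#' Evaluate the light-response model
#'
#' Net photosynthesis at the given PPFD values, computed via the numerically
#' stable conjugate form of the non-rectangular hyperbola (continuous in
#' kappa down to 0).
#'
#' @param params A [light_response_params()] object.
#' @param q PPFD values (umol photons m^-2 s^-1), all >= 0.
#' @return Net photosynthesis rate(s) (umol CO2 m^-2 s^-1).
#' @export
eval_light_response <- function(params, q) {
  stopifnot(inherits(params, "light_response_params"))
  stop_if_not_number(q, "q")
  if (any(q < 0)) stop("PPFD `q` must be non-negative", call. = FALSE)
  nrh_gross(params$alpha, params$pn_max, params$kappa, q) - params$rd
}

#' Evaluate the CO2-response model
#'
#' @param params A [co2_response_params()] object.
#' @param ci Intercellular CO2 mole fraction(s) (umol mol^-1), all >= 0.
#' @return Net photosynthesis rate(s) (umol CO2 m^-2 s^-1).
#' @export
eval_co2_response <- function(params, ci) {
  stopifnot(inherits(params, "co2_response_params"))
  stop_if_not_number(ci, "ci")
  if (any(ci < 0)) stop("`ci` must be non-negative", call. = FALSE)
  with(params, epsilon * pn_sat * ci / (epsilon * ci + pn_sat) - rp)
}

#' CO2 compensation point
#'
#' The intercellular CO2 mole fraction at which net photosynthesis of the
#' CO2-response model crosses zero:
#' \eqn{C_i^* = R_p P_{sat} / (\varepsilon (P_{sat} - R_p))}.
#'
#' @param params A [co2_response_params()] object with `pn_sat > rp`.
#' @return Compensation point (umol mol^-1).
#' @export
co2_compensation_point <- function(params) {
  stopifnot(inherits(params, "co2_response_params"))
  if (params$pn_sat <= params$rp) {
    stop("curve never crosses zero: `pn_sat` must exceed `rp`", call. = FALSE)
  }
  with(params, rp * pn_sat / (epsilon * (pn_sat - rp)))
}

new_curve_fit <- function(params, rss, r_squared, converged, n_points, stderr) {
  structure(list(params = params, rss = rss, r_squared = r_squared,
                 converged = converged, n_points = n_points, stderr = stderr),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat("Curve fit (", class(x$params)[1], ")\n", sep = "")
  est <- unlist(x$params[names(x$params)])
  se <- x$stderr[names(est)]
  print(data.frame(estimate = est, std_error = unname(se)))
  cat(sprintf("RSS %.4g  R^2 %.5f  n %d  converged %s\n",
              x$rss, x$r_squared, x$n_points, x$converged))
  invisible(x)
}

fit_checks <- function(x, y, min_n, xname) {
  stop_if_not_number(x, xname)
  stop_if_not_number(y, "pn_values")
  if (length(x) != length(y)) stop("setpoint and response lengths differ",
                                   call. = FALSE)
  if (length(unique(x)) < min_n) {
    stop(sprintf("need at least %d distinct %s values to identify the model",
                 min_n, xname), call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("degenerate data: response is constant across setpoints",
         call. = FALSE)
  }
}

# Initial slope from an OLS line over the k lowest nonzero setpoints.
init_slope <- function(x, y, k = 3) {
  ok <- x > 0
  o <- order(x[ok])[seq_len(min(k, sum(ok)))]
  fit <- stats::lm(y[ok][o] ~ x[ok][o])
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}

run_nlsLM <- function(formula, data, start, lower, upper, maxit = 500) {
  tryCatch(
    withCallingHandlers(
      minpack.lm::nlsLM(formula, data = data, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = maxit, ftol = 1e-15, ptol = 1e-15)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
}

finish_fit <- function(fit, y, make_params) {
  if (inherits(fit, "error")) {
    stop("curve fit failed: ", conditionMessage(fit), call. = FALSE)
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  new_curve_fit(make_params(cf), rss = rss, r_squared = 1 - rss / tss,
                converged = isTRUE(fit$convInfo$isConv),
                n_points = length(y), stderr = se)
}

#' Fit the light-response curve
#'
#' Bounded Levenberg–Marquardt least squares of the non-rectangular hyperbola
#' on (PPFD, Pn) pairs.  Starting values are data-driven: alpha from the OLS
#' slope over the three lowest nonzero-PPFD points, Rd from the Pn measured in
#' darkness (or the OLS intercept), Pn_max from the observed maximum, and
#' kappa from the midrange of its admissible interval.  kappa is constrained
#' to \[0, 1\]; the remaining parameters to positive values with loose upper
#' bounds implied by the data scale.
#'
#' @param q_values PPFD setpoints (umol m^-2 s^-1), distinct, >= 0.
#' @param pn_values Measured net photosynthesis (umol CO2 m^-2 s^-1).
#' @param kappa_start Starting value for the convexity (default 0.8).
#' @param max_iter Maximum optimizer iterations.
#' @return A `curve_fit` object: fitted [light_response_params()], residual
#'   sum of squares, R^2, per-parameter standard errors, convergence flag.
#' @export
#' @examples
#' truth <- light_response_params(0.052, 19.9, 0.53, 2.07)
#' q <- c(2000, 1500, 1000, 700, 400, 200, 100, 50, 20, 0)
#' fit <- fit_light_response(q, eval_light_response(truth, q))
#' fit$params$pn_max
fit_light_response <- function(q_values, pn_values, kappa_start = 0.8,
                               max_iter = 500) {
  if (any(q_values < 0)) stop("PPFD must be non-negative", call. = FALSE)
  fit_checks(q_values, pn_values, min_n = 5, xname = "q_values")

  sl <- init_slope(q_values, pn_values)
  rd0 <- if (any(q_values == 0)) {
    max(-pn_values[q_values == 0][1], 0.01)
  } else {
    max(-sl$intercept, 0.01)
  }
  alpha0 <- max(sl$slope, 1e-4)
  pnmax0 <- max(pn_values) + rd0
  start <- list(alpha = alpha0, pn_max = pnmax0, kappa = kappa_start, rd = rd0)
  lower <- c(alpha = 1e-8, pn_max = 1e-8, kappa = 0, rd = 0)
  upper <- c(alpha = 10 * alpha0, pn_max = 10 * pnmax0, kappa = 1,
             rd = 10 * (rd0 + 1))

  dat <- data.frame(q = q_values, pn = pn_values)
  fit <- run_nlsLM(
    pn ~ 2 * alpha * q * pn_max /
      ((alpha * q + pn_max) +
         sqrt(pmax((alpha * q + pn_max)^2 - 4 * kappa * alpha * q * pn_max,
                   0))) - rd,
    data = dat, start = start, lower = lower, upper = upper, maxit = max_iter)
  finish_fit(fit, pn_values, function(cf) {
    light_response_params(cf[["alpha"]], cf[["pn_max"]], cf[["kappa"]],
                          cf[["rd"]])
  })
}

#' Fit the CO2-response curve
#'
#' Bounded Levenberg–Marquardt least squares of the CO2-response hyperbola on
#' (Ci, Pn) pairs.  Starting values: epsilon from the OLS slope over the three
#' lowest Ci points, Rp from Pn extrapolated to Ci = 0, Pn_sat from the
#' observed maximum.
#'
#' @param ci_values Intercellular CO2 setpoints (umol mol^-1), distinct, >= 0.
#' @param pn_values Measured net photosynthesis (umol CO2 m^-2 s^-1).
#' @param max_iter Maximum optimizer iterations.
#' @return A `curve_fit` object holding [co2_response_params()].
#' @export
fit_co2_response <- function(ci_values, pn_values, max_iter = 500) {
  if (any(ci_values < 0)) stop("`ci_values` must be non-negative", call. = FALSE)
  fit_checks(ci_values, pn_values, min_n = 4, xname = "ci_values")

  sl <- init_slope(ci_values, pn_values)
  rp0 <- if (any(ci_values == 0)) {
    max(-pn_values[ci_values == 0][1], 0.01)
  } else {
    max(-sl$intercept, 0.01)
  }
  eps0 <- max(sl$slope, 1e-4)
  pnsat0 <- max(pn_values) + rp0
  start <- list(epsilon = eps0, pn_sat = pnsat0, rp = rp0)
  lower <- c(epsilon = 1e-8, pn_sat = 1e-8, rp = 0)
  upper <- c(epsilon = 10 * eps0, pn_sat = 20 * pnsat0, rp = 10 * (rp0 + 1))

  dat <- data.frame(ci = ci_values, pn = pn_values)
  fit <- run_nlsLM(
    pn ~ epsilon * pn_sat * ci / (epsilon * ci + pn_sat) - rp,
    data = dat, start = start, lower = lower, upper = upper, maxit = max_iter)
  finish_fit(fit, pn_values, function(cf) {
    co2_response_params(cf[["epsilon"]], cf[["pn_sat"]], cf[["rp"]])
  })
}
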