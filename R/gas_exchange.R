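# Derived leaf-level gas-exchange metrics.

#' Intrinsic water-use efficiency
#'
#' Ratio of net photosynthesis to stomatal conductance, Pn/gs
#' (umol CO2 mol^-1 H2O).  For treatment summaries the ratio is computed per
#' observation and then averaged (mean of ratios); because Pn/gs and gs are
#' negatively associated under stomatal closure, this exceeds the ratio of
#' treatment means — both aggregations are reported by
#' [summarize_gas_exchange()].
#'
#' @param pn Net photosynthesis (umol m^-2 s^-1).
#' @param gs Stomatal conductance (mol m^-2 s^-1), > 0.
#' @return Intrinsic WUE (umol CO2 mol^-1 H2O).
#' @export
intrinsic_wue <- function(pn, gs) {
  stop_if_not_number(pn, "pn")
  stop_if_not_number(gs, "gs", positive = TRUE)
  pn / gs
}

#' Intercellular-to-ambient CO2 ratio
#'
#' @param ci Intercellular CO2 (umol mol^-1), >= 0.
#' @param ca Ambient CO2 (umol mol^-1), > 0.
#' @return Ci/Ca (dimensionless).  Values above 1 are physically suspect and
#'   flagged with a warning (tolerated up to 1.2).
#' @export
ci_ca_ratio <- function(ci, ca) {
  stop_if_not_number(ci, "ci", nonneg = TRUE)
  stop_if_not_number(ca, "ca", positive = TRUE)
  r <- ci / ca
  if (any(r > 1)) warning("Ci/Ca above 1: check chamber records")
  r
}

#' Percent reduction relative to a reference
#'
#' (reference - treatment)/reference x 100, rounded half-up to one decimal,
#' the convention used when reporting salinity-induced declines between
#' treatment means.
#'
#' @param reference Reference value (nonzero).
#' @param treatment Treatment value.
#' @param digits Decimals in the reported percentage (default 1).
#' @return Percent reduction (positive when the treatment is lower).
#' @export
#' @examples
#' percent_reduction(21.2, 13.2)  # 37.7
percent_reduction <- function(reference, treatment, digits = 1) {
  stop_if_not_number(reference, "reference")
  stop_if_not_number(treatment, "treatment")
  if (any(reference == 0)) stop("`reference` must be nonzero", call. = FALSE)
  round_half_up((reference - treatment) / reference * 100, digits)
}

#' Log-linear Pn–gs relationship
#'
#' Ordinary least squares of net photosynthesis on the natural logarithm of
#' stomatal conductance, Pn = a + b ln(gs) — the characteristic saturating
#' relationship of pooled spot gas-exchange data.
#'
#' @param pn Net photosynthesis values.
#' @param gs Stomatal conductance values, > 0, length >= 3.
#' @return List with `intercept` (a), `slope` (b), `r_squared`, `p_value`
#'   (slope t-test), `n`, and the underlying `lm` fit.
#' @export
fit_pn_gs_log <- function(pn, gs) {
  stop_if_not_number(pn, "pn")
  stop_if_not_number(gs, "gs", positive = TRUE)
  if (length(pn) != length(gs)) stop("`pn` and `gs` lengths differ",
                                     call. = FALSE)
  if (length(pn) < 3) stop("need at least 3 observations", call. = FALSE)
  x <- log(gs)
  if (stats::sd(x) == 0) stop("singular design: `gs` has no variation",
                              call. = FALSE)
  fit <- stats::lm(pn ~ x)
  sm <- suppressWarnings(summary(fit))
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = sm$r.squared,
       p_value = if (sm$sigma == 0) 0 else sm$coefficients[2, 4],
       n = length(pn),
       fit = fit)
}

#' Treatment-level gas-exchange summary
#'
#' Marginal means of Pn, gs, Ci/Ca and intrinsic WUE over each factor of the
#' salinity-by-leaching design, mirroring the layout of a factorial
#' gas-exchange table.  Both WUE aggregations are reported: the mean of
#' per-observation Pn/gs ratios (`wue_mean_of_ratios`) and the ratio of the
#' marginal means (`wue_ratio_of_means`).
#'
#' @param obs Gas-exchange observations: data frame with columns `ec`, `lf`,
#'   `pn`, `gs`, `ci`, `ca`.
#' @return Data frame with one row per factor level (`factor`, `level`,
#'   `pn`, `gs`, `ci_ca`, `wue_mean_of_ratios`, `wue_ratio_of_means`, `n`).
#' @export
summarize_gas_exchange <- function(obs) {
  stopifnot(is.data.frame(obs))
  need <- c("ec", "lf", "pn", "gs", "ci", "ca")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  obs$wue <- intrinsic_wue(obs$pn, obs$gs)
  obs$ci_ca <- obs$ci / obs$ca
  one_factor <- function(fac) {
    sp <- split(obs, obs[[fac]])
    rows <- lapply(names(sp), function(lev) {
      d <- sp[[lev]]
      data.frame(factor = fac, level = lev,
                 pn = mean(d$pn), gs = mean(d$gs), ci_ca = mean(d$ci_ca),
                 wue_mean_of_ratios = mean(d$wue),
                 wue_ratio_of_means = mean(d$pn) / mean(d$gs),
                 n = nrow(d), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(one_factor("ec"), one_factor("lf"))
  rownames(out) <- NULL
  out
}
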