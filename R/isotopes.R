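# Stable-isotope metrics: delta13C, delta15N, carbon isotope discrimination,
# and elemental accumulation.

#' Carbon isotope composition (delta13C)
#'
#' \eqn{\delta^{13}C = (R_{sample}/R_{standard} - 1) \times 1000} per mil,
#' where R is the 13C/12C ratio and the standard is PDB (Pee Dee Belemnite).
#'
#' @param r_sample 13C/12C ratio of the sample, > 0.
#' @param r_standard 13C/12C ratio of the standard; defaults to PDB
#'   (0.0112372).
#' @return delta13C in per mil.
#' @export
delta13c <- function(r_sample, r_standard = 0.0112372) {
  stop_if_not_number(r_sample, "r_sample", positive = TRUE)
  stop_if_not_number(r_standard, "r_standard", positive = TRUE)
  (r_sample / r_standard - 1) * 1000
}

#' Nitrogen isotope composition (delta15N)
#'
#' \eqn{\delta^{15}N = (R_s/R_b - 1) \times 1000} per mil, where R is the
#' 15N/(14N + 15N) fraction and the atmospheric-N2 standard is 0.3663 atom
#' percent 15N.
#'
#' @param r_s 15N fraction of the sample.  A plain fraction by default; atom
#'   percent accepted with `unit = "at_percent"`.
#' @param r_b Standard 15N fraction (default 0.003663, i.e. 0.3663 at%).
#' @param unit Unit of `r_s` and `r_b`: `"fraction"` or `"at_percent"`.
#' @return delta15N in per mil.
#' @export
delta15n <- function(r_s, r_b = 0.003663, unit = c("fraction", "at_percent")) {
  unit <- match.arg(unit)
  stop_if_not_number(r_s, "r_s", positive = TRUE)
  stop_if_not_number(r_b, "r_b", positive = TRUE)
  if (unit == "at_percent") {
    r_s <- r_s / 100
    r_b <- r_b / 100
  }
  (r_s / r_b - 1) * 1000
}

#' Carbon isotope discrimination (Delta13C)
#'
#' Discrimination of plant material against 13C relative to source air:
#' \deqn{\Delta^{13}C = \frac{\delta_a - \delta_p}{1 + \delta_p}}
#' with the deltas as *fractions*.  Inputs and output are in per mil; the
#' conversion to fractional units happens internally, since the formula is
#' only dimensionally consistent on that scale (a literal per-mil denominator
#' would shrink the result roughly 25-fold).
#'
#' @param delta_p Carbon isotope composition of plant material, per mil.
#' @param delta_a Carbon isotope composition of source air, per mil
#'   (default -8).
#' @return Discrimination in per mil.
#' @export
#' @examples
#' big_delta13c(delta_p = -30.88)  # ~23.61 per mil
big_delta13c <- function(delta_p, delta_a = -8) {
  stop_if_not_number(delta_p, "delta_p")
  stop_if_not_number(delta_a, "delta_a")
  if (any(abs(delta_p) >= 1000) || any(abs(delta_a) >= 1000)) {
    stop("delta values must lie strictly within (-1000, 1000) per mil",
         call. = FALSE)
  }
  dp <- delta_p / 1000
  da <- delta_a / 1000
  (da - dp) / (1 + dp) * 1000
}

#' Invert the discrimination relation
#'
#' Returns the plant delta13C that yields a given discrimination under a
#' given source-air composition; the algebraic inverse of [big_delta13c()].
#'
#' @param big_delta Discrimination Delta13C, per mil.
#' @param delta_a Source-air delta13C, per mil (default -8).
#' @return Plant delta13C, per mil.
#' @export
invert_big_delta <- function(big_delta, delta_a = -8) {
  stop_if_not_number(big_delta, "big_delta")
  bd <- big_delta / 1000
  da <- delta_a / 1000
  (da - bd) / (1 + bd) * 1000
}

#' Total elemental accumulation
#'
#' Element mass per plant from tissue content and dry biomass:
#' content/100 x biomass.
#'
#' @param content_percent Elemental content in percent of dry weight,
#'   in \[0, 100\].
#' @param dry_biomass Dry biomass (g per plant), >= 0.
#' @return Accumulation (g per plant).
#' @export
total_accumulation <- function(content_percent, dry_biomass) {
  stop_if_not_number(content_percent, "content_percent", nonneg = TRUE)
  stop_if_not_number(dry_biomass, "dry_biomass", nonneg = TRUE)
  if (any(content_percent > 100)) {
    stop("`content_percent` cannot exceed 100", call. = FALSE)
  }
  content_percent / 100 * dry_biomass
}

#' Derive isotope metrics for a sample table
#'
#' Adds discrimination and accumulation columns to an isotope assay table.
#' Input columns: `delta13c_permil` (or `r_sample` + `r_standard`),
#' `c_content_pct`, `n_content_pct`, `leaf_dry_biomass_g`; optional
#' `delta15n_permil` or `r_s`.
#'
#' @param samples A data frame of per-plant isotope assays.
#' @param delta_a Source-air delta13C, per mil.
#' @return The input with `big_delta13c_permil`, `total_c_g`, `total_n_g`
#'   columns added.
#' @export
isotope_metrics <- function(samples, delta_a = -8) {
  stopifnot(is.data.frame(samples))
  if (is.null(samples$delta13c_permil)) {
    if (is.null(samples$r_sample)) {
      stop("need `delta13c_permil` or `r_sample` (+ `r_standard`) columns",
           call. = FALSE)
    }
    samples$delta13c_permil <- delta13c(samples$r_sample,
                                        samples$r_standard %||% 0.0112372)
  }
  if (is.null(samples$delta15n_permil) && !is.null(samples$r_s)) {
    samples$delta15n_permil <- delta15n(samples$r_s)
  }
  samples$big_delta13c_permil <- big_delta13c(samples$delta13c_permil, delta_a)
  samples$total_c_g <- total_accumulation(samples$c_content_pct,
                                          samples$leaf_dry_biomass_g)
  samples$total_n_g <- total_accumulation(samples$n_content_pct,
                                          samples$leaf_dry_biomass_g)
  samples
}
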