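# Pot water balance, leaching-fraction scheduling and seasonal accounting.
#
# The weighing water balance for one inter-irrigation interval is
#   ET = W_n - W_{n+1} + (AW - D) * rho,
# with W the pot weights just before consecutive irrigations (g), AW the
# applied irrigation water and D the drainage (L), and rho the bulk density
# of water (g L^-1).  Scheduling follows AW/ET = 1/(1 - LF).

#' Evapotranspiration from the weighing water balance
#'
#' @param w_before Pot weight just before this irrigation (g).
#' @param w_next Pot weight just before the next irrigation (g).
#' @param applied_water Irrigation applied at this event (L).
#' @param drainage Drainage collected after this event (L), in
#'   \[0, applied_water\].
#' @param rho Water bulk density (g L^-1, default 1000).
#' @return Evapotranspiration over the interval (g).  Small negative values
#'   (possible with weighing noise) are returned as-is with a warning, never
#'   clipped.
#' @export
compute_et <- function(w_before, w_next, applied_water, drainage, rho = 1000) {
  stop_if_not_number(w_before, "w_before", positive = TRUE)
  stop_if_not_number(w_next, "w_next", positive = TRUE)
  stop_if_not_number(applied_water, "applied_water", nonneg = TRUE)
  stop_if_not_number(drainage, "drainage", nonneg = TRUE)
  stop_if_not_number(rho, "rho", positive = TRUE)
  if (any(drainage > applied_water)) {
    stop("drainage cannot exceed applied water", call. = FALSE)
  }
  et <- w_before - w_next + (applied_water - drainage) * rho
  if (any(et < 0)) {
    warning("negative evapotranspiration computed; check weighing records")
  }
  et
}

#' Irrigation requirement for a target leaching fraction
#'
#' Applied water needed to replace the measured evapotranspiration while
#' leaching the target fraction: AW = (ET/rho) / (1 - LF).  In
#' `"paper_multiplier"` mode the exact factor 1/(1 - LF) is replaced by its
#' value rounded to one decimal (1.2 for LF 0.17, 1.4 for LF 0.29), the
#' rounded percentages commonly used when scheduling by hand.
#'
#' @param et Evapotranspiration since the last irrigation (g), >= 0.
#' @param lf Target leaching fraction, in \[0, 1).
#' @param rho Water bulk density (g L^-1, default 1000).
#' @param mode `"exact"` or `"paper_multiplier"`.
#' @return Applied water (L).
#' @export
#' @examples
#' required_applied_water(1000, lf = 0.17)                       # 1.2048 L
#' required_applied_water(1000, lf = 0.17, mode = "paper_multiplier")  # 1.2 L
required_applied_water <- function(et, lf, rho = 1000,
                                   mode = c("exact", "paper_multiplier")) {
  mode <- match.arg(mode)
  stop_if_not_number(et, "et", nonneg = TRUE)
  stop_if_not_number(lf, "lf")
  if (any(lf < 0) || any(lf >= 1)) {
    stop("`lf` must lie in [0, 1)", call. = FALSE)
  }
  mult <- if (mode == "exact") 1 / (1 - lf) else round_half_up(1 / (1 - lf), 1)
  et / rho * mult
}

#' Leaching fraction implied by an irrigation ratio
#'
#' Rearranges AW/ET = 1/(1 - LF) to LF = 1 - (ET/rho)/AW.
#'
#' @param aw Applied water (L), > 0.
#' @param et Evapotranspiration (g), >= 0.
#' @param rho Water bulk density (g L^-1, default 1000).
#' @return Implied leaching fraction; negative values (over-dry irrigation)
#'   are clipped to 0 with a warning.
#' @export
#' @examples
#' implied_lf(aw = 1.2, et = 1000)  # 0.1667
implied_lf <- function(aw, et, rho = 1000) {
  stop_if_not_number(aw, "aw", positive = TRUE)
  stop_if_not_number(et, "et", nonneg = TRUE)
  lf <- 1 - (et / rho) / aw
  if (any(lf < 0)) {
    warning("applied water below evapotranspiration; leaching fraction clipped to 0")
    lf <- pmax(lf, 0)
  }
  lf
}

#' Seasonal actual leaching fraction
#'
#' Per-pot ratio of total seasonal drainage to total applied water,
#' optionally aggregated over treatments.
#'
#' @param ledger Irrigation ledger: data frame with columns `pot_id`,
#'   `applied_L`, `drainage_L` and optionally `ec` and `lf` treatment labels.
#' @return Data frame with one row per pot (`pot_id`, `actual_lf`, plus any
#'   treatment labels); the treatment-level means, if labels are present, are
#'   attached as attribute `"by_treatment"`.
#' @export
seasonal_actual_lf <- function(ledger) {
  stopifnot(is.data.frame(ledger))
  need <- c("pot_id", "applied_L", "drainage_L")
  miss <- setdiff(need, names(ledger))
  if (length(miss)) stop("ledger missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tot_aw <- tapply(ledger$applied_L, ledger$pot_id, sum)
  tot_d <- tapply(ledger$drainage_L, ledger$pot_id, sum)
  if (any(tot_aw == 0)) stop("zero total applied water for at least one pot",
                             call. = FALSE)
  out <- data.frame(pot_id = names(tot_aw),
                    actual_lf = as.numeric(tot_d / tot_aw),
                    stringsAsFactors = FALSE)
  labs <- intersect(c("ec", "lf"), names(ledger))
  if (length(labs)) {
    key <- unique(ledger[c("pot_id", labs)])
    out <- merge(out, key, by = "pot_id", sort = FALSE)
    if ("lf" %in% labs) {
      byt <- stats::aggregate(actual_lf ~ lf, data = out, FUN = mean)
      attr(out, "by_treatment") <- byt
    }
  }
  out[order(out$pot_id), , drop = FALSE]
}

#' Season water-balance closure report
#'
#' Telescoping check: the sum of per-interval evapotranspiration equals
#' (W_start - W_end) + (sum AW - sum D) * rho.  Returns per-pot seasonal
#' totals and the closure residual (exactly zero for a consistent ledger, up
#' to floating-point error).
#'
#' @param ledger Irrigation ledger with columns `pot_id`, `event_index`,
#'   `w_before_g`, `w_next_g`, `applied_L`, `drainage_L`.
#' @param rho Water bulk density (g L^-1, default 1000).
#' @return Data frame: `pot_id`, `total_et_g`, `total_applied_L`,
#'   `total_drainage_L`, `actual_lf`, `closure_residual_g`, `n_negative_et`.
#' @export
water_balance_report <- function(ledger, rho = 1000) {
  stopifnot(is.data.frame(ledger))
  sp <- split(ledger, ledger$pot_id)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$event_index), ]
    et <- suppressWarnings(
      compute_et(d$w_before_g, d$w_next_g, d$applied_L, d$drainage_L, rho))
    closure <- (d$w_before_g[1] - d$w_next_g[nrow(d)]) +
      (sum(d$applied_L) - sum(d$drainage_L)) * rho
    data.frame(pot_id = d$pot_id[1],
               total_et_g = sum(et),
               total_applied_L = sum(d$applied_L),
               total_drainage_L = sum(d$drainage_L),
               actual_lf = sum(d$drainage_L) / sum(d$applied_L),
               closure_residual_g = sum(et) - closure,
               n_negative_et = sum(et < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
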