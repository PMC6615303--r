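# End-to-end orchestration: simulate (or load) -> fit -> derive -> analyze ->
# report, with one seed and a manifest.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!is.null(config$inputs) && !is.null(config$simulate)) {
    stop("config must provide either `inputs` or `simulate`, not both",
         call. = FALSE)
  }
  if (is.null(config$inputs) && is.null(config$simulate)) {
    config$simulate <- list()
  }
  config
}

load_inputs <- function(paths) {
  need <- c("units", "gas_exchange", "light_curves", "co2_curves",
            "isotopes", "irrigation")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("`inputs` missing path(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(paths[need], function(p)
    utils::read.csv(p, stringsAsFactors = FALSE))
  names(out) <- need
  out
}

require_cols <- function(df, cols, stage) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("[%s] missing column(s): %s", stage,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

fit_all_curves <- function(curves, kind) {
  sp <- split(curves, curves$pot_id)
  rows <- lapply(sp, function(d) {
    fit <- tryCatch(
      if (kind == "light") fit_light_response(d$setpoint, d$pn)
      else fit_co2_response(d$setpoint, d$pn),
      error = function(e) NULL)
    base <- data.frame(pot_id = d$pot_id[1], ec = d$ec[1], lf = d$lf[1],
                       stringsAsFactors = FALSE)
    if (is.null(fit)) {
      base$converged <- FALSE
      return(base)
    }
    est <- fit$params[names(fit$params)]
    for (nm in names(est)) base[[nm]] <- est[[nm]]
    base$rss <- fit$rss
    base$r_squared <- fit$r_squared
    base$converged <- fit$converged
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

marginal_table <- function(data, responses, alpha = 0.05,
                           pooling = "average") {
  lapply(stats::setNames(responses, responses), function(v) {
    treatment_table(data, v, alpha = alpha, pooling = pooling)
  })
}

flatten_treatment_tables <- function(tabs) {
  rows <- lapply(names(tabs), function(v) {
    tt <- tabs[[v]]
    mk <- function(df, fac) {
      data.frame(response = v, factor = fac, level = df$level,
                 mean = df$mean, letters = df$letters,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(mk(tt$means_a, "ec"), mk(tt$means_b, "lf"))
    out$stars_lf <- tt$stars[["lf"]]
    out$stars_ec <- tt$stars[["ec"]]
    out$stars_interaction <- tt$stars[[3]]
    out
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the experiment tables, fits every response curve,
#' derives gas-exchange and isotope metrics, runs the factorial statistics,
#' and writes a report bundle of CSVs plus a JSON manifest to `outdir`.
#' Everything is driven by one seed, so a config + seed pair reproduces the
#' bundle exactly.
#'
#' @param config A list (or path to a YAML file) with optional elements:
#'   `simulate` (list with optional `design` arguments for
#'   [experiment_design()] and `noise_free` flag), `inputs` (named CSV
#'   paths: units, gas_exchange, light_curves, co2_curves, isotopes,
#'   irrigation), `analysis` (list: `alpha`, `pooling`, `lf_mode`), `seed`,
#'   `outdir`.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a named list with all stage outputs (`tables`,
#'   `curve_fits`, `gas_exchange_summary`, `treatment_tables`,
#'   `water_balance`, `regressions`, `ancova`, `manifest`).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  config <- read_config(config)
  seed <- config$seed %||% 20150428
  outdir <- config$outdir
  analysis <- config$analysis %||% list()
  alpha <- analysis$alpha %||% 0.05
  pooling <- analysis$pooling %||% "average"
  lf_mode <- analysis$lf_mode %||% "exact"
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(config$inputs)) {
    tables <- load_inputs(config$inputs)
    say("stage load: %d tables read", length(tables))
  } else {
    sim <- config$simulate
    des_args <- sim$design %||% list()
    des_args$rng_seed <- des_args$rng_seed %||% seed
    design <- do.call(experiment_design, des_args)
    model <- generation_model()
    if (isTRUE(sim$noise_free)) model <- noise_free(model)
    tables <- generate_experiment(design, model,
                                  leaves_per_pot = sim$leaves_per_pot %||% 1,
                                  lf_mode = lf_mode)
    say("stage simulate: %d units, seed %d", nrow(tables$units), seed)
  }

  require_cols(tables$gas_exchange, c("pot_id", "ec", "lf", "pn", "gs", "ci", "ca"),
               "gas_exchange")
  require_cols(tables$light_curves, c("pot_id", "ec", "lf", "setpoint", "pn"),
               "light_curves")
  require_cols(tables$co2_curves, c("pot_id", "ec", "lf", "setpoint", "pn"),
               "co2_curves")
  require_cols(tables$irrigation,
               c("pot_id", "event_index", "w_before_g", "w_next_g",
                 "applied_L", "drainage_L"), "irrigation")

  ge <- tables$gas_exchange
  ge$wue <- intrinsic_wue(ge$pn, ge$gs)
  ge$ci_ca <- suppressWarnings(ci_ca_ratio(ge$ci, ge$ca))
  n_flag <- sum(ge$ci_ca > 1)
  if (n_flag > 0) say("warning: %d observations with Ci/Ca > 1", n_flag)
  ge_summary <- summarize_gas_exchange(ge)
  ge_tabs <- marginal_table(ge, c("pn", "gs", "ci_ca", "wue"),
                            alpha = alpha, pooling = pooling)
  say("stage gas-exchange: %d observations", nrow(ge))

  light_fits <- fit_all_curves(tables$light_curves, "light")
  co2_fits <- fit_all_curves(tables$co2_curves, "co2")
  curve_fits <- merge(light_fits, co2_fits,
                      by = c("pot_id", "ec", "lf"),
                      suffixes = c("_light", "_co2"))
  curve_vars <- intersect(c("alpha", "pn_max", "kappa", "rd",
                            "epsilon", "pn_sat", "rp"), names(curve_fits))
  curve_tabs <- marginal_table(curve_fits, curve_vars,
                               alpha = alpha, pooling = pooling)
  say("stage curve-fits: %d light + %d co2 fits (%d converged)",
      nrow(light_fits), nrow(co2_fits),
      sum(light_fits$converged) + sum(co2_fits$converged))

  iso <- isotope_metrics(tables$isotopes)
  iso_tabs <- marginal_table(iso, c("big_delta13c_permil", "c_content_pct",
                                    "total_c_g", "delta15n_permil",
                                    "total_n_g", "leaf_dry_biomass_g"),
                             alpha = alpha, pooling = pooling)
  say("stage isotopes: %d samples", nrow(iso))

  wb <- water_balance_report(tables$irrigation)
  wb <- merge(wb, tables$units[c("pot_id", "ec", "lf")], by = "pot_id")
  neg <- sum(wb$n_negative_et)
  if (neg > 0) say("warning: %d intervals with negative ET", neg)
  say("stage water-balance: %d pots, mean actual LF %.3f",
      nrow(wb), mean(wb$actual_lf))

  anc <- ancova_slope_test(ge$pn, ge$gs, ge$ec, alpha = alpha)
  iso_mean <- stats::aggregate(big_delta13c_permil ~ ec, data = iso, FUN = mean)
  reg_delta_ec <- linear_regression_r2(iso_mean$ec, iso_mean$big_delta13c_permil)
  regressions <- data.frame(
    relationship = c("pn_vs_ln_gs", "big_delta13c_vs_ec"),
    slope = c(anc$common_slope, reg_delta_ec$slope),
    r_squared = c(summary(anc$fit_additive)$r.squared, reg_delta_ec$r_squared),
    p_value = c(anc$interaction_p, reg_delta_ec$p_value),
    n = c(nrow(ge), reg_delta_ec$n),
    stringsAsFactors = FALSE)
  say("stage regressions: ANCOVA interaction p = %.3g", anc$interaction_p)

  result <- list(tables = tables,
                 curve_fits = curve_fits,
                 gas_exchange_summary = ge_summary,
                 treatment_tables = c(ge_tabs, curve_tabs, iso_tabs),
                 water_balance = wb,
                 regressions = regressions,
                 ancova = anc)

  manifest <- list(package = "pepperphys",
                   version = as.character(utils::packageVersion("pepperphys")),
                   seed = seed,
                   mode = if (is.null(config$inputs)) "simulate" else "inputs",
                   analysis = list(alpha = alpha, pooling = pooling,
                                   lf_mode = lf_mode),
                   n_units = nrow(tables$units),
                   r_version = as.character(getRversion()))
  result$manifest <- manifest

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) utils::write.csv(
      df, file.path(outdir, name), row.names = FALSE)
    wr(flatten_treatment_tables(ge_tabs), "table1_gas_exchange.csv")
    wr(flatten_treatment_tables(curve_tabs), "table2_curve_params.csv")
    wr(flatten_treatment_tables(iso_tabs), "table3_isotopes.csv")
    wr(ge_summary, "gas_exchange_summary.csv")
    wr(curve_fits, "curve_fits.csv")
    wr(wb, "water_balance_report.csv")
    wr(regressions, "regressions.csv")
    for (nm in names(tables)) wr(tables[[nm]], paste0(nm, ".csv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("report bundle written to %s", outdir)
  }
  invisible(result)
}
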