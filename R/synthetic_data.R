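# Synthetic-experiment generator: a complete salinity x leaching-fraction pot
# experiment (design, spot gas exchange, response curves, isotope assays,
# irrigation ledger) with the statistical structure the downstream analysis
# assumes.  All randomness flows from one master seed; each table draws from
# its own deterministic child stream.

#' Experiment design configuration
#'
#' Factorial layout of the pot experiment: irrigation-water salinity levels
#' (EC_iw, dS m^-1) crossed with target leaching fractions, replicated pots,
#' spot-measurement days, and the chamber setpoints for the response curves.
#' The defaults reproduce the reference design: 3 salinities x 2 leaching
#' fractions x 4 pots (24 experimental units), spot measurements on days 23,
#' 39 and 76 after transplanting, ten PPFD setpoints from 2000 down to 0
#' umol m^-2 s^-1 and nine CO2 setpoints in the instrument's measurement
#' order.
#'
#' @param ec_levels Irrigation-water salinities (dS m^-1).
#' @param lf_levels Target leaching fractions, each in \[0, 1).
#' @param n_replicates Pots per treatment cell.
#' @param measurement_days Spot gas-exchange days (days after transplanting).
#' @param ppfd_setpoints Light-curve PPFD setpoints (umol m^-2 s^-1).
#' @param co2_setpoints CO2-curve setpoints (umol mol^-1), in measurement
#'   order (order is irrelevant to fitting).
#' @param rng_seed Master seed; every generated table derives its stream
#'   from it.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(ec_levels = c(0.9, 4.7, 7.0),
                              lf_levels = c(0.17, 0.29),
                              n_replicates = 4,
                              measurement_days = c(23, 39, 76),
                              ppfd_setpoints = c(2000, 1500, 1000, 700, 400,
                                                 200, 100, 50, 20, 0),
                              co2_setpoints = c(400, 250, 150, 100, 50,
                                                500, 700, 1000, 1500),
                              rng_seed = 20150428) {
  if (length(ec_levels) < 1 || length(lf_levels) < 1) {
    stop("factor levels must be non-empty", call. = FALSE)
  }
  if (any(lf_levels < 0) || any(lf_levels >= 1)) {
    stop("leaching fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(ppfd_setpoints < 0) || any(co2_setpoints < 0)) {
    stop("setpoints must be non-negative", call. = FALSE)
  }
  if (n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  structure(list(ec_levels = ec_levels, lf_levels = lf_levels,
                 n_replicates = as.integer(n_replicates),
                 measurement_days = measurement_days,
                 ppfd_setpoints = ppfd_setpoints,
                 co2_setpoints = co2_setpoints,
                 rng_seed = as.integer(rng_seed)),
            class = "experiment_design")
}

# Marginal treatment means anchoring the generator.  EC margins are indexed
# by salinity level, LF margins by leaching fraction; nitrogen content is
# derived as total N accumulation / leaf biomass so that per-plant
# accumulations stay internally consistent.
default_marginals <- function() {
  list(
    pn        = list(ec = c(21.2, 16.0, 13.2),    lf = c(16.9, 17.5)),
    gs        = list(ec = c(0.81, 0.41, 0.32),    lf = c(0.51, 0.56)),
    ci_ca     = list(ec = c(0.80, 0.74, 0.70),    lf = c(0.75, 0.75)),
    alpha     = list(ec = c(0.052, 0.047, 0.030), lf = c(0.045, 0.042)),
    pn_max    = list(ec = c(19.9, 15.7, 8.6),     lf = c(16.4, 14.2)),
    kappa     = list(ec = c(0.53, 0.78, 0.83),    lf = c(0.64, 0.75)),
    rd        = list(ec = c(2.07, 1.78, 1.43),    lf = c(1.68, 1.96)),
    epsilon   = list(ec = c(0.224, 0.188, 0.109), lf = c(0.179, 0.168)),
    pn_sat    = list(ec = c(61.0, 55.7, 42.8),    lf = c(52.1, 54.2)),
    rp        = list(ec = c(12.7, 11.2, 7.5),     lf = c(10.5, 10.4)),
    big_delta13c = list(ec = c(23.61, 23.04, 22.17), lf = c(22.87, 23.09)),
    c_content = list(ec = c(40.14, 38.54, 35.43), lf = c(36.71, 39.72)),
    delta15n  = list(ec = c(2.44, 2.68, 2.82),    lf = c(2.69, 2.58)),
    leaf_biomass = list(ec = c(14.3, 9.8, 7.0),   lf = c(9.6, 11.1)),
    n_content = list(ec = c(0.606 / 14.3, 0.379 / 9.8, 0.238 / 7.0) * 100,
                     lf = c(0.382 / 9.6, 0.435 / 11.1) * 100)
  )
}

default_noise_sd <- function() {
  c(pn = 1.5, gs = 0.06, ci_ca = 0.03,
    alpha = 0.004, pn_max = 1.0, kappa = 0.05, rd = 0.2,
    epsilon = 0.012, pn_sat = 3.0, rp = 0.8,
    curve_pn = 0.3,
    big_delta13c = 0.25, c_content = 1.0, delta15n = 0.15,
    leaf_biomass = 0.8, n_content = 0.25)
}

#' Generation model for the synthetic experiment
#'
#' Holds the per-cell treatment means, the per-variable Gaussian noise
#' standard deviations, and the log-linear Pn–gs link used to couple spot
#' observations.  Cell means default to an additive reconstruction from the
#' factor marginal means (salinity margin + leaching-fraction contrast around
#' its own mean), since only marginal means are available; an interaction
#' offset can be injected per variable via `interaction`.
#'
#' @param marginals Named list; each element has numeric `ec` and `lf`
#'   components giving the factor marginal means (defaults anchored to the
#'   reference experiment's treatment tables).
#' @param noise_sd Named numeric vector of Gaussian noise standard
#'   deviations; set to zero (e.g. via `noise_free()`) for exact generation.
#' @param pn_gs_slope Slope b of the Pn = a + b ln(gs) link; the intercept is
#'   set per cell so the link passes through the cell's (gs, Pn) means.
#' @param interaction Optional named list of matrices
#'   (length(ec) x length(lf)) of cell-mean offsets, one per variable.
#' @return An object of class `generation_model`.
#' @export
generation_model <- function(marginals = default_marginals(),
                             noise_sd = default_noise_sd(),
                             pn_gs_slope = 8.6,
                             interaction = list()) {
  if (any(noise_sd < 0)) stop("noise standard deviations must be >= 0",
                              call. = FALSE)
  structure(list(marginals = marginals, noise_sd = noise_sd,
                 pn_gs_slope = pn_gs_slope, interaction = interaction),
            class = "generation_model")
}

#' Zero-noise copy of a generation model
#'
#' @param model A [generation_model()].
#' @return The same model with every noise standard deviation set to zero.
#' @export
noise_free <- function(model) {
  model$noise_sd[] <- 0
  model
}

# Additive cell mean: EC margin + (LF margin - mean of LF margins), plus any
# configured interaction offset.  Reproduces the EC margins exactly and the
# LF contrast exactly.
cell_mean <- function(model, var, ec_idx, lf_idx) {
  m <- model$marginals[[var]]
  if (is.null(m)) stop("unknown generator variable: ", var, call. = FALSE)
  val <- m$ec[ec_idx] + (m$lf[lf_idx] - mean(m$lf))
  inter <- model$interaction[[var]]
  if (!is.null(inter)) val <- val + inter[ec_idx, lf_idx]
  val
}

noise_of <- function(model, var) {
  sd <- model$noise_sd[[var]]
  if (is.null(sd) || is.na(sd)) return(0)
  if (sd < 0) stop("noise standard deviation for `", var,
                   "` must be non-negative", call. = FALSE)
  sd
}

#' Generate the experimental-unit table
#'
#' One row per pot with its salinity level, target leaching fraction, and
#' block label.  Pots are assigned to blocks in a randomized-block layout
#' (one replicate of every treatment per block); the block carries no effect
#' in the default generator.
#'
#' @param design An [experiment_design()].
#' @return Data frame: `pot_id`, `ec`, `lf`, `block`, `ec_idx`, `lf_idx`.
#' @export
#' @examples
#' nrow(generate_design(experiment_design()))  # 24
generate_design <- function(design = experiment_design()) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- expand.grid(rep = seq_len(design$n_replicates),
                      lf_idx = seq_along(design$lf_levels),
                      ec_idx = seq_along(design$ec_levels))
  n <- nrow(grid)
  data.frame(pot_id = sprintf("pot%02d", seq_len(n)),
             ec = design$ec_levels[grid$ec_idx],
             lf = design$lf_levels[grid$lf_idx],
             block = grid$rep,
             ec_idx = grid$ec_idx,
             lf_idx = grid$lf_idx,
             stringsAsFactors = FALSE)
}

#' Generate spot gas-exchange observations
#'
#' One observation per pot x measurement day x leaf.  Stomatal conductance is
#' drawn around its cell mean (truncated above zero); net photosynthesis
#' follows the log-linear link Pn = a_cell + b ln(gs) plus noise, with a_cell
#' chosen so the link passes through the cell's (gs, Pn) means — in
#' noise-free mode every row reproduces the cell means exactly.  Ci is
#' Ci/Ca x Ca with ambient CO2 fixed at the 400 umol mol^-1 chamber setpoint.
#'
#' @param units Unit table from [generate_design()].
#' @param model A [generation_model()].
#' @param design The [experiment_design()] (for days and seed).
#' @param leaves_per_pot Leaves measured per pot per day (default 1).
#' @param ca Ambient CO2 (umol mol^-1, default 400).
#' @param ppfd Chamber PPFD for spot measurements (default 1200).
#' @return Data frame: `pot_id`, `ec`, `lf`, `day`, `leaf`, `pn`, `gs`,
#'   `ci`, `ca`, `ppfd`.
#' @export
generate_spot_gas_exchange <- function(units, model, design = experiment_design(),
                                       leaves_per_pot = 1, ca = 400,
                                       ppfd = 1200) {
  stopifnot(inherits(model, "generation_model"))
  days <- design$measurement_days
  set.seed(child_seed(design$rng_seed, 1L))
  rows <- expand.grid(leaf = seq_len(leaves_per_pot), day = days,
                      unit = seq_len(nrow(units)))
  n <- nrow(rows)
  u <- units[rows$unit, ]
  gs_mean <- mapply(function(i, j) cell_mean(model, "gs", i, j),
                    u$ec_idx, u$lf_idx)
  pn_mean <- mapply(function(i, j) cell_mean(model, "pn", i, j),
                    u$ec_idx, u$lf_idx)
  cc_mean <- mapply(function(i, j) cell_mean(model, "ci_ca", i, j),
                    u$ec_idx, u$lf_idx)
  if (any(gs_mean <= 0) || any(pn_mean <= 0)) {
    stop("cell means for pn and gs must be positive", call. = FALSE)
  }
  b <- model$pn_gs_slope
  gs <- rnorm_trunc(n, gs_mean, noise_of(model, "gs"), lower = 1e-4)
  a_cell <- pn_mean - b * log(gs_mean)
  pn <- a_cell + b * log(gs) + stats::rnorm(n, 0, noise_of(model, "pn"))
  ci_ca <- pmin(pmax(cc_mean + stats::rnorm(n, 0, noise_of(model, "ci_ca")),
                     0), 1.2)
  data.frame(pot_id = u$pot_id, ec = u$ec, lf = u$lf,
             day = rows$day, leaf = rows$leaf,
             pn = pn, gs = gs, ci = ci_ca * ca, ca = ca, ppfd = ppfd,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Per-unit curve parameter draws (cell mean + Gaussian noise, truncated to
# the parameter domain).
draw_curve_params <- function(units, model, kind) {
  vars <- if (kind == "light") c("alpha", "pn_max", "kappa", "rd") else
    c("epsilon", "pn_sat", "rp")
  out <- units[c("pot_id", "ec", "lf")]
  for (v in vars) {
    mu <- mapply(function(i, j) cell_mean(model, v, i, j),
                 units$ec_idx, units$lf_idx)
    lo <- if (v %in% c("rd", "rp", "kappa")) 0 else 1e-6
    x <- rnorm_trunc(nrow(units), mu, noise_of(model, v), lower = lo)
    if (v == "kappa") x <- pmin(x, 1)
    out[[v]] <- x
  }
  out
}

#' Generate response-curve measurements
#'
#' For every unit, draws a parameter set around its cell means (convexity
#' clipped to \[0, 1\], rates kept positive), evaluates the corresponding
#' model at the design's setpoints, and adds Gaussian measurement noise
#' (`noise_sd["curve_pn"]`).  With a noise-free model the measurements lie
#' exactly on the generating curve, so refitting recovers the parameters.
#'
#' @param units Unit table from [generate_design()].
#' @param model A [generation_model()].
#' @param kind `"light"` (Pn–PPFD) or `"co2"` (Pn–Ci).
#' @param design The [experiment_design()] (for setpoints and seed).
#' @return Data frame with one row per unit x setpoint: `pot_id`, `ec`,
#'   `lf`, `setpoint`, `pn`.  The generating parameters are attached as
#'   attribute `"true_params"`.
#' @export
generate_curve_data <- function(units, model, kind = c("light", "co2"),
                                design = experiment_design()) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "generation_model"))
  set.seed(child_seed(design$rng_seed, if (kind == "light") 2L else 3L))
  pars <- draw_curve_params(units, model, kind)
  setpts <- if (kind == "light") design$ppfd_setpoints else design$co2_setpoints
  sd_meas <- noise_of(model, "curve_pn")
  rows <- lapply(seq_len(nrow(pars)), function(r) {
    p <- pars[r, ]
    pn <- if (kind == "light") {
      eval_light_response(
        light_response_params(p$alpha, p$pn_max, p$kappa, p$rd), setpts)
    } else {
      eval_co2_response(
        co2_response_params(p$epsilon, p$pn_sat, p$rp), setpts)
    }
    data.frame(pot_id = p$pot_id, ec = p$ec, lf = p$lf,
               setpoint = setpts,
               pn = pn + stats::rnorm(length(setpts), 0, sd_meas),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_params") <- pars
  out
}

#' Generate the isotope and biomass assay table
#'
#' One row per pot.  The plant delta13C is generated by inverting the
#' discrimination relation at the cell-mean discrimination (source air at
#' -8 per mil), so the noise-free round trip through [big_delta13c()]
#' returns the configured cell means exactly.  Elemental accumulations are
#' content x biomass by construction.
#'
#' @param units Unit table from [generate_design()].
#' @param model A [generation_model()].
#' @param design The [experiment_design()] (for the seed).
#' @param delta_a Source-air delta13C, per mil.
#' @return Data frame: `pot_id`, `ec`, `lf`, `delta13c_permil`,
#'   `delta15n_permil`, `c_content_pct`, `n_content_pct`,
#'   `leaf_dry_biomass_g`, `total_c_g`, `total_n_g`.
#' @export
generate_isotope_table <- function(units, model, design = experiment_design(),
                                   delta_a = -8) {
  stopifnot(inherits(model, "generation_model"))
  set.seed(child_seed(design$rng_seed, 4L))
  n <- nrow(units)
  cm <- function(v) mapply(function(i, j) cell_mean(model, v, i, j),
                           units$ec_idx, units$lf_idx)
  bd <- cm("big_delta13c") + stats::rnorm(n, 0, noise_of(model, "big_delta13c"))
  c_pct <- rnorm_trunc(n, cm("c_content"), noise_of(model, "c_content"),
                       lower = 0, upper = 100)
  n_pct <- rnorm_trunc(n, cm("n_content"), noise_of(model, "n_content"),
                       lower = 0, upper = 100)
  if (any(cm("c_content") <= 0) || any(cm("c_content") >= 100) ||
      any(cm("n_content") <= 0) || any(cm("n_content") >= 100)) {
    stop("elemental contents must lie strictly within (0, 100) %DW",
         call. = FALSE)
  }
  biomass <- rnorm_trunc(n, cm("leaf_biomass"), noise_of(model, "leaf_biomass"),
                         lower = 0)
  d15n <- cm("delta15n") + stats::rnorm(n, 0, noise_of(model, "delta15n"))
  data.frame(pot_id = units$pot_id, ec = units$ec, lf = units$lf,
             delta13c_permil = invert_big_delta(bd, delta_a = delta_a),
             delta15n_permil = d15n,
             c_content_pct = c_pct,
             n_content_pct = n_pct,
             leaf_dry_biomass_g = biomass,
             total_c_g = total_accumulation(c_pct, biomass),
             total_n_g = total_accumulation(n_pct, biomass),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate the irrigation ledger
#'
#' Per pot, a season of weighing/irrigation/drainage events that are mutually
#' consistent under the weighing water balance: applied water is scheduled
#' from the interval's evapotranspiration via the leaching relation
#' (AW = ET/rho / (1 - LF), or the 1-decimal multiplier in
#' `"paper_multiplier"` mode), drainage is the surplus AW - ET/rho, and
#' successive weights satisfy the balance identity exactly, so recomputing
#' ET from the ledger returns the input trajectory.
#'
#' @param units Unit table from [generate_design()].
#' @param design The [experiment_design()] (for the seed).
#' @param n_events Irrigation events per pot over the season (default 24).
#' @param et_trajectory Per-interval evapotranspiration (g), length
#'   `n_events`; defaults to a linear seasonal ramp from 300 to 1500 g per
#'   interval.
#' @param mode Scheduling mode, `"exact"` or `"paper_multiplier"` (see
#'   [required_applied_water()]).
#' @param start_weight Pot weight before the first irrigation (g).
#' @param rho Water bulk density (g L^-1).
#' @param et_noise_sd Multiplicative log-normal-free jitter: per-event ET is
#'   perturbed by N(0, sd) g, truncated above 1 g (default 0, i.e. the
#'   trajectory is used exactly).
#' @return Data frame: `pot_id`, `ec`, `lf`, `event_index`, `w_before_g`,
#'   `w_next_g`, `applied_L`, `drainage_L`.
#' @export
generate_irrigation_ledger <- function(units, design = experiment_design(),
                                       n_events = 24,
                                       et_trajectory = NULL,
                                       mode = c("exact", "paper_multiplier"),
                                       start_weight = 12500, rho = 1000,
                                       et_noise_sd = 0) {
  mode <- match.arg(mode)
  if (is.null(et_trajectory)) {
    et_trajectory <- seq(300, 1500, length.out = n_events)
  }
  if (length(et_trajectory) != n_events) {
    stop("`et_trajectory` must have length `n_events`", call. = FALSE)
  }
  if (any(et_trajectory <= 0)) stop("`et_trajectory` must be positive",
                                    call. = FALSE)
  set.seed(child_seed(design$rng_seed, 5L))
  rows <- lapply(seq_len(nrow(units)), function(r) {
    u <- units[r, ]
    et <- rnorm_trunc(n_events, et_trajectory, et_noise_sd, lower = 1)
    aw <- required_applied_water(et, u$lf, rho = rho, mode = mode)
    dr <- aw - et / rho
    w <- numeric(n_events + 1)
    w[1] <- start_weight
    for (k in seq_len(n_events)) w[k + 1] <- w[k] - et[k] + (aw[k] - dr[k]) * rho
    data.frame(pot_id = u$pot_id, ec = u$ec, lf = u$lf,
               event_index = seq_len(n_events),
               w_before_g = w[seq_len(n_events)],
               w_next_g = w[-1],
               applied_L = aw, drainage_L = dr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic experiment
#'
#' Runs every generator off one design and model: units, spot gas exchange,
#' light and CO2 curves, isotope assays, irrigation ledger.  Deterministic
#' for a fixed `design$rng_seed`.
#'
#' @param design An [experiment_design()].
#' @param model A [generation_model()].
#' @param leaves_per_pot Leaves per pot per spot-measurement day.
#' @param lf_mode Irrigation scheduling mode (see
#'   [generate_irrigation_ledger()]).
#' @return Named list of data frames: `units`, `gas_exchange`,
#'   `light_curves`, `co2_curves`, `isotopes`, `irrigation`.
#' @export
generate_experiment <- function(design = experiment_design(),
                                model = generation_model(),
                                leaves_per_pot = 1,
                                lf_mode = "exact") {
  units <- generate_design(design)
  list(units = units,
       gas_exchange = generate_spot_gas_exchange(units, model, design,
                                                 leaves_per_pot = leaves_per_pot),
       light_curves = generate_curve_data(units, model, "light", design),
       co2_curves = generate_curve_data(units, model, "co2", design),
       isotopes = generate_isotope_table(units, model, design),
       irrigation = generate_irrigation_ledger(units, design, mode = lf_mode))
}
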