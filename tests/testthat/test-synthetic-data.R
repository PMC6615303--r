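test_that("design generation obeys the product rule and balance", {
  expect_equal(nrow(generate_design(experiment_design())), 24)
  d1 <- experiment_design(ec_levels = 1, lf_levels = 0.1, n_replicates = 1)
  expect_equal(nrow(generate_design(d1)), 1)
  d2 <- experiment_design(ec_levels = c(1, 2), lf_levels = c(0.1, 0.2, 0.3),
                          n_replicates = 5)
  u2 <- generate_design(d2)
  expect_equal(nrow(u2), 30)
  expect_true(all(table(u2$ec, u2$lf) == 5))
  # every block holds one replicate of every treatment
  expect_true(all(table(u2$block, u2$ec, u2$lf) == 1))
  expect_error(experiment_design(ec_levels = numeric(0)), "non-empty")
  expect_error(experiment_design(lf_levels = 1), "\\[0, 1\\)")
})

test_that("generation is deterministic under a fixed seed", {
  des <- experiment_design(rng_seed = 77)
  ex1 <- generate_experiment(des, generation_model())
  ex2 <- generate_experiment(des, generation_model())
  expect_identical(ex1, ex2)
  ex3 <- generate_experiment(experiment_design(rng_seed = 78),
                             generation_model())
  expect_false(identical(ex1$gas_exchange$pn, ex3$gas_exchange$pn))
})

test_that("noise-free spot gas exchange reproduces cell means exactly", {
  units <- generate_design(experiment_design())
  m <- noise_free(generation_model())
  ge <- generate_spot_gas_exchange(units, m)
  # EC marginal means equal the configured margins exactly
  expect_equal(as.numeric(tapply(ge$pn, ge$ec, mean)), c(21.2, 16.0, 13.2),
               tolerance = 1e-12)
  expect_equal(as.numeric(tapply(ge$gs, ge$ec, mean)), c(0.81, 0.41, 0.32),
               tolerance = 1e-12)
  # within a cell every row is identical (no noise)
  cell <- ge[ge$ec == 0.9 & ge$lf == 0.17, ]
  expect_equal(length(unique(cell$pn)), 1)
  # Ci is the ratio times the 400 umol/mol chamber ambient
  expect_equal(ge$ci / ge$ca, unname(ge$ci) / 400)
  expect_true(all(ge$gs > 0))
})

test_that("noisy spot means concentrate around cell means (CLT check)", {
  des <- experiment_design(n_replicates = 200, measurement_days = 1,
                           rng_seed = 9)
  units <- generate_design(des)
  m <- generation_model()
  m$noise_sd[] <- 0
  m$noise_sd["pn"] <- 1.0
  ge <- generate_spot_gas_exchange(units, m, des)
  cell <- ge[ge$ec == 0.9 & ge$lf == 0.17, ]
  expect_equal(nrow(cell), 200)
  # sd 1, n 200: sample mean within 0.2 of the cell mean (~2.8 se)
  cell_mean_pn <- 21.2 + (16.9 - mean(c(16.9, 17.5)))
  expect_lt(abs(mean(cell$pn) - cell_mean_pn), 0.2)
  m$noise_sd["pn"] <- -1
  expect_error(generate_spot_gas_exchange(units, m, des), ">= 0|non-negative")
})

test_that("noise-free curve data lie on the generating model", {
  des <- experiment_design()
  units <- generate_design(des)
  m <- noise_free(generation_model())
  lc <- generate_curve_data(units, m, "light", des)
  expect_equal(nrow(lc), 24 * 10)
  # darkness rows equal minus the cell dark respiration
  dark <- lc[lc$setpoint == 0 & lc$ec == 0.9, "pn"]
  rd_cells <- c(2.07 + (1.68 - 1.82), 2.07 + (1.96 - 1.82))
  expect_setequal(round(unique(dark), 10), round(-rd_cells, 10))
  cc <- generate_curve_data(units, m, "co2", des)
  # Ci = 0 is not a setpoint, but the fitted intercept is; check forward
  # values at the lowest setpoint against the attached true parameters
  tp <- attr(cc, "true_params")
  p1 <- tp[tp$pot_id == "pot01", ]
  want <- eval_co2_response(
    co2_response_params(p1$epsilon, p1$pn_sat, p1$rp), 50)
  expect_equal(cc$pn[cc$pot_id == "pot01" & cc$setpoint == 50], want)
  expect_error(generate_curve_data(units, m, "banana", des))
})

test_that("noise-free curves round-trip through fitting to the generating parameters", {
  des <- experiment_design()
  units <- generate_design(des)[c(1, 12, 24), ]
  m <- noise_free(generation_model())
  lc <- generate_curve_data(units, m, "light", des)
  tp <- attr(lc, "true_params")
  for (pid in units$pot_id) {
    d <- lc[lc$pot_id == pid, ]
    fit <- fit_light_response(d$setpoint, d$pn)
    truth <- tp[tp$pot_id == pid, ]
    expect_lt(rel_err(fit$params$alpha, truth$alpha), 1e-6)
    expect_lt(rel_err(fit$params$pn_max, truth$pn_max), 1e-6)
    expect_lt(rel_err(fit$params$kappa, truth$kappa), 1e-6)
    expect_lt(rel_err(fit$params$rd, truth$rd), 1e-6)
  }
})

test_that("isotope table is internally consistent and inverts discrimination", {
  des <- experiment_design()
  units <- generate_design(des)
  m <- noise_free(generation_model())
  iso <- generate_isotope_table(units, m, des)
  expect_equal(nrow(iso), 24)
  # noise-free: discrimination recomputed from delta13C equals cell means,
  # EC margins exactly
  bd <- big_delta13c(iso$delta13c_permil)
  expect_equal(as.numeric(tapply(bd, iso$ec, mean)), c(23.61, 23.04, 22.17),
               tolerance = 1e-9)
  # the 23.61 cell-mean discrimination corresponds to delta13C -30.88
  expect_equal(round_half_up(invert_big_delta(23.61), 2), -30.88)
  # accumulations are content x biomass rows, not copied marginals
  expect_equal(iso$total_c_g,
               iso$c_content_pct / 100 * iso$leaf_dry_biomass_g)
  expect_equal(iso$total_n_g,
               iso$n_content_pct / 100 * iso$leaf_dry_biomass_g)
  # zero biomass propagates to zero accumulation
  expect_equal(total_accumulation(40, 0), 0)
})

test_that("irrigation ledger has 24 events per pot and honours degenerate targets", {
  units <- generate_design(experiment_design())
  led <- generate_irrigation_ledger(units)
  expect_equal(as.integer(table(led$pot_id)), rep(24L, 24))
  # zero-leaching pots drain nothing
  u0 <- units[1, ]; u0$lf <- 0
  led0 <- generate_irrigation_ledger(u0, n_events = 5,
                                     et_trajectory = rep(500, 5))
  expect_equal(led0$drainage_L, rep(0, 5))
  expect_error(generate_irrigation_ledger(units, n_events = 3,
                                          et_trajectory = c(-1, 2, 3)),
               "positive")
})

test_that("full noise-free pipeline closes on the configured cell means", {
  res <- run_pipeline(list(simulate = list(noise_free = TRUE), seed = 1),
                      quiet = TRUE)
  sm <- res$gas_exchange_summary
  ec <- sm[sm$factor == "ec", ]
  expect_equal(ec$pn[order(as.numeric(ec$level))], c(21.2, 16.0, 13.2),
               tolerance = 1e-9)
  expect_equal(ec$gs[order(as.numeric(ec$level))], c(0.81, 0.41, 0.32),
               tolerance = 1e-9)
  # fitted curve parameters reproduce the configured EC margins
  cf <- res$curve_fits
  expect_equal(as.numeric(tapply(cf$pn_max, cf$ec, mean)), c(19.9, 15.7, 8.6),
               tolerance = 1e-6)
  expect_equal(as.numeric(tapply(cf$pn_sat, cf$ec, mean)), c(61.0, 55.7, 42.8),
               tolerance = 1e-6)
})
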