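# Shared fixtures: the three salinity-level parameter rows of the reference
# experiment's curve tables, and the chamber setpoints.

light_rows <- list(
  ec0.9 = list(alpha = 0.052, pn_max = 19.9, kappa = 0.53, rd = 2.07),
  ec4.7 = list(alpha = 0.047, pn_max = 15.7, kappa = 0.78, rd = 1.78),
  ec7.0 = list(alpha = 0.030, pn_max = 8.6, kappa = 0.83, rd = 1.43)
)

co2_rows <- list(
  ec0.9 = list(epsilon = 0.224, pn_sat = 61.0, rp = 12.7),
  ec4.7 = list(epsilon = 0.188, pn_sat = 55.7, rp = 11.2),
  ec7.0 = list(epsilon = 0.109, pn_sat = 42.8, rp = 7.5)
)

ppfd_setpoints <- c(2000, 1500, 1000, 700, 400, 200, 100, 50, 20, 0)
co2_setpoints <- c(400, 250, 150, 100, 50, 500, 700, 1000, 1500)

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Literal printed form of the non-rectangular hyperbola (divides by 2*kappa);
# used as the comparison form in stable-form tests.
nrh_literal <- function(alpha, pn_max, kappa, rd, q) {
  s <- alpha * q + pn_max
  (s - sqrt(s^2 - 4 * kappa * alpha * q * pn_max)) / (2 * kappa) - rd
}

# Brute-force OLS via normal equations, independent of lm().
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}
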