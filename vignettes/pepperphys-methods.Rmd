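---
title: "Models and methods in pepperphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pepperphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepperphys)
```

`pepperphys` analyses factorial pot experiments in which hot pepper
(*Capsicum annuum*) is irrigated with saline water at several salinities
(EC~iw~, dS m^-1^) under different target leaching fractions (LF).  This
vignette documents the models, the numerical choices, and the synthetic-data
generator that makes the whole pipeline testable without field data.

## Photosynthesis models

**Light response.**  Net photosynthesis versus PPFD (*Q*) follows the
non-rectangular hyperbola

$$P_n(Q) = \frac{\alpha Q + P_{n\,max} -
  \sqrt{(\alpha Q + P_{n\,max})^2 - 4\kappa\,\alpha Q\,P_{n\,max}}}{2\kappa}
  - R_d,$$

with apparent quantum yield $\alpha$ (mol CO~2~ mol^-1^ photons),
irradiance-saturated gross rate $P_{n\,max}$ (µmol m^-2^ s^-1^), convexity
$\kappa \in [0,1]$ and dark respiration $R_d$.  $\kappa$ interpolates
between a rectangular hyperbola ($\kappa = 0$) and a Blackman two-line
response ($\kappa = 1$).

The printed form divides by $2\kappa$ and subtracts two nearly equal terms
at low $Q$, so `eval_light_response()` evaluates the algebraically
equivalent conjugate form

$$P_n(Q) = \frac{2\,\alpha Q\,P_{n\,max}}
  {(\alpha Q + P_{n\,max}) + \sqrt{(\alpha Q + P_{n\,max})^2 -
   4\kappa\,\alpha Q\,P_{n\,max}}} - R_d,$$

which is free of cancellation and continuous through $\kappa \to 0$.  The
test suite checks agreement with the literal form to $10^{-10}$ relative
wherever the literal form is well conditioned, and both limits exactly.

**CO~2~ response.**  Net photosynthesis versus intercellular CO~2~ ($C_i$)
uses

$$P_n(C_i) = \frac{\varepsilon\,P_{n\,sat}\,C_i}
  {\varepsilon\,C_i + P_{n\,sat}} - R_p,$$

with carboxylation efficiency $\varepsilon$ (the initial slope),
photosynthetic capacity $P_{n\,sat}$, and photorespiration rate $R_p$.
Algebraically this is a rectangular hyperbola offset by $R_p$; we implement
it exactly as written.  The compensation point
$C_i^* = R_p P_{n\,sat} / (\varepsilon(P_{n\,sat} - R_p))$ is provided as a
derived quantity.

**Fitting.**  Both curves are fit by bounded Levenberg–Marquardt least
squares (`minpack.lm::nlsLM`) with tolerances of $10^{-15}$ on cost and
parameters and at most 500 iterations.  Starting values are data-driven and
reproducible: the initial slope from an OLS line through the three lowest
nonzero setpoints, the respiration offset from the measurement in darkness
(or the OLS intercept), the asymptote from the observed maximum plus the
respiration offset, and $\kappa_0 = 0.8$.  Bounds keep $\kappa \in [0,1]$
hard and the remaining parameters positive with loose upper bounds at ten
times the data-implied scale; the source experiment did not state its
constraint scheme, so we fix our own and document it here.  Measurement
order is irrelevant — the nine CO~2~ setpoints are visited in the
instrument's non-monotone order (400, 250, ..., 1500) and treated as i.i.d.
points.  Degenerate inputs (constant response, fewer points than parameters
plus one) are rejected with an error; non-convergence is reported through
the `converged` flag, never silently.

## Isotope metrics

Carbon and nitrogen isotope compositions follow the standard ratio
definitions, $\delta = (R_{sample}/R_{standard} - 1) \times 1000$‰, against
PDB for carbon and atmospheric N~2~ (0.3663 at% ^15^N, stored as the
fraction 0.003663) for nitrogen.  Discrimination of leaf material against
^13^C is

$$\Delta^{13}C = \frac{\delta_a - \delta_p}{1 + \delta_p},$$

with source air $\delta_a = -8$‰ by default.  This expression is only
dimensionally coherent when the deltas are fractions; `big_delta13c()`
therefore converts per-mil inputs to fractions internally and returns
per-mil.  A literal per-mil denominator $(1 + \delta_p)$ would shrink leaf
values roughly 25-fold, and a test asserts that this wrong reading is far
from the correct ~23‰ scale.  Elemental accumulation is content/100 ×
dry biomass, computed per plant and aggregated afterwards — products of
marginal means need not equal means of per-plant products, which is why a
reconstructed table can differ in the second decimal from a published one.

## Water balance and leaching

For each inter-irrigation interval, evapotranspiration is obtained from pot
weighings:

$$ET = W_n - W_{n+1} + (AW - D)\,\rho,$$

with $W$ the pot weights just before consecutive irrigations (g), $AW$
applied water, $D$ drainage (L), and $\rho = 1000$ g L^-1^.  Weights are
taken just before each irrigation event.  Scheduling follows
$AW/ET = 1/(1 - LF)$.  Two modes are provided: `"exact"` applies the exact
multiplier (1.2048 for LF 0.17, 1.4085 for 0.29), while
`"paper_multiplier"` applies the factor rounded to one decimal (120% and
140% of ET), the form used when irrigating by hand.  The rounded factors
imply actual leaching fractions of 0.1667 and 0.2857 — the latter sits
visibly below the nominal 0.29 target, which is how a season can end with
an actual LF near 0.27 against a 0.29 target; reports surface both numbers
rather than reconciling them.  Reported LFs are rounded half-up to two
decimals, matching presentation conventions.  Negative interval ET can
arise from weighing noise; it is flagged in reports, never clipped.

## Gas-exchange metrics

Intrinsic water-use efficiency is $P_n/g_s$.  Because $P_n/g_s$ and $g_s$
are negatively associated under stomatal closure, the mean of
per-observation ratios systematically exceeds the ratio of treatment means;
published factorial tables are consistent with the former, so summaries
default to mean-of-ratios but always report both aggregations side by side.
Percent reductions between treatments are computed from treatment means and
rounded half-up to one decimal.  The pooled $P_n$–$g_s$ relationship is fit
as $P_n = a + b\,\ln g_s$ by OLS.

## Factorial statistics

The treatment layer mirrors the standard agronomic workflow: a balanced
two-way fixed-effects ANOVA (EC~iw~ × LF with interaction; type I and
type III coincide under balance, and unbalanced data are rejected rather
than silently switching SS types), Duncan's multiple range test for the
letter displays, and ANCOVA for slope homogeneity of $P_n$ on $\ln g_s$.
Duncan's critical value for a range of $p$ ordered means uses the
studentized-range quantile at the protection level
$\alpha_p = 1 - (1 - \alpha)^{p-1}$; ranges contained in a larger
homogeneous range are not retested, and letters are assigned to the maximal
homogeneous ranges in order of descending mean starting at "a".  The
block label of the randomized-block layout is generated but carries no
effect and is not included in the ANOVA by default, matching the analysis
the treatment tables describe (only EC~iw~, LF and their interaction);
significance stars map *, **, *** to p < 0.05, 0.01, 0.001.

Spot gas exchange is measured on three days; the default analysis averages
the days per pot before testing (24 experimental units, 18 error df), since
days on the same pot are not independent replicates.  A `"pool"` mode that
treats every observation as a replicate is available for comparison.

## The synthetic-data generator

The generator emulates the reference design: 3 EC~iw~ levels (0.9, 4.7,
7.0 dS m^-1^) × 2 LFs (0.17, 0.29) × 4 pots, spot measurements at 23, 39
and 76 days after transplanting at PPFD 1200 and ambient CO~2~
400 µmol mol^-1^, light curves at PPFD 2000, 1500, 1000, 700, 400, 200,
100, 50, 20, 0 and CO~2~ curves at 400, 250, 150, 100, 50, 500, 700, 1000,
1500 µmol mol^-1^, and 24 irrigation events per pot.

Only factor **marginal** means are available from the reference treatment
tables, so cell means default to an additive reconstruction: the EC margin
plus the LF margin's contrast about its own mean.  This reproduces the EC
margins and the LF contrast exactly; because the two sets of printed
margins disagree slightly in their grand means (rounding), the absolute LF
margins are offset by that small constant.  The reconstruction is unbiased
by construction and an `interaction` hook lets users inject the
LF × EC~iw~ interaction that marginal means cannot encode.  Noise is
independent Gaussian per variable, truncated where positivity is required
($g_s$, biomass, rates) and with $\kappa$ clipped to $[0,1]$; default
standard deviations are set to plausible leaf-to-leaf and pot-to-pot
spreads (e.g. 1.5 µmol m^-2^ s^-1^ for $P_n$, 0.06 mol m^-2^ s^-1^ for
$g_s$, 0.3 µmol m^-2^ s^-1^ for curve residuals).  Spot $P_n$ is generated
through the link $P_n = a_{cell} + b \ln g_s$ (default $b = 8.6$, the slope
implied by the salinity margins) so pooled data show the characteristic
logarithmic $P_n$–$g_s$ relationship; $a_{cell}$ is chosen so the link
passes through each cell's means, making noise-free generation reproduce
them exactly.  Plant $\delta^{13}$C is generated by inverting the
discrimination relation at the cell-mean $\Delta^{13}$C, and accumulations
are per-plant products, so every downstream identity closes.  The
irrigation ledger is built so the weighing balance holds exactly at every
event (drainage is the scheduled surplus), making the season's telescoping
closure and the construction inverse (`compute_et()` returning the input
trajectory) exact.

One master seed (`rng_seed`) drives everything; each table uses a
deterministically derived child seed, so tables are independent but the
whole experiment is bit-for-bit reproducible.  What the generator does
*not* emulate: within-canopy leaf heterogeneity, soil-salinity dynamics and
their feedback on ET, weather-driven ET variation, or non-Gaussian
measurement error.  Passing tests therefore demonstrate the correctness of
the estimators and their plumbing, not robustness to every feature of real
field data.

## Problem sizes and determinism

Simulation-based tests use sizes that make sampling error negligible
relative to their tolerances while keeping runs short: 200 replicate noisy
curve fits for the bias checks, 1000 simulated null datasets for the
ANOVA type-I-error check (binomial tolerance 0.035–0.065 at nominal 0.05),
and 200 pots per cell for the central-limit check on generated means.  All
are fixed-seed.  `run_pipeline()` records seed, options and versions in a
manifest; the same config and seed reproduce a byte-identical report
bundle.

## Known limitations

* Cell means reconstructed from marginal means cannot recover a true
  LF × EC~iw~ interaction; the default generator is additive.
* The ANOVA layer is balanced-only by design; unbalanced field data would
  need a different SS strategy than this package intends to offer.
* Duncan's test controls its classical protection levels, not the
  familywise error rate; it is provided because it is the convention in
  this literature, not because it is the most conservative choice.
* The CO~2~-response model is empirical; it does not partition limitations
  mechanistically (no V~cmax~/J~max~), and mesophyll conductance is ignored.
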