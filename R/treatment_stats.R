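# Factorial statistics: two-way fixed-effects ANOVA, Duncan's multiple range
# test with compact letter display, ANCOVA slope-homogeneity, and simple
# regression summaries.

check_balanced <- function(a, b, min_rep = 2) {
  tab <- table(a, b)
  if (any(tab == 0)) stop("empty design cells: balanced designs only",
                          call. = FALSE)
  if (length(unique(as.vector(tab))) != 1) {
    stop("unbalanced design: this analysis is restricted to balanced data",
         call. = FALSE)
  }
  if (tab[1] < min_rep) stop(sprintf("need at least %d replicates per cell",
                                     min_rep), call. = FALSE)
  invisible(as.vector(tab)[1])
}

#' Two-way fixed-effects ANOVA
#'
#' Factorial analysis of variance for a balanced two-factor design with
#' interaction (type I and type III sums of squares coincide under balance).
#' Unbalanced data are rejected rather than silently switching SS types.
#'
#' @param response Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible), same length as
#'   `response`.
#' @param names_ab Length-2 character: labels for the two factors in the
#'   output (default `c("A", "B")`).
#' @return Data frame with rows A, B, A:B, Residuals and columns `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p_value`, `stars`.
#' @export
two_way_anova <- function(response, factor_a, factor_b,
                          names_ab = c("A", "B")) {
  stop_if_not_number(response, "response")
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (length(a) != length(response) || length(b) != length(response)) {
    stop("factor lengths must match the response", call. = FALSE)
  }
  check_balanced(a, b)
  fit <- stats::aov(response ~ a * b)
  tab <- summary(fit)[[1]]
  term <- c(names_ab[1], names_ab[2],
            paste(names_ab[1], names_ab[2], sep = ":"), "Residuals")
  out <- data.frame(term = term,
                    df = tab[["Df"]],
                    sumsq = tab[["Sum Sq"]],
                    meansq = tab[["Mean Sq"]],
                    statistic = tab[["F value"]],
                    p_value = tab[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  out$stars <- p_stars(out$p_value)
  out
}

#' Duncan's multiple range test
#'
#' Stepwise range procedure on a set of treatment means sharing a pooled
#' error.  For a range spanning p ordered means the critical value uses the
#' studentized-range distribution at Duncan's protection level
#' \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}}:
#' \eqn{R_p = q_{1-\alpha_p}(p, df) \sqrt{MS_E/n}}.  A range is declared
#' homogeneous if its extremes differ by at most \eqn{R_p} or if it is
#' contained in a larger homogeneous range (the usual protection rule).
#' Letters are assigned to the maximal homogeneous ranges, in order of
#' descending mean, starting at "a".
#'
#' @param means Named numeric vector of group means.
#' @param ms_error Pooled error mean square from the ANOVA.
#' @param df_error Error degrees of freedom, > 0.
#' @param n_per_group Common group size (equal sizes required).
#' @param alpha Comparisonwise significance level (default 0.05).
#' @return Data frame (`level`, `mean`, `letters`), ordered by descending
#'   mean; groups sharing any letter are not significantly different.
#' @export
#' @examples
#' duncan_mrt(c(low = 21.2, mid = 16.0, high = 13.2),
#'            ms_error = 1.5, df_error = 18, n_per_group = 8)
duncan_mrt <- function(means, ms_error, df_error, n_per_group, alpha = 0.05) {
  stop_if_not_number(means, "means")
  stop_if_not_number(ms_error, "ms_error", nonneg = TRUE)
  if (df_error <= 0) stop("`df_error` must be positive", call. = FALSE)
  if (length(n_per_group) != 1 || n_per_group < 1) {
    stop("`n_per_group` must be a single common group size (equal sizes only)",
         call. = FALSE)
  }
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("group", seq_len(k))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]

  nonsig <- diag(TRUE, k)
  if (k >= 2) {
    for (span in k:2) {
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        contained <- FALSE
        if (span < k) {
          for (i2 in seq_len(i)) for (j2 in j:k) {
            if ((i2 < i || j2 > j) && nonsig[i2, j2]) contained <- TRUE
          }
        }
        if (contained) {
          nonsig[i, j] <- TRUE
        } else {
          a_p <- 1 - (1 - alpha)^(span - 1)
          r_p <- stats::qtukey(1 - a_p, span, df_error) *
            sqrt(ms_error / n_per_group)
          nonsig[i, j] <- (m[i] - m[j]) <= r_p
        }
      }
    }
  }

  # maximal homogeneous ranges -> compact letter display
  ranges <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if (nonsig[i, j]) {
      maximal <- !any(vapply(seq_len(k), function(i2) {
        any(vapply(seq_len(k), function(j2) {
          i2 <= i && j2 >= j && (i2 < i || j2 > j) && nonsig[i2, j2]
        }, logical(1)))
      }, logical(1)))
      if (maximal) ranges[[length(ranges) + 1]] <- c(i, j)
    }
  }
  ranges <- unique(ranges)
  ranges <- ranges[order(vapply(ranges, `[`, numeric(1), 1),
                         vapply(ranges, `[`, numeric(1), 2))]
  lett <- character(k)
  for (r in seq_along(ranges)) {
    idx <- ranges[[r]][1]:ranges[[r]][2]
    lett[idx] <- paste0(lett[idx], letters[r])
  }
  data.frame(level = names(m), mean = unname(m), letters = lett,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ANCOVA slope-homogeneity test for Pn vs ln(gs)
#'
#' Fits the general linear model Pn ~ group + ln(gs) + group:ln(gs) and tests
#' the group-by-covariate interaction; a non-significant interaction supports
#' a common slope, in which case the additive model is refit and its slope
#' reported.
#'
#' @param pn Net photosynthesis values.
#' @param gs Stomatal conductance values, > 0.
#' @param group Grouping factor (e.g. salinity level), >= 3 points per group.
#' @param alpha Level used to decide whether to adopt the common slope.
#' @return List with `slopes` (per group), `common_slope`,
#'   `interaction_f`, `interaction_p`, `interaction_df`, `common_slope_adopted`,
#'   and the full and additive `lm` fits.
#' @export
ancova_slope_test <- function(pn, gs, group, alpha = 0.05) {
  stop_if_not_number(pn, "pn")
  stop_if_not_number(gs, "gs", positive = TRUE)
  g <- factor(group)
  if (length(pn) != length(gs) || length(pn) != length(g)) {
    stop("input lengths differ", call. = FALSE)
  }
  if (any(table(g) < 3)) stop("need at least 3 observations per group",
                              call. = FALSE)
  x <- log(gs)
  if (any(tapply(x, g, stats::sd) == 0)) {
    stop("singular design: no covariate variation within a group",
         call. = FALSE)
  }
  full <- stats::lm(pn ~ g * x)
  additive <- stats::lm(pn ~ g + x)
  atab <- stats::anova(additive, full)
  f_int <- atab$F[2]
  p_int <- atab$`Pr(>F)`[2]

  cf <- stats::coef(full)
  base_slope <- cf[["x"]]
  lv <- levels(g)
  slopes <- stats::setNames(rep(base_slope, length(lv)), lv)
  for (l in lv[-1]) {
    nm <- paste0("g", l, ":x")
    if (nm %in% names(cf)) slopes[l] <- base_slope + cf[[nm]]
  }
  list(slopes = slopes,
       common_slope = unname(stats::coef(additive)[["x"]]),
       interaction_ss = atab$`Sum of Sq`[2],
       interaction_f = f_int,
       interaction_p = p_int,
       interaction_df = c(atab$Df[2], atab$Res.Df[2]),
       common_slope_adopted = !is.na(p_int) && p_int >= alpha,
       fit_full = full, fit_additive = additive)
}

#' Simple linear regression with R-squared
#'
#' OLS of y on x with the two-sided t-test on the slope; the workhorse for
#' trait-vs-salinity and trait-vs-trait correlations.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`, `fit`.
#' @export
linear_regression_r2 <- function(x, y) {
  stop_if_not_number(x, "x")
  stop_if_not_number(y, "y")
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in `x`", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = if (sm$sigma == 0) 0 else sm$coefficients[2, 4],
       n = length(x),
       fit = fit)
}

#' Factorial treatment table for one response
#'
#' Convenience wrapper reproducing the layout of a factorial treatment-mean
#' table: marginal means with Duncan letters per factor (letters from the
#' two-way ANOVA's pooled error), plus the ANOVA star codes.
#'
#' @param data Data frame containing the response and the factors.
#' @param response Name of the response column.
#' @param factor_a,factor_b Names of the two factor columns (default
#'   `"ec"`, `"lf"`).
#' @param alpha Level for the Duncan letters.
#' @param pooling For repeated spot measurements: `"average"` first averages
#'   the response per experimental unit (column `pot_id`) before testing;
#'   `"pool"` uses every row as a replicate.
#' @return List with `anova` (the [two_way_anova()] table), `means_a`,
#'   `means_b` (marginal means with letters), and `stars` named by term.
#' @export
treatment_table <- function(data, response, factor_a = "ec", factor_b = "lf",
                            alpha = 0.05, pooling = c("average", "pool")) {
  pooling <- match.arg(pooling)
  stopifnot(is.data.frame(data))
  need <- c(response, factor_a, factor_b)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (pooling == "average" && "pot_id" %in% names(data) &&
      anyDuplicated(data$pot_id)) {
    agg <- stats::aggregate(data[[response]],
                            by = list(pot_id = data$pot_id,
                                      a = data[[factor_a]],
                                      b = data[[factor_b]]),
                            FUN = mean)
    y <- agg$x; a <- agg$a; b <- agg$b
  } else {
    y <- data[[response]]; a <- data[[factor_a]]; b <- data[[factor_b]]
  }
  an <- two_way_anova(y, a, b, names_ab = c(factor_a, factor_b))
  mse <- an$meansq[an$term == "Residuals"]
  dfe <- an$df[an$term == "Residuals"]
  letters_for <- function(f) {
    mm <- tapply(y, factor(f), mean)
    n_g <- length(y) / length(mm)
    duncan_mrt(mm, ms_error = mse, df_error = dfe, n_per_group = n_g,
               alpha = alpha)
  }
  list(anova = an,
       means_a = letters_for(a),
       means_b = letters_for(b),
       stars = stats::setNames(an$stars[1:3], an$term[1:3]))
}
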