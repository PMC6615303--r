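# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; treatment tables in this field are
#' conventionally presented with half-up rounding, so reported quantities
#' (leaching fractions, percent reductions) go through this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed from a master seed, so each generated table gets
# its own stream without coupling.  Kept below 2^31 - 1.
child_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + offset * 7919) %%
               2147483647)
}

# Gaussian draw truncated below (rejection sampling; the generator means sit
# many sd above the bound, so resampling terminates immediately in practice).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("noise standard deviation must be non-negative")
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

stop_if_not_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric and non-missing", name), call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  if (nonneg && any(x < 0)) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

#' Significance star codes
#'
#' Maps p-values to the star convention used in the treatment tables:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `NS` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  out <- rep("NS", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
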