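## Small shared helpers.

#' Logit and inverse-logit transforms
#'
#' Thin wrappers around [stats::qlogis()] and [stats::plogis()] used
#' throughout the modelling code. Prevalences are clamped to
#' `[floor, 1 - floor]` before the logit so that boundary observations do not
#' map to infinity.
#'
#' @param p proportions in `[0, 1]`.
#' @param x values on the logit scale.
#' @param floor clamping floor applied before transforming, default `1e-7`.
#' @return numeric vector.
#' @keywords internal
logit <- function(p, floor = 1e-7) {
  stats::qlogis(pmin(pmax(p, floor), 1 - floor))
}

#' @rdname logit
#' @keywords internal
inv_logit <- function(x) stats::plogis(x)

## Clamp a vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Sample-size-safe variance (n - 1 normalisation, NA for n < 2).
var_n1 <- function(x) if (length(x) < 2) NA_real_ else stats::var(x)

## Draw one Dirichlet(1) vector of length k (uniform on the simplex).
rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1, rate = 1)
  g / sum(g)
}

## Percentile summary used for 1000-draw uncertainty intervals.
draw_summary <- function(x, probs = c(0.025, 0.975), center = c("mean", "median")) {
  center <- match.arg(center)
  q <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
  c(if (center == "mean") mean(x) else stats::median(x), q[1], q[2])
}

## Stable cell key used to align data frames on the estimation grid.
cell_key <- function(df, cols = c("location_id", "year", "age_group", "sex")) {
  do.call(paste, c(unname(df[cols]), list(sep = "|")))
}

## The six GBD under-5 age bins, youngest first. The integer rank order is
## what the age-similarity weight in the spatiotemporal smoother uses.
AGE_GROUPS <- c("0-6d", "7-27d", "1-5m", "6-11m", "12-23m", "2-4y")

SEXES <- c("male", "female")

age_rank <- function(age_group) {
  r <- match(age_group, AGE_GROUPS)
  if (anyNA(r)) stop("unknown age group: ", paste(unique(age_group[is.na(r)]), collapse = ", "))
  r
}
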