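## The ten component distribution families of the z-score ensemble, each
## parameterised by method of moments from a common (mean, variance) pair.
##
## Conventions:
##   * normal and Gumbel act directly on the z-score scale (full real support).
##   * positive-support families (log-normal, log-logistic, exponential,
##     gamma, inverse gamma, Weibull) are fit to the shifted variable
##     w = z + shift, with moments (mean + shift, variance).
##   * mirrored families (mirrored gamma, mirrored Gumbel) are fit to
##     w = mirror_anchor - z, with moments (mirror_anchor - mean, variance),
##     so they contribute a left-skewed shape on the z scale.

EULER_GAMMA <- 0.57721566490153286

FAMILY_NAMES <- c(
  "normal", "log_normal", "log_logistic", "exponential", "gamma",
  "mirrored_gamma", "inverse_gamma", "gumbel", "mirrored_gumbel", "weibull"
)

## Families needing a positive shifted mean / positive mirrored mean.
POSITIVE_FAMILIES <- c("log_normal", "log_logistic", "exponential", "gamma",
                       "inverse_gamma", "weibull")
MIRRORED_FAMILIES <- c("mirrored_gamma", "mirrored_gumbel")

## --- Gumbel and inverse-gamma primitives (closed form) ---------------------

dgumbel_ <- function(x, loc, scale) {
  z <- (x - loc) / scale
  exp(-z - exp(-z)) / scale
}
pgumbel_ <- function(q, loc, scale) exp(-exp(-(q - loc) / scale))
rgumbel_ <- function(n, loc, scale) loc - scale * log(-log(stats::runif(n)))

## X ~ InvGamma(shape, scale) in the e^{-scale/x} parameterisation;
## 1/X ~ Gamma(shape, rate = scale).
dinvgamma_ <- function(x, shape, scale) {
  out <- numeric(length(x))
  ok <- x > 0
  out[ok] <- exp(shape * log(scale) - lgamma(shape) -
                   (shape + 1) * log(x[ok]) - scale / x[ok])
  out
}
pinvgamma_ <- function(q, shape, scale) {
  out <- numeric(length(q))
  ok <- q > 0
  out[ok] <- stats::pgamma(1 / q[ok], shape = shape, rate = scale,
                           lower.tail = FALSE)
  out
}
rinvgamma_ <- function(n, shape, scale) 1 / stats::rgamma(n, shape = shape, rate = scale)

## --- Shape solvers for the two families without closed-form moments --------
##
## Weibull and log-logistic shapes are monotone in the squared coefficient of
## variation; we invert with a precomputed monotone spline (built lazily,
## cached in the package namespace) and polish with uniroot, which keeps the
## solve cheap inside the SD-optimisation hot loop.

.shape_cache <- new.env(parent = emptyenv())

weibull_cv2 <- function(k) expm1(lgamma(1 + 2 / k) - 2 * lgamma(1 + 1 / k))

llogis_cv2 <- function(b) {
  th <- pi / b
  m1 <- th / sin(th)
  m2 <- 2 * th / sin(2 * th)
  m2 / m1^2 - 1
}

.shape_spline <- function(which) {
  key <- paste0("spline_", which)
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  if (which == "weibull") {
    lk <- seq(log(0.12), log(400), length.out = 800)
    lc <- log(weibull_cv2(exp(lk)))
  } else {
    lk <- seq(log(1e-5), log(5000), length.out = 800)  # log(b - 2)
    lc <- log(llogis_cv2(2 + exp(lk)))
  }
  ## cv2 decreases in shape, so reverse for an increasing interpolant
  f <- stats::splinefun(rev(lc), rev(lk), method = "monoH.FC")
  .shape_cache[[key]] <- f
  f
}

.solve_shape <- function(cv2, which) {
  fun <- if (which == "weibull") weibull_cv2 else function(b) llogis_cv2(2 + b)
  g <- function(l) log(fun(exp(l))) - log(cv2)
  ## spline estimate + secant polish (log(cv2) is smooth and monotone in
  ## log(shape), so 3-4 secant steps reach ~1e-12)
  x0 <- .shape_spline(which)(log(cv2))
  x1 <- x0 + 1e-4
  f0 <- g(x0); f1 <- g(x1)
  for (i in 1:8) {
    if (!is.finite(f0) || !is.finite(f1) || f1 == f0) break
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    x0 <- x1; f0 <- f1
    x1 <- x2; f1 <- g(x2)
    if (abs(f1) < 1e-13) break
  }
  if (!is.finite(x1) || abs(f1) > 1e-6) {
    r <- stats::uniroot(g, interval = c(x1 - 2, x1 + 2), extendInt = "yes",
                        tol = 1e-12)
    x1 <- r$root
  }
  exp(x1)
}

weibull_shape <- function(cv2) .solve_shape(cv2, "weibull")
llogis_shape <- function(cv2) 2 + .solve_shape(cv2, "llogis")

## --- Method-of-moments parameter solves, per family ------------------------
##
## `m` and `v` are already on the family's own scale (shifted or mirrored).
## Each returns a named numeric vector, or NULL when the moments are
## infeasible for the family.

.mom_solve <- function(family, m, v) {
  if (!is.finite(m) || !is.finite(v) || v <= 0) return(NULL)
  switch(family,
    normal = c(mean = m, sd = sqrt(v)),
    gumbel = {
      s <- sqrt(6 * v) / pi
      c(loc = m - EULER_GAMMA * s, scale = s)
    },
    log_normal = {
      if (m <= 0) return(NULL)
      s2 <- log1p(v / m^2)
      c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    log_logistic = {
      if (m <= 0) return(NULL)
      b <- llogis_shape(v / m^2)
      th <- pi / b
      c(shape = b, scale = m * sin(th) / th)
    },
    exponential = {
      if (m <= 0) return(NULL)
      c(rate = 1 / m)  # one-parameter family: matches the mean only
    },
    gamma = ,
    mirrored_gamma = {
      if (m <= 0) return(NULL)
      c(shape = m^2 / v, rate = m / v)
    },
    inverse_gamma = {
      if (m <= 0) return(NULL)
      a <- m^2 / v + 2
      c(shape = a, scale = m * (a - 1))
    },
    mirrored_gumbel = {
      if (m <= 0) return(NULL)
      s <- sqrt(6 * v) / pi
      c(loc = m - EULER_GAMMA * s, scale = s)
    },
    weibull = {
      if (m <= 0) return(NULL)
      k <- weibull_shape(v / m^2)
      c(shape = k, scale = exp(log(m) - lgamma(1 + 1 / k)))
    },
    stop("unknown family: ", family)
  )
}

## Moments on the family's own scale given z-scale mean/variance.
.family_scale_mean <- function(family, mean_z, shift, anchor) {
  if (family %in% POSITIVE_FAMILIES) mean_z + shift
  else if (family %in% MIRRORED_FAMILIES) anchor - mean_z
  else mean_z
}

## CDF of the family's z-scale contribution at z-scale points `t`.
.family_cdf <- function(family, par, t, shift, anchor) {
  switch(family,
    normal = stats::pnorm(t, par[["mean"]], par[["sd"]]),
    gumbel = pgumbel_(t, par[["loc"]], par[["scale"]]),
    log_normal = stats::plnorm(t + shift, par[["meanlog"]], par[["sdlog"]]),
    log_logistic = flexsurv::pllogis(pmax(t + shift, 0), shape = par[["shape"]],
                                     scale = par[["scale"]]),
    exponential = stats::pexp(pmax(t + shift, 0), rate = par[["rate"]]),
    gamma = stats::pgamma(pmax(t + shift, 0), shape = par[["shape"]], rate = par[["rate"]]),
    inverse_gamma = pinvgamma_(t + shift, par[["shape"]], par[["scale"]]),
    weibull = stats::pweibull(pmax(t + shift, 0), shape = par[["shape"]],
                              scale = par[["scale"]]),
    mirrored_gamma = stats::pgamma(pmax(anchor - t, 0), shape = par[["shape"]],
                                   rate = par[["rate"]], lower.tail = FALSE),
    mirrored_gumbel = 1 - pgumbel_(anchor - t, par[["loc"]], par[["scale"]]),
    stop("unknown family: ", family)
  )
}

## Density of the family's z-scale contribution at z-scale points `x`.
## Points outside a family's support contribute exactly zero density.
.family_pdf <- function(family, par, x, shift, anchor) {
  if (family %in% c("normal", "gumbel", "mirrored_gumbel")) {
    return(switch(family,
      normal = stats::dnorm(x, par[["mean"]], par[["sd"]]),
      gumbel = dgumbel_(x, par[["loc"]], par[["scale"]]),
      mirrored_gumbel = dgumbel_(anchor - x, par[["loc"]], par[["scale"]])))
  }
  out <- numeric(length(x))
  if (family == "mirrored_gamma") {
    ok <- x < anchor
    out[ok] <- stats::dgamma(anchor - x[ok], shape = par[["shape"]],
                             rate = par[["rate"]])
    return(out)
  }
  w <- x + shift
  ok <- w > 0
  out[ok] <- switch(family,
    log_normal = stats::dlnorm(w[ok], par[["meanlog"]], par[["sdlog"]]),
    log_logistic = flexsurv::dllogis(w[ok], shape = par[["shape"]],
                                     scale = par[["scale"]]),
    exponential = stats::dexp(w[ok], rate = par[["rate"]]),
    gamma = stats::dgamma(w[ok], shape = par[["shape"]], rate = par[["rate"]]),
    inverse_gamma = dinvgamma_(w[ok], par[["shape"]], par[["scale"]]),
    weibull = stats::dweibull(w[ok], shape = par[["shape"]],
                              scale = par[["scale"]]),
    stop("unknown family: ", family)
  )
  out
}

## Random draws from the family on the z scale.
.family_rng <- function(family, par, n, shift, anchor) {
  switch(family,
    normal = stats::rnorm(n, par[["mean"]], par[["sd"]]),
    gumbel = rgumbel_(n, par[["loc"]], par[["scale"]]),
    log_normal = stats::rlnorm(n, par[["meanlog"]], par[["sdlog"]]) - shift,
    log_logistic = flexsurv::rllogis(n, shape = par[["shape"]], scale = par[["scale"]]) - shift,
    exponential = stats::rexp(n, rate = par[["rate"]]) - shift,
    gamma = stats::rgamma(n, shape = par[["shape"]], rate = par[["rate"]]) - shift,
    inverse_gamma = rinvgamma_(n, par[["shape"]], par[["scale"]]) - shift,
    weibull = stats::rweibull(n, shape = par[["shape"]], scale = par[["scale"]]) - shift,
    mirrored_gamma = anchor - stats::rgamma(n, shape = par[["shape"]], rate = par[["rate"]]),
    mirrored_gumbel = anchor - rgumbel_(n, par[["loc"]], par[["scale"]]),
    stop("unknown family: ", family)
  )
}
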