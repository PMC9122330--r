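# Ensemble distribution machinery: method-of-moments solves, mixture
# pdf/cdf, and global weight fitting.

test_that("method-of-moments solves reproduce closed-form parameters", {
  spec <- ensemble_spec(c(normal = 1))
  p <- mom_params("normal", list(mean = -1.88, variance = 1), spec)
  expect_equal(unname(p), c(-1.88, 1))

  # gamma on the shifted scale: m = -2 + 10 = 8, v = 1 -> shape 64, rate 8
  p <- mom_params("gamma", list(mean = -2, variance = 1), spec)
  expect_equal(unname(p), c(64, 8))

  # Gumbel with mean 0, var pi^2/6 has unit scale and location -gamma_Euler
  p <- mom_params("gumbel", list(mean = 0, variance = pi^2 / 6), spec)
  expect_equal(unname(p), c(-0.57721566490153286, 1), tolerance = 1e-12)
})

test_that("every family round-trips its target moments through sampling", {
  spec <- ensemble_spec(c(normal = 1))
  m <- -1.6; v <- 1.1
  n <- 1e6
  for (f in setdiff(cgfdist:::FAMILY_NAMES, "exponential")) {
    par <- mom_params(f, list(mean = m, variance = v), spec)
    set.seed(101)
    z <- cgfdist:::.family_rng(f, par, n, spec$shift, spec$mirror_anchor)
    se_mean <- sqrt(v / n)
    expect_lt(abs(mean(z) - m), 3 * se_mean + 1e-9, label = paste(f, "mean"))
    # variance within 3 SEs of its sampling distribution (4th-moment based)
    s2 <- var(z)
    se_var <- sqrt((mean((z - mean(z))^4) - s2^2) / n)
    expect_lt(abs(s2 - v), 3 * se_var, label = paste(f, "variance"))
  }
  # exponential is one-parameter: mean matches, variance cannot
  par <- mom_params("exponential", list(mean = m, variance = v), spec)
  set.seed(101)
  z <- cgfdist:::.family_rng("exponential", par, n, spec$shift, spec$mirror_anchor)
  expect_lt(abs(mean(z) - m), 3 * (m + spec$shift) / sqrt(n))
})

test_that("infeasible moments signal family-infeasible rather than crash", {
  spec <- ensemble_spec(c(normal = 1))
  # shifted mean is negative for a positive-support family
  expect_error(mom_params("gamma", list(mean = -12, variance = 1), spec),
               class = "cgf_family_infeasible")
  # the mixture renormalises around the infeasible component
  sp <- ensemble_spec(c(normal = 0.5, gamma = 0.5))
  d <- ensemble_pdf(sp, list(mean = -12, variance = 1), -12)
  expect_equal(d, dnorm(0, 0, 1))
})

test_that("ensemble pdf behaves as a proper mixture density", {
  spec <- ensemble_spec(c(normal = 1))
  expect_equal(ensemble_pdf(spec, list(mean = 0, variance = 1), 0),
               0.39894, tolerance = 1e-5)

  # half-and-half of the same family is the family itself
  # (equal-weight mixture of identical components)
  w <- ensemble_spec(c(normal = 0.5, gumbel = 0.5))
  x <- seq(-5, 3, by = 0.5)
  mo <- list(mean = -1, variance = 1.2)
  expect_equal(ensemble_pdf(w, mo, x),
               0.5 * ensemble_pdf(ensemble_spec(c(normal = 1)), mo, x) +
                 0.5 * ensemble_pdf(ensemble_spec(c(gumbel = 1)), mo, x),
               tolerance = 1e-12)

  # the full ten-family mixture integrates to one
  wfull <- rep(0.1, 10); names(wfull) <- cgfdist:::FAMILY_NAMES
  sp <- ensemble_spec(wfull)
  g <- seq(-30, 50, by = 0.005)
  expect_equal(sum(ensemble_pdf(sp, mo, g)) * 0.005, 1, tolerance = 2e-3)
})

test_that("mirrored families are reflections of their base family", {
  spec <- ensemble_spec(c(mirrored_gamma = 1))
  mo <- list(mean = -1.5, variance = 0.9)
  x <- c(-3, -2, -1, 0, 2)
  mirrored_m <- spec$mirror_anchor - mo$mean
  par <- cgfdist:::.mom_solve("gamma", mirrored_m, mo$variance)
  expect_equal(ensemble_pdf(spec, mo, x),
               dgamma(spec$mirror_anchor - x, shape = par[["shape"]],
                      rate = par[["rate"]]),
               tolerance = 1e-12)
})

test_that("prevalence_below matches normal CDF identities and is monotone", {
  spec <- ensemble_spec(c(normal = 1))
  expect_equal(prevalence_below(spec, list(mean = -2, variance = 1), -2), 0.5)
  expect_equal(prevalence_below(spec, list(mean = -2, variance = 1), -3),
               0.15866, tolerance = 1e-4)

  set.seed(42)
  for (i in 1:15) {
    w <- rgamma(10, 1); w <- w / sum(w); names(w) <- cgfdist:::FAMILY_NAMES
    sp <- ensemble_spec(w)
    mo <- list(mean = runif(1, -3, 0), variance = runif(1, 0.3, 2.5))
    thr <- seq(-6, 2, by = 0.5)
    p <- prevalence_below(sp, mo, thr)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("weight fitting honours its optimizer contract", {
  set.seed(7)
  mk <- function(n, m, s) {
    structure(list(source_id = paste0("s", m), location_id = "C1", year = 2000,
                   kind = "microdata",
                   records = data.frame(age_group = "2-4y", sex = "male",
                                        z = rnorm(n, m, s))),
              class = "survey_source")
  }
  srcs <- lapply(1:6, function(i) mk(1500, -2.2 + 0.12 * i, 0.85 + 0.06 * i))

  fit <- fit_ensemble_weights(srcs, n_restarts = 6, seed = 3, maxit = 250)
  expect_s3_class(fit$spec, "ensemble_spec")
  expect_equal(sum(fit$spec$weights), 1, tolerance = 1e-9)
  # best objective is the minimum over restarts
  expect_equal(fit$objective, min(fit$restart_objectives))

  # beats uniform weights
  unif <- rep(0.1, 10); names(unif) <- cgfdist:::FAMILY_NAMES
  obj_of <- function(w) {
    sum(vapply(fit$source_stats, function(s) {
      pred <- cgfdist:::.ens_cdf(w, s$mean, s$variance, c(-1, -2, -3), 10, 10)
      sum((pred - s$emp)^2)
    }, numeric(1)))
  }
  expect_lt(fit$objective, obj_of(unif))

  # fitted prevalence predictions track the empirical ones closely
  for (s in fit$source_stats) {
    pred <- prevalence_below(fit$spec, list(mean = s$mean, variance = s$variance),
                             c(-1, -2, -3))
    expect_lt(max(abs(pred - s$emp)), 0.02)
  }
})

test_that("weight fitting degenerates and invariances", {
  set.seed(8)
  mk <- function(n, m, s, id) {
    structure(list(source_id = id, location_id = "C1", year = 2000,
                   kind = "microdata",
                   records = data.frame(age_group = "2-4y", sex = "male",
                                        z = rnorm(n, m, s))),
              class = "survey_source")
  }
  srcs <- lapply(1:5, function(i) mk(800, -2 + 0.1 * i, 1, i))

  # a single candidate family gets weight one regardless of data
  fit1 <- fit_ensemble_weights(srcs, families = "gumbel", seed = 1)
  expect_equal(unname(fit1$spec$weights[["gumbel"]]), 1)

  # source order does not change the fit
  fa <- fit_ensemble_weights(srcs, n_restarts = 4, seed = 5, maxit = 200)
  fb <- fit_ensemble_weights(rev(srcs), n_restarts = 4, seed = 5, maxit = 200)
  expect_equal(fa$objective, fb$objective, tolerance = 1e-10)
  expect_equal(fa$spec$weights, fb$spec$weights, tolerance = 1e-8)

  # zero-variance sources are dropped with a warning; all-degenerate errors
  degen <- mk(50, -2, 0, "d"); degen$records$z <- -2
  expect_warning(fit_ensemble_weights(c(srcs, list(degen)), n_restarts = 2,
                                      seed = 1, maxit = 50),
                 "degenerate")
  expect_error(suppressWarnings(fit_ensemble_weights(list(degen), seed = 1)),
               "degenerate|nothing to fit")
})

test_that("weights serialise to CSV and back", {
  sp <- ensemble_spec(c(normal = 0.6, weibull = 0.4))
  path <- tempfile(fileext = ".csv")
  write_ensemble_weights(sp, path)
  sp2 <- read_ensemble_weights(path)
  expect_equal(sp2$weights, sp$weights)
})
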