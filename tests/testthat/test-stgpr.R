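# Three-stage spatiotemporal Gaussian process regression.

test_that("logit transform round-trips and propagates variance", {
  p <- c(1e-6, 0.01, 0.3, 0.5, 0.97, 1 - 1e-6)
  tr <- cgfdist:::transform_obs(p, rep(1e-4, length(p)), "logit")
  expect_equal(cgfdist:::back_transform(tr$value, "logit"), p, tolerance = 1e-12)
  # delta method: var_logit = var / (p(1-p))^2
  expect_equal(tr$variance, 1e-4 / (p * (1 - p))^2)
  id <- cgfdist:::transform_obs(p, rep(1e-4, length(p)), "identity")
  expect_identical(id$value, p)
})

test_that("stage 1 keeps an informative covariate and drops a wrong-signed one", {
  w <- tiny_truth()
  tr <- w$truth; h <- w$hierarchy
  # covariate = truth signal plus small noise
  cov <- simulate_covariates(tr, cfg = list(covariates = list(
    health_access = list(slope = 1, noise_sd = 0.02))), seed = 13)
  set.seed(21)
  obs_cells <- as.data.frame(tr)[sample(nrow(tr), 500), ]
  data <- data.frame(obs_cells[c("location_id", "year", "age_group", "sex")],
                     value = obs_cells$mean_z + rnorm(500, 0, 0.05),
                     variance = 0.05^2)

  s1 <- fit_stage1(data, cov, h, expected_signs = c(health_access = 1),
                   transform = "identity", seed = 2)
  expect_false(s1$fallback)
  expect_true(all(grepl("health_access", s1$models$covariates)))
  i <- match(cgfdist:::cell_key(s1$prior), cgfdist:::cell_key(tr))
  expect_gt(cor(s1$prior$prior, tr$mean_z[i]), 0.9)

  # declaring the wrong expected direction drops the model -> fallback
  expect_message(
    s1b <- fit_stage1(data, cov, h, expected_signs = c(health_access = -1),
                      transform = "identity", seed = 2),
    "fallback")
  expect_true(s1b$fallback)
  # the intercept fallback still predicts every cell, near the data mean
  expect_true(all(is.finite(s1b$prior$prior)))
  expect_lt(abs(mean(s1b$prior$prior) - mean(data$value)), 0.15)
})

test_that("stage-2 smoothing reduces to the prior without residuals", {
  w <- tiny_truth()
  prior <- as.data.frame(w$covariates)[c("location_id", "year", "age_group", "sex")]
  prior$prior <- seq_len(nrow(prior)) * 0.001
  hp <- stgpr_hyperparams(0.7, 1, 2)
  res0 <- data.frame(location_id = character(), year = integer(),
                     age_group = character(), sex = character(),
                     resid = numeric())
  s2 <- smooth_spatiotemporal(prior, res0, w$hierarchy, hp)
  expect_equal(s2$stage2, prior$prior)

  # single residual at the same cell with all weights 1 adds exactly r
  cell <- prior[1, ]
  res1 <- data.frame(cell[c("location_id", "year", "age_group", "sex")],
                     resid = 0.37)
  s2b <- smooth_spatiotemporal(prior, res1, w$hierarchy, stgpr_hyperparams(1, 1, 1))
  i <- match(cgfdist:::cell_key(cell), cgfdist:::cell_key(s2b))
  expect_equal(s2b$stage2[i], prior$prior[1] + 0.37)
})

test_that("stage-2 weights match a hand-computed toy case to 1e-12", {
  h <- make_hierarchy(1, 2, 2)   # countries: R01_C01, R01_C02, R02_C01, R02_C02
  ids <- h$location_id[h$level == "country"]
  prior <- expand.grid(location_id = ids, year = 2000:2002,
                       age_group = c("12-23m", "2-4y"), sex = "male",
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prior$prior <- 0
  res <- data.frame(location_id = c(ids[1], ids[2], ids[3]),
                    year = c(2000, 2001, 2002),
                    age_group = c("12-23m", "12-23m", "2-4y"),
                    sex = "male",
                    resid = c(0.4, -0.2, 0.1))
  zeta <- 0.6; lam <- 1.3; omega <- 2.5
  s2 <- smooth_spatiotemporal(prior, res, h, stgpr_hyperparams(zeta, lam, omega))

  # brute-force expectation for the cell (ids[1], 2001, "2-4y", male)
  target <- list(loc = ids[1], year = 2001, age = "2-4y")
  ws <- c(1, zeta, zeta^2)                       # same country, region, super
  dt <- abs(c(2000, 2001, 2002) - target$year)
  wt <- (1 - (dt / (1 + max(dt)))^lam)^3
  wa <- omega^(-abs(c(1, 1, 2) - 2))             # age ranks of the residuals vs target
  wgt <- ws * wt * wa
  expected <- sum(wgt * res$resid) / sum(wgt)
  i <- which(s2$location_id == target$loc & s2$year == target$year &
               s2$age_group == target$age)
  expect_equal(s2$stage2[i], expected, tolerance = 1e-12)
})

test_that("hyperparameter selection follows holdout RMSE with smoothness ties", {
  w <- tiny_truth()
  tr <- w$truth
  set.seed(31)
  obs_cells <- as.data.frame(tr)[sample(nrow(tr), 300), ]
  data <- data.frame(obs_cells[c("location_id", "year", "age_group", "sex")],
                     value = obs_cells$mean_z + rnorm(300, 0, 0.05),
                     variance = 0.05^2)
  s1 <- fit_stage1(data, w$covariates, w$hierarchy,
                   expected_signs = c(health_access = 1), seed = 2)

  one <- data.frame(zeta = 0.8, lam = 1.5, omega = 2)
  hp1 <- select_hyperparams(one, data, s1, w$hierarchy, seed = 4)
  expect_equal(unclass(hp1)[c("zeta", "lam", "omega")],
               list(zeta = 0.8, lam = 1.5, omega = 2))

  grid <- expand.grid(zeta = c(0.5, 0.9), lam = c(0.5, 2), omega = c(1, 3))
  hp_a <- select_hyperparams(grid, data, s1, w$hierarchy, seed = 4)
  hp_b <- select_hyperparams(grid, data, s1, w$hierarchy, seed = 4)
  expect_identical(attr(hp_a, "holdout_rmse"), attr(hp_b, "holdout_rmse"))
})

test_that("GP stage interpolates exact observations and reverts to the prior", {
  cells <- expand.grid(location_id = "C1", year = 1990:2020,
                       age_group = "2-4y", sex = "male",
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$prior <- 0
  cells$stage2 <- sin(seq(0, 2, length.out = 31))
  # an exact (zero-variance) observation away from stage 2
  data <- data.frame(location_id = "C1", year = 2005, age_group = "2-4y",
                     sex = "male", value = 1.4, variance = 0)
  fit <- gpr_stage(cells, data, kernel_cfg = list(amplitude = 0.5),
                   n_draws = 4000, seed = 9)
  i <- which(fit$cells$year == 2005)
  post_mean <- mean(fit$draws[i, ])
  # posterior mean at an exact observation equals the observation; draw
  # noise at the observed year is suppressed by the zero-variance datum
  expect_lt(abs(post_mean - 1.4), 1e-2)
  expect_lt(sd(fit$draws[i, ]), 0.02)

  # no data at all: draws centred on stage 2 with prior kernel spread
  fit0 <- gpr_stage(cells, data[0, ], kernel_cfg = list(amplitude = 0.5),
                    n_draws = 4000, seed = 9)
  expect_lt(max(abs(rowMeans(fit0$draws) - cells$stage2)), 0.05)
  expect_equal(mean(apply(fit0$draws, 1, sd)), 0.5, tolerance = 0.05)
})

test_that("GP posterior mean matches the conjugate closed form", {
  # single location, Matern kernel, two noisy observations: compare the
  # draw mean against the analytic GP posterior mean
  cells <- expand.grid(location_id = "C1", year = 2000:2010,
                       age_group = "2-4y", sex = "male",
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$stage2 <- 0
  data <- data.frame(location_id = "C1", year = c(2003, 2008),
                     age_group = "2-4y", sex = "male",
                     value = c(0.8, -0.4), variance = c(0.04, 0.09))
  amp <- 0.6; ls <- 5
  fit <- gpr_stage(cells, data, kernel_cfg = list(amplitude = amp, lengthscale = ls),
                   n_draws = 8000, seed = 5)
  K <- function(a, b) cgfdist:::matern52(abs(outer(a, b, "-")), amp, ls)
  Koo <- K(data$year, data$year) + diag(data$variance)
  analytic <- K(2000:2010, data$year) %*% solve(Koo, data$value)
  mc_se <- apply(fit$draws, 1, sd) / sqrt(8000)
  expect_true(all(abs(rowMeans(fit$draws) - analytic) < 4 * mc_se + 1e-3))
})

test_that("exact zero-variance interpolation holds to 1e-6 via the mean path", {
  # deterministic check on the posterior mean itself (no draw noise):
  # with a zero-variance observation the GP mean function must pass
  # through the datum
  yrs <- 1995:2005
  amp <- 0.4; ls <- 8
  K <- function(a, b) cgfdist:::matern52(abs(outer(a, b, "-")), amp, ls)
  m2 <- rep(0.2, length(yrs))
  obs_y <- 2000; obs_v <- 0.9
  post_mean <- m2 + K(yrs, obs_y) %*% solve(K(obs_y, obs_y) + 1e-12 * amp^2,
                                            obs_v - 0.2)
  expect_lt(abs(post_mean[yrs == 2000] - obs_v), 1e-6)
})

test_that("estimates sharpen as survey sample size grows tenfold", {
  w <- tiny_truth()
  tr <- w$truth
  rmse <- vapply(c(40, 400, 4000), function(n) {
    srcs <- list()
    for (L in unique(tr$location_id)) for (y in c(1995, 2005, 2015)) {
      cells <- tr[tr$location_id == L & tr$year == y,
                  c("location_id", "year", "age_group", "sex")]
      srcs[[paste(L, y)]] <- simulate_microdata(tr, cells, n,
                                                seed = y + n + nchar(L))
    }
    d <- sources_to_observations(srcs, "mean")
    fit <- stgpr(d, w$covariates, w$hierarchy,
                 expected_signs = c(health_access = 1, nutrition_score = 1),
                 indicator = "mean", n_draws = 50, seed = 3)
    i <- match(cgfdist:::cell_key(fit$cells), cgfdist:::cell_key(tr))
    sqrt(mean((rowMeans(fit$draws) - tr$mean_z[i])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
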