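# Synthetic-data generators: hierarchy, truth surfaces, surveys, splitting.

test_that("hierarchy construction is complete and deterministic", {
  h <- make_hierarchy(1, 1, 1, seed = 0)
  expect_equal(nrow(h), 4)
  expect_equal(sum(h$level == "global"), 1)

  h2 <- make_hierarchy(7, 3, 4, seed = 1)
  expect_equal(sum(h2$level == "super_region"), 7)
  expect_equal(sum(h2$level == "region"), 21)
  expect_equal(sum(h2$level == "country"), 84)
  expect_false(any(duplicated(h2$location_id)))
  # every non-root parent exists one level up
  lvl <- c(global = 0, super_region = 1, region = 2, country = 3)
  for (i in which(h2$level != "global")) {
    p <- h2[h2$location_id == h2$parent_id[i], ]
    expect_equal(lvl[[p$level]], lvl[[h2$level[i]]] - 1)
  }

  expect_identical(make_hierarchy(3, 2, 2, seed = 9),
                   make_hierarchy(3, 2, 2, seed = 9))
})

test_that("hierarchy rejects non-positive counts", {
  expect_error(make_hierarchy(0, 1, 1), ">= 1")
})

test_that("truth surface follows the configured trend", {
  h <- make_hierarchy(1, 1, 2)
  # no random effects: pure linear path hitting both endpoints
  tr <- simulate_truth(h, 1990:2020,
                       trend_cfg = list(mean_start = -1.88, mean_end = -1.65,
                                        re_sd = c(super = 0, region = 0, country = 0),
                                        sd_re_sd = 0, age_groups = "2-4y"),
                       seed = 1)
  one <- tr[tr$location_id == tr$location_id[1] & tr$sex == "male", ]
  one <- one[order(one$year), ]
  expect_equal(one$mean_z[1], -1.88)
  expect_equal(one$mean_z[31], -1.65)
  expect_true(all(diff(one$mean_z) > 0))   # monotone path between endpoints
  expect_true(all(tr$sd_z > 0))

  # zero trend, zero random effects: constant surface
  tr0 <- simulate_truth(h, 1990:2000,
                        trend_cfg = list(mean_start = -1.8, mean_end = -1.8,
                                         sd_start = 1, sd_end = 1,
                                         re_sd = c(super = 0, region = 0, country = 0),
                                         sd_re_sd = 0),
                        seed = 2)
  expect_equal(length(unique(tr0$mean_z)), 1)
  expect_equal(length(unique(tr0$sd_z)), 1)

  expect_error(simulate_truth(h, trend_cfg = list(sd_min = 0)), "sd_min")
})

test_that("different seeds change country offsets but not the global trend", {
  h <- make_hierarchy(2, 2, 2)
  t1 <- simulate_truth(h, seed = 1)
  t2 <- simulate_truth(h, seed = 2)
  c1 <- attr(t1, "components"); c2 <- attr(t2, "components")
  expect_equal(c1$mean_path, c2$mean_path)   # deterministic global component
  expect_false(isTRUE(all.equal(c1$u_country, c2$u_country)))
})

test_that("microdata draws follow the cell's ensemble distribution", {
  h <- make_hierarchy(1, 1, 1)
  tr <- simulate_truth(h, 2000:2000,
                       trend_cfg = list(mean_start = -2, mean_end = -2,
                                        sd_start = 1, sd_end = 1,
                                        re_sd = c(super = 0, region = 0, country = 0),
                                        sd_re_sd = 0, age_groups = "2-4y"),
                       seed = 1)
  cells <- tr[tr$sex == "male", c("location_id", "year", "age_group", "sex")]
  src <- simulate_microdata(tr, cells, 1e5, seed = 3)
  expect_equal(src$kind, "microdata")
  expect_lt(abs(mean(src$records$z) + 2), 0.01)
  # empirical tail fraction matches the ensemble CDF at -2 (3 binomial SEs)
  p <- pnorm(-2, -2, 1)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(src$records$z < -2) - p), 3 * se)

  empty <- simulate_microdata(tr, cells, 0, seed = 3)
  expect_equal(nrow(empty$records), 0)

  bad <- cells; bad$year <- 1900
  expect_error(simulate_microdata(tr, bad, 10), "unknown cell")
})

test_that("tabulated draws are trinomial and internally consistent", {
  h <- make_hierarchy(1, 1, 1)
  tr <- simulate_truth(h, 2000:2000,
                       trend_cfg = list(mean_start = -2, mean_end = -2,
                                        sd_start = 1, sd_end = 1,
                                        re_sd = c(super = 0, region = 0, country = 0),
                                        sd_re_sd = 0, age_groups = "2-4y"),
                       seed = 1)
  cells <- tr[c("location_id", "year", "age_group", "sex")]

  # n = 1e6: prevalences within 3 binomial SDs of the truth CDF
  src <- simulate_tabulated(tr, cells[1, ], 1e6, seed = 5)
  p2 <- pnorm(-2, -2, 1); p3 <- pnorm(-3, -2, 1)
  expect_lt(abs(src$records$prev2 - p2), 3 * sqrt(p2 * (1 - p2) / 1e6))
  expect_lt(abs(src$records$prev3 - p3), 3 * sqrt(p3 * (1 - p3) / 1e6))

  # prev3 <= prev2 on every draw, by the joint trinomial construction
  for (s in 1:25) {
    r <- simulate_tabulated(tr, cells, 40, seed = s)$records
    expect_true(all(r$prev3 <= r$prev2))
  }

  # zero truth below -3 forces prev3 = 0 always
  trhi <- simulate_truth(h, 2000:2000,
                         trend_cfg = list(mean_start = 2, mean_end = 2,
                                          sd_start = 0.3, sd_end = 0.3,
                                          re_sd = c(super = 0, region = 0, country = 0),
                                          sd_re_sd = 0, age_groups = "2-4y"),
                         seed = 1)
  chi <- trhi[c("location_id", "year", "age_group", "sex")]
  for (s in 1:5)
    expect_equal(simulate_tabulated(trhi, chi[1, ], 500, seed = s)$records$prev3, 0)
})

test_that("aggregate splitting conserves the population-weighted mean", {
  h <- make_hierarchy(1, 1, 1)
  tr <- simulate_truth(h, 2000:2000,
                       trend_cfg = list(age_effects = c("0-6d" = 0.5, "2-4y" = -0.4),
                                        sex_effects = c(male = -0.15)),
                       seed = 4)
  cov <- simulate_covariates(tr, seed = 5)
  cells <- tr[c("location_id", "year", "age_group", "sex")]
  agg <- simulate_tabulated(tr, cells, 5000, seed = 6, aggregate = TRUE,
                            populations = cov)
  pat <- as.data.frame(tr)
  pat$prev2 <- pnorm(-2, pat$mean_z, pat$sd_z)
  pat$prev3 <- pnorm(-3, pat$mean_z, pat$sd_z)
  sp <- split_aggregated(agg, pat[c("age_group", "sex", "prev2", "prev3")], cov)

  m <- merge(sp$records, cov[c("age_group", "sex", "population")],
             by = c("age_group", "sex"))
  expect_lt(abs(sum(m$prev2 * m$population) / sum(m$population) -
                  agg$records$prev2), 1e-10)
  expect_lt(abs(sum(m$prev3 * m$population) / sum(m$population) -
                  agg$records$prev3), 1e-10)

  # flat pattern: every cell equals the aggregate
  flat <- pat; flat$prev2 <- 0.3; flat$prev3 <- 0.1
  spf <- split_aggregated(agg, flat[c("age_group", "sex", "prev2", "prev3")], cov)
  expect_true(all(abs(spf$records$prev2 - agg$records$prev2) < 1e-12))

  # all-zero pattern with positive aggregate is an error
  zero <- pat; zero$prev2 <- 0; zero$prev3 <- 0
  expect_error(split_aggregated(agg, zero[c("age_group", "sex", "prev2", "prev3")], cov),
               "zero prevalence")
})

test_that("two-cell split follows the closed-form ratio", {
  # pattern ratio 2:1 with equal populations -> outputs in ratio 2:1 and
  # mean preserved: x = 2a/(1.5), y = a/(1.5) for aggregate a
  agg <- structure(list(source_id = "a", location_id = "C", year = 2000,
                        kind = "tabulated",
                        records = data.frame(age_group = "all", sex = "both",
                                             prev2 = 0.3, prev3 = 0.1, n = 100)),
                   class = "survey_source")
  pattern <- data.frame(age_group = c("12-23m", "2-4y"), sex = "male",
                        prev2 = c(0.4, 0.2), prev3 = c(0.2, 0.1))
  pops <- data.frame(location_id = "C", year = 2000,
                     age_group = c("12-23m", "2-4y"), sex = "male",
                     population = c(1000, 1000))
  out <- split_aggregated(agg, pattern, pops)$records
  out <- out[order(out$age_group), ]
  expect_equal(out$prev2, c(0.3 * 2 / 1.5, 0.3 / 1.5))
  expect_equal(out$prev2[1] / out$prev2[2], 2)
})

test_that("generators are bit-reproducible given config and seed", {
  h <- make_hierarchy(2, 1, 2)
  expect_identical(simulate_truth(h, seed = 3), simulate_truth(h, seed = 3))
  tr <- simulate_truth(h, seed = 3)
  cells <- tr[tr$location_id == tr$location_id[1] & tr$year == 1995,
              c("location_id", "year", "age_group", "sex")]
  expect_identical(simulate_microdata(tr, cells, 50, seed = 4),
                   simulate_microdata(tr, cells, 50, seed = 4))
  expect_identical(simulate_tabulated(tr, cells, 100, seed = 5),
                   simulate_tabulated(tr, cells, 100, seed = 5))
  expect_identical(simulate_covariates(tr, seed = 6),
                   simulate_covariates(tr, seed = 6))
})
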