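# Shared fixtures, built in code. Heavy objects are memoised so several test
# files (and several acceptance checks) reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A small two-age-bin world used by unit tests: 12 countries, 31 years.
tiny_truth <- function() memo("tiny_truth", function() {
  h <- make_hierarchy(2, 2, 3, seed = 0)
  tr <- simulate_truth(h, years = 1990:2020,
                       trend_cfg = list(age_groups = c("12-23m", "2-4y"),
                                        age_effects = c("12-23m" = -0.25),
                                        sex_effects = c(male = -0.08)),
                       seed = 11)
  list(hierarchy = h, truth = tr,
       covariates = simulate_covariates(tr, seed = 12))
})

# Hand-rolled growth surface: constant prevalence draws per cell.
flat_surface <- function(cells, prev_list, n_draws = 40) {
  growth_surface(cells, lapply(prev_list, function(p)
    matrix(rep(p, n_draws), nrow = nrow(cells), ncol = n_draws)))
}

# The acceptance-scale synthetic world: 10 countries, 31 years, 100 draws,
# full pipeline. Built once; reused by several acceptance checks.
acceptance_world <- function() memo("acceptance_world", function() {
  cfg <- run_config(
    out_dir = file.path(tempdir(), "cgf_acceptance_world"),
    seed = 20260920,
    years = 1990:2020,
    age_groups = c("12-23m", "2-4y"),
    n_draws = 100, n_restarts = 10, n_weight_sources = 12,
    hierarchy_dims = c(2, 1, 5),
    trend_cfg = list(mean_start = -1.88, mean_end = -1.65,
                     sd_start = 1.15, sd_end = 1.0,
                     age_effects = c("12-23m" = -0.2),
                     sex_effects = c(male = -0.05)),
    survey_years = seq(1990, 2020, by = 2),
    n_microdata_per_cell = 1000, n_tabulated = 10000,
    hp = expand.grid(zeta = c(0.3, 0.9), lam = c(1, 2), omega = c(1, 3)))
  run_pipeline(cfg)
})

# True prevalence below a threshold for every cell of a (normal-ensemble)
# truth surface, in cell order of `cells`.
truth_prevalence <- function(truth, cells, threshold) {
  i <- match(cgfdist:::cell_key(cells), cgfdist:::cell_key(truth))
  stats::pnorm(threshold, truth$mean_z[i], truth$sd_z[i])
}
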