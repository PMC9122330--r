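## End-to-end pipeline orchestration: simulate -> fit-weights -> stgpr (three
## indicators) -> integrate -> change / disruption / transition, with plain
## CSV intermediates, a single config, per-stage logging and a run manifest
## of file digests.

#' Assemble a pipeline run configuration
#'
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param seed master integer seed; each stage derives its own sub-seed.
#' @param years estimation years.
#' @param age_groups age bins (subset of the six under-5 bins).
#' @param n_draws posterior draws per cell.
#' @param n_restarts ensemble weight-fitting restarts.
#' @param n_weight_sources cap on the number of microdata sources entering
#'   weight fitting (an evenly spaced subset is used; the global curve shape
#'   is well identified by a modest source sample).
#' @param hierarchy_dims `c(n_super, n_regions_per, n_countries_per)`.
#' @param trend_cfg passed to [simulate_truth()].
#' @param covariate_cfg passed to [simulate_covariates()].
#' @param survey_years years in which surveys are simulated.
#' @param n_microdata_per_cell records per microdata cell.
#' @param n_tabulated sample size per tabulated cell.
#' @param expected_signs stage-1 covariate sign declarations (natural
#'   direction for the mean z-score model; prevalence models flip them).
#' @param hp an [stgpr_hyperparams()] or a candidate data frame for
#'   [select_hyperparams()].
#' @param stages character vector of stages to run, in order; any of
#'   `"simulate"`, `"fit_weights"`, `"stgpr"`, `"integrate"`, `"change"`,
#'   `"disruption"`, `"transition"`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("cgfrun"), seed = 1,
                       years = 1990:2020,
                       age_groups = c("12-23m", "2-4y"),
                       n_draws = 100, n_restarts = 20, n_weight_sources = 16,
                       hierarchy_dims = c(2, 1, 5),
                       trend_cfg = list(), covariate_cfg = list(),
                       survey_years = seq(1991, 2019, by = 3),
                       n_microdata_per_cell = 400, n_tabulated = 2000,
                       expected_signs = c(health_access = 1, nutrition_score = 1),
                       hp = stgpr_hyperparams(zeta = 0.9, lam = 1, omega = 2),
                       stages = c("simulate", "fit_weights", "stgpr",
                                  "integrate", "change", "disruption",
                                  "transition")) {
  structure(list(out_dir = out_dir, seed = seed, years = years,
                 age_groups = age_groups, n_draws = n_draws,
                 n_restarts = n_restarts, n_weight_sources = n_weight_sources,
                 hierarchy_dims = hierarchy_dims,
                 trend_cfg = trend_cfg, covariate_cfg = covariate_cfg,
                 survey_years = survey_years,
                 n_microdata_per_cell = n_microdata_per_cell,
                 n_tabulated = n_tabulated, expected_signs = expected_signs,
                 hp = hp, stages = stages),
            class = "run_config")
}

## CSV with a seed/provenance comment header.
write_stage_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cgfdist v%s seed=%d",
                     as.character(utils::packageVersion("cgfdist")), seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname run_pipeline
#' @param path a stage CSV written by the pipeline.
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full synthetic-world pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs as seed-stamped CSVs under `config$out_dir` and returning a
#' manifest of file digests, timings and warning counts. A rerun with the
#' same config reproduces identical digests.
#'
#' @param config a [run_config()].
#' @return a `run_manifest` list: per-stage `files` (MD5 digests), `timing`
#'   in seconds, `warnings` counts, plus the `seed` and completed stage
#'   names. The in-memory stage objects are attached in `$objects`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = character(),
                   files = list(), timing = list(), warnings = list())
  obj <- list()
  seed_for <- function(i) (config$seed * 97L + i * 1009L) %% .Machine$integer.max

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    nwarn <- 0L
    withCallingHandlers(fun(),
                        warning = function(w) {
                          nwarn <<- nwarn + 1L
                          invokeRestart("muffleWarning")
                        })
    manifest$stages <<- c(manifest$stages, name)
    manifest$timing[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    manifest$warnings[[name]] <<- nwarn
    .log_stage(name, "done in ", manifest$timing[[name]], "s")
  }
  emit <- function(stage, name, df, seed) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    write_stage_csv(df, path, seed)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
  }

  run_stage("simulate", function() {
    sd <- seed_for(1)
    obj$hierarchy <<- make_hierarchy(config$hierarchy_dims[1],
                                     config$hierarchy_dims[2],
                                     config$hierarchy_dims[3], seed = sd)
    tc <- utils::modifyList(list(age_groups = config$age_groups), config$trend_cfg)
    obj$truth <<- simulate_truth(obj$hierarchy, config$years, tc, seed = sd)
    obj$covariates <<- simulate_covariates(obj$truth, config$covariate_cfg,
                                           seed = sd + 1)
    ctries <- unique(obj$truth$location_id)
    srcs <- list()
    for (L in ctries) for (y in config$survey_years) {
      cells <- obj$truth[obj$truth$location_id == L & obj$truth$year == y,
                         c("location_id", "year", "age_group", "sex")]
      srcs[[paste0("m_", L, "_", y)]] <-
        simulate_microdata(obj$truth, cells, config$n_microdata_per_cell,
                           seed = sd + 7L * match(L, ctries) + y)
      srcs[[paste0("t_", L, "_", y)]] <-
        simulate_tabulated(obj$truth, cells, config$n_tabulated,
                           seed = sd + 13L * match(L, ctries) + y)
    }
    obj$sources <<- srcs
    emit("simulate", "truth", as.data.frame(obj$truth), sd)
    emit("simulate", "hierarchy", as.data.frame(obj$hierarchy), sd)
    emit("simulate", "covariates", as.data.frame(obj$covariates), sd)
  })

  run_stage("fit_weights", function() {
    sd <- seed_for(2)
    micro <- Filter(function(s) s$kind == "microdata", obj$sources)
    if (length(micro) > config$n_weight_sources)
      micro <- micro[round(seq(1, length(micro),
                               length.out = config$n_weight_sources))]
    obj$weight_fit <<- fit_ensemble_weights(micro, n_restarts = config$n_restarts,
                                            seed = sd, maxit = 300)
    path <- file.path(config$out_dir, "ensemble_weights.csv")
    write_ensemble_weights(obj$weight_fit, path)
    manifest$files[["ensemble_weights"]] <<- unname(tools::md5sum(path))
  })

  run_stage("stgpr", function() {
    sd <- seed_for(3)
    signs <- config$expected_signs
    fits <- list()
    for (ind in c("mean", "prev2", "prev3")) {
      d <- sources_to_observations(obj$sources, ind)
      ## covariates increase with mean z; prevalences move opposite to it
      sg <- if (ind == "mean") signs else -signs
      fits[[ind]] <- stgpr(d, obj$covariates, obj$hierarchy, sg,
                           indicator = ind, hp = config$hp,
                           n_draws = config$n_draws,
                           seed = sd + match(ind, c("mean", "prev2", "prev3")))
      emit("stgpr", paste0("stgpr_", ind, "_summary"), fits[[ind]]$summary, sd)
    }
    obj$stgpr <<- fits
  })

  run_stage("integrate", function() {
    fits <- obj$stgpr
    obj$surface <<- integrate_surface(obj$weight_fit$spec, fits$mean$cells,
                                      fits$mean$draws, fits$prev2$draws,
                                      fits$prev3$draws)
    summ <- summarize_surface(obj$surface)
    emit("integrate", "final_estimates", summ, seed_for(4))
  })

  run_stage("change", function() {
    yrs <- range(config$years)
    sel_ref <- obj$surface$cells$year == yrs[1]
    sel_cur <- obj$surface$cells$year == yrs[2]
    obj$change <<- relative_change(surface_subset(obj$surface, sel_cur),
                                   surface_subset(obj$surface, sel_ref),
                                   obj$covariates)
    summ <- summarize_change(obj$change)
    summ$year_range <- paste(yrs, collapse = "-")
    emit("change", "relative_change", summ, seed_for(5))
  })

  run_stage("disruption", function() {
    obj$annual <<- annual_changes(obj$surface, obj$covariates, obj$covariates)
    emit("disruption", "annual_changes", obj$annual, seed_for(6))
  })

  run_stage("transition", function() {
    sd <- seed_for(7)
    summ <- summarize_surface(obj$surface)
    cov <- as.data.frame(obj$covariates)
    uhc_ly <- unique(cov[c("location_id", "year", "uhc")])
    fits_by_sev <- list()
    for (sv in names(obj$surface$prev)) {
      pts <- summ[summ$measure == sv, ]
      i <- match(paste(pts$location_id, pts$year),
                 paste(uhc_ly$location_id, uhc_ly$year))
      pts$uhc <- uhc_ly$uhc[i]
      pts$prevalence <- clamp(pts$mean, 1e-7, 1 - 1e-7)
      ## age-sex-specific fits, aggregated with population weights
      fits <- list()
      for (ag in unique(pts$age_group)) for (sx in unique(pts$sex)) {
        sel <- pts$age_group == ag & pts$sex == sx
        fits[[paste(ag, sx, sep = "|")]] <-
          fit_spline_ensemble(pts[sel, ], seed = sd + match(sv, names(obj$surface$prev)))
      }
      fits_by_sev[[sv]] <- aggregate_splines(fits, cov[cov$age_group %in% unique(pts$age_group), ])
    }
    obj$transition <<- scale_trajectories(fits_by_sev, uhc_min = min(uhc_ly$uhc))
    curves <- do.call(rbind, lapply(names(obj$transition$curves), function(sv)
      cbind(severity = sv, obj$transition$curves[[sv]])))
    emit("transition", "transition_curves", curves, sd)
  })

  jsonlite::write_json(
    manifest[c("seed", "stages", "files", "timing", "warnings")],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  manifest$objects <- obj
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ") stages:",
      paste(x$stages, collapse = " -> "), "\n")
  for (nm in names(x$files))
    cat(sprintf("  %-24s %s\n", nm, x$files[[nm]]))
  invisible(x)
}
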