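## Synthetic-data generators: location hierarchies, true growth surfaces,
## microdata and tabulated surveys, covariates/UHC/SDI/population tables.
## Every downstream stage of the pipeline can therefore be validated against
## known truth.

#' Build a synthetic three-level location hierarchy
#'
#' A complete tree: one global root, `n_super` super-regions, each with
#' `n_regions_per` regions, each with `n_countries_per` countries. This
#' mirrors the nesting (super-region / region / country) assumed by the
#' spatiotemporal model's random effects and space weights.
#'
#' @param n_super,n_regions_per,n_countries_per positive counts.
#' @param seed integer seed (the construction is deterministic; the seed is
#'   recorded for provenance).
#' @return a `location_hierarchy`: data frame with columns `location_id`,
#'   `level` (`global`/`super_region`/`region`/`country`), `parent_id`.
#' @examples
#' h <- make_hierarchy(2, 2, 3)
#' table(h$level)
#' @export
make_hierarchy <- function(n_super, n_regions_per, n_countries_per, seed = 0) {
  if (any(c(n_super, n_regions_per, n_countries_per) < 1))
    stop("all counts must be >= 1")
  rows <- list(data.frame(location_id = "G", level = "global",
                          parent_id = NA_character_))
  for (s in seq_len(n_super)) {
    sid <- sprintf("SR%02d", s)
    rows[[length(rows) + 1L]] <- data.frame(location_id = sid,
                                            level = "super_region",
                                            parent_id = "G")
    for (r in seq_len(n_regions_per)) {
      rid <- sprintf("%s_R%02d", sid, r)
      rows[[length(rows) + 1L]] <- data.frame(location_id = rid,
                                              level = "region",
                                              parent_id = sid)
      for (k in seq_len(n_countries_per)) {
        cid <- sprintf("%s_C%02d", rid, k)
        rows[[length(rows) + 1L]] <- data.frame(location_id = cid,
                                                level = "country",
                                                parent_id = rid)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("location_hierarchy", "data.frame")
  out
}

## Country table with region / super-region ancestry resolved.
hierarchy_countries <- function(hierarchy) {
  h <- as.data.frame(hierarchy)
  ctry <- h[h$level == "country", ]
  reg <- h[h$level == "region", ]
  ctry$region_id <- ctry$parent_id
  ctry$super_region_id <- reg$parent_id[match(ctry$region_id, reg$location_id)]
  ctry[c("location_id", "region_id", "super_region_id")]
}

#' Simulate a true growth surface
#'
#' Generates the ground-truth mean z-score and SD per
#' (country, year, age group, sex) cell. The global mean follows a linear
#' path from `mean_start` to `mean_end` plus an optional Brownian-bridge
#' random walk (so the endpoints are preserved); `log(sd)` interpolates
#' linearly from `log(sd_start)` to `log(sd_end)`, emulating the narrowing of
#' z-score curves over time. Zero-mean Gaussian offsets are added at the
#' super-region, region and country levels, matching the nested
#' random-effects structure the spatiotemporal model assumes.
#'
#' @param hierarchy a [make_hierarchy()] result.
#' @param years estimation years, default `1990:2020`.
#' @param trend_cfg list of generator settings (all optional):
#'   `mean_start` (-1.88), `mean_end` (-1.65), `sd_start` (1.15), `sd_end`
#'   (1.0), `sd_min` (0.2, must be > 0), `rw_sd` (0, per-year SD of the
#'   bridge walk on the mean), `re_sd` (named vector
#'   `c(super = , region = , country = )`, default all 0.08), `sd_re_sd`
#'   (0.03, country-level offset on `log(sd)`), `age_effects` / `sex_effects`
#'   (named offsets on the mean; defaults 0), `age_groups`
#'   (default all six under-5 bins), `ensemble` (an [ensemble_spec()];
#'   default normal).
#' @param seed integer seed.
#' @return a `true_surface`: data frame of cells with `mean_z`, `sd_z`
#'   columns; the generating ensemble is in `attr(, "ensemble")`.
#' @export
simulate_truth <- function(hierarchy, years = 1990:2020, trend_cfg = list(),
                           seed = 1) {
  cfg <- utils::modifyList(list(
    mean_start = -1.88, mean_end = -1.65,
    sd_start = 1.15, sd_end = 1.0, sd_min = 0.2,
    rw_sd = 0, re_sd = c(super = 0.08, region = 0.08, country = 0.08),
    sd_re_sd = 0.03,
    age_effects = NULL, sex_effects = NULL,
    age_groups = AGE_GROUPS,
    ensemble = ensemble_spec(c(normal = 1))
  ), trend_cfg)
  if (cfg$sd_min <= 0) stop("trend_cfg$sd_min must be > 0")
  ny <- length(years)
  set.seed(seed)

  frac <- if (ny > 1) (seq_len(ny) - 1) / (ny - 1) else 0
  mean_path <- cfg$mean_start + frac * (cfg$mean_end - cfg$mean_start)
  if (cfg$rw_sd > 0 && ny > 2) {
    w <- cumsum(stats::rnorm(ny, 0, cfg$rw_sd))
    mean_path <- mean_path + (w - frac * w[ny])  # Brownian bridge: endpoints kept
  }
  log_sd_path <- log(cfg$sd_start) + frac * (log(cfg$sd_end) - log(cfg$sd_start))

  ctry <- hierarchy_countries(hierarchy)
  sr <- unique(ctry$super_region_id)
  rg <- unique(ctry$region_id)
  u_sr <- stats::setNames(stats::rnorm(length(sr), 0, cfg$re_sd[["super"]]), sr)
  u_rg <- stats::setNames(stats::rnorm(length(rg), 0, cfg$re_sd[["region"]]), rg)
  u_ct <- stats::setNames(stats::rnorm(nrow(ctry), 0, cfg$re_sd[["country"]]),
                          ctry$location_id)
  u_sd <- stats::setNames(stats::rnorm(nrow(ctry), 0, cfg$sd_re_sd),
                          ctry$location_id)

  age_eff <- stats::setNames(numeric(length(cfg$age_groups)), cfg$age_groups)
  if (!is.null(cfg$age_effects)) age_eff[names(cfg$age_effects)] <- cfg$age_effects
  sex_eff <- stats::setNames(numeric(2), SEXES)
  if (!is.null(cfg$sex_effects)) sex_eff[names(cfg$sex_effects)] <- cfg$sex_effects

  grid <- expand.grid(location_id = ctry$location_id, year = years,
                      age_group = cfg$age_groups, sex = SEXES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  yi <- match(grid$year, years)
  loc_off <- u_sr[ctry$super_region_id[match(grid$location_id, ctry$location_id)]] +
    u_rg[ctry$region_id[match(grid$location_id, ctry$location_id)]] +
    u_ct[grid$location_id]
  grid$mean_z <- mean_path[yi] + unname(loc_off) +
    age_eff[grid$age_group] + sex_eff[grid$sex]
  grid$sd_z <- pmax(exp(log_sd_path[yi] + unname(u_sd[grid$location_id])),
                    cfg$sd_min)
  attr(grid, "ensemble") <- cfg$ensemble
  attr(grid, "seed") <- seed
  attr(grid, "components") <- list(mean_path = mean_path,
                                   log_sd_path = log_sd_path,
                                   u_super = u_sr, u_region = u_rg,
                                   u_country = u_ct)
  class(grid) <- c("true_surface", "data.frame")
  grid
}

.truth_lookup <- function(truth, cells) {
  i <- match(cell_key(cells), cell_key(truth))
  if (anyNA(i))
    stop("unknown cell(s): ",
         paste(utils::head(cell_key(cells)[is.na(i)], 3), collapse = "; "))
  i
}

#' Simulate an individual-level (microdata) survey source
#'
#' Draws i.i.d. z-scores from the truth's ensemble distribution, with each
#' cell's true mean and SD, for every requested cell. All cells must share
#' one location-year (a survey measures one country in one year).
#'
#' @param truth a [simulate_truth()] surface.
#' @param cells data frame of cells (`location_id`, `year`, `age_group`,
#'   `sex`) covered by the survey; all rows must exist in `truth` and share
#'   a single location and year.
#' @param n_per_cell records per cell (0 gives an empty record set).
#' @param seed integer seed.
#' @param source_id identifier, default derived from location and year.
#' @return a `survey_source` list: `source_id`, `location_id`, `year`,
#'   `kind = "microdata"`, and `records` (`age_group`, `sex`, `z`).
#' @export
simulate_microdata <- function(truth, cells, n_per_cell, seed = 1,
                               source_id = NULL) {
  idx <- .truth_lookup(truth, cells)
  loc <- unique(cells$location_id); yr <- unique(cells$year)
  if (length(loc) != 1 || length(yr) != 1)
    stop("a microdata source covers a single location-year")
  spec <- attr(truth, "ensemble")
  set.seed(seed)
  recs <- lapply(seq_len(nrow(cells)), function(j) {
    if (n_per_cell == 0) return(NULL)
    z <- ensemble_draws(n_per_cell, spec,
                        list(mean = truth$mean_z[idx[j]],
                             variance = truth$sd_z[idx[j]]^2))
    data.frame(age_group = cells$age_group[j], sex = cells$sex[j], z = z)
  })
  recs <- if (all(vapply(recs, is.null, logical(1))))
    data.frame(age_group = character(), sex = character(), z = numeric())
  else do.call(rbind, recs)
  structure(list(source_id = source_id %||% paste0("micro_", loc, "_", yr),
                 location_id = loc, year = yr, kind = "microdata",
                 records = recs),
            class = "survey_source")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a tabulated (prevalence-only) survey source
#'
#' Emulates report-style sources that publish only prevalences below -2 and
#' -3 SD with a sample size. Counts in the three categories (below -3,
#' between -3 and -2, above -2) are drawn jointly from one trinomial with
#' probabilities given by the truth's ensemble CDF, which guarantees
#' `prev3 <= prev2` on every draw.
#'
#' @inheritParams simulate_microdata
#' @param n sample size per cell (>= 1).
#' @param aggregate if `TRUE`, a single both-sex all-age row is produced by
#'   population-weighting the cell CDFs (requires `populations`).
#' @param populations covariate/population table (see
#'   [simulate_covariates()]); used only when `aggregate = TRUE`.
#' @return a `survey_source` with `kind = "tabulated"` and `records`
#'   (`age_group`, `sex`, `prev2`, `prev3`, `n`).
#' @export
simulate_tabulated <- function(truth, cells, n, seed = 1, aggregate = FALSE,
                               populations = NULL, source_id = NULL) {
  if (n < 1) stop("n must be >= 1")
  idx <- .truth_lookup(truth, cells)
  loc <- unique(cells$location_id); yr <- unique(cells$year)
  if (length(loc) != 1 || length(yr) != 1)
    stop("a tabulated source covers a single location-year")
  spec <- attr(truth, "ensemble")
  cdf <- function(j) prevalence_below(
    spec, list(mean = truth$mean_z[j], variance = truth$sd_z[j]^2), c(-3, -2))
  set.seed(seed)
  draw_row <- function(p3, p2) {
    pr <- c(p3, p2 - p3, 1 - p2)
    x <- stats::rmultinom(1, n, pr)[, 1]
    c(prev3 = x[1] / n, prev2 = (x[1] + x[2]) / n)
  }
  if (aggregate) {
    if (is.null(populations)) stop("aggregate = TRUE requires populations")
    pop <- merge(cells, populations, by = c("location_id", "year", "age_group", "sex"))
    w <- pop$population / sum(pop$population)
    cps <- vapply(idx, cdf, numeric(2))
    p3 <- sum(w * cps[1, ]); p2 <- sum(w * cps[2, ])
    pr <- draw_row(p3, p2)
    recs <- data.frame(age_group = "all", sex = "both",
                       prev2 = pr[["prev2"]], prev3 = pr[["prev3"]], n = n)
  } else {
    recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
      ps <- cdf(idx[j])
      pr <- draw_row(ps[1], ps[2])
      data.frame(age_group = cells$age_group[j], sex = cells$sex[j],
                 prev2 = pr[["prev2"]], prev3 = pr[["prev3"]], n = n)
    }))
  }
  structure(list(source_id = source_id %||% paste0("tab_", loc, "_", yr),
                 location_id = loc, year = yr, kind = "tabulated",
                 records = recs),
            class = "survey_source")
}

#' Split an age-sex-aggregated prevalence into specific cells
#'
#' Distributes a both-sex under-5 aggregate prevalence across age-sex cells
#' in proportion to a pattern surface's cell prevalences, rescaled so the
#' population-weighted mean of the split values reproduces the aggregate
#' exactly. Applied independently to the -2 SD and -3 SD prevalences.
#'
#' @param aggregate a tabulated `survey_source` whose records contain a
#'   single `age_group = "all"`, `sex = "both"` row.
#' @param pattern data frame with `age_group`, `sex` and prevalence columns
#'   `prev2`, `prev3` giving the age-sex pattern for this location-year
#'   (e.g. derived from a fitted or true surface).
#' @param populations covariate table rows for this location-year, used as
#'   split weights.
#' @return a `survey_source` with age-sex-specific `records`.
#' @export
split_aggregated <- function(aggregate, pattern, populations) {
  stopifnot(inherits(aggregate, "survey_source"), aggregate$kind == "tabulated")
  agg <- aggregate$records
  if (nrow(agg) != 1 || agg$age_group != "all" || agg$sex != "both")
    stop("aggregate source must contain one both-sex all-age row")
  keep <- rep(TRUE, nrow(populations))
  if ("location_id" %in% names(populations))
    keep <- keep & populations$location_id == aggregate$location_id
  if ("year" %in% names(populations))
    keep <- keep & populations$year == aggregate$year
  pop <- merge(pattern, as.data.frame(populations)[keep, ],
               by = intersect(intersect(c("location_id", "year", "age_group", "sex"),
                                        names(populations)), names(pattern)))
  if (nrow(pop) != nrow(pattern)) stop("populations do not cover the pattern cells")
  w <- pop$population / sum(pop$population)
  split_one <- function(agg_val, pat) {
    wm <- sum(w * pat)
    if (wm <= 0) {
      if (agg_val > 0) stop("pattern has zero prevalence everywhere but aggregate is positive")
      return(numeric(length(pat)))
    }
    agg_val * pat / wm
  }
  out <- data.frame(age_group = pop$age_group, sex = pop$sex,
                    prev2 = split_one(agg$prev2, pop$prev2),
                    prev3 = split_one(agg$prev3, pop$prev3),
                    n = round(agg$n * w))
  structure(list(source_id = paste0(aggregate$source_id, "_split"),
                 location_id = aggregate$location_id, year = aggregate$year,
                 kind = "tabulated", records = out),
            class = "survey_source")
}

#' Simulate covariates, UHC/SDI series and populations
#'
#' Generates, per cell on the truth grid: named covariates that are monotone
#' linear transforms of the true mean z-score plus Gaussian noise (so the
#' stage-1 covariate selection has real signal to find); a UHC index and SDI
#' in `[0, 100]` at location-year level (logistic transforms of the true
#' country-year mean plus noise); and a population count.
#'
#' @param truth a [simulate_truth()] surface.
#' @param cfg optional list: `covariates` (named list of
#'   `list(slope =, noise_sd =)` describing each covariate's dependence on
#'   the true mean z), `uhc_noise_sd` (0.15), `sdi_noise_sd` (0.2),
#'   `pop_meanlog` (`log(5e5)`), `pop_sdlog` (0.5).
#' @param seed integer seed.
#' @return a `covariate_table`: data frame keyed by cell with one column per
#'   covariate plus `uhc`, `sdi`, `population`.
#' @export
simulate_covariates <- function(truth, cfg = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    covariates = list(
      health_access = list(slope = 1.0, noise_sd = 0.10),
      nutrition_score = list(slope = 0.8, noise_sd = 0.15)
    ),
    uhc_noise_sd = 0.15, sdi_noise_sd = 0.2,
    pop_meanlog = log(5e5), pop_sdlog = 0.5
  ), cfg)
  set.seed(seed)
  out <- as.data.frame(truth)[c("location_id", "year", "age_group", "sex")]
  n <- nrow(out)
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    out[[nm]] <- cv$slope * truth$mean_z + stats::rnorm(n, 0, cv$noise_sd)
  }
  ## location-year level indices from the country-year mean of the truth
  ly <- stats::aggregate(mean_z ~ location_id + year, data = as.data.frame(truth), FUN = mean)
  ly$uhc <- 100 * stats::plogis(1.2 * (ly$mean_z + 1.4) +
                                  stats::rnorm(nrow(ly), 0, cfg$uhc_noise_sd))
  ly$sdi <- 100 * stats::plogis(0.9 * (ly$mean_z + 1.3) +
                                  stats::rnorm(nrow(ly), 0, cfg$sdi_noise_sd))
  i <- match(paste(out$location_id, out$year), paste(ly$location_id, ly$year))
  out$uhc <- ly$uhc[i]
  out$sdi <- ly$sdi[i]
  out$population <- round(stats::rlnorm(n, cfg$pop_meanlog, cfg$pop_sdlog))
  attr(out, "seed") <- seed
  class(out) <- c("covariate_table", "data.frame")
  out
}
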