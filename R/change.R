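## Draw-level relative change, population aggregation, median-based
## summaries, annual-change disruption analysis by UHC direction, and
## two-sample Kolmogorov-Smirnov comparisons.

## Population-weighted aggregation of prevalence draws to both-sex under-5,
## per location. Returns list(location_id, draws matrix).
.aggregate_draws <- function(cells, draw_mat, populations) {
  pop <- merge(cells, as.data.frame(populations),
               by = c("location_id", "year", "age_group", "sex"), sort = FALSE)
  i <- match(cell_key(cells), cell_key(pop))
  if (anyNA(i)) stop("populations do not cover all cells")
  popv <- pop$population[i]
  locs <- sort(unique(cells$location_id))
  agg <- matrix(NA_real_, length(locs), ncol(draw_mat),
                dimnames = list(locs, NULL))
  for (k in seq_along(locs)) {
    sel <- cells$location_id == locs[k]
    w <- popv[sel]
    if (sum(w) <= 0) stop("zero population total for ", locs[k])
    agg[k, ] <- colSums(draw_mat[sel, , drop = FALSE] * w) / sum(w)
  }
  agg
}

#' Draw-level relative change in prevalence since a reference year
#'
#' Computes, per location and severity, the relative change
#' `(reference - current) / reference` on every draw, with positive values
#' denoting decreases in prevalence (improvement). Age- and sex-specific
#' prevalence draws are aggregated to both-sex under-5 totals with
#' population weights BEFORE the ratio is taken. Draws whose reference
#' aggregate is below `ref_floor` are dropped (their count is recorded);
#' near-zero reference prevalences otherwise produce unbounded ratios.
#'
#' @param current,reference `growth_surface` objects (see
#'   [integrate_surface()]) for the comparison and reference years;
#'   draw-aligned.
#' @param populations covariate table with populations for both years'
#'   cells.
#' @param severities which prevalence thresholds to process, default all in
#'   the surface.
#' @param ref_floor reference-draw floor, default `1e-9`.
#' @return a `change_draws` object: `locations`, named list `draws` of
#'   (location x draw) matrices per severity, `n_dropped` per severity.
#' @export
relative_change <- function(current, reference, populations,
                            severities = names(current$prev),
                            ref_floor = 1e-9) {
  stopifnot(inherits(current, "growth_surface"),
            inherits(reference, "growth_surface"),
            ncol(current$mean_z) == ncol(reference$mean_z))
  out <- list(); dropped <- integer()
  for (sv in severities) {
    cur <- .aggregate_draws(current$cells, current$prev[[sv]], populations)
    ref <- .aggregate_draws(reference$cells, reference$prev[[sv]], populations)
    stopifnot(identical(rownames(cur), rownames(ref)))
    ch <- (ref - cur) / ref
    bad <- ref < ref_floor
    ch[bad] <- NA_real_
    dropped[sv] <- sum(bad)
    out[[sv]] <- ch
  }
  structure(list(locations = rownames(out[[1]]), draws = out,
                 n_dropped = dropped),
            class = "change_draws")
}

#' Summarise relative-change draws
#'
#' The median of the draw distribution with a 95% uncertainty interval
#' (2.5th / 97.5th percentiles). The median, not the mean, is the headline
#' statistic: reference draws near zero give the change distribution a heavy
#' right tail that makes the mean unrepresentative.
#'
#' @param change a `change_draws` from [relative_change()], or a numeric
#'   vector of draws.
#' @return data frame `location_id`, `severity`, `median`, `lower`, `upper`
#'   (or a named vector for numeric input).
#' @export
summarize_change <- function(change) {
  if (is.numeric(change)) {
    s <- draw_summary(change[is.finite(change)], center = "median")
    return(c(median = s[1], lower = s[2], upper = s[3]))
  }
  stopifnot(inherits(change, "change_draws"))
  do.call(rbind, lapply(names(change$draws), function(sv) {
    m <- change$draws[[sv]]
    s <- t(apply(m, 1, function(x) draw_summary(x[is.finite(x)], center = "median")))
    data.frame(location_id = rownames(m), severity = sv,
               median = s[, 1], lower = s[, 2], upper = s[, 3],
               row.names = NULL)
  }))
}

#' Annual relative changes classified by UHC index direction
#'
#' For every location-year from 1991 to 2019 and every severity, computes
#' the relative change in both-sex under-5 prevalence versus the prior year
#' (draw-level, summarised by the median) and labels the record by whether
#' the UHC index improved or worsened that year. Records are kept only if
#' the location-year's mean prevalence exceeds `prev_floor` (one per
#' million) and its under-5 population exceeds `pop_floor` (300,000);
#' location-years with no UHC movement (|delta| < 1e-9) are excluded, as are
#' 1990 (no reference year) and 2020.
#'
#' @param surface a `growth_surface` covering consecutive years 1990-2020
#'   (or any contiguous span).
#' @param uhc covariate table with a `uhc` column per location-year.
#' @param populations covariate table with populations.
#' @param severities severity names to process.
#' @param prev_floor,pop_floor inclusion filters, defaults `1e-6` and
#'   `3e5`.
#' @param years analysis years, default `1991:2019`.
#' @return data frame of `annual_change` records: `location_id`, `year`,
#'   `severity`, `change` (median draw-level relative annual change,
#'   positive = improvement), `uhc_direction` (`improved` / `worsened`).
#' @export
annual_changes <- function(surface, uhc, populations,
                           severities = names(surface$prev),
                           prev_floor = 1e-6, pop_floor = 3e5,
                           years = 1991:2019) {
  stopifnot(inherits(surface, "growth_surface"))
  cells <- surface$cells
  uhc_ly <- unique(as.data.frame(uhc)[c("location_id", "year", "uhc")])
  pop <- as.data.frame(populations)
  recs <- list()
  for (sv in severities) {
    agg_by_year <- list()
    for (y in sort(unique(cells$year))) {
      sel <- cells$year == y
      agg_by_year[[as.character(y)]] <-
        .aggregate_draws(cells[sel, ], surface$prev[[sv]][sel, , drop = FALSE],
                         pop)
    }
    pop_by_ly <- stats::aggregate(population ~ location_id + year, data = pop, FUN = sum)
    for (y in years) {
      cur <- agg_by_year[[as.character(y)]]
      ref <- agg_by_year[[as.character(y - 1)]]
      if (is.null(cur) || is.null(ref)) {
        message("annual_changes: missing year ", y, " or ", y - 1, "; skipped")
        next
      }
      for (L in rownames(cur)) {
        du <- uhc_ly$uhc[uhc_ly$location_id == L & uhc_ly$year == y] -
          uhc_ly$uhc[uhc_ly$location_id == L & uhc_ly$year == y - 1]
        if (!length(du) || abs(du) < 1e-9) next
        pL <- pop_by_ly$population[pop_by_ly$location_id == L & pop_by_ly$year == y]
        if (!length(pL) || pL <= pop_floor) next
        if (mean(cur[L, ]) <= prev_floor) next
        ch <- (ref[L, ] - cur[L, ]) / ref[L, ]
        ch <- ch[is.finite(ch) & ref[L, ] > 1e-9]
        if (!length(ch)) next
        recs[[length(recs) + 1L]] <- data.frame(
          location_id = L, year = y, severity = sv,
          change = stats::median(ch),
          uhc_direction = if (du > 0) "improved" else "worsened")
      }
    }
  }
  if (!length(recs))
    return(data.frame(location_id = character(), year = integer(),
                      severity = character(), change = numeric(),
                      uhc_direction = character()))
  do.call(rbind, recs)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum absolute difference between the two empirical CDFs, with the
#' asymptotic two-sample p-value. Used to compare distributions of annual
#' relative change between UHC-improved and UHC-worsened location-years.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return list with elements `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
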