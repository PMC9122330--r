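## Variance recovery and threshold integration: reconcile the three ST-GPR
## indicator models (mean z-score, prevalence < -2 SD, prevalence < -3 SD)
## into one continuous ensemble curve per cell-draw, then integrate the curve
## at every severity threshold.

#' Severity thresholds for child growth failure
#'
#' The four z-score cutoffs used throughout: auxiliary (-1 SD, used only in
#' ensemble weight fitting), overall (-2 SD), severe (-3 SD) and extreme
#' (-4 SD).
#'
#' @return named numeric vector, strictly decreasing.
#' @export
severity_thresholds <- function() {
  c(auxiliary = -1, overall = -2, severe = -3, extreme = -4)
}

## Build a fast closure computing ensemble prevalences below `thresholds`
## for fixed spec. Family dispatch is resolved once at construction and the
## component CDFs are evaluated in closed form, which keeps the SD
## optimisation's objective cheap (it runs once per cell-draw).
.make_cdf_fun <- function(spec, thresholds) {
  act <- names(spec$weights)[spec$weights > 1e-12]
  w <- unname(spec$weights[act])
  shift <- spec$shift; anchor <- spec$mirror_anchor
  t <- thresholds
  ts <- pmax(t + shift, 0)     # shifted-scale evaluation points
  tm <- pmax(anchor - t, 0)    # mirrored-scale evaluation points
  nt <- length(t)
  ## per-family closed-form CDF evaluators: f(ms, v) with ms the mean on the
  ## family's own scale; return NULL when infeasible
  evals <- lapply(act, function(f) switch(f,
    normal = function(ms, v) stats::pnorm(t, ms, sqrt(v)),
    gumbel = function(ms, v) {
      s <- sqrt(6 * v) / pi
      exp(-exp(-(t - (ms - EULER_GAMMA * s)) / s))
    },
    mirrored_gumbel = function(ms, v) {
      if (ms <= 0) return(NULL)
      s <- sqrt(6 * v) / pi
      1 - exp(-exp(-(tm - (ms - EULER_GAMMA * s)) / s))
    },
    log_normal = function(ms, v) {
      if (ms <= 0) return(NULL)
      s2 <- log1p(v / ms^2)
      stats::pnorm((log(ts) - (log(ms) - s2 / 2)) / sqrt(s2))
    },
    log_logistic = function(ms, v) {
      if (ms <= 0) return(NULL)
      b <- llogis_shape(v / ms^2)
      th <- pi / b
      alpha <- ms * sin(th) / th
      ifelse(ts > 0, 1 / (1 + (ts / alpha)^(-b)), 0)
    },
    exponential = function(ms, v) {
      if (ms <= 0) return(NULL)
      -expm1(-ts / ms)
    },
    gamma = function(ms, v) {
      if (ms <= 0) return(NULL)
      stats::pgamma(ts, shape = ms^2 / v, rate = ms / v)
    },
    mirrored_gamma = function(ms, v) {
      if (ms <= 0) return(NULL)
      stats::pgamma(tm, shape = ms^2 / v, rate = ms / v, lower.tail = FALSE)
    },
    inverse_gamma = function(ms, v) {
      if (ms <= 0) return(NULL)
      a <- ms^2 / v + 2
      ifelse(ts > 0,
             stats::pgamma(1 / ts, shape = a, rate = ms * (a - 1),
                           lower.tail = FALSE), 0)
    },
    weibull = function(ms, v) {
      if (ms <= 0) return(NULL)
      k <- weibull_shape(v / ms^2)
      -expm1(-(ts / exp(log(ms) - lgamma(1 + 1 / k)))^k)
    },
    stop("unknown family: ", f)
  ))
  mirrored <- act %in% MIRRORED_FAMILIES
  positive <- act %in% POSITIVE_FAMILIES
  function(mean_z, variance) {
    out <- numeric(nt)
    tot <- 0
    for (j in seq_along(act)) {
      ms <- if (mirrored[j]) anchor - mean_z
            else if (positive[j]) mean_z + shift else mean_z
      p <- evals[[j]](ms, variance)
      if (is.null(p)) next
      out <- out + w[j] * p
      tot <- tot + w[j]
    }
    if (tot <= 0) return(rep(NA_real_, nt))
    clamp(out / tot, 0, 1)
  }
}

#' Solve for the ensemble SD matching modelled threshold prevalences
#'
#' Finds the standard deviation that, with the mean anchored at `mean_z`,
#' makes the ensemble's prevalences below -2 SD and -3 SD best match the
#' ST-GPR modelled targets (least squares, both thresholds weighted equally).
#' The search runs Nelder-Mead over a logistic reparameterisation of the
#' bracket `[0.05, 5]` z-score units, restarting from SD = 0.5, 1 and 2 and
#' keeping the best solution. When `target_prev3` is numerically zero the SD
#' is fit to the -2 SD target alone, which avoids degeneracy in
#' near-zero-prevalence cells.
#'
#' @param spec an [ensemble_spec()].
#' @param mean_z anchored mean z-score.
#' @param target_prev2,target_prev3 modelled prevalences below -2 and -3 SD;
#'   must satisfy `target_prev3 <= target_prev2`.
#' @param bracket positive SD search range, default `c(0.05, 5)`.
#' @param starts restart SD values, default `c(0.5, 1, 2)`.
#' @param zero_floor prevalence below which the -3 SD target is treated as
#'   numerically zero, default `1e-7`.
#' @return the fitted SD (scalar), with the attained objective in attribute
#'   `"objective"`.
#' @examples
#' spec <- ensemble_spec(c(normal = 1))
#' optimize_sd(spec, -2, 0.5, pnorm(-1))  # recovers sd = 1
#' @export
optimize_sd <- function(spec, mean_z, target_prev2, target_prev3,
                        bracket = c(0.05, 5), starts = c(0.5, 1, 2),
                        zero_floor = 1e-7) {
  if (!is.finite(target_prev2) || !is.finite(target_prev3))
    stop("targets must be finite")
  if (target_prev3 > target_prev2 + 1e-12)
    stop(errorCondition("inconsistent targets: prev3 > prev2",
                        class = c("cgf_inconsistent_targets", "error", "condition")))
  cdf2 <- .make_cdf_fun(spec, c(-2, -3))
  use3 <- target_prev3 > zero_floor
  obj_sd <- function(s) {
    p <- cdf2(mean_z, s^2)
    if (anyNA(p)) return(1e6)
    if (use3) (p[1] - target_prev2)^2 + (p[2] - target_prev3)^2
    else (p[1] - target_prev2)^2
  }
  .optimize_sd_core(obj_sd, bracket, starts)
}

## Shared bracketed 1-D Nelder-Mead minimiser over sd.
.optimize_sd_core <- function(obj_sd, bracket, starts) {
  lo <- bracket[1]; hi <- bracket[2]
  to_sd <- function(u) lo + (hi - lo) * stats::plogis(u)
  to_u <- function(s) stats::qlogis((s - lo) / (hi - lo))
  fn <- function(u) obj_sd(to_sd(u))
  best <- NULL
  for (s0 in starts) {
    s0 <- clamp(s0, lo + 1e-6, hi - 1e-6)
    fit <- suppressWarnings(
      stats::optim(to_u(s0), fn, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-12, warn.1d.NelderMead = FALSE)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  sd_hat <- to_sd(best$par)
  if (sd_hat < lo + 1e-4 || sd_hat > hi - 1e-4)
    warning("optimize_sd solution at bracket bound (sd = ",
            format(sd_hat, digits = 4), ")")
  structure(sd_hat, objective = best$value)
}

#' Integrate ST-GPR draws into a multi-severity growth surface
#'
#' For every cell and draw, solves [optimize_sd()] against that draw's
#' modelled prevalences (mean anchored at the draw's mean z-score), then
#' evaluates the ensemble prevalence below every severity threshold. The
#' severity ordering extreme <= severe <= overall holds by CDF monotonicity.
#' Draws for which the SD solve fails are imputed from the cell's median
#' fitted SD; the count is reported in the result.
#'
#' @param spec an [ensemble_spec()].
#' @param cells data frame with columns `location_id`, `year`, `age_group`,
#'   `sex` (one row per cell, aligned with the draw matrices).
#' @param mean_draws,prev2_draws,prev3_draws numeric matrices
#'   (cells x draws), draw-aligned across the three indicators.
#' @param thresholds named thresholds, default [severity_thresholds()]
#'   without the auxiliary cutoff.
#' @param warm_start reuse the previous draw's SD as the single restart for
#'   subsequent draws in a cell (default `TRUE`; the first draw always uses
#'   the full restart set).
#' @return a `growth_surface` object: `cells`, `mean_z` and `sd_z` draw
#'   matrices, a named list `prev` of draw matrices (one per threshold), and
#'   `n_imputed`.
#' @export
integrate_surface <- function(spec, cells, mean_draws, prev2_draws, prev3_draws,
                              thresholds = severity_thresholds()[c("overall", "severe", "extreme")],
                              warm_start = TRUE) {
  n_cell <- nrow(cells)
  n_draw <- ncol(mean_draws)
  stopifnot(nrow(mean_draws) == n_cell,
            identical(dim(mean_draws), dim(prev2_draws)),
            identical(dim(mean_draws), dim(prev3_draws)))
  cdf2 <- .make_cdf_fun(spec, c(-2, -3))
  cdft <- .make_cdf_fun(spec, unname(thresholds))
  sd_z <- matrix(NA_real_, n_cell, n_draw)
  prev <- lapply(thresholds, function(t) matrix(NA_real_, n_cell, n_draw))
  names(prev) <- names(thresholds)
  n_imputed <- 0L
  bracket <- c(0.05, 5)
  for (i in seq_len(n_cell)) {
    prev_sd <- NA_real_
    prev_in <- c(NA_real_, NA_real_, NA_real_)
    for (d in seq_len(n_draw)) {
      m <- mean_draws[i, d]
      p2 <- clamp(prev2_draws[i, d], 0, 1)
      p3 <- min(clamp(prev3_draws[i, d], 0, 1), p2)
      if (identical(c(m, p2, p3), prev_in)) {  # repeated draw: reuse solve
        sd_z[i, d] <- prev_sd
        next
      }
      prev_in <- c(m, p2, p3)
      use3 <- p3 > 1e-7
      obj <- function(s) {
        p <- cdf2(m, s^2)
        if (anyNA(p)) return(1e6)
        if (use3) (p[1] - p2)^2 + (p[2] - p3)^2 else (p[1] - p2)^2
      }
      s_hat <- tryCatch({
        if (warm_start && is.finite(prev_sd)) {
          ## bounded golden-section solve in a bracket around the previous
          ## draw's solution; falls back to the full bracket if it pins to
          ## a sub-bracket edge
          lo2 <- max(bracket[1], prev_sd * 0.6)
          hi2 <- min(bracket[2], prev_sd * 1.7)
          o <- stats::optimize(obj, c(lo2, hi2), tol = 1e-5)
          if ((o$minimum - lo2 < 1e-3 && lo2 > bracket[1] + 1e-9) ||
              (hi2 - o$minimum < 1e-3 && hi2 < bracket[2] - 1e-9))
            o <- stats::optimize(obj, bracket, tol = 1e-5)
          o$minimum
        } else {
          suppressWarnings(as.numeric(.optimize_sd_core(obj, bracket, c(0.5, 1, 2))))
        }
      }, error = function(e) NA_real_)
      sd_z[i, d] <- s_hat
      if (is.finite(s_hat)) prev_sd <- s_hat
    }
    bad <- !is.finite(sd_z[i, ])
    if (any(bad)) {
      med <- stats::median(sd_z[i, !bad])
      if (!is.finite(med)) med <- 1
      sd_z[i, bad] <- med
      n_imputed <- n_imputed + sum(bad)
    }
    for (d in seq_len(n_draw)) {
      p <- cdft(mean_draws[i, d], sd_z[i, d]^2)
      for (k in seq_along(thresholds)) prev[[k]][i, d] <- p[k]
    }
  }
  if (n_imputed > 0)
    message("integrate_surface: imputed SD for ", n_imputed, " draw(s)")
  structure(list(cells = cells, mean_z = mean_draws, sd_z = sd_z,
                 prev = prev, thresholds = thresholds,
                 n_imputed = n_imputed),
            class = "growth_surface")
}

#' Construct a growth surface from draw matrices
#'
#' Lightweight constructor used when severity-prevalence draws come from
#' elsewhere than [integrate_surface()] (e.g. subsetting or tests).
#'
#' @param cells cell data frame (`location_id`, `year`, `age_group`, `sex`).
#' @param prev named list of (cells x draws) prevalence matrices, one per
#'   severity.
#' @param mean_z,sd_z optional draw matrices; default `NA` matrices.
#' @return a `growth_surface`.
#' @export
growth_surface <- function(cells, prev, mean_z = NULL, sd_z = NULL) {
  stopifnot(is.list(prev), length(prev) >= 1, !is.null(names(prev)))
  nd <- ncol(prev[[1]])
  for (m in prev) stopifnot(nrow(m) == nrow(cells), ncol(m) == nd)
  blank <- matrix(NA_real_, nrow(cells), nd)
  structure(list(cells = cells, mean_z = mean_z %||% blank,
                 sd_z = sd_z %||% blank, prev = prev,
                 thresholds = severity_thresholds()[names(prev)],
                 n_imputed = 0L),
            class = "growth_surface")
}

#' Subset a growth surface by cell
#'
#' @param surface a `growth_surface`.
#' @param sel logical or integer row selector over `surface$cells`.
#' @return the subsetted `growth_surface`.
#' @export
surface_subset <- function(surface, sel) {
  growth_surface(surface$cells[sel, , drop = FALSE],
                 lapply(surface$prev, function(m) m[sel, , drop = FALSE]),
                 mean_z = surface$mean_z[sel, , drop = FALSE],
                 sd_z = surface$sd_z[sel, , drop = FALSE])
}

#' @export
print.growth_surface <- function(x, ...) {
  cat("Growth surface:", nrow(x$cells), "cells x", ncol(x$mean_z), "draws;",
      "thresholds:", paste(names(x$prev), collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a growth surface across draws
#'
#' Mean with 2.5th/97.5th percentile uncertainty intervals, per cell and
#' severity, plus the mean z-score summaries.
#'
#' @param surface a `growth_surface` from [integrate_surface()].
#' @return data frame with columns `location_id`, `year`, `age_group`, `sex`,
#'   `measure` (`mean_z`, `sd_z` or a severity name), `mean`, `lower`,
#'   `upper`.
#' @export
summarize_surface <- function(surface) {
  stopifnot(inherits(surface, "growth_surface"))
  mats <- c(list(mean_z = surface$mean_z, sd_z = surface$sd_z), surface$prev)
  mats <- Filter(function(m) !all(is.na(m)), mats)
  out <- do.call(rbind, lapply(names(mats), function(nm) {
    s <- t(apply(mats[[nm]], 1, draw_summary))
    data.frame(surface$cells, measure = nm,
               mean = s[, 1], lower = s[, 2], upper = s[, 3],
               row.names = NULL)
  }))
  out
}

#' Share of overall cases that are at a deeper severity
#'
#' The proportion of children below the overall threshold who are also below
#' a deeper one, e.g. the share of stunted children who are extremely
#' stunted: `subset_prev / overall_prev`. Vectorised; with draw matrices the
#' ratio is taken per draw.
#'
#' @param overall_prev prevalence(s) below the overall threshold (> 0).
#' @param subset_prev prevalence(s) below the deeper threshold,
#'   `<= overall_prev`.
#' @return proportions in `[0, 1]` with the shape of the inputs.
#' @examples
#' severity_share(0.488, 0.113)  # 0.2316: ~23.2% of stunted children extreme
#' @export
severity_share <- function(overall_prev, subset_prev) {
  if (any(overall_prev <= 0)) stop("overall_prev must be positive")
  if (any(subset_prev > overall_prev + 1e-12))
    stop("subset_prev must not exceed overall_prev")
  subset_prev / overall_prev
}
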