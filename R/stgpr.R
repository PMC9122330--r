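## Three-stage spatiotemporal Gaussian process regression (ST-GPR):
##   stage 1 — ensemble mixed-effects linear prior over candidate covariate
##             subsets, with sign/significance filtering and out-of-sample
##             RMSE weighting;
##   stage 2 — residual smoothing across space (hierarchy), time and age,
##             controlled by hyperparameters zeta / lambda / omega;
##   stage 3 — per-series Gaussian process over years, sampled into draws.
##
## Prevalence indicators are modelled in logit space, mean z-score in
## identity space.

#' ST-GPR hyperparameters
#'
#' @param zeta space weight in `(0, 1]`: residuals from the same country get
#'   weight 1, same region `zeta`, same super-region `zeta^2`, elsewhere 0.
#' @param lam time-window exponent (> 0) of the tricube-style weight
#'   `(1 - (|dt| / (1 + max |dt|))^lam)^3`.
#' @param omega age-similarity decay (> 0): weight `omega^-|rank distance|`
#'   across the six age bins.
#' @return a `stgpr_hyperparams` list.
#' @export
stgpr_hyperparams <- function(zeta = 0.9, lam = 1, omega = 2) {
  stopifnot(zeta > 0, zeta <= 1, lam > 0, omega > 0,
            is.finite(zeta), is.finite(lam), is.finite(omega))
  structure(list(zeta = zeta, lam = lam, omega = omega),
            class = "stgpr_hyperparams")
}

## --- transform helpers ------------------------------------------------------

## Forward transform of observed values and (delta-method) variances.
transform_obs <- function(value, variance, transform, floor = 1e-7) {
  if (transform == "identity") return(list(value = value, variance = variance))
  p <- clamp(value, floor, 1 - floor)
  list(value = stats::qlogis(p), variance = variance / (p * (1 - p))^2)
}

back_transform <- function(x, transform) {
  if (transform == "identity") x else stats::plogis(x)
}

## --- observation preparation ------------------------------------------------

#' Collapse survey sources into ST-GPR observations
#'
#' Microdata sources contribute cell means (indicator `mean`: sample mean of
#' z with variance s^2/n) or empirical threshold proportions (indicators
#' `prev2` / `prev3`, binomial variance). Tabulated sources contribute their
#' reported prevalences with binomial variance; they carry no information on
#' the mean z-score.
#'
#' @param sources list of `survey_source` objects.
#' @param indicator one of `"mean"`, `"prev2"`, `"prev3"`.
#' @param min_n minimum records per microdata cell, default 2.
#' @return data frame `location_id`, `year`, `age_group`, `sex`, `value`,
#'   `variance`, `source_id`.
#' @export
sources_to_observations <- function(sources, indicator = c("mean", "prev2", "prev3"),
                                    min_n = 2) {
  indicator <- match.arg(indicator)
  thr <- c(prev2 = -2, prev3 = -3)
  rows <- lapply(sources, function(s) {
    if (s$kind == "microdata") {
      r <- s$records
      if (!nrow(r)) return(NULL)
      sp <- split(r$z, paste(r$age_group, r$sex, sep = "|"))
      out <- do.call(rbind, lapply(names(sp), function(k) {
        z <- sp[[k]]
        if (length(z) < min_n) return(NULL)
        ag <- strsplit(k, "|", fixed = TRUE)[[1]]
        if (indicator == "mean") {
          data.frame(age_group = ag[1], sex = ag[2],
                     value = mean(z), variance = var_n1(z) / length(z))
        } else {
          p <- mean(z < thr[[indicator]])
          pc <- clamp(p, 1 / (length(z) + 1), 1 - 1 / (length(z) + 1))
          data.frame(age_group = ag[1], sex = ag[2],
                     value = p, variance = pc * (1 - pc) / length(z))
        }
      }))
      if (is.null(out)) return(NULL)
    } else {
      if (indicator == "mean") return(NULL)
      r <- s$records
      r <- r[r$age_group != "all" & r$sex != "both", , drop = FALSE]
      if (!nrow(r)) return(NULL)
      p <- r[[indicator]]
      pc <- clamp(p, 1 / (r$n + 1), 1 - 1 / (r$n + 1))
      out <- data.frame(age_group = r$age_group, sex = r$sex,
                        value = p, variance = pc * (1 - pc) / r$n)
    }
    cbind(location_id = s$location_id, year = s$year, out,
          source_id = s$source_id)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable observations for indicator ", indicator)
  rownames(out) <- NULL
  out
}

## --- stage 1: ensemble linear prior ----------------------------------------

## Random-effects formula using only grouping levels with >= 2 groups.
.re_terms <- function(df) {
  terms <- character()
  for (g in c("super_region_id", "region_id", "location_id"))
    if (length(unique(df[[g]])) >= 2)
      terms <- c(terms, paste0("(1|", g, ")"))
  terms
}

.attach_hierarchy <- function(df, hierarchy) {
  ctry <- hierarchy_countries(hierarchy)
  i <- match(df$location_id, ctry$location_id)
  if (anyNA(i)) stop("observation locations missing from hierarchy")
  df$region_id <- ctry$region_id[i]
  df$super_region_id <- ctry$super_region_id[i]
  df
}

.fit_mixed <- function(formula_str, df) {
  f <- stats::as.formula(formula_str)
  if (grepl("\\|", formula_str)) {
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
  } else {
    stats::lm(f, data = df)
  }
}

.predict_mixed <- function(fit, newdata) {
  if (inherits(fit, "merMod")) {
    suppressMessages(suppressWarnings(
      stats::predict(fit, newdata = newdata, allow.new.levels = TRUE)))
  } else {
    stats::predict(fit, newdata = newdata)
  }
}

#' Fit the stage-1 ensemble linear prior
#'
#' Enumerates covariate subsets (size-capped), fits each as a linear mixed
#' model with nested super-region / region / location random intercepts in
#' transform space, drops models whose covariate coefficients are not
#' significant (Wald, p < 0.05) or not in the declared expected direction,
#' ranks survivors by location-grouped out-of-sample RMSE, and averages the
#' top performers with weights proportional to `exp(-rmse / min(rmse))`. If
#' every candidate is dropped, an intercept-plus-random-effects model is used
#' and a message is logged.
#'
#' @param data observations (natural space) from [sources_to_observations()].
#' @param covariates a [simulate_covariates()]-style table covering the full
#'   estimation grid.
#' @param hierarchy a [make_hierarchy()] result.
#' @param expected_signs named numeric vector (+1 / -1) giving each candidate
#'   covariate's a-priori coefficient direction on the transform scale.
#' @param transform `"identity"` or `"logit"`.
#' @param holdout_cfg list: `n_folds` (5) location-grouped CV folds,
#'   `max_subset` (3) covariate subset size cap, `top_n` (10) models kept in
#'   the ensemble.
#' @param seed integer seed for the fold assignment.
#' @return a `stage1_prior`: `prior` (grid data frame with column `prior` in
#'   transform space), `models` (retained subsets with RMSE and weight),
#'   `transform`, `fallback` flag.
#' @export
fit_stage1 <- function(data, covariates, hierarchy, expected_signs,
                       transform = "identity",
                       holdout_cfg = list(), seed = 1) {
  cfg <- utils::modifyList(list(n_folds = 5, max_subset = 3, top_n = 10),
                           holdout_cfg)
  cand <- names(expected_signs)
  stopifnot(length(cand) >= 1, all(cand %in% names(covariates)))
  obs <- merge(data, as.data.frame(covariates),
               by = c("location_id", "year", "age_group", "sex"))
  obs <- .attach_hierarchy(obs, hierarchy)
  tr <- transform_obs(obs$value, obs$variance, transform)
  obs$y <- tr$value
  grid <- .attach_hierarchy(as.data.frame(covariates), hierarchy)

  subsets <- list()
  for (k in seq_len(min(cfg$max_subset, length(cand))))
    subsets <- c(subsets, utils::combn(cand, k, simplify = FALSE))

  re <- .re_terms(obs)
  ## age and sex enter every candidate as fixed effects so demographic
  ## contrasts are absorbed by the prior rather than leaking into the
  ## spatiotemporal residuals
  demo <- c(if (length(unique(obs$age_group)) > 1) "age_group",
            if (length(unique(obs$sex)) > 1) "sex")
  form <- function(cs) paste("y ~", paste(c(cs, demo, re), collapse = " + "))

  keep_subset <- function(cs) {
    fit <- try(.fit_mixed(form(cs), obs), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    co <- if (inherits(fit, "merMod")) summary(fit)$coefficients
          else summary(fit)$coefficients[, 1:3, drop = FALSE]
    for (v in cs) {
      if (!v %in% rownames(co)) return(NULL)
      est <- co[v, "Estimate"]; tval <- co[v, "t value"]
      p <- 2 * stats::pnorm(-abs(tval))
      if (p >= 0.05 || sign(est) != sign(expected_signs[[v]])) return(NULL)
    }
    fit
  }

  fits <- lapply(subsets, keep_subset)
  kept <- !vapply(fits, is.null, logical(1))
  subsets <- subsets[kept]; fits <- fits[kept]

  fallback <- length(subsets) == 0
  if (fallback) {
    message("fit_stage1: all candidate models dropped; intercept fallback")
    f0 <- .fit_mixed(paste("y ~", paste(c("1", demo, re), collapse = " + ")), obs)
    prior <- grid[c("location_id", "year", "age_group", "sex")]
    prior$prior <- as.numeric(.predict_mixed(f0, grid))
    return(structure(list(prior = prior, models = NULL, transform = transform,
                          fallback = TRUE), class = "stage1_prior"))
  }

  ## location-grouped out-of-sample RMSE
  set.seed(seed)
  locs <- unique(obs$location_id)
  fold <- stats::setNames(sample(rep_len(seq_len(min(cfg$n_folds, length(locs))),
                                         length(locs))), locs)
  oos_rmse <- vapply(seq_along(subsets), function(j) {
    errs <- unlist(lapply(seq_len(max(fold)), function(fd) {
      tr_i <- fold[obs$location_id] != fd
      if (all(tr_i) || !any(tr_i)) return(NULL)
      fit <- try(.fit_mixed(form(subsets[[j]]), obs[tr_i, ]), silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      pred <- .predict_mixed(fit, obs[!tr_i, ])
      (pred - obs$y[!tr_i])^2
    }))
    if (!length(errs)) return(Inf)
    sqrt(mean(errs))
  }, numeric(1))

  ord <- order(oos_rmse)
  ord <- ord[seq_len(min(cfg$top_n, length(ord)))]
  ord <- ord[is.finite(oos_rmse[ord])]
  if (!length(ord)) ord <- seq_along(subsets)[1]
  rmse <- oos_rmse[ord]
  w <- exp(-rmse / min(rmse)); w <- w / sum(w)

  preds <- vapply(ord, function(j) as.numeric(.predict_mixed(fits[[j]], grid)),
                  numeric(nrow(grid)))
  prior <- grid[c("location_id", "year", "age_group", "sex")]
  prior$prior <- as.numeric(preds %*% w)

  models <- data.frame(
    covariates = vapply(subsets[ord], paste, character(1), collapse = "+"),
    oos_rmse = rmse, weight = w)
  structure(list(prior = prior, models = models, transform = transform,
                 fallback = FALSE), class = "stage1_prior")
}

## --- stage 2: spatiotemporal residual smoothing ----------------------------

#' Smooth data-minus-prior residuals over space, time and age
#'
#' For every grid cell, forms a weighted average of observed residuals where
#' the weight is the product of a space weight (1 for the same country,
#' `zeta` for the same region, `zeta^2` for the same super-region, 0
#' otherwise), a tricube-style time weight
#' `(1 - (|dt| / (1 + max |dt|))^lam)^3`, and an age weight
#' `omega^-|rank distance|` over the six age bins. Only same-sex residuals
#' are pooled. Cells with no in-scope residuals keep the prior.
#'
#' @param prior the `stage1_prior` from [fit_stage1()] (or any data frame of
#'   grid cells with a `prior` column in transform space).
#' @param residuals data frame with cell columns plus `resid`
#'   (observation minus prior, transform space).
#' @param hierarchy a [make_hierarchy()] result.
#' @param hp an [stgpr_hyperparams()].
#' @return the grid data frame with an added `stage2` column.
#' @export
smooth_spatiotemporal <- function(prior, residuals, hierarchy, hp) {
  grid <- if (inherits(prior, "stage1_prior")) prior$prior else prior
  stopifnot("prior" %in% names(grid))
  ctry <- hierarchy_countries(hierarchy)
  gi <- match(grid$location_id, ctry$location_id)
  ri <- match(residuals$location_id, ctry$location_id)
  g_reg <- ctry$region_id[gi]; g_sup <- ctry$super_region_id[gi]
  r_reg <- ctry$region_id[ri]; r_sup <- ctry$super_region_id[ri]
  r_age <- age_rank(residuals$age_group)
  g_age <- age_rank(grid$age_group)

  stage2 <- grid$prior
  if (nrow(residuals)) {
    for (i in seq_len(nrow(grid))) {
      ws <- ifelse(residuals$location_id == grid$location_id[i], 1,
            ifelse(r_reg == g_reg[i], hp$zeta,
            ifelse(r_sup == g_sup[i], hp$zeta^2, 0)))
      scope <- ws > 0 & residuals$sex == grid$sex[i]
      if (!any(scope)) next
      dt <- abs(residuals$year[scope] - grid$year[i])
      wt <- (1 - (dt / (1 + max(dt)))^hp$lam)^3
      wa <- hp$omega^(-abs(r_age[scope] - g_age[i]))
      w <- ws[scope] * wt * wa
      sw <- sum(w)
      if (sw > 0)
        stage2[i] <- grid$prior[i] + sum(w * residuals$resid[scope]) / sw
    }
  }
  grid$stage2 <- stage2
  grid
}

#' Select smoothing hyperparameters by holdout predictive validity
#'
#' Holds out a fraction of observations, smooths residuals from the rest
#' under every candidate hyperparameter set, and returns the candidate
#' minimising RMSE against the held-out observations (transform space). Ties
#' are broken toward smoother settings: larger `lam`, then larger `zeta`.
#'
#' @param grid data frame of candidates with columns `zeta`, `lam`, `omega`.
#' @param data observations (natural space).
#' @param prior a `stage1_prior`.
#' @param hierarchy a [make_hierarchy()] result.
#' @param holdout_cfg list: `prop` holdout fraction (default 0.2).
#' @param seed integer seed for the holdout split.
#' @return an [stgpr_hyperparams()] with attribute `"holdout_rmse"`.
#' @export
select_hyperparams <- function(grid, data, prior, hierarchy,
                               holdout_cfg = list(), seed = 1) {
  cfg <- utils::modifyList(list(prop = 0.2), holdout_cfg)
  stopifnot(nrow(grid) >= 1)
  pr <- prior$prior
  tr <- transform_obs(data$value, data$variance, prior$transform)
  data$y <- tr$value
  i <- match(cell_key(data), cell_key(pr))
  if (anyNA(i)) stop("observations outside the prior grid")
  data$resid <- data$y - pr$prior[i]

  set.seed(seed)
  n <- nrow(data)
  hold <- rep(FALSE, n)
  hold[sample.int(n, max(1, round(cfg$prop * n)))] <- TRUE
  if (all(hold)) hold[1] <- FALSE

  rmse <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- stgpr_hyperparams(grid$zeta[g], grid$lam[g], grid$omega[g])
    s2 <- smooth_spatiotemporal(pr, data[!hold, ], hierarchy, hp)
    j <- match(cell_key(data[hold, ]), cell_key(s2))
    sqrt(mean((s2$stage2[j] - data$y[hold])^2))
  }, numeric(1))

  best <- which(rmse <= min(rmse) + 1e-12)
  if (length(best) > 1) {
    best <- best[order(-grid$lam[best], -grid$zeta[best])][1]
  }
  out <- stgpr_hyperparams(grid$zeta[best], grid$lam[best], grid$omega[best])
  attr(out, "holdout_rmse") <- rmse[best]
  attr(out, "rmse_grid") <- cbind(grid, rmse = rmse)
  out
}

## --- stage 3: Gaussian process draws ---------------------------------------

## Matern-5/2: k(d) = s^2 (1 + r + r^2/3) exp(-r), r = sqrt(5) d / l.
matern52 <- function(d, amplitude, lengthscale) {
  r <- sqrt(5) * d / lengthscale
  amplitude^2 * (1 + r + r^2 / 3) * exp(-r)
}

.chol_jitter <- function(K, base) {
  for (j in c(0, 10^seq(-10, -6))) {
    L <- try(chol(K + diag(j * base, nrow(K))), silent = TRUE)
    if (!inherits(L, "try-error")) return(L)
  }
  stop("covariance not positive definite after jitter escalation")
}

#' Gaussian-process smoothing and draw generation (stage 3)
#'
#' Per (location, age group, sex) series, places a Gaussian process over
#' years with mean equal to the stage-2 surface and a Matern-5/2 kernel,
#' conditions on the observations with their measurement variances as
#' heteroskedastic noise, and samples `n_draws` posterior trajectories.
#' Series without data revert to the GP prior around stage 2. Draws are
#' back-transformed to natural space for logit-modelled indicators.
#'
#' @param stage2 grid data frame from [smooth_spatiotemporal()] (`stage2`
#'   column, transform space).
#' @param data observations (natural space) with `value` and `variance`.
#' @param kernel_cfg list: `lengthscale` in years (default 10), `amplitude`
#'   (default `NULL`: 1.4826 x median absolute data-minus-stage2 residual,
#'   floored at `min_amplitude` = 0.05).
#' @param n_draws posterior samples per cell, default 1000.
#' @param seed integer seed.
#' @param transform `"identity"` or `"logit"` (how `stage2` was modelled).
#' @return an `stgpr_fit`: `cells`, `stage2` (transform space), `draws`
#'   (natural space, cells x draws), `summary` (mean / lower / upper),
#'   `amplitude`, `transform`.
#' @export
gpr_stage <- function(stage2, data, kernel_cfg = list(), n_draws = 1000,
                      seed = 1, transform = "identity") {
  cfg <- utils::modifyList(list(lengthscale = 10, amplitude = NULL,
                                min_amplitude = 0.05), kernel_cfg)
  tr <- transform_obs(data$value, data$variance, transform)
  data$y <- tr$value
  data$vy <- pmax(tr$variance, 0)
  i <- match(cell_key(data), cell_key(stage2))
  if (anyNA(i)) stop("observations outside the stage-2 grid")
  data$m2 <- stage2$stage2[i]

  amp <- cfg$amplitude
  if (is.null(amp)) {
    amp <- 1.4826 * stats::median(abs(data$y - data$m2))
    amp <- max(amp, cfg$min_amplitude)
  }

  set.seed(seed)
  key <- paste(stage2$location_id, stage2$age_group, stage2$sex, sep = "|")
  draws <- matrix(NA_real_, nrow(stage2), n_draws)
  for (k in unique(key)) {
    gi <- which(key == k)
    gi <- gi[order(stage2$year[gi])]
    yrs <- stage2$year[gi]
    m <- stage2$stage2[gi]
    di <- which(paste(data$location_id, data$age_group, data$sex, sep = "|") == k)
    Kgg <- matern52(abs(outer(yrs, yrs, "-")), amp, cfg$lengthscale)
    if (length(di)) {
      yo <- data$year[di]
      Koo <- matern52(abs(outer(yo, yo, "-")), amp, cfg$lengthscale) +
        diag(data$vy[di], length(di))
      Kgo <- matern52(abs(outer(yrs, yo, "-")), amp, cfg$lengthscale)
      sol <- solve(Koo + diag(1e-12 * amp^2, length(di)),
                   cbind(data$y[di] - data$m2[di], t(Kgo)))
      post_mean <- m + Kgo %*% sol[, 1]
      post_cov <- Kgg - Kgo %*% sol[, -1, drop = FALSE]
    } else {
      post_mean <- m
      post_cov <- Kgg
    }
    L <- .chol_jitter((post_cov + t(post_cov)) / 2, amp^2)
    z <- matrix(stats::rnorm(length(gi) * n_draws), length(gi), n_draws)
    draws[gi, ] <- as.numeric(post_mean) + crossprod(L, z)
  }
  draws_nat <- back_transform(draws, transform)
  s <- t(apply(draws_nat, 1, draw_summary))
  summ <- data.frame(stage2[c("location_id", "year", "age_group", "sex")],
                     mean = s[, 1], lower = s[, 2], upper = s[, 3])
  structure(list(cells = stage2[c("location_id", "year", "age_group", "sex")],
                 stage2 = stage2$stage2, draws = draws_nat, summary = summ,
                 amplitude = amp, transform = transform,
                 lengthscale = cfg$lengthscale),
            class = "stgpr_fit")
}

#' @export
print.stgpr_fit <- function(x, ...) {
  cat("ST-GPR fit:", nrow(x$cells), "cells x", ncol(x$draws), "draws;",
      "transform:", x$transform, "; amplitude:", format(x$amplitude, digits = 3), "\n")
  invisible(x)
}

#' Run the full three-stage ST-GPR for one indicator
#'
#' Convenience wrapper: stage-1 prior, hyperparameter selection (optional),
#' stage-2 smoothing, stage-3 GP draws.
#'
#' @inheritParams fit_stage1
#' @inheritParams gpr_stage
#' @param hp an [stgpr_hyperparams()], or a data frame grid to pass through
#'   [select_hyperparams()].
#' @param indicator `"mean"`, `"prev2"` or `"prev3"`; chooses the transform
#'   (identity for the mean, logit for prevalences).
#' @return an `stgpr_fit` with the stage-1 prior attached as `$stage1` and
#'   hyperparameters as `$hyperparams`.
#' @export
stgpr <- function(data, covariates, hierarchy, expected_signs,
                  indicator = c("mean", "prev2", "prev3"),
                  hp = stgpr_hyperparams(), kernel_cfg = list(),
                  n_draws = 1000, holdout_cfg = list(), seed = 1) {
  indicator <- match.arg(indicator)
  transform <- if (indicator == "mean") "identity" else "logit"
  s1 <- fit_stage1(data, covariates, hierarchy, expected_signs,
                   transform = transform, holdout_cfg = holdout_cfg,
                   seed = seed)
  if (is.data.frame(hp))
    hp <- select_hyperparams(hp, data, s1, hierarchy, seed = seed + 1)
  tr <- transform_obs(data$value, data$variance, transform)
  data$y <- tr$value
  i <- match(cell_key(data), cell_key(s1$prior))
  res <- data.frame(data[c("location_id", "year", "age_group", "sex")],
                    resid = data$y - s1$prior$prior[i])
  s2 <- smooth_spatiotemporal(s1, res, hierarchy, hp)
  fit <- gpr_stage(s2, data, kernel_cfg = kernel_cfg, n_draws = n_draws,
                   seed = seed + 2, transform = transform)
  fit$stage1 <- s1
  fit$hyperparams <- hp
  fit
}
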