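## Epidemiological transition analysis: ensemble of monotone-decreasing
## quadratic splines relating CGF prevalence (logit space) to the UHC index,
## with 0.5% tail trimming, optional linear SDI covariate, population
## aggregation of age-sex-specific fits, and anchored scaling across
## severities.
##
## Each submodel is a C1 quadratic spline (truncated-power basis: intercept,
## u, u^2, and (u - k_j)^2_+ for 4 interior knots -> 5 quadratic segments)
## with a non-positive first derivative enforced on a dense grid via
## linearly-constrained least squares (mgcv::pcls). The UHC index is scaled
## to [0, 1] internally for conditioning.

.spline_basis <- function(u, knots) {
  X <- cbind(1, u, u^2)
  for (k in knots) X <- cbind(X, pmax(u - k, 0)^2)
  X
}

.spline_deriv_basis <- function(u, knots) {
  D <- cbind(0, 1, 2 * u)
  for (k in knots) D <- cbind(D, 2 * pmax(u - k, 0))
  D
}

## Draw 4 interior knots uniformly over the [q05, q95] quantile span of the
## observed UHC values, with minimum spacing (0.05 on the unit scale).
.draw_knots <- function(u_obs, n_knots = 4, min_space = 0.05, max_tries = 200) {
  qs <- stats::quantile(u_obs, c(0.05, 0.95), names = FALSE)
  for (i in seq_len(max_tries)) {
    k <- sort(stats::runif(n_knots, qs[1], qs[2]))
    if (all(diff(k) >= min_space)) return(k)
  }
  seq(qs[1], qs[2], length.out = n_knots + 2)[2:(n_knots + 1)]
}

## Monotone-constrained least squares fit of one submodel.
## X: basis (+ optional sdi column appended last); D: derivative rows
## (zero-padded for the sdi column). Returns coefficients.
.fit_constrained <- function(X, y, D) {
  p0 <- numeric(ncol(X))
  p0[2] <- -1e-3  # strictly decreasing start: interior-feasible for pcls
  M <- list(y = y, w = rep(1, length(y)), X = X, C = matrix(0, 0, ncol(X)),
            S = list(), off = array(0, 0), sp = array(0, 0), p = p0,
            Ain = -D, bin = rep(0, nrow(D)))
  mgcv::pcls(M)
}

#' Fit a monotone quadratic-spline ensemble of prevalence on the UHC index
#'
#' Fits 20 submodels, each a five-segment quadratic spline in logit
#' prevalence over the UHC domain with randomised interior knots and a
#' non-increasing constraint, weights them by out-of-sample predictive
#' validity (5-fold location-grouped cross-validation RMSE, weights
#' proportional to `exp(-rmse)`), and applies one trim-refit cycle removing
#' the lowest and highest 0.5% of points by signed residual against the
#' ensemble fit.
#'
#' @param points data frame with columns `uhc` (0-100), `prevalence` in
#'   (0, 1), `location_id`; optionally `sdi` when `use_sdi = TRUE`. At least
#'   50 points.
#' @param cfg list: `n_submodels` (20), `n_knots` (4), `trim` (0.005 per
#'   tail), `n_folds` (5), `constraint_grid` (201 points over 0-100).
#' @param seed integer seed for knot draws and fold assignment.
#' @param use_sdi include a linear SDI covariate in logit space.
#' @return a `spline_ensemble` object: `submodels` (knots + coefficients),
#'   `weights`, `trimmed` (row indices of trimmed points), `use_sdi`,
#'   `domain`.
#' @export
fit_spline_ensemble <- function(points, cfg = list(), seed = 1,
                                use_sdi = FALSE) {
  cfg <- utils::modifyList(list(n_submodels = 20, n_knots = 4, trim = 0.005,
                                n_folds = 5, constraint_grid = 201), cfg)
  stopifnot(nrow(points) >= 50)
  if (any(points$prevalence <= 0 | points$prevalence >= 1)) {
    warning("prevalences at 0 or 1 floored into (1e-7, 1 - 1e-7)")
  }
  y_all <- logit(points$prevalence)
  u_all <- points$uhc / 100
  sdi_all <- if (use_sdi) points$sdi / 100 else NULL
  ugrid <- seq(0, 1, length.out = cfg$constraint_grid)

  set.seed(seed)
  knot_sets <- replicate(cfg$n_submodels, .draw_knots(u_all, cfg$n_knots),
                         simplify = FALSE)
  locs <- unique(points$location_id)
  fold <- stats::setNames(sample(rep_len(seq_len(min(cfg$n_folds, length(locs))),
                                         length(locs))), locs)

  fit_all <- function(keep) {
    u <- u_all[keep]; y <- y_all[keep]
    sdi <- if (use_sdi) sdi_all[keep] else NULL
    floc <- fold[points$location_id[keep]]
    subm <- vector("list", cfg$n_submodels)
    score <- numeric(cfg$n_submodels)
    for (j in seq_len(cfg$n_submodels)) {
      kn <- knot_sets[[j]]
      X <- .spline_basis(u, kn)
      D <- .spline_deriv_basis(ugrid, kn)
      if (use_sdi) { X <- cbind(X, sdi); D <- cbind(D, 0) }
      beta <- .fit_constrained(X, y, D)
      ## location-grouped CV
      errs <- unlist(lapply(seq_len(max(fold)), function(fd) {
        tr <- floc != fd
        if (all(tr) || !any(tr)) return(NULL)
        Xt <- X[tr, , drop = FALSE]
        bt <- tryCatch(.fit_constrained(Xt, y[tr], D), error = function(e) NULL)
        if (is.null(bt)) return(NULL)
        (X[!tr, , drop = FALSE] %*% bt - y[!tr])^2
      }))
      score[j] <- if (length(errs)) sqrt(mean(errs)) else Inf
      subm[[j]] <- list(knots = kn, coef = beta)
    }
    w <- exp(-(score - min(score[is.finite(score)])))
    w[!is.finite(score)] <- 0
    list(submodels = subm, weights = w / sum(w), score = score)
  }

  predict_rows <- function(fit, u, sdi = NULL) {
    pred <- 0
    for (j in seq_along(fit$submodels)) {
      X <- .spline_basis(u, fit$submodels[[j]]$knots)
      if (use_sdi) X <- cbind(X, sdi)
      pred <- pred + fit$weights[j] * as.numeric(X %*% fit$submodels[[j]]$coef)
    }
    pred
  }

  keep <- rep(TRUE, nrow(points))
  fit0 <- fit_all(keep)
  resid <- y_all - predict_rows(fit0, u_all, sdi_all)
  n_trim <- ceiling(cfg$trim * nrow(points))
  ord <- order(resid)
  trimmed <- c(ord[seq_len(n_trim)], rev(ord)[seq_len(n_trim)])
  keep[trimmed] <- FALSE
  fit1 <- fit_all(keep)

  structure(list(submodels = fit1$submodels, weights = fit1$weights,
                 cv_rmse = fit1$score, trimmed = sort(trimmed),
                 use_sdi = use_sdi, transform = "logit",
                 domain = c(0, 100), n_points = nrow(points)),
            class = "spline_ensemble")
}

#' @export
print.spline_ensemble <- function(x, ...) {
  cat("Monotone spline ensemble:", length(x$submodels), "submodels,",
      x$n_points, "points (", length(x$trimmed), "trimmed );",
      if (x$use_sdi) "with SDI covariate" else "UHC only", "\n")
  invisible(x)
}

#' Predict from a fitted spline ensemble
#'
#' Ensemble prediction is the weight-averaged submodel prediction in logit
#' space (a convex combination, so monotonicity in UHC is preserved),
#' optionally back-transformed to prevalence.
#'
#' @param object a `spline_ensemble`.
#' @param uhc UHC index values (0-100).
#' @param sdi SDI values (required iff the fit used SDI).
#' @param type `"response"` (prevalence) or `"link"` (logit).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.spline_ensemble <- function(object, uhc, sdi = NULL,
                                    type = c("response", "link"), ...) {
  type <- match.arg(type)
  u <- uhc / 100
  if (object$use_sdi) {
    if (is.null(sdi)) stop("fit includes an SDI covariate; supply sdi")
    sdi <- rep_len(sdi / 100, length(u))
  }
  pred <- 0
  for (j in seq_along(object$submodels)) {
    X <- .spline_basis(u, object$submodels[[j]]$knots)
    if (object$use_sdi) X <- cbind(X, sdi)
    pred <- pred + object$weights[j] * as.numeric(X %*% object$submodels[[j]]$coef)
  }
  if (type == "response") inv_logit(pred) else pred
}

#' Fit the UHC spline ensemble with a linear SDI covariate
#'
#' Identical specification to [fit_spline_ensemble()] plus a linear SDI term
#' in logit space.
#'
#' @inheritParams fit_spline_ensemble
#' @export
fit_with_sdi <- function(points, cfg = list(), seed = 1) {
  stopifnot("sdi" %in% names(points))
  fit_spline_ensemble(points, cfg = cfg, seed = seed, use_sdi = TRUE)
}

#' Expected-prevalence curves at fixed SDI levels
#'
#' @param fit a `spline_ensemble` fitted with SDI.
#' @param sdi_values SDI levels, default `c(20, 40, 60, 80)`.
#' @param uhc_grid UHC evaluation grid, default 0-100 by 0.5.
#' @return data frame `uhc`, `sdi`, `prevalence`.
#' @export
predict_at_sdi <- function(fit, sdi_values = c(20, 40, 60, 80),
                           uhc_grid = seq(0, 100, by = 0.5)) {
  stopifnot(inherits(fit, "spline_ensemble"), fit$use_sdi)
  do.call(rbind, lapply(sdi_values, function(s) {
    data.frame(uhc = uhc_grid, sdi = s,
               prevalence = predict(fit, uhc_grid, sdi = s))
  }))
}

#' Population-aggregate age-sex-specific spline fits
#'
#' Evaluates every age-sex-specific fit on a common UHC grid in natural
#' (prevalence) space and averages with population weights, producing the
#' both-sex under-5 expected-prevalence curve.
#'
#' @param fits named list of `spline_ensemble` objects, names
#'   `"<age_group>|<sex>"`, covering all six age bins and both sexes.
#' @param populations covariate table; populations are summed per age-sex
#'   cell over locations and years to form the weights.
#' @param uhc_grid evaluation grid, default 0-100 by 0.5.
#' @return data frame `uhc`, `value` (aggregated prevalence).
#' @export
aggregate_splines <- function(fits, populations, uhc_grid = seq(0, 100, by = 0.5)) {
  pop <- stats::aggregate(population ~ age_group + sex,
                          data = as.data.frame(populations), FUN = sum)
  keys <- paste(pop$age_group, pop$sex, sep = "|")
  missing <- setdiff(names(fits), keys)
  if (length(setdiff(keys, names(fits))))
    stop("missing spline fit for cell(s): ",
         paste(setdiff(keys, names(fits)), collapse = ", "))
  w <- pop$population / sum(pop$population)
  agg <- numeric(length(uhc_grid))
  for (i in seq_along(keys))
    agg <- agg + w[i] * predict(fits[[keys[i]]], uhc_grid)
  data.frame(uhc = uhc_grid, value = agg)
}

#' Scale per-severity transition curves to a common anchor
#'
#' Multiplies each severity's expected-prevalence curve by the ratio of the
#' overall curve to that severity's curve at the lowest observed UHC index,
#' so all scaled curves coincide at the anchor. Relative decline rates
#' across severities can then be compared directly.
#'
#' @param curves named list of data frames (`uhc`, `value`), one per
#'   severity; must include `"overall"`.
#' @param uhc_min anchor UHC value (lowest observed UHC index).
#' @return a `scaled_trajectory`: list of scaled curves plus the scalars.
#' @export
scale_trajectories <- function(curves, uhc_min) {
  stopifnot("overall" %in% names(curves))
  at_anchor <- vapply(curves, function(cv)
    stats::approx(cv$uhc, cv$value, xout = uhc_min, rule = 2)$y, numeric(1))
  if (any(at_anchor <= 0)) stop("curve value at the anchor must be positive")
  scalars <- at_anchor[["overall"]] / at_anchor
  scaled <- lapply(names(curves), function(sv) {
    cv <- curves[[sv]]
    cv$value <- cv$value * scalars[[sv]]
    cv
  })
  names(scaled) <- names(curves)
  structure(list(curves = scaled, scalars = scalars, uhc_min = uhc_min),
            class = "scaled_trajectory")
}
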