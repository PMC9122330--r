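## Ensemble z-score distribution: a convex mixture of ten named families,
## every component parameterised from the same (mean, variance) pair by
## method of moments.

#' Construct an ensemble distribution specification
#'
#' An ensemble spec holds the mixture weights over the ten component families
#' together with the shift applied to positive-support families and the upper
#' anchor used by mirrored families. Weights must be non-negative and sum to
#' one (to within `1e-9`); families omitted from `weights` get weight zero.
#'
#' @param weights named numeric vector of family weights. Valid names:
#'   `normal`, `log_normal`, `log_logistic`, `exponential`, `gamma`,
#'   `mirrored_gamma`, `inverse_gamma`, `gumbel`, `mirrored_gumbel`,
#'   `weibull`.
#' @param shift z-score offset added before fitting positive-support families
#'   (log-normal, log-logistic, exponential, gamma, inverse gamma, Weibull).
#'   Default 10, so any plausible z-score above -10 maps to positive support.
#' @param mirror_anchor upper anchor for the mirrored (left-skewed) families;
#'   they are fit to `mirror_anchor - z`. Default 10.
#' @return an object of class `ensemble_spec`.
#' @examples
#' ensemble_spec(c(normal = 0.6, weibull = 0.4))
#' @export
ensemble_spec <- function(weights, shift = 10, mirror_anchor = 10) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a named vector")
  unknown <- setdiff(names(weights), FAMILY_NAMES)
  if (length(unknown))
    stop("unknown families: ", paste(unknown, collapse = ", "))
  if (any(weights < -1e-12)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  if (!is.finite(shift) || !is.finite(mirror_anchor))
    stop("shift and mirror_anchor must be finite")
  w <- stats::setNames(numeric(length(FAMILY_NAMES)), FAMILY_NAMES)
  w[names(weights)] <- pmax(weights, 0)
  w <- w / sum(w)
  structure(list(weights = w, shift = shift, mirror_anchor = mirror_anchor),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("Ensemble z-score distribution spec\n")
  nz <- x$weights[x$weights > 0]
  cat(sprintf("  %-16s %.4f\n", names(nz), nz), sep = "")
  cat(sprintf("  shift = %g, mirror_anchor = %g\n", x$shift, x$mirror_anchor))
  invisible(x)
}

#' Method-of-moments parameters for one ensemble component
#'
#' Solves the component family's parameters so that its mean and variance on
#' the z-score scale equal the target moments. Positive-support families are
#' solved on the shifted scale `z + shift`, mirrored families on
#' `mirror_anchor - z`. The exponential family has a single parameter and is
#' matched on the mean only; its variance mismatch is left for the weight
#' optimiser to penalise.
#'
#' @param family one of the ten family names (see [ensemble_spec()]).
#' @param moments list or numeric vector with elements `mean` and `variance`
#'   (z-score scale; `variance > 0`).
#' @param spec an [ensemble_spec()] supplying shift and mirror anchor.
#' @return named numeric vector of family parameters (on the family's own
#'   scale). Infeasible moments (e.g. shifted mean not positive) raise an
#'   error of class `cgf_family_infeasible`.
#' @examples
#' spec <- ensemble_spec(c(normal = 1))
#' mom_params("gamma", list(mean = -2, variance = 1), spec)
#' @export
mom_params <- function(family, moments, spec) {
  family <- match.arg(family, FAMILY_NAMES)
  m <- moments[["mean"]]; v <- moments[["variance"]]
  if (!is.finite(v) || v <= 0) stop("variance must be positive")
  ms <- .family_scale_mean(family, m, spec$shift, spec$mirror_anchor)
  par <- .mom_solve(family, ms, v)
  if (is.null(par))
    stop(errorCondition(
      paste0("moments infeasible for family '", family, "'"),
      class = c("cgf_family_infeasible", "error", "condition")))
  par
}

## Solve all families at once; returns list of parameter vectors (NULL where
## infeasible) plus the renormalised weights. Internal hot path.
.ensemble_components <- function(weights, mean_z, variance, shift, anchor,
                                 tol = 1e-12) {
  pars <- vector("list", length(FAMILY_NAMES))
  names(pars) <- FAMILY_NAMES
  w <- weights
  for (f in FAMILY_NAMES) {
    if (w[[f]] <= tol) { w[[f]] <- 0; next }
    p <- .mom_solve(f, .family_scale_mean(f, mean_z, shift, anchor), variance)
    if (is.null(p)) w[[f]] <- 0 else pars[[f]] <- p
  }
  tot <- sum(w)
  if (tot <= 0)
    stop("all ensemble families infeasible for mean ", mean_z,
         ", variance ", variance)
  list(weights = w / tot, pars = pars)
}

#' Ensemble probability density
#'
#' Density of the weighted mixture at z-score points `x`, with every
#' component parameterised by method of moments from the same target mean and
#' variance. Families whose moments are infeasible contribute zero and the
#' remaining weights are renormalised.
#'
#' @inheritParams mom_params
#' @param spec an [ensemble_spec()].
#' @param x z-score points (vectorised).
#' @return non-negative densities, one per element of `x`.
#' @export
ensemble_pdf <- function(spec, moments, x) {
  cmp <- .ensemble_components(spec$weights, moments[["mean"]],
                              moments[["variance"]], spec$shift,
                              spec$mirror_anchor)
  out <- numeric(length(x))
  for (f in FAMILY_NAMES) {
    if (cmp$weights[[f]] > 0)
      out <- out + cmp$weights[[f]] *
        .family_pdf(f, cmp$pars[[f]], x, spec$shift, spec$mirror_anchor)
  }
  out
}

#' Ensemble prevalence below a z-score threshold
#'
#' Weighted sum of closed-form component CDFs: the proportion of the ensemble
#' distribution lying below `threshold`. This is the quantity compared with
#' survey prevalences below -1, -2 and -3 SD during weight fitting, and
#' integrated at -1/-2/-3/-4 SD to produce final severity prevalences.
#'
#' @inheritParams ensemble_pdf
#' @param threshold z-score threshold(s), vectorised.
#' @return proportions in `[0, 1]`, non-decreasing in `threshold`.
#' @examples
#' spec <- ensemble_spec(c(normal = 1))
#' prevalence_below(spec, list(mean = -2, variance = 1), -2)  # 0.5
#' @export
prevalence_below <- function(spec, moments, threshold) {
  cmp <- .ensemble_components(spec$weights, moments[["mean"]],
                              moments[["variance"]], spec$shift,
                              spec$mirror_anchor)
  out <- numeric(length(threshold))
  for (f in FAMILY_NAMES) {
    if (cmp$weights[[f]] > 0)
      out <- out + cmp$weights[[f]] *
        .family_cdf(f, cmp$pars[[f]], threshold, spec$shift, spec$mirror_anchor)
  }
  clamp(out, 0, 1)
}

## Fast internal CDF working from a raw weight vector (already validated),
## used inside optimisation loops to avoid spec re-validation.
.ens_cdf <- function(weights, mean_z, variance, thresholds, shift, anchor) {
  cmp <- .ensemble_components(weights, mean_z, variance, shift, anchor)
  out <- numeric(length(thresholds))
  for (f in FAMILY_NAMES) {
    if (cmp$weights[[f]] > 0)
      out <- out + cmp$weights[[f]] *
        .family_cdf(f, cmp$pars[[f]], thresholds, shift, anchor)
  }
  clamp(out, 0, 1)
}

#' Random draws from an ensemble distribution
#'
#' Samples family labels by weight, then draws from each moment-parameterised
#' component. Infeasible families are renormalised away, as in
#' [ensemble_pdf()].
#'
#' @inheritParams ensemble_pdf
#' @param n number of draws.
#' @return numeric vector of z-scores.
#' @export
ensemble_draws <- function(n, spec, moments) {
  cmp <- .ensemble_components(spec$weights, moments[["mean"]],
                              moments[["variance"]], spec$shift,
                              spec$mirror_anchor)
  idx <- sample.int(length(FAMILY_NAMES), n, replace = TRUE, prob = cmp$weights)
  out <- numeric(n)
  for (j in seq_along(FAMILY_NAMES)) {
    sel <- idx == j
    if (!any(sel)) next
    f <- FAMILY_NAMES[j]
    out[sel] <- .family_rng(f, cmp$pars[[f]], sum(sel), spec$shift,
                            spec$mirror_anchor)
  }
  out
}

#' Fit global ensemble weights to microdata sources
#'
#' Finds the mixture weights that minimise the summed squared error in
#' predicting each microdata source's empirical prevalence below the -1, -2
#' and -3 SD thresholds, given the source's empirical mean and variance
#' (n - 1 normalisation). All sources are weighted evenly. The weight simplex
#' is searched with Nelder-Mead from `n_restarts` random Dirichlet(1) starting
#' points (softmax parameterisation keeps iterates on the simplex); the best
#' restart is returned.
#'
#' @param sources list of microdata survey sources (see
#'   [simulate_microdata()]), each with at least two z-score records.
#' @param thresholds z-score thresholds entering the objective, default
#'   `c(-1, -2, -3)`.
#' @param n_restarts number of random restarts, default 100.
#' @param seed integer seed for the restart draws.
#' @param families optional subset of family names to restrict the candidate
#'   mixture to.
#' @param shift,mirror_anchor conventions passed to [ensemble_spec()].
#' @param maxit Nelder-Mead iteration cap per restart.
#' @return a `weight_fit` object: `spec` (the fitted [ensemble_spec()]),
#'   `objective`, `n_restarts`, `restart_objectives`, and the per-source
#'   summary statistics used.
#' @export
fit_ensemble_weights <- function(sources, thresholds = c(-1, -2, -3),
                                 n_restarts = 100, seed = 1,
                                 families = FAMILY_NAMES,
                                 shift = 10, mirror_anchor = 10,
                                 maxit = 400) {
  families <- match.arg(families, FAMILY_NAMES, several.ok = TRUE)
  if (!length(sources)) stop("at least one microdata source is required")
  stats_list <- lapply(sources, function(s) {
    z <- s$records$z
    if (length(z) < 2) return(NULL)
    v <- var_n1(z)
    if (!is.finite(v) || v <= 0) return(NULL)
    list(mean = mean(z), variance = v,
         emp = vapply(thresholds, function(t) mean(z < t), numeric(1)))
  })
  dropped <- vapply(stats_list, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " degenerate source(s) dropped from weight fitting")
  stats_list <- stats_list[!dropped]
  if (!length(stats_list)) stop("all sources degenerate; nothing to fit")

  k <- length(families)
  objective <- function(w) {
    wfull <- stats::setNames(numeric(length(FAMILY_NAMES)), FAMILY_NAMES)
    wfull[families] <- w
    tot <- 0
    for (s in stats_list) {
      pred <- .ens_cdf(wfull, s$mean, s$variance, thresholds, shift, mirror_anchor)
      tot <- tot + sum((pred - s$emp)^2)
    }
    tot
  }
  softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

  if (k == 1) {
    w <- stats::setNames(1, families)
    obj <- objective(w)
    spec <- ensemble_spec(w, shift, mirror_anchor)
    return(structure(list(spec = spec, objective = obj, n_restarts = 0L,
                          restart_objectives = obj,
                          source_stats = stats_list),
                     class = "weight_fit"))
  }

  set.seed(seed)
  best <- NULL
  restart_obj <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    w0 <- rdirichlet1(k)
    x0 <- log(pmax(w0, 1e-8))
    x0 <- x0[-1] - x0[1]
    fn <- function(x) objective(softmax(c(0, x)))
    fit <- stats::optim(x0, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    restart_obj[r] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  w <- softmax(c(0, best$par))
  ## snap numerically-zero weights and renormalise
  w[w < 1e-8] <- 0
  w <- w / sum(w)
  spec <- ensemble_spec(stats::setNames(w, families), shift, mirror_anchor)
  structure(list(spec = spec, objective = best$value,
                 n_restarts = as.integer(n_restarts),
                 restart_objectives = restart_obj,
                 source_stats = stats_list),
            class = "weight_fit")
}

#' @export
print.weight_fit <- function(x, ...) {
  cat("Ensemble weight fit over", length(x$source_stats), "sources;",
      "objective =", format(x$objective, digits = 6), "\n")
  print(x$spec)
  invisible(x)
}

#' Write / read fitted ensemble weights as CSV
#'
#' Two-column layout (`family`, `weight`), one row per family with
#' non-zero weight.
#'
#' @param fit a `weight_fit` or [ensemble_spec()].
#' @param path CSV path.
#' @return `write_ensemble_weights` returns `path` invisibly;
#'   `read_ensemble_weights` returns an [ensemble_spec()].
#' @export
write_ensemble_weights <- function(fit, path) {
  spec <- if (inherits(fit, "weight_fit")) fit$spec else fit
  nz <- spec$weights[spec$weights > 0]
  df <- data.frame(family = names(nz), weight = unname(nz))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_weights
#' @param shift,mirror_anchor conventions for the reconstructed spec.
#' @export
read_ensemble_weights <- function(path, shift = 10, mirror_anchor = 10) {
  df <- utils::read.csv(path)
  ensemble_spec(stats::setNames(df$weight, df$family), shift, mirror_anchor)
}
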