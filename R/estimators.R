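# 95% normal quantile used throughout (CIs and rejection decisions)
qz <- function() 1.959964

new_mr_estimate <- function(method, estimate, se, n_variants, extras = list()) {
  z <- qz()
  structure(list(method = method,
                 estimate = estimate,
                 se = se,
                 ci_lower = estimate - z * se,
                 ci_upper = estimate + z * se,
                 p_value = 2 * stats::pnorm(-abs(estimate / se)),
                 n_variants = n_variants,
                 extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %s (SE %s), 95%% CI [%s, %s], P = %s, J = %d\n",
              x$method,
              format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits),
              format.pval(x$p_value, digits = digits),
              x$n_variants))
  if (!is.null(x$extras$egger_intercept))
    cat(sprintf("  intercept: %s (SE %s), P = %s\n",
                format(x$extras$egger_intercept, digits = digits),
                format(x$extras$egger_intercept_se, digits = digits),
                format.pval(x$extras$egger_intercept_p, digits = digits)))
  invisible(x)
}

#' Per-variant ratio (Wald) estimates with weights
#'
#' For each variant computes the ratio estimate
#' \eqn{\hat\beta_j = \hat\Gamma_j / \hat\gamma_j} — the causal effect the
#' variant identifies if it is a valid instrument — and attaches the
#' unstandardized weight used by the downstream estimators. Estimates are
#' sorted ascending (ties broken by `variant_id` so results are invariant to
#' input row permutation).
#'
#' Weight schemes:
#' \describe{
#'   \item{`inverse_variance`}{\eqn{w'_j = \hat\gamma_j^2 / \sigma_{Yj}^2},
#'     the first-order delta-method inverse variance of the ratio estimate —
#'     identical to the weights of the IVW estimator.}
#'   \item{`inverse_se`}{\eqn{w'_j = |\hat\gamma_j| / \sigma_{Yj}}, an
#'     alternative down-weighting of imprecise variants.}
#'   \item{`equal`}{\eqn{w'_j = 1}; yields the simple median.}
#' }
#'
#' @param data an [mr_data] object; every `beta_exposure` must be nonzero.
#' @param weight_scheme one of `"inverse_variance"` (default),
#'   `"inverse_se"`, `"equal"`.
#' @return An object of class `mr_ratios`: list with `beta` (ascending ratio
#'   estimates), `weight` (aligned unstandardized weights), `variant_id`, and
#'   the scheme used.
#' @export
ratio_estimates <- function(data,
                            weight_scheme = c("inverse_variance",
                                              "inverse_se", "equal")) {
  stopifnot(inherits(data, "mr_data"))
  if (nrow(data) < 1L) stop("at least one variant is required", call. = FALSE)
  weight_scheme <- match.arg(weight_scheme)
  zero <- which(data$beta_exposure == 0)
  if (length(zero))
    stop("ratio estimate undefined (beta_exposure = 0) for variant(s): ",
         paste(data$variant_id[zero], collapse = ", "), call. = FALSE)
  beta <- data$beta_outcome / data$beta_exposure
  weight <- switch(weight_scheme,
                   inverse_variance = data$beta_exposure^2 / data$se_outcome^2,
                   inverse_se = abs(data$beta_exposure) / data$se_outcome,
                   equal = rep(1, nrow(data)))
  o <- order(beta, data$variant_id)
  structure(list(beta = beta[o], weight = weight[o],
                 variant_id = data$variant_id[o],
                 weight_scheme = weight_scheme),
            class = "mr_ratios")
}

#' Weighted empirical distribution of the ratio estimates
#'
#' Standardizes the weights to sum to one (\eqn{w_j = w'_j / \sum_k w'_k}),
#' forms the cumulative sums \eqn{s_j = \sum_{k \le j} w_k}, and assigns the
#' \eqn{j}th ordered ratio estimate the percentile anchor
#' \eqn{p_j = 100\,(s_j - w_j/2)}. The anchors are computed from the
#' unstandardized weights as \eqn{100\,(S_j - w'_j/2)/S_J} — algebraically the
#' same quantity, but exact in floating point for equal weights, which makes
#' the weighted median with equal weights collapse to the closed-form simple
#' median exactly.
#'
#' @param ratios an `mr_ratios` object from [ratio_estimates()].
#' @return An object of class `mr_wcdf`: list with `beta`, standardized
#'   weights `w`, cumulative sums `s`, and percentile anchors `p`.
#' @export
build_weighted_cdf <- function(ratios) {
  stopifnot(inherits(ratios, "mr_ratios"))
  wp <- ratios$weight
  if (any(wp <= 0))
    stop("all weights must be strictly positive", call. = FALSE)
  total <- sum(wp)
  S <- cumsum(wp)
  structure(list(beta = ratios$beta,
                 w = wp / total,
                 s = S / total,
                 p = 100 * (S - wp / 2) / total,
                 variant_id = ratios$variant_id),
            class = "mr_wcdf")
}

# interpolated 50th percentile of a weighted empirical CDF; clamps to the
# boundary estimate when 50 falls outside [p_1, p_J]
wcdf_median <- function(beta, p) {
  J <- length(beta)
  if (50 <= p[1L]) return(beta[1L])
  if (50 >= p[J]) return(beta[J])
  k <- findInterval(50, p)            # p[k] <= 50 < p[k+1]
  beta[k] + (beta[k + 1L] - beta[k]) * (50 - p[k]) / (p[k + 1L] - p[k])
}

#' Weighted median of the ratio estimates
#'
#' The weighted median estimator is the median of the distribution that has
#' the \eqn{j}th ordered ratio estimate as its \eqn{p_j}th percentile (see
#' [build_weighted_cdf()]), interpolating linearly between neighbouring ratio
#' estimates: with \eqn{p_k \le 50 \le p_{k+1}},
#' \deqn{\hat\beta_{WM} = \hat\beta_k + (\hat\beta_{k+1} - \hat\beta_k)
#'   \frac{50 - p_k}{p_{k+1} - p_k}.}
#' It is consistent for the causal effect when at least 50% of the weight
#' comes from valid instruments. If the 50th percentile falls outside
#' \eqn{[p_1, p_J]} the boundary estimate is returned. A single variant
#' carrying more than half the total weight triggers a warning: the 50%
#' validity condition then reduces to assuming that one variant is valid.
#'
#' @param x an `mr_wcdf` from [build_weighted_cdf()], an `mr_ratios`, or an
#'   [mr_data] object (converted with inverse-variance weights).
#' @return The point estimate (a number). Use [mr_bootstrap()] or [mr_fit()]
#'   for standard errors and confidence intervals.
#' @examples
#' d <- mr_data(paste0("v", 1:3), beta_exposure = c(0.1, 0.1, 0.1),
#'              beta_outcome = c(0.02, 0.03, 0.05), se_outcome = 0.01)
#' weighted_median(d)
#' @export
weighted_median <- function(x) {
  cdf <- as_wcdf(x)
  if (max(cdf$w) > 0.5)
    warning("a single variant carries more than 50% of the weight; the 50% ",
            "validity assumption then amounts to assuming that variant is valid",
            call. = FALSE)
  wcdf_median(cdf$beta, cdf$p)
}

as_wcdf <- function(x, weight_scheme = "inverse_variance") {
  if (inherits(x, "mr_wcdf")) return(x)
  if (inherits(x, "mr_data")) x <- ratio_estimates(x, weight_scheme)
  if (!inherits(x, "mr_ratios"))
    stop("expected an mr_wcdf, mr_ratios or mr_data object", call. = FALSE)
  build_weighted_cdf(x)
}

#' Simple median of the ratio estimates
#'
#' The middle ordered ratio estimate for an odd number of variants
#' (\eqn{J = 2k+1}), or the mean of the two middle estimates for an even
#' number (\eqn{J = 2k}). Equal to [weighted_median()] with equal weights
#' (and computed that way), it is consistent when at least 50% of the
#' variants are valid instruments.
#'
#' @param x an [mr_data] or `mr_ratios` object.
#' @return The point estimate (a number).
#' @export
simple_median <- function(x) {
  if (inherits(x, "mr_data")) x <- ratio_estimates(x, "equal")
  stopifnot(inherits(x, "mr_ratios"))
  eq <- x
  eq$weight <- rep(1, length(x$beta))
  cdf <- build_weighted_cdf(eq)
  wcdf_median(cdf$beta, cdf$p)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' The inverse-variance weighted mean of the per-variant ratio estimates,
#' \deqn{\hat\beta_{IVW} = \frac{\sum_j \hat\gamma_j^2 \sigma_{Yj}^{-2}
#'   \hat\beta_j}{\sum_j \hat\gamma_j^2 \sigma_{Yj}^{-2}},}
#' the standard efficient combination when every variant is a valid
#' instrument (0% breakdown level: a single invalid variant biases it).
#' The default standard error is the fixed-effect meta-analysis form
#' \eqn{\sqrt{1/\sum_j w'_j}}; with `random_effects = TRUE` it is inflated
#' multiplicatively by the residual standard deviation
#' \eqn{\sqrt{Q/(J-1)}} of the weighted regression through the origin when
#' that exceeds one.
#'
#' @param x an [mr_data] object or an `mr_ratios` set carrying
#'   inverse-variance weights.
#' @param random_effects logical; default `FALSE` (fixed-effect SE).
#' @return An `mr_estimate` with method `"ivw"`.
#' @export
mr_ivw <- function(x, random_effects = FALSE) {
  r <- if (inherits(x, "mr_data")) ratio_estimates(x, "inverse_variance") else x
  stopifnot(inherits(r, "mr_ratios"))
  if (r$weight_scheme != "inverse_variance")
    stop("IVW requires inverse-variance weights", call. = FALSE)
  est <- sum(r$weight * r$beta) / sum(r$weight)
  se <- sqrt(1 / sum(r$weight))
  extras <- list()
  if (length(r$beta) >= 2L) {
    Q <- sum(r$weight * (r$beta - est)^2)
    extras <- list(Q = Q, df = length(r$beta) - 1L)
    if (random_effects)
      se <- se * max(1, sqrt(Q / (length(r$beta) - 1L)))
  }
  new_mr_estimate("ivw", est, se, length(r$beta), extras)
}

# closed-form weighted least squares of y on x with intercept;
# returns coef, cov scale (X'WX)^-1 and weighted RSS
wls_fit <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x * x); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (det <= .Machine$double.eps * sw * swxx)
    stop("MR-Egger regression is not identified: all (reoriented) exposure ",
         "associations are equal", call. = FALSE)
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  rss <- sum(w * (y - intercept - slope * x)^2)
  list(intercept = intercept, slope = slope, rss = rss,
       var_slope_scale = sw / det, var_intercept_scale = swxx / det)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with an intercept,
#' \eqn{\hat\Gamma_j = \beta_{0E} + \beta_E \hat\gamma_j}, weights
#' \eqn{\sigma_{Yj}^{-2}}. Each variant is first reoriented so its exposure
#' association is positive (negating both coordinates), since allele
#' orientation is arbitrary but changes the intercept. The slope
#' \eqn{\hat\beta_E} is a consistent causal estimate even when all variants
#' are invalid, provided pleiotropic effects are independent of instrument
#' strength (the InSIDE assumption); the intercept estimates the average
#' pleiotropic effect, and its test is a test of directional pleiotropy.
#' Omitting the intercept recovers the IVW estimate exactly.
#'
#' By default the residual variance is estimated from the fit (weighted RSS /
#' (J - 2), not forced to 1) and inference uses normal quantiles; both are
#' switchable.
#'
#' @param data an [mr_data] object with at least 3 variants.
#' @param dispersion `"estimated"` (default) or `"unit"` (residual variance
#'   fixed at 1).
#' @param ci_dist `"normal"` (default) or `"t"` (t on J - 2 df).
#' @param intercept logical; `FALSE` forces the regression through the origin
#'   (then the slope equals the IVW estimate).
#' @return An `mr_estimate` with method `"egger"`; the intercept estimate,
#'   its SE and P-value are in `$extras`.
#' @export
mr_egger <- function(data, dispersion = c("estimated", "unit"),
                     ci_dist = c("normal", "t"), intercept = TRUE) {
  stopifnot(inherits(data, "mr_data"))
  dispersion <- match.arg(dispersion)
  ci_dist <- match.arg(ci_dist)
  J <- nrow(data)
  if (intercept && J < 3L)
    stop("MR-Egger regression requires at least 3 variants", call. = FALSE)
  flip <- data$beta_exposure < 0
  gx <- ifelse(flip, -data$beta_exposure, data$beta_exposure)
  gy <- ifelse(flip, -data$beta_outcome, data$beta_outcome)
  w <- 1 / data$se_outcome^2
  if (!intercept) {
    slope <- sum(w * gx * gy) / sum(w * gx^2)
    se <- sqrt(1 / sum(w * gx^2))
    return(new_mr_estimate("egger_no_intercept", slope, se, J))
  }
  fit <- wls_fit(gx, gy, w)
  df <- J - 2L
  sigma2 <- switch(dispersion, estimated = fit$rss / df, unit = 1)
  se_slope <- sqrt(sigma2 * fit$var_slope_scale)
  se_int <- sqrt(sigma2 * fit$var_intercept_scale)
  pfun <- if (ci_dist == "t") {
    function(est, se) 2 * stats::pt(-abs(est / se), df)
  } else {
    function(est, se) 2 * stats::pnorm(-abs(est / se))
  }
  crit <- if (ci_dist == "t") stats::qt(0.975, df) else qz()
  out <- new_mr_estimate("egger", fit$slope, se_slope, J,
                         extras = list(egger_intercept = fit$intercept,
                                       egger_intercept_se = se_int,
                                       egger_intercept_p = pfun(fit$intercept,
                                                                se_int)))
  # override the normal-theory CI/P set by the constructor when t is requested
  out$ci_lower <- fit$slope - crit * se_slope
  out$ci_upper <- fit$slope + crit * se_slope
  out$p_value <- pfun(fit$slope, se_slope)
  out
}
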