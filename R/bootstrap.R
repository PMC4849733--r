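# Deterministic 31-bit substream seed for (master seed, counter) pairs.
# Base R has no counter-based generator; this LCG-style hash gives each
# replicate its own stream so results do not depend on evaluation order.
substream_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + (as.double(index) + 1) * 69621) %% 2147483647
  as.integer((x * 16807) %% 2147483647)
}

# fast median-family point estimate from raw per-variant summaries;
# beta/weights need not be pre-sorted
median_point_estimate <- function(gx, gy, se_outcome,
                                  estimator = c("weighted_median",
                                                "simple_median",
                                                "penalized_weighted_median")) {
  estimator <- match.arg(estimator)
  beta <- gy / gx
  o <- order(beta)
  beta <- beta[o]
  if (estimator == "simple_median") {
    wp <- rep(1, length(beta))
  } else {
    wp <- (gx^2 / se_outcome^2)[o]
    if (estimator == "penalized_weighted_median") {
      ivw <- sum(wp * beta) / sum(wp)
      q <- stats::pchisq(wp * (beta - ivw)^2, df = 1, lower.tail = FALSE)
      wp <- wp * pmin(1, 20 * q)
    }
  }
  S <- cumsum(wp)
  p <- 100 * (S - wp / 2) / S[length(S)]
  wcdf_median(beta, p)
}

#' Parametric-bootstrap inference for the median-based estimators
#'
#' The median estimators have no closed-form standard error; following the
#' parametric-bootstrap approach, each replicate redraws the summary
#' statistics from their estimated sampling distributions —
#' \eqn{\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{\gamma j}^2)} and
#' \eqn{\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{Yj}^2)} independently
#' (the two-sample situation) — and recomputes the selected estimator. The
#' bootstrap SE is the standard deviation of the replicate estimates; the
#' default 95% CI is normal-theory, `point estimate ± 1.959964 × SE`, with a
#' percentile CI behind a flag. Replicates are driven by per-replicate
#' substreams of `seed`, so results are bit-reproducible and independent of
#' evaluation order. A replicate that happens to draw
#' \eqn{\hat\gamma_j^* = 0} exactly is retried with fresh draws (bounded).
#'
#' @param data an [mr_data] object; `se_exposure` must be present unless
#'   `perturb = "outcome"`.
#' @param estimator `"weighted_median"` (default), `"simple_median"`, or
#'   `"penalized_weighted_median"`.
#' @param n_boot number of replicates (>= 100; a warning is issued below
#'   1000).
#' @param seed integer master seed (mandatory for reproducibility).
#' @param perturb `"both"` (default: redraw exposure and outcome
#'   associations) or `"outcome"` (redraw the outcome side only).
#' @param ci_type `"normal"` (default) or `"percentile"`.
#' @return An object of class `mr_boot`: list with `estimate` (on the
#'   original data), `se`, `ci_lower`, `ci_upper`, `n_boot`, `seed`,
#'   `ci_type`, and the replicate estimates in `replicates`.
#' @examples
#' d <- mr_data(paste0("v", 1:10), beta_exposure = seq(0.05, 0.14, 0.01),
#'              se_exposure = 0.01,
#'              beta_outcome = 0.1 * seq(0.05, 0.14, 0.01) + 0.002,
#'              se_outcome = 0.005)
#' mr_bootstrap(d, n_boot = 200, seed = 7)
#' @export
mr_bootstrap <- function(data,
                         estimator = c("weighted_median", "simple_median",
                                       "penalized_weighted_median"),
                         n_boot = 1000, seed,
                         perturb = c("both", "outcome"),
                         ci_type = c("normal", "percentile")) {
  stopifnot(inherits(data, "mr_data"))
  estimator <- match.arg(estimator)
  perturb <- match.arg(perturb)
  ci_type <- match.arg(ci_type)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  J <- nrow(data)
  se_x <- data$se_exposure
  if (perturb == "both" && anyNA(se_x))
    stop("perturb = \"both\" requires se_exposure for every variant; ",
         "use perturb = \"outcome\" otherwise", call. = FALSE)
  if (n_boot < 1000)
    warning("n_boot < 1000; bootstrap SE may be imprecise", call. = FALSE)

  point <- median_point_estimate(data$beta_exposure, data$beta_outcome,
                                 data$se_outcome, estimator)
  reps <- numeric(n_boot)
  n_retried <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(substream_seed(seed, b))
    for (attempt in 1:100) {
      gx <- if (perturb == "both")
        stats::rnorm(J, data$beta_exposure, se_x) else data$beta_exposure
      gy <- stats::rnorm(J, data$beta_outcome, data$se_outcome)
      if (all(gx != 0)) break
      n_retried <- n_retried + 1L
      if (attempt == 100)
        stop("bootstrap replicate kept drawing a zero exposure association",
             call. = FALSE)
    }
    reps[b] <- median_point_estimate(gx, gy, data$se_outcome, estimator)
  }
  se <- stats::sd(reps)
  if (ci_type == "normal") {
    ci <- point + c(-1, 1) * qz() * se
  } else {
    ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  }
  structure(list(estimate = point, se = se,
                 ci_lower = ci[1], ci_upper = ci[2],
                 n_boot = n_boot, seed = seed, estimator = estimator,
                 ci_type = ci_type, perturb = perturb,
                 n_retried = n_retried, replicates = reps),
            class = "mr_boot")
}

#' @export
print.mr_boot <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %s (bootstrap SE %s, %d reps), 95%% %s CI [%s, %s]\n",
              x$estimator, format(x$estimate, digits = digits),
              format(x$se, digits = digits), x$n_boot, x$ci_type,
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits)))
  invisible(x)
}
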