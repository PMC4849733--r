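#' Cochran's Q decomposition across instruments
#'
#' Quantifies heterogeneity of the per-variant ratio estimates about the IVW
#' estimate \eqn{\hat\beta}:
#' \deqn{Q = \sum_j Q_j = \sum_j w'_j (\hat\beta_j - \hat\beta)^2,}
#' with \eqn{w'_j = \hat\gamma_j^2/\sigma_{Yj}^2}. Under the null that all
#' variants are valid instruments identifying the same causal effect, Q is
#' chi-squared on \eqn{J-1} degrees of freedom and each component \eqn{Q_j}
#' approximately chi-squared on 1; `q` holds the one-sided upper chi-squared(1)
#' P-value of each component (no continuity correction).
#'
#' @param x an [mr_data] object or an `mr_ratios` set with inverse-variance
#'   weights (at least 2 variants).
#' @return An object of class `mr_qdecomp`: list with total `Q`, per-variant
#'   `Q_j`, upper P-values `q`, degrees of freedom `df`, the global P-value
#'   `p_value` of Q, and `variant_id`.
#' @seealso [penalize_weights()]
#' @export
cochran_q <- function(x) {
  r <- if (inherits(x, "mr_data")) ratio_estimates(x, "inverse_variance") else x
  stopifnot(inherits(r, "mr_ratios"))
  if (r$weight_scheme != "inverse_variance")
    stop("Cochran's Q requires inverse-variance weights", call. = FALSE)
  J <- length(r$beta)
  if (J < 2L)
    stop("Cochran's Q is undefined for fewer than 2 variants", call. = FALSE)
  beta_ivw <- sum(r$weight * r$beta) / sum(r$weight)
  Q_j <- r$weight * (r$beta - beta_ivw)^2
  Q <- sum(Q_j)
  # floor against upper-tail underflow so q stays in (0, 1] and penalized
  # weights stay strictly positive for extreme outliers
  q <- pmax(stats::pchisq(Q_j, df = 1, lower.tail = FALSE),
            .Machine$double.xmin)
  structure(list(Q = Q, Q_j = Q_j,
                 q = q,
                 df = J - 1L,
                 p_value = stats::pchisq(Q, df = J - 1L, lower.tail = FALSE),
                 variant_id = r$variant_id),
            class = "mr_qdecomp")
}

#' @export
print.mr_qdecomp <- function(x, digits = 4, ...) {
  cat(sprintf("Cochran's Q = %s on %d df (P = %s)\n",
              format(x$Q, digits = digits), x$df,
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' Penalize the weights of heterogeneous variants
#'
#' One-shot down-weighting of outlying instruments for the penalized weighted
#' median: each unstandardized weight is multiplied by
#' \eqn{\min(1,\, 20\,q_j)}, where \eqn{q_j} is the one-sided upper
#' chi-squared(1) P-value of the variant's Q component from [cochran_q()].
#' Variants whose component P-value exceeds 0.05 are untouched
#' (\eqn{20 q_j \ge 1}); strongly heterogeneous variants are severely
#' down-weighted. The ordering of the estimates is unchanged and the IVW
#' centre is not re-estimated after penalization.
#'
#' @param ratios an `mr_ratios` set (inverse-variance weights).
#' @param qd optionally a precomputed `mr_qdecomp` aligned with `ratios`;
#'   computed from `ratios` when omitted.
#' @return A new `mr_ratios` set with penalized weights.
#' @export
penalize_weights <- function(ratios, qd = NULL) {
  stopifnot(inherits(ratios, "mr_ratios"))
  if (is.null(qd)) qd <- cochran_q(ratios)
  stopifnot(inherits(qd, "mr_qdecomp"))
  if (length(qd$q) != length(ratios$beta))
    stop("Q decomposition and ratio set have different lengths", call. = FALSE)
  out <- ratios
  out$weight <- ratios$weight * pmin(1, 20 * qd$q)
  out$weight_scheme <- paste0("penalized_", ratios$weight_scheme)
  out
}

#' Penalized weighted median of the ratio estimates
#'
#' [weighted_median()] applied to the penalized weights of
#' [penalize_weights()]: equivalent to the weighted median when the ratio
#' estimates are homogeneous, but with the contribution of heterogeneous
#' (likely pleiotropic) variants severely reduced, which improves
#' finite-sample behaviour under directional pleiotropy.
#'
#' @param x an [mr_data] object or an `mr_ratios` set with inverse-variance
#'   weights (at least 2 variants, so Q is defined).
#' @return The point estimate (a number).
#' @export
penalized_weighted_median <- function(x) {
  r <- if (inherits(x, "mr_data")) ratio_estimates(x, "inverse_variance") else x
  weighted_median(penalize_weights(r))
}
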