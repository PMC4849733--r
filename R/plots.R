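#' Diagnostic plots for a summary-data MR analysis
#'
#' Two standard displays. `type = "scatter"`: per-variant outcome
#' associations \eqn{\hat\Gamma_j} against exposure associations
#' \eqn{\hat\gamma_j}, with the fitted causal slopes overlaid — solid line
#' IVW, dashed line weighted median (through the origin), dotted line
#' MR-Egger (with its intercept). `type = "funnel"`: instrument strength
#' \eqn{\hat\gamma_j/\sigma_{Yj}} against the per-variant ratio estimates;
#' asymmetry about the causal estimate suggests directional pleiotropy.
#' Both are headless-safe base-graphics plots; no numerical output depends
#' on them.
#'
#' @param x an [mr_fit] object.
#' @param type `"scatter"` (default) or `"funnel"`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, type = c("scatter", "funnel"), ...) {
  type <- match.arg(type)
  d <- x$data
  if (type == "scatter") {
    graphics::plot(d$beta_exposure, d$beta_outcome,
                   xlab = "Genetic association with exposure",
                   ylab = "Genetic association with outcome",
                   pch = 19, ...)
    graphics::abline(h = 0, v = 0, col = "grey85")
    e <- x$estimates
    legend_lty <- integer(0); legend_lab <- character(0)
    if (!is.null(e$ivw)) {
      graphics::abline(0, e$ivw$estimate, lty = 1)
      legend_lty <- c(legend_lty, 1); legend_lab <- c(legend_lab, "IVW")
    }
    if (!is.null(e$weighted_median)) {
      graphics::abline(0, e$weighted_median$estimate, lty = 2)
      legend_lty <- c(legend_lty, 2)
      legend_lab <- c(legend_lab, "Weighted median")
    }
    if (!is.null(e$egger)) {
      graphics::abline(e$egger$extras$egger_intercept, e$egger$estimate,
                       lty = 3)
      legend_lty <- c(legend_lty, 3); legend_lab <- c(legend_lab, "MR-Egger")
    }
    if (length(legend_lab))
      graphics::legend("topleft", legend = legend_lab, lty = legend_lty,
                       bty = "n")
  } else {
    r <- ratio_estimates(d, "inverse_variance")
    strength <- (abs(d$beta_exposure) / d$se_outcome)[match(r$variant_id,
                                                            d$variant_id)]
    graphics::plot(r$beta, strength,
                   xlab = "Ratio estimate",
                   ylab = "Instrument strength",
                   pch = 19, ...)
    if (!is.null(x$estimates$ivw))
      graphics::abline(v = x$estimates$ivw$estimate, lty = 1)
    if (!is.null(x$estimates$weighted_median))
      graphics::abline(v = x$estimates$weighted_median$estimate, lty = 2)
  }
  invisible(x)
}
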