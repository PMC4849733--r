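#' Generate small deterministic summary-data fixtures
#'
#' Self-contained example datasets for tests and documentation.
#' \describe{
#'   \item{`proportional`}{Every outcome association is exactly `slope` times
#'     the exposure association: all ratio estimates equal `slope`, every
#'     estimator recovers it and the MR-Egger intercept is 0.}
#'   \item{`fig2`}{Ten variants, six valid instruments scattered about a
#'     common causal slope and four invalid ones with positive pleiotropic
#'     offsets on the outcome association — the classic picture in which the
#'     IVW estimate is dragged upward while the median resists.}
#'   \item{`random`}{All variants valid, with noise consistent with the
#'     reported standard errors.}
#' }
#'
#' @param kind `"proportional"`, `"fig2"` or `"random"`.
#' @param seed integer seed; the same seed always yields the same dataset
#'   (and file, when `path` is given).
#' @param path optional file path; if supplied the fixture is also written as
#'   a TSV via the standard results header.
#' @param n_variants number of variants (fixed at 10 for `"fig2"`).
#' @param slope true causal effect; default 0.1.
#' @return An [mr_data] object; for `"fig2"` the true validity flags are in
#'   `attr(, "invalid")`.
#' @export
make_fixture <- function(kind = c("proportional", "fig2", "random"),
                         seed = 1, path = NULL, n_variants = 10,
                         slope = 0.1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "fig2") n_variants <- 10L
  gx <- stats::runif(n_variants, 0.05, 0.15)
  se_x <- rep(0.01, n_variants)
  se_y <- rep(0.01, n_variants)
  invalid <- rep(FALSE, n_variants)
  gy <- switch(kind,
    proportional = slope * gx,
    fig2 = {
      invalid <- rep(c(FALSE, TRUE), c(6L, 4L))[sample.int(10L)]
      offs <- ifelse(invalid, stats::runif(n_variants, 0.05, 0.12), 0)
      slope * gx + offs * gx + stats::rnorm(n_variants, sd = se_y / 5)
    },
    random = slope * gx + stats::rnorm(n_variants, sd = se_y))
  out <- mr_data(sprintf("fx%02d", seq_len(n_variants)),
                 beta_exposure = gx, se_exposure = se_x,
                 beta_outcome = gy, se_outcome = se_y)
  attr(out, "invalid") <- invalid
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    cat("# medianMR ", as.character(utils::packageVersion("medianMR")),
        " fixture=", kind, " seed=", seed, "\n", sep = "", file = con)
    utils::write.table(format_full(as.data.frame(out)), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
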