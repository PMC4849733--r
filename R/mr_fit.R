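#' Fit the full family of summary-data MR estimators
#'
#' The package's main fitting function: given harmonized per-variant summary
#' statistics, computes any subset of the inverse-variance weighted, simple
#' median, weighted median, penalized weighted median and MR-Egger causal
#' estimates, with analytic standard errors for IVW and MR-Egger and
#' parametric-bootstrap standard errors ([mr_bootstrap()]) for the
#' median-based methods. The methods make progressively weaker assumptions:
#' IVW requires every variant to be a valid instrument; the medians require
#' half the variants (or half the weight) to be valid; MR-Egger tolerates
#' 100% invalid variants under the InSIDE assumption, and its intercept is a
#' test of directional pleiotropy. A failure in one estimator (e.g.
#' MR-Egger with fewer than 3 variants) is reported as a warning and the
#' remaining methods are still returned.
#'
#' @param data an [mr_data] object (or data frame with the same columns).
#' @param methods subset of `c("ivw", "simple_median", "weighted_median",
#'   "penalized_weighted_median", "egger")`; default all.
#' @param n_boot bootstrap replicates for the median-based methods; default
#'   1000.
#' @param seed master seed for the bootstrap; default 1.
#' @param boot_perturb passed to [mr_bootstrap()] (`"both"` or
#'   `"outcome"`).
#' @param ... further arguments passed to [mr_ivw()] and [mr_egger()]
#'   (e.g. `random_effects`, `dispersion`, `ci_dist`).
#' @return An object of class `mr_fit`: list with `estimates` (named list of
#'   `mr_estimate`), the `data`, `seed` and failure messages (`failed`).
#' @examples
#' d <- make_fixture("fig2", seed = 3)
#' fit <- mr_fit(d, n_boot = 200, seed = 1)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(data, methods = sim_methods, n_boot = 1000, seed = 1,
                   boot_perturb = c("both", "outcome"), ...) {
  if (!inherits(data, "mr_data")) data <- validate_mr_data(as.data.frame(data))
  methods <- match.arg(methods, sim_methods, several.ok = TRUE)
  boot_perturb <- match.arg(boot_perturb)
  if (boot_perturb == "both" && anyNA(data$se_exposure))
    boot_perturb <- "outcome"
  dots <- list(...)
  arg <- function(f, nm) dots[intersect(nm, names(dots))]
  estimates <- list()
  failed <- character()
  for (m in methods) {
    res <- tryCatch({
      if (m == "ivw") {
        do.call(mr_ivw, c(list(data), arg(mr_ivw, "random_effects")))
      } else if (m == "egger") {
        do.call(mr_egger, c(list(data),
                            arg(mr_egger, c("dispersion", "ci_dist"))))
      } else {
        b <- mr_bootstrap(data, estimator = m, n_boot = n_boot,
                          seed = substream_seed(seed, match(m, sim_methods)),
                          perturb = boot_perturb)
        e <- new_mr_estimate(m, b$estimate, b$se, nrow(data),
                             extras = list(n_boot = n_boot))
        if (m != "simple_median") {
          qd <- cochran_q(data)
          e$extras$Q <- qd$Q
          e$extras$df <- qd$df
        }
        e
      }
    }, error = function(err) conditionMessage(err))
    if (inherits(res, "mr_estimate")) estimates[[m]] <- res
    else {
      failed[m] <- res
      warning("method '", m, "' failed: ", res, call. = FALSE)
    }
  }
  if (!length(estimates))
    stop("all requested methods failed", call. = FALSE)
  structure(list(estimates = estimates, data = data, seed = seed,
                 n_boot = n_boot, failed = failed),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Summary-data Mendelian randomization,", nrow(x$data), "variants\n\n")
  for (e in x$estimates) print(e, digits = digits)
  if (length(x$failed))
    cat("\nfailed:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  tab <- results_table(object)
  structure(list(table = tab, n_variants = nrow(object$data),
                 seed = object$seed, failed = object$failed),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  cat("Summary-data Mendelian randomization,", x$n_variants,
      "variants (bootstrap seed", paste0(x$seed, ")"), "\n")
  tab <- x$table
  tab$extra <- NULL
  for (j in which(vapply(tab, is.numeric, TRUE)))
    tab[[j]] <- signif(tab[[j]], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$estimate, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only 95% intervals are computed; refit for other levels",
         call. = FALSE)
  out <- t(vapply(object$estimates,
                  function(e) c(e$ci_lower, e$ci_upper), numeric(2)))
  colnames(out) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}
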