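#' Construct a harmonized summary-data set for Mendelian randomization
#'
#' Bundles per-variant GWAS association estimates into the container used by
#' every estimator in the package: for each genetic variant, its association
#' with the exposure (`beta_exposure`, per effect allele) and with the outcome
#' (`beta_outcome`, e.g. a log odds ratio per effect allele), together with
#' their standard errors. Rows are assumed to be harmonized to a common
#' effect-allele convention across exposure and outcome; the constructor
#' validates, it never flips alleles (orientation for MR-Egger is handled
#' internally by [mr_egger()]).
#'
#' @param variant_id character vector of unique variant labels (e.g. rsids).
#' @param beta_exposure numeric, per-allele association with the exposure.
#' @param se_exposure numeric, standard error of `beta_exposure` (strictly
#'   positive). May be `NA` when only outcome-side weights are needed — all
#'   estimators here weight by the outcome standard error — in which case a
#'   warning is issued and bootstrap perturbation of the exposure side is
#'   unavailable.
#' @param beta_outcome numeric, per-allele association with the outcome.
#' @param se_outcome numeric, standard error of `beta_outcome` (strictly
#'   positive); this is the \eqn{\sigma_{Yj}} entering all weights.
#' @param pvalues optional data frame (or named list) of per-exposure
#'   association P-values, one column per candidate exposure, used by
#'   [select_variants()].
#'
#' @return An object of class `mr_data`: a data frame with the columns above
#'   (P-value columns prefixed `pval_`).
#' @seealso [read_summary_table()], [select_variants()], [mr_fit()]
#' @examples
#' d <- mr_data(paste0("rs", 1:3),
#'              beta_exposure = c(0.10, 0.08, 0.12),
#'              se_exposure   = c(0.01, 0.01, 0.01),
#'              beta_outcome  = c(0.010, 0.008, 0.012),
#'              se_outcome    = c(0.004, 0.004, 0.004))
#' d
#' @export
mr_data <- function(variant_id, beta_exposure, se_exposure = NA_real_,
                    beta_outcome, se_outcome, pvalues = NULL) {
  variant_id <- as.character(variant_id)
  n <- length(variant_id)
  se_exposure <- rep_len(as.numeric(se_exposure), n)
  x <- data.frame(variant_id = variant_id,
                  beta_exposure = as.numeric(beta_exposure),
                  se_exposure = se_exposure,
                  beta_outcome = as.numeric(beta_outcome),
                  se_outcome = as.numeric(se_outcome),
                  stringsAsFactors = FALSE)
  if (!is.null(pvalues)) {
    pvalues <- as.data.frame(pvalues)
    if (nrow(pvalues) != n)
      stop("'pvalues' must have one row per variant", call. = FALSE)
    names(pvalues) <- ifelse(startsWith(names(pvalues), "pval_"),
                             names(pvalues), paste0("pval_", names(pvalues)))
    x <- cbind(x, pvalues)
  }
  validate_mr_data(x)
}

validate_mr_data <- function(x) {
  required <- c("variant_id", "beta_exposure", "se_exposure",
                "beta_outcome", "se_outcome")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- c("beta_exposure", "beta_outcome", "se_outcome")
  for (col in num) {
    bad <- which(!is.finite(x[[col]]))
    if (length(bad))
      stop("non-finite '", col, "' for variant(s): ",
           paste(x$variant_id[bad], collapse = ", "),
           " (row ", paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(x$variant_id))
    stop("duplicated variant_id: ",
         paste(unique(x$variant_id[duplicated(x$variant_id)]), collapse = ", "),
         call. = FALSE)
  bad <- which(x$se_outcome <= 0)
  if (length(bad))
    stop("non-positive outcome standard error for variant(s): ",
         paste(x$variant_id[bad], collapse = ", "), call. = FALSE)
  if (all(is.na(x$se_exposure))) {
    warning("se_exposure absent: outcome-side weights are unaffected, but ",
            "exposure-side bootstrap perturbation is unavailable",
            call. = FALSE)
  } else {
    bad <- which(!is.na(x$se_exposure) & x$se_exposure <= 0)
    if (length(bad))
      stop("non-positive exposure standard error for variant(s): ",
           paste(x$variant_id[bad], collapse = ", "), call. = FALSE)
  }
  class(x) <- c("mr_data", "data.frame")
  x
}

#' Read per-variant summary statistics from a delimited text file
#'
#' Reads a TSV/CSV with a header row and maps its columns onto the logical
#' fields of [mr_data()]. Lines starting with `#` are treated as comments.
#'
#' @param path path to a delimited text file.
#' @param column_map named character vector or list mapping logical names
#'   (`variant_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, and optionally `pval_<exposure>` entries) to column names
#'   in the file. Defaults to the identity mapping for the logical names.
#' @param sep field separator; `"\t"` (default) or `","`.
#'
#' @return A validated [mr_data] object.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(snp = c("rs1", "rs2", "rs3"),
#'              bx = c(0.1, 0.08, 0.12), bxse = 0.01,
#'              by = c(0.01, 0.008, 0.012), byse = 0.004),
#'   f, sep = "\t", row.names = FALSE, quote = FALSE)
#' read_summary_table(f, c(variant_id = "snp", beta_exposure = "bx",
#'                         se_exposure = "bxse", beta_outcome = "by",
#'                         se_outcome = "byse"))
#' @export
read_summary_table <- function(path, column_map = NULL, sep = "\t") {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variant_id", "beta_exposure", "se_exposure",
                "beta_outcome", "se_outcome")
  if (is.null(column_map)) {
    column_map <- stats::setNames(as.list(names(raw)), names(raw))
    column_map <- column_map[names(column_map) %in%
                               c(required, grep("^pval_", names(raw), value = TRUE))]
  }
  column_map <- as.list(column_map)
  hard <- setdiff(required, "se_exposure")
  miss_map <- setdiff(hard, names(column_map))
  if (length(miss_map))
    stop("column_map does not define: ", paste(miss_map, collapse = ", "),
         call. = FALSE)
  miss_file <- unlist(column_map)[!unlist(column_map) %in% names(raw)]
  if (length(miss_file))
    stop("column(s) not present in ", path, ": ",
         paste(miss_file, collapse = ", "), call. = FALSE)

  get_num <- function(logical_name) {
    if (!logical_name %in% names(column_map)) return(NA_real_)
    v <- raw[[column_map[[logical_name]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & v != "NA")
    if (length(bad))
      stop("column '", column_map[[logical_name]], "' not numeric at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    out
  }
  pv_names <- grep("^pval_", names(column_map), value = TRUE)
  pvalues <- if (length(pv_names)) {
    stats::setNames(as.data.frame(lapply(pv_names, get_num)), pv_names)
  } else NULL
  mr_data(variant_id = raw[[column_map[["variant_id"]]]],
          beta_exposure = get_num("beta_exposure"),
          se_exposure = get_num("se_exposure"),
          beta_outcome = get_num("beta_outcome"),
          se_outcome = get_num("se_outcome"),
          pvalues = pvalues)
}

#' Select genome-wide significant variants, optionally by primary association
#'
#' Implements the two variant-selection strategies used in multi-exposure
#' applied analyses: (a) keep variants associated with the target exposure at
#' genome-wide significance (`P < gw_threshold`, default \eqn{10^{-8}}), and
#' (b) additionally keep only variants whose target-exposure P-value is
#' strictly smaller than the P-value for every nontarget exposure ("primary
#' association with the target exposure"). Ties in (b) drop the variant, as
#' only strict inequality is specified.
#'
#' @param data an [mr_data] object carrying `pval_<exposure>` columns.
#' @param target name of the target exposure (with or without the `pval_`
#'   prefix).
#' @param gw_threshold genome-wide significance threshold on the target
#'   P-value; default `1e-8`.
#' @param primary logical; if `TRUE` apply rule (b) in addition to (a).
#' @return A filtered [mr_data] (row order preserved).
#' @export
select_variants <- function(data, target, gw_threshold = 1e-8,
                            primary = FALSE) {
  stopifnot(inherits(data, "mr_data"))
  tcol <- if (startsWith(target, "pval_")) target else paste0("pval_", target)
  if (!tcol %in% names(data))
    stop("no P-value column for exposure '", target, "' (expected column '",
         tcol, "')", call. = FALSE)
  pt <- data[[tcol]]
  if (anyNA(pt))
    stop("missing target P-values for variant(s): ",
         paste(data$variant_id[is.na(pt)], collapse = ", "), call. = FALSE)
  keep <- pt < gw_threshold
  if (primary) {
    others <- setdiff(grep("^pval_", names(data), value = TRUE), tcol)
    for (col in others) {
      po <- data[[col]]
      if (anyNA(po))
        stop("missing P-values in column '", col, "'", call. = FALSE)
      keep <- keep & (pt < po)
    }
  }
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(data)
  out
}

#' @export
print.mr_data <- function(x, ...) {
  cat("Summary-data MR dataset: ", nrow(x), " variant",
      if (nrow(x) != 1) "s", "\n", sep = "")
  pv <- grep("^pval_", names(x), value = TRUE)
  if (length(pv))
    cat("Exposure P-value columns:", paste(sub("^pval_", "", pv),
                                           collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

results_columns <- c("method", "n_variants", "estimate", "se",
                     "ci_lower", "ci_upper", "p_value", "extra")

#' Write causal-effect estimates to a rectangular TSV results table
#'
#' Writes one row per estimate with fixed columns `method`, `n_variants`,
#' `estimate`, `se`, `ci_lower`, `ci_upper`, `p_value`, `extra` at full
#' floating precision. The MR-Egger intercept is emitted as an additional row
#' keyed `method = "egger_intercept"` so the table stays rectangular; the Q
#' statistic and other named extras are packed into the `extra` column as
#' `name=value` pairs separated by `;`. A comment header records the package
#' version and, when present, seed and configuration hash.
#'
#' @param estimates a single `mr_estimate`, a list of them, or an [mr_fit]
#'   object.
#' @param path output file path.
#' @param seed optional integer recorded in the header.
#' @param config_hash optional string recorded in the header.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(estimates, path, seed = NULL, config_hash = NULL) {
  rows <- results_table(estimates)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  cat("# medianMR ", as.character(utils::packageVersion("medianMR")),
      if (!is.null(seed)) paste0(" seed=", seed),
      if (!is.null(config_hash)) paste0(" config=", config_hash),
      "\n", sep = "", file = con)
  utils::write.table(format_full(rows), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# full-precision formatting so read/write round-trips to < 1e-15 relative
format_full <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

results_table <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  if (inherits(estimates, "mr_fit")) estimates <- estimates$estimates
  rows <- lapply(estimates, function(e) {
    stopifnot(inherits(e, "mr_estimate"))
    extras <- e$extras
    intercept_row <- NULL
    if (!is.null(extras$egger_intercept)) {
      z <- qz()
      b0 <- extras$egger_intercept
      s0 <- extras$egger_intercept_se
      intercept_row <- data.frame(
        method = "egger_intercept", n_variants = e$n_variants,
        estimate = b0, se = s0, ci_lower = b0 - z * s0,
        ci_upper = b0 + z * s0,
        p_value = extras$egger_intercept_p, extra = "",
        stringsAsFactors = FALSE)
      extras <- extras[setdiff(names(extras),
                               c("egger_intercept", "egger_intercept_se",
                                 "egger_intercept_p"))]
    }
    extra <- if (length(extras))
      paste(sprintf("%s=%.17g", names(extras), unlist(extras)),
            collapse = ";") else ""
    rbind(data.frame(method = e$method, n_variants = e$n_variants,
                     estimate = e$estimate, se = e$se,
                     ci_lower = e$ci_lower, ci_upper = e$ci_upper,
                     p_value = e$p_value, extra = extra,
                     stringsAsFactors = FALSE),
          intercept_row)
  })
  if (!length(rows))
    return(stats::setNames(
      data.frame(character(), integer(), numeric(), numeric(), numeric(),
                 numeric(), numeric(), character(), stringsAsFactors = FALSE),
      results_columns))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read back a results table written by [write_results()]
#'
#' @param path path to a results TSV.
#' @return A data frame with the fixed results columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    stop("results file not found: ", path, call. = FALSE)
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(method = "character",
                                          extra = "character"))
  missing_cols <- setdiff(results_columns, names(out))
  if (length(missing_cols))
    stop("not a medianMR results table; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out
}
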