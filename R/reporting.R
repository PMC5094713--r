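# Validation metrics and the multiplicative cost-breakdown report.

#' Prediction metrics on log10 scale
#'
#' Root mean squared error between predicted and measured concentrations on
#' log10 scale, the corresponding typical fold error `10^RMSE`, and the
#' Pearson correlation of the log10 values. Entities missing from either
#' vector are excluded (and listed), never imputed.
#'
#' @param predicted Named concentrations in mM.
#' @param measured Named concentrations in mM.
#' @return An object of class `prediction_metrics`: `rmse_log10`,
#'   `fold_error`, `pearson_r` (NA when either vector is constant),
#'   `n_pairs`, `excluded`.
#' @export
prediction_metrics <- function(predicted, measured) {
  if (is.null(names(predicted)) || is.null(names(measured))) {
    stopf("predicted and measured vectors must be named")
  }
  predicted <- predicted[!is.na(predicted)]
  measured <- measured[!is.na(measured)]
  common <- intersect(names(predicted), names(measured))
  excluded <- setdiff(union(names(predicted), names(measured)), common)
  if (length(common) < 2L) {
    stopf("at least two overlapping (predicted, measured) pairs are required",
          class = "ecm_domain_error")
  }
  p <- predicted[common]
  m <- measured[common]
  bad <- common[p <= 0 | m <= 0]
  if (length(bad) > 0L) {
    stopf("nonpositive value(s) for entity(ies): %s",
          paste(bad, collapse = ", "), class = "ecm_domain_error")
  }
  lp <- log10(p)
  lm_ <- log10(m)
  rmse <- sqrt(mean((lp - lm_)^2))
  r <- if (stats::sd(lp) == 0 || stats::sd(lm_) == 0) NA_real_
  else stats::cor(lp, lm_)
  structure(
    list(rmse_log10 = rmse, fold_error = 10^rmse, pearson_r = r,
         n_pairs = length(common), excluded = excluded),
    class = "prediction_metrics"
  )
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf(
    "<prediction_metrics> RMSE(log10) = %.4g, fold error = %.3g, r = %s, n = %d\n",
    x$rmse_log10, x$fold_error,
    if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r),
    x$n_pairs
  ))
  if (length(x$excluded) > 0L) {
    cat("  excluded (missing on one side):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Multiplicative cost breakdown on log scale
#'
#' Decomposes each reaction's enzyme cost into additive log-scale terms:
#' the capacity term `ln v - ln kcat_fwd + ln h_E` plus the three
#' efficiency penalties `-ln eta_rev`, `-ln eta_kin`, `-ln eta_reg`. The
#' terms sum to `ln q_l` exactly; a factor equal to 1 contributes exactly
#' 0.
#'
#' @param breakdown The `breakdown` data frame of an [enzyme_cost()] or
#'   [ecm_solve()] result.
#' @return Data frame with columns `reaction`, `capacity`, `reversibility`,
#'   `saturation`, `regulation`, `ln_q`.
#' @export
cost_breakdown_report <- function(breakdown) {
  data.frame(
    reaction = breakdown$reaction,
    capacity = log(breakdown$v) - log(breakdown$kcat_fwd) +
      log(breakdown$h_E),
    reversibility = -log(breakdown$eta_rev),
    saturation = -log(breakdown$eta_kin),
    regulation = -log(breakdown$eta_reg),
    ln_q = log(breakdown$q_l),
    stringsAsFactors = FALSE
  )
}

#' Write a solved state to disk
#'
#' Writes the solution as TSV tables (metabolite levels, enzyme levels and
#' efficiency factors, log-scale cost breakdown) plus a JSON run report
#' with solver status and configuration echo.
#'
#' @param sol An [ecm_solve()] result.
#' @param dir Output directory (created if needed).
#' @param config_echo Optional list echoed verbatim into the JSON report.
#' @return `dir`, invisibly.
#' @export
write_solution <- function(sol, dir, config_echo = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  met <- data.frame(
    Metabolite = names(sol$c_opt),
    `Concentration [mM]` = sol$c_opt,
    `Log concentration` = sol$x_opt,
    check.names = FALSE
  )
  utils::write.table(met, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sol$breakdown, file.path(dir, "enzymes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cost_breakdown_report(sol$breakdown),
                     file.path(dir, "cost_breakdown.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(
    total_cost = sol$q_opt,
    converged = sol$diagnostics$converged,
    start = sol$diagnostics$start,
    projected_gradient_norm = sol$diagnostics$projected_gradient_norm,
    regularizer = list(lambda = sol$regularizer$lambda),
    config = config_echo
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
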