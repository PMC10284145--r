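# Scoring predicted enthalpies against experimental ITC values.

#' Root-mean-square error between paired vectors
#'
#' @param pred,exp equal-length numeric vectors (kcal/mol), no missing
#'   values.
#' @return `sqrt(mean((pred - exp)^2))`.
#' @export
rmse <- function(pred, exp) {
  if (length(pred) != length(exp)) stop("length mismatch")
  if (length(pred) < 1L) stop("need at least one pair")
  if (anyNA(pred) || anyNA(exp)) stop("missing values; drop pairs first")
  sqrt(mean((pred - exp)^2))
}

#' Squared correlation between predictions and experiment
#'
#' By default the square of the Pearson correlation coefficient — the
#' conventional reading of R^2 in this literature, with accuracy reported
#' separately as RMSE. `method = "identity"` instead gives the coefficient
#' of determination about the identity line,
#' `1 - sum((pred - exp)^2) / sum((exp - mean(exp))^2)`, as a sensitivity
#' alternative (it can be negative).
#'
#' @param pred,exp paired numeric vectors, n >= 2.
#' @param method `"pearson"` or `"identity"`.
#' @return unitless scalar.
#' @export
r_squared <- function(pred, exp, method = c("pearson", "identity")) {
  method <- match.arg(method)
  if (length(pred) != length(exp)) stop("length mismatch")
  if (length(pred) < 2L) stop("correlation needs n >= 2")
  if (stats::var(exp) == 0 ||
      (method == "pearson" && stats::var(pred) == 0)) {
    stop("undefined metric: zero variance input")
  }
  if (method == "pearson") {
    stats::cor(pred, exp)^2
  } else {
    1 - sum((pred - exp)^2) / sum((exp - mean(exp))^2)
  }
}

#' Kendall rank correlation (tau-b, tie-corrected)
#'
#' Direct pair counting: over all n(n-1)/2 pairs,
#' `tau_b = (concordant - discordant) /
#'  sqrt((pairs - ties_pred) (pairs - ties_exp))`.
#' O(n^2), which is exact and ample at benchmark sizes (n ~ 10).
#'
#' @param pred,exp paired numeric vectors, n >= 2.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(pred, exp) {
  if (length(pred) != length(exp)) stop("length mismatch")
  n <- length(pred)
  if (n < 2L) stop("Kendall tau needs n >= 2")
  conc <- disc <- tx <- ty <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sx <- sign(pred[i] - pred[j]); sy <- sign(exp[i] - exp[j])
      if (sx == 0) tx <- tx + 1L
      if (sy == 0) ty <- ty + 1L
      if (sx * sy > 0) conc <- conc + 1L
      if (sx * sy < 0) disc <- disc + 1L
    }
  }
  n0 <- n * (n - 1L) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) stop("undefined metric: all pairs tied")
  (conc - disc) / denom
}

#' Flag predictions beyond an absolute-error limit
#'
#' Strict inequality: a deviation exactly at the threshold is on the
#' boundary line, not outside it.
#'
#' @param deviations named non-negative numeric vector of per-system
#'   absolute deviations (kcal/mol).
#' @param threshold error limit (default 2.0 kcal/mol).
#' @return character vector of system ids with deviation > threshold,
#'   sorted by deviation descending.
#' @export
flag_outliers <- function(deviations, threshold = 2.0) {
  if (any(deviations < 0)) stop("deviations must be >= 0")
  out <- deviations[deviations > threshold]
  names(sort(out, decreasing = TRUE))
}

#' Score a prediction table against an experimental table
#'
#' Joins on `system_id`; systems missing from either side are dropped
#' pairwise with a warning, never imputed.
#'
#' @param pred data.frame with `system_id`, `dH` (predicted, kcal/mol).
#' @param exp data.frame with `system_id`, `dH` (experimental).
#' @param threshold outlier limit (kcal/mol).
#' @return a `benchmark_result` list: `n`, `rmse`, `r_squared`,
#'   `kendall_tau`, `deviations` (named vector), `outlier_ids`.
#' @export
benchmark_predictions <- function(pred, exp, threshold = 2.0) {
  common <- intersect(pred$system_id, exp$system_id)
  dropped <- union(setdiff(pred$system_id, common),
                   setdiff(exp$system_id, common))
  if (length(dropped) > 0L) {
    bc_log("WARN", "dropping unpaired system(s): ",
           paste(dropped, collapse = ", "))
  }
  if (length(common) < 2L) stop("need at least 2 paired systems")
  p <- pred$dH[match(common, pred$system_id)]
  e <- exp$dH[match(common, exp$system_id)]
  dev <- stats::setNames(abs(p - e), common)
  structure(list(n = length(common), rmse = rmse(p, e),
                 r_squared = r_squared(p, e), kendall_tau = kendall_tau(p, e),
                 deviations = dev,
                 outlier_ids = flag_outliers(dev, threshold)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> n = %d: RMSE = %.2f kcal/mol, R2 = %.2f, Kendall tau = %.2f\n",
              x$n, x$rmse, x$r_squared, x$kendall_tau))
  if (length(x$outlier_ids) > 0L) {
    cat("  outliers (> 2 kcal/mol):", paste(x$outlier_ids, collapse = ", "),
        "\n")
  }
  invisible(x)
}
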