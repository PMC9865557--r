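# Experiment-calculation agreement statistics for solvation/partition
# datasets: absolute error metrics, ranking coefficients and outlier counts.

.asPaired <- function(data) {
  if (is.data.frame(data)) {
    stopifnot(all(c("calc", "expt") %in% names(data)))
    list(calc = as.numeric(data$calc), expt = as.numeric(data$expt))
  } else stop("data must be a data.frame with 'calc' and 'expt' columns",
              call. = FALSE)
}

#' Paired calculation/experiment dataset
#'
#' Validated data.frame of per-solute calculated and experimental values in a
#' common unit (kcal/mol for free energies).
#'
#' @param label per-entry labels.
#' @param calc calculated values.
#' @param expt experimental values.
#' @return data.frame with columns `label`, `calc`, `expt`.
#' @export
pairedData <- function(label, calc, expt) {
  stopifnot(length(calc) == length(expt), length(label) == length(calc))
  if (any(!is.finite(calc)) || any(!is.finite(expt)))
    stop("non-finite value in paired data", call. = FALSE)
  data.frame(label = as.character(label), calc = as.numeric(calc),
             expt = as.numeric(expt), stringsAsFactors = FALSE)
}

#' Absolute error metrics
#'
#' Mean absolute error, mean signed error and root-mean-squared error of
#' `calc - expt`, in the data's units. Always RMSE >= MAE >= |MSE|.
#'
#' @param data paired data.frame (`calc`, `expt` columns).
#' @return named numeric `c(mae, mse, rmse)`.
#' @export
errorMetrics <- function(data) {
  d <- .asPaired(data)
  stopifnot(length(d$calc) >= 1L)
  err <- d$calc - d$expt
  c(mae = mean(abs(err)), mse = mean(err), rmse = sqrt(mean(err^2)))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau between calculated and experimental values,
#' via [stats::cor()]. When either variable is constant the coefficient is
#' undefined and `NA` is returned with a warning.
#'
#' @param data paired data.frame.
#' @return tau-b in [-1, 1], or `NA`.
#' @export
kendallTau <- function(data) {
  d <- .asPaired(data)
  stopifnot(length(d$calc) >= 2L)
  if (stats::var(d$calc) == 0 || stats::var(d$expt) == 0) {
    warning("all values tied in one variable: Kendall tau undefined")
    return(NA_real_)
  }
  unname(stats::cor(d$calc, d$expt, method = "kendall"))
}

#' Pearlman predictive index
#'
#' Pairwise ranking agreement weighted by the experimental differences:
#' \deqn{PI = \sum_{j>i} w_{ij} c_{ij} / \sum_{j>i} w_{ij}}
#' with \eqn{w_{ij} = |expt_j - expt_i|} and \eqn{c_{ij} = 1} when the
#' experimental and calculated differences share a sign, \eqn{-1} when they
#' oppose, and 0 when the calculated values tie. Emphasises getting the
#' large experimental gaps in the right order.
#'
#' @param data paired data.frame.
#' @return PI in [-1, 1].
#' @export
pearlmanPI <- function(data) {
  d <- .asPaired(data)
  n <- length(d$calc)
  stopifnot(n >= 2L)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(2:n, function(k) k:n))
  de <- d$expt[j] - d$expt[i]
  dc <- d$calc[j] - d$calc[i]
  w <- abs(de)
  if (sum(w) == 0)
    stop("all experimental values equal: PI weights undefined", call. = FALSE)
  cij <- ifelse(dc == 0, 0, sign(de / dc))
  cij[de == 0] <- 0   # zero-weight pairs contribute nothing anyway
  sum(w * cij) / sum(w)
}

#' Pearson correlation
#'
#' Product-moment correlation between calculation and experiment.
#'
#' @param data paired data.frame.
#' @return r in [-1, 1], `NA` with a warning for zero variance.
#' @export
pearsonR <- function(data) {
  d <- .asPaired(data)
  stopifnot(length(d$calc) >= 2L)
  if (stats::var(d$calc) == 0 || stats::var(d$expt) == 0) {
    warning("zero variance: Pearson r undefined")
    return(NA_real_)
  }
  unname(stats::cor(d$calc, d$expt, method = "pearson"))
}

#' Outlier counts per deviation threshold
#'
#' For each threshold t, the number of entries with |calc - expt| > t. The
#' defaults are the +/-1 and +/-2 kcal/mol bands conventional in solvation
#' free-energy benchmarking.
#'
#' @param data paired data.frame.
#' @param thresholds positive, sorted ascending.
#' @return named integer vector of counts.
#' @export
outlierCounts <- function(data, thresholds = c(1, 2)) {
  d <- .asPaired(data)
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  err <- abs(d$calc - d$expt)
  out <- vapply(thresholds, function(t) sum(err > t), integer(1))
  names(out) <- format(thresholds)
  out
}

#' Full quality-metrics report
#'
#' @param data paired data.frame (see [pairedData()]).
#' @param thresholds outlier thresholds, data units.
#' @return a [MetricsReport-class].
#' @examples
#' d <- pairedData(letters[1:4], c(-4.1, -3.0, -1.2, 0.4),
#'                 c(-4.0, -3.5, -1.0, 0.0))
#' qualityMetrics(d)
#' @export
qualityMetrics <- function(data, thresholds = c(1, 2)) {
  em <- errorMetrics(data)
  new("MetricsReport",
      mae = em[["mae"]], mse = em[["mse"]], rmse = em[["rmse"]],
      tau = suppressWarnings(kendallTau(data)),
      pi = pearlmanPI(data),
      pearsonR = suppressWarnings(pearsonR(data)),
      outliers = outlierCounts(data, thresholds),
      n = nrow(data))
}

#' Report as a one-row data.frame
#'
#' @param report a [MetricsReport-class].
#' @return data.frame suitable for CSV export.
#' @export
metricsAsData <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  out <- data.frame(n = report@n, mae = report@mae, mse = report@mse,
                    rmse = report@rmse, tau = report@tau, pi = report@pi,
                    pearson_r = report@pearsonR)
  for (k in seq_along(report@outliers))
    out[[paste0("outliers_gt_", trimws(names(report@outliers)[k]))]] <-
      report@outliers[[k]]
  out
}
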