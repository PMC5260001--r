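## Evaluation metrics and cross-validation folds.
##
## All three metrics operate on paired actual/predicted survival times in
## years. The correlation is the plain centred product-moment coefficient;
## MAE is unsquared by default (a `squared` switch reproduces a squared
## variant); SEE uses the regression convention of n - 2 denominator degrees
## of freedom.

check_pairs <- function(actual, predicted, min_n = 2) {
  if (length(actual) != length(predicted)) stop("actual and predicted lengths differ")
  if (length(actual) < min_n) stop("need at least ", min_n, " prediction pairs")
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) {
    stop("non-finite values in predictions")
  }
  invisible(TRUE)
}

#' Pearson correlation between actual and predicted survival
#'
#' @param actual,predicted numeric vectors of equal length (years).
#' @return Correlation in `[-1, 1]`. Zero variance in either vector is an
#'   error, not a silent zero.
#' @export
pearson_r <- function(actual, predicted) {
  check_pairs(actual, predicted)
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined: zero variance in ",
         if (stats::sd(actual) == 0) "actual" else "predicted", " values")
  }
  as.numeric(stats::cor(actual, predicted))
}

#' Mean absolute error
#'
#' @inheritParams pearson_r
#' @param squared if `TRUE`, average the squared absolute residuals instead
#'   (a mean squared error under another name); the default is the standard
#'   unsquared MAE, in years.
#' @return Non-negative error.
#' @export
mean_absolute_error <- function(actual, predicted, squared = FALSE) {
  check_pairs(actual, predicted)
  res <- abs(predicted - actual)
  if (squared) mean(res^2) else mean(res)
}

#' Standard error of estimates
#'
#' `sqrt(sum((predicted - actual)^2) / (n - 2))`, the regression standard
#' error of the estimate.
#'
#' @inheritParams pearson_r
#' @return Non-negative error; requires at least 3 pairs.
#' @export
standard_error_of_estimates <- function(actual, predicted) {
  check_pairs(actual, predicted, min_n = 3)
  sqrt(sum((predicted - actual)^2) / (length(actual) - 2))
}

#' Bundle the three metrics into one report
#'
#' @inheritParams mean_absolute_error
#' @return List with `r`, `mae_years`, `mae_months` (years x 12) and `see`.
#' @export
metrics_report <- function(actual, predicted, squared = FALSE) {
  mae <- mean_absolute_error(actual, predicted, squared = squared)
  list(r = pearson_r(actual, predicted),
       mae_years = mae, mae_months = mae * 12,
       see = standard_error_of_estimates(actual, predicted))
}

#' Random balanced cross-validation folds
#'
#' Partitions `n_samples` into `n_folds` random folds whose sizes differ by
#' at most one, deterministically for a given seed.
#'
#' @param n_samples,n_folds integers, `n_folds <= n_samples`.
#' @param seed integer seed.
#' @return A `fold_assignment`: integer vector of fold labels in
#'   `1..n_folds`, with attributes `n_folds` and `seed`.
#' @export
make_folds <- function(n_samples, n_folds = 10, seed = 1L) {
  if (n_folds > n_samples) stop("n_folds (", n_folds,
                                ") exceeds n_samples (", n_samples, ")")
  if (n_folds < 2) stop("need at least 2 folds")
  labels <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n_samples)))
  structure(as.integer(labels), n_folds = as.integer(n_folds),
            seed = as.integer(seed), class = "fold_assignment")
}
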