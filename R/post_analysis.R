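## Downstream analyses of a selected feature set: main-effect-difference
## (MED) ranking by orthogonal experimental design, per-feature effect and
## knock-out analyses, and the two regression baselines (stepwise multiple
## linear regression and elastic net).

## CV fitness of an explicit feature subset under fixed decoded
## hyperparameters. An empty subset scores -1 (degenerate convention).
subset_fitness <- function(feature_ids, cohort, hp, folds, standardize = TRUE,
                           cache = NULL) {
  if (!length(feature_ids)) return(-1)
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(sort(feature_ids), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  X <- t(cohort$expression[feature_ids, , drop = FALSE])
  y <- cohort$survival_years
  pred <- rep(NA_real_, length(y))
  for (k in seq_len(attr(folds, "n_folds"))) {
    te <- which(folds == k); tr <- which(folds != k)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      par <- standardize_fit(Xtr)
      Xtr <- standardize_apply(Xtr, par); Xte <- standardize_apply(Xte, par)
    }
    m <- fit_nusvr(Xtr, y[tr], hp["C"], hp["gamma"], hp["nu"])
    pred[te] <- predict_nusvr(m, Xte)
  }
  val <- if (stats::sd(pred) == 0) -1 else as.numeric(stats::cor(y, pred))
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Main-effect-difference (MED) feature ranking
#'
#' Builds a two-level orthogonal array with one factor per selected feature
#' (level 1 = included, level 2 = excluded), evaluates the cross-validated
#' fitness of the feature subset encoded by every row under fixed
#' hyperparameters, and scores each feature by the difference between its
#' mean fitness at level 1 and at level 2. Rows encoding the empty subset
#' score -1 by the degenerate convention.
#'
#' @param selected character vector of (unique) selected feature ids, >= 2.
#' @param cohort a [cohort()].
#' @param hp decoded named hyperparameters `(C, gamma, nu)`, typically from
#'   [decode_hyperparams()] on the overall-best chromosome.
#' @param folds fold assignment for the fitness evaluations.
#' @param standardize z-score features per training fold.
#' @return A `data.frame(feature_id, med, rank)` sorted by descending MED
#'   (raw signed differences; no clipping at zero).
#' @export
med_analysis <- function(selected, cohort, hp, folds, standardize = TRUE) {
  if (anyDuplicated(selected)) stop("selected feature ids must be unique")
  m <- length(selected)
  if (m < 2) stop("MED analysis needs at least 2 selected features")
  missing_feats <- setdiff(selected, rownames(cohort$expression))
  if (length(missing_feats)) stop("unknown feature(s): ",
                                  paste(missing_feats, collapse = ", "))
  oa <- build_orthogonal_array(m)
  cache <- new.env(parent = emptyenv())
  fits <- vapply(seq_len(nrow(oa)), function(i) {
    subset_fitness(selected[oa[i, ] == 1L], cohort, hp, folds, standardize, cache)
  }, numeric(1))
  med <- vapply(seq_len(m), function(j) {
    mean(fits[oa[, j] == 1L]) - mean(fits[oa[, j] == 2L])
  }, numeric(1))
  ord <- order(-med, selected)
  data.frame(feature_id = selected[ord], med = med[ord], rank = seq_len(m),
             stringsAsFactors = FALSE)
}

## Coarse 4x4x4 sub-grid used when re-tuning single-feature models.
coarse_grid_points <- function(grid, step = 5) {
  idx <- seq(1, 16, by = step)
  expand.grid(C = grid$C[idx], gamma = grid$gamma[idx], nu = grid$nu[idx])
}

#' Individual (single-feature) effect analysis
#'
#' Fits one nu-SVR per selected feature alone, re-tuning `(C, gamma, nu)`
#' over a coarse sub-grid by the same pooled-CV criterion, and reports each
#' feature's pooled correlation and MAE in months.
#'
#' @inheritParams med_analysis
#' @param grid an [hyperparam_grid()]; tuning uses a 4x4x4 sub-grid of it.
#' @return A `data.frame(feature_id, r, mae_months)`, one row per feature,
#'   in the input order.
#' @export
individual_effect_analysis <- function(selected, cohort, folds,
                                       grid = hyperparam_grid(),
                                       standardize = TRUE) {
  if (!length(selected)) stop("selected must be non-empty")
  pts <- coarse_grid_points(grid)
  y <- cohort$survival_years
  rows <- lapply(selected, function(fid) {
    best <- list(r = -Inf, mae = NA_real_)
    for (i in seq_len(nrow(pts))) {
      hp <- c(C = pts$C[i], gamma = pts$gamma[i], nu = pts$nu[i])
      X <- t(cohort$expression[fid, , drop = FALSE])
      pred <- rep(NA_real_, length(y))
      for (k in seq_len(attr(folds, "n_folds"))) {
        te <- which(folds == k); tr <- which(folds != k)
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        if (standardize) {
          par <- standardize_fit(Xtr)
          Xtr <- standardize_apply(Xtr, par); Xte <- standardize_apply(Xte, par)
        }
        m <- fit_nusvr(Xtr, y[tr], hp["C"], hp["gamma"], hp["nu"])
        pred[te] <- predict_nusvr(m, Xte)
      }
      r <- if (stats::sd(pred) == 0) -1 else as.numeric(stats::cor(y, pred))
      if (r > best$r) best <- list(r = r, mae = mean(abs(pred - y)))
    }
    data.frame(feature_id = fid, r = best$r, mae_months = best$mae * 12,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Leave-one-out knock-out analysis
#'
#' Measures each feature's contribution as the drop in cross-validated
#' fitness when it is removed from the full selected set:
#' `delta_r = fitness(all) - fitness(all minus feature)`, with
#' hyperparameters held fixed.
#'
#' @inheritParams med_analysis
#' @return A `data.frame(feature_id, delta_r)` in the input order, with
#'   attribute `full_fitness`.
#' @export
knockout_analysis <- function(selected, cohort, hp, folds, standardize = TRUE) {
  if (length(selected) < 2) stop("knock-out analysis needs at least 2 features")
  if (anyDuplicated(selected)) stop("selected feature ids must be unique")
  cache <- new.env(parent = emptyenv())
  full <- subset_fitness(selected, cohort, hp, folds, standardize, cache)
  delta <- vapply(seq_along(selected), function(j) {
    full - subset_fitness(selected[-j], cohort, hp, folds, standardize, cache)
  }, numeric(1))
  out <- data.frame(feature_id = selected, delta_r = delta,
                    stringsAsFactors = FALSE)
  attr(out, "full_fitness") <- full
  out
}

## ---- regression baselines -------------------------------------------------

## Pooled-CV predictions of an OLS fit on the given features.
mlr_cv_predictions <- function(cohort, feature_ids, folds) {
  X <- t(cohort$expression[feature_ids, , drop = FALSE])
  y <- cohort$survival_years
  pred <- rep(NA_real_, length(y))
  for (k in seq_len(attr(folds, "n_folds"))) {
    te <- which(folds == k); tr <- which(folds != k)
    df_tr <- data.frame(y = y[tr], X[tr, , drop = FALSE], check.names = FALSE)
    fit <- stats::lm(y ~ ., data = df_tr)
    pred[te] <- stats::predict(fit,
      newdata = data.frame(X[te, , drop = FALSE], check.names = FALSE))
  }
  pred
}

#' Stepwise (forward) multiple linear regression baseline
#'
#' Starts from the empty model and greedily adds the feature that maximises
#' the pooled cross-validated correlation, stopping when the improvement
#' falls below `enter_threshold` or `max_features` is reached.
#'
#' @param cohort a [cohort()].
#' @param folds fold assignment.
#' @param max_features largest model size considered.
#' @param enter_threshold minimum pooled-r improvement to admit a feature.
#' @return A `baseline_result` with the selected features, pooled metrics
#'   and out-of-fold predictions.
#' @export
stepwise_mlr <- function(cohort, folds, max_features = 15,
                         enter_threshold = 0.005) {
  p <- nrow(cohort$expression)
  n <- ncol(cohort$expression)
  if (n < max_features + 3) stop("need at least max_features + 3 samples")
  y <- cohort$survival_years
  chosen <- character(0)
  current_r <- -Inf
  current_pred <- NULL
  repeat {
    if (length(chosen) >= max_features) break
    candidates <- setdiff(rownames(cohort$expression), chosen)
    best <- list(r = -Inf, id = NULL, pred = NULL)
    for (fid in candidates) {
      pred <- tryCatch(
        suppressWarnings(mlr_cv_predictions(cohort, c(chosen, fid), folds)),
        error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred)) || stats::sd(pred) == 0) next
      r <- as.numeric(stats::cor(y, pred))
      if (r > best$r) best <- list(r = r, id = fid, pred = pred)
    }
    if (is.null(best$id)) break
    gain <- if (is.finite(current_r)) best$r - current_r else best$r
    if (gain < enter_threshold) break
    chosen <- c(chosen, best$id)
    current_r <- best$r
    current_pred <- best$pred
  }
  if (!length(chosen)) stop("no feature admitted by the stepwise procedure")
  baseline_result("stepwise_mlr", chosen, y, current_pred)
}

baseline_result <- function(method, features, actual, predicted) {
  degenerate <- stats::sd(predicted) == 0
  if (degenerate) warning("degenerate baseline predictions; r set to -1",
                          call. = FALSE)
  structure(list(
    method = method,
    n_features_selected = length(features),
    features = features,
    r = if (degenerate) -1 else as.numeric(stats::cor(actual, predicted)),
    mae_years = mean(abs(predicted - actual)),
    see = sqrt(sum((predicted - actual)^2) / max(length(actual) - 2, 1)),
    predictions = list(actual = as.numeric(actual),
                       predicted = as.numeric(predicted))),
    class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("%s: %d features, r = %.3f, MAE = %.3f years, SEE = %.3f\n",
              x$method, x$n_features_selected, x$r, x$mae_years, x$see))
  invisible(x)
}

#' Elastic-net baseline
#'
#' For each outer fold, tunes the mixing parameter over `l1_ratio_grid` and
#' the penalty by inner cross-validation (glmnet), predicts the held-out
#' samples, and pools the predictions. The reported feature count comes from
#' a final full-data fit tuned the same way.
#'
#' @param cohort a [cohort()].
#' @param folds outer fold assignment.
#' @param l1_ratio_grid mixing parameters (glmnet `alpha`) searched.
#' @param lambda_rule `"1se"` (default, stronger regularisation) or `"min"`.
#' @param seed seed for glmnet's inner fold assignment.
#' @return A `baseline_result`; an all-zero final model reports `r = -1`
#'   with a warning.
#' @export
elastic_net_baseline <- function(cohort, folds,
                                 l1_ratio_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                                 lambda_rule = c("1se", "min"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  X <- t(cohort$expression)
  y <- cohort$survival_years
  pick <- function(Xtr, ytr, inner_foldid) {
    best <- NULL
    for (alpha in l1_ratio_grid) {
      cvfit <- glmnet::cv.glmnet(Xtr, ytr, alpha = alpha, foldid = inner_foldid,
                                 family = "gaussian")
      lam <- if (lambda_rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
      score <- cvfit$cvm[match(lam, cvfit$lambda)]
      if (is.null(best) || score < best$score) {
        best <- list(alpha = alpha, lambda = lam, score = score, fit = cvfit)
      }
    }
    best
  }
  pred <- rep(NA_real_, length(y))
  for (k in seq_len(attr(folds, "n_folds"))) {
    te <- which(folds == k); tr <- which(folds != k)
    inner <- with_seed(derive_seed(seed, paste0("enet-inner-", k)),
                       sample(rep(seq_len(5), length.out = length(tr))))
    b <- pick(X[tr, , drop = FALSE], y[tr], inner)
    pred[te] <- as.numeric(stats::predict(b$fit, newx = X[te, , drop = FALSE],
                                          s = b$lambda))
  }
  inner_full <- with_seed(derive_seed(seed, "enet-final"),
                          sample(rep(seq_len(5), length.out = length(y))))
  b <- pick(X, y, inner_full)
  coefs <- as.numeric(stats::coef(b$fit, s = b$lambda))[-1]   # drop intercept
  features <- rownames(cohort$expression)[coefs != 0]
  res <- baseline_result("elastic_net", features, y, pred)
  res$n_features_selected <- length(features)
  res$tuned <- list(alpha = b$alpha, lambda = b$lambda)
  res
}
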