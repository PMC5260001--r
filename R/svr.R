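## nu-SVR engine: chromosome encoding, hyperparameter decoding, cross-validated
## fitness, and the final model handle. The quadratic program itself is
## delegated to e1071's libsvm binding; this module owns everything around it.

#' Default 4-bit hyperparameter grid
#'
#' Sixteen values per hyperparameter so each maps exactly onto a 4-bit gene:
#' `C = 2^(-10..5)`, `gamma = 2^(-15..0)`, `nu = (1..16)/16`. With z-scored
#' features and a response of a few years, C above 2^5 buys no additional
#' model flexibility while slowing the solver drastically, so the cost grid
#' tops out there.
#'
#' @param C_values,gamma_values,nu_values optional replacement grids; each
#'   must hold exactly 16 strictly increasing values (nu in (0, 1]).
#' @return An `hp_grid` list.
#' @export
hyperparam_grid <- function(C_values = 2^seq(-10, 5),
                            gamma_values = 2^seq(-15, 0),
                            nu_values = seq_len(16) / 16) {
  for (v in list(C_values, gamma_values, nu_values)) {
    if (length(v) != 16) stop("each hyperparameter grid must have exactly 16 values")
    if (any(diff(v) <= 0)) stop("grid values must be strictly increasing")
  }
  if (any(C_values <= 0) || any(gamma_values <= 0)) stop("C and gamma must be positive")
  if (any(nu_values <= 0) || any(nu_values > 1)) stop("nu values must lie in (0, 1]")
  structure(list(C = as.numeric(C_values), gamma = as.numeric(gamma_values),
                 nu = as.numeric(nu_values)), class = "hp_grid")
}

#' Construct a chromosome
#'
#' A chromosome holds `n` binary feature genes (exactly `r` ones inside a
#' stage) and three 4-bit hyperparameter genes indexing C, gamma and nu in
#' the grid (0-based indices 0..15).
#'
#' @param features integer/logical vector of 0/1 feature genes.
#' @param hp integer vector of length 3, values in 0..15, ordered (C, gamma, nu).
#' @return A `chromosome` list.
#' @export
chromosome <- function(features, hp) {
  features <- as.integer(features)
  if (any(!features %in% c(0L, 1L))) stop("feature genes must be 0/1")
  hp <- as.integer(hp)
  if (length(hp) != 3 || any(hp < 0 | hp > 15)) {
    stop("hp genes must be three integers in 0..15")
  }
  structure(list(f = features, hp = hp), class = "chromosome")
}

n_selected <- function(chrom) sum(chrom$f)

chrom_signature <- function(chrom) {
  paste(paste(which(chrom$f == 1L), collapse = ","), paste(chrom$hp, collapse = ","),
        sep = "|")
}

## Lexicographic tie-break: TRUE if a's feature-gene vector is strictly
## smaller than b's (gene-by-gene), with the hp genes breaking residual ties.
chrom_less <- function(a, b) {
  d <- a$f - b$f
  i <- which(d != 0L)
  if (length(i)) return(d[i[1]] < 0L)
  d <- a$hp - b$hp
  i <- which(d != 0L)
  if (length(i)) return(d[i[1]] < 0L)
  FALSE
}

#' Decode the hyperparameter genes of a chromosome
#'
#' @param chrom a [chromosome()].
#' @param grid an [hyperparam_grid()].
#' @return Named numeric `(C, gamma, nu)` by direct table lookup.
#' @export
decode_hyperparams <- function(chrom, grid = hyperparam_grid()) {
  stopifnot(inherits(chrom, "chromosome"), inherits(grid, "hp_grid"))
  c(C = grid$C[chrom$hp[1] + 1L],
    gamma = grid$gamma[chrom$hp[2] + 1L],
    nu = grid$nu[chrom$hp[3] + 1L])
}

## Single nu-SVR fit; X is samples x features.
fit_nusvr <- function(X, y, C, gamma, nu) {
  e1071::svm(X, y, type = "nu-regression", kernel = "radial",
             cost = C, gamma = gamma, nu = nu, scale = FALSE, fitted = FALSE)
}

## Fast RBF prediction from the support vectors (equivalent to predict.svm,
## without its input rebuilding overhead; equality is covered by a test).
predict_nusvr <- function(model, X) {
  SV <- model$SV
  if (is.null(SV) || nrow(SV) == 0) return(rep(-model$rho, nrow(X)))
  d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * tcrossprod(X, SV)
  d2[d2 < 0] <- 0
  as.numeric(exp(-model$gamma * d2) %*% model$coefs - model$rho)
}

## Per-feature z-scoring parameters learned on training data only.
standardize_fit <- function(Xtr) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(center = mu, scale = sd)
}
standardize_apply <- function(X, par) {
  sweep(sweep(X, 2, par$center, "-"), 2, par$scale, "/")
}

#' Cross-validated fitness of a chromosome
#'
#' For each fold, fits a radial-kernel nu-SVR on the training split restricted
#' to the chromosome's selected features (z-scored on the training split when
#' `standardize` is on), predicts the held-out split, pools all out-of-fold
#' predictions, and scores them. The fitness value the GA maximises is the
#' pooled Pearson correlation; a degenerate pooling (zero variance) scores -1
#' with a warning so the GA can still rank it.
#'
#' @param chrom a [chromosome()] with at least one selected feature.
#' @param cohort a [cohort()].
#' @param folds a [make_folds()] assignment over the cohort samples.
#' @param grid an [hyperparam_grid()].
#' @param standardize z-score features per training fold (default `TRUE`).
#' @param cache optional environment memoising results by chromosome signature.
#' @return A `fitness_result`: list with `fitness`, `r`, `mae_years`, `see`,
#'   and `predictions` (actual/predicted in original sample order).
#' @export
evaluate_fitness <- function(chrom, cohort, folds, grid = hyperparam_grid(),
                             standardize = TRUE, cache = NULL) {
  stopifnot(inherits(chrom, "chromosome"), inherits(cohort, "cohort"))
  if (n_selected(chrom) < 1) stop("chromosome selects no features")
  if (!is.null(cache)) {
    key <- paste0(chrom_signature(chrom), "#", attr(folds, "n_folds"), "#",
                  attr(folds, "seed"), "#", standardize)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  sel <- which(chrom$f == 1L)
  hp <- decode_hyperparams(chrom, grid)
  X <- t(cohort$expression[sel, , drop = FALSE])   # samples x features
  y <- cohort$survival_years
  n <- length(y)
  if (length(folds) != n) stop("fold assignment does not match cohort size")
  pred <- rep(NA_real_, n)
  for (k in seq_len(attr(folds, "n_folds"))) {
    te <- which(folds == k)
    tr <- which(folds != k)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      par <- standardize_fit(Xtr)
      Xtr <- standardize_apply(Xtr, par)
      Xte <- standardize_apply(Xte, par)
    }
    m <- fit_nusvr(Xtr, y[tr], hp["C"], hp["gamma"], hp["nu"])
    pred[te] <- predict_nusvr(m, Xte)
  }
  res <- fitness_from_predictions(y, pred)
  if (!is.null(cache)) cache[[key]] <- res
  res
}

## Score pooled out-of-fold predictions; degenerate -> fitness -1.
fitness_from_predictions <- function(actual, predicted) {
  degenerate <- stats::sd(actual) == 0 || stats::sd(predicted) == 0
  if (degenerate) {
    warning("degenerate predictions (zero variance); fitness set to -1",
            call. = FALSE)
    r <- -1
  } else {
    r <- as.numeric(stats::cor(actual, predicted))
  }
  structure(list(fitness = r, r = r,
                 mae_years = mean(abs(predicted - actual)),
                 see = sqrt(sum((predicted - actual)^2) /
                              max(length(actual) - 2, 1)),
                 predictions = list(actual = as.numeric(actual),
                                    predicted = as.numeric(predicted))),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("fitness (pooled r) = %.4f, MAE = %.3f years, SEE = %.3f\n",
              x$fitness, x$mae_years, x$see))
  invisible(x)
}

#' Train the final nu-SVR on the full cohort
#'
#' Fits once on all samples with the chromosome's selected features and
#' decoded hyperparameters; the returned handle predicts on any expression
#' matrix carrying those features and survives a save/load round trip.
#'
#' @inheritParams evaluate_fitness
#' @return An `svr_model` handle (selected feature ids, decoded
#'   hyperparameters, standardisation parameters, fitted solver object).
#' @export
train_final_model <- function(chrom, cohort, grid = hyperparam_grid(),
                              standardize = TRUE) {
  stopifnot(inherits(chrom, "chromosome"), inherits(cohort, "cohort"))
  if (n_selected(chrom) < 1) stop("chromosome selects no features")
  sel <- which(chrom$f == 1L)
  hp <- decode_hyperparams(chrom, grid)
  X <- t(cohort$expression[sel, , drop = FALSE])
  par <- NULL
  if (standardize) {
    par <- standardize_fit(X)
    X <- standardize_apply(X, par)
  }
  m <- tryCatch(fit_nusvr(X, cohort$survival_years, hp["C"], hp["gamma"], hp["nu"]),
                error = function(e) {
                  stop("nu-SVR training failed for chromosome [",
                       chrom_signature(chrom), "]: ", conditionMessage(e))
                })
  structure(list(model = m, feature_ids = rownames(cohort$expression)[sel],
                 hyperparams = hp, standardize = par, chromosome = chrom),
            class = "svr_model")
}

#' Predict survival from a trained model handle
#'
#' @param object an `svr_model` from [train_final_model()].
#' @param expression expression matrix (features x samples) carrying all the
#'   model's selected features; extra features are ignored.
#' @param ... unused.
#' @return Named numeric vector of predicted survival times (years).
#' @export
predict.svr_model <- function(object, expression, ...) {
  missing_feats <- setdiff(object$feature_ids, rownames(expression))
  if (length(missing_feats)) {
    stop("expression matrix lacks selected feature(s): ",
         paste(missing_feats, collapse = ", "))
  }
  X <- t(expression[object$feature_ids, , drop = FALSE])
  if (!is.null(object$standardize)) X <- standardize_apply(X, object$standardize)
  p <- predict_nusvr(object$model, X)
  names(p) <- colnames(expression)
  p
}

#' Save / load a trained model handle
#'
#' @param model an `svr_model`.
#' @param path file path.
#' @return `save_model` the path invisibly; `load_model` the restored handle.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svr_model"))
  atomic_write(path, function(tmp) saveRDS(model, tmp))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "svr_model")) stop("file does not contain an svr_model")
  m
}
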