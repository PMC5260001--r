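## Synthetic cohorts with planted informative features.
##
## The generator emulates the scale and survival support of a bulk miRNA
## expression cohort (hundreds of samples, hundreds of features, survival
## roughly 0.4-11 years) with a small planted set of informative features,
## so every downstream stage is testable with known ground truth.

#' Specify a synthetic cohort
#'
#' Defaults describe the emulated study conditions: 247 samples by 470
#' features, 10 informative features with distinct, sign-alternating effect
#' sizes, survival support 0.4-11 years, and 1 year of additive noise.
#'
#' @param n_samples,n_features cohort dimensions.
#' @param informative_features number `k` of features carrying signal.
#' @param effect_sizes length-`k` numeric; default `seq(1.5, 0.5)` magnitudes
#'   with alternating signs, so that effect *ranks* are well defined.
#' @param link `"linear"` or `"nonlinear_rbf"` (Gaussian-bump response that
#'   linear models cannot fully capture).
#' @param noise_sd additive Gaussian noise, in years.
#' @param survival_range `(min, max)` survival support in years; `min > 0`.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 247, n_features = 470,
                           informative_features = 10,
                           effect_sizes = NULL,
                           link = c("linear", "nonlinear_rbf"),
                           noise_sd = 1, survival_range = c(0.4, 11),
                           seed = 1L) {
  link <- match.arg(link)
  k <- informative_features
  if (k < 1) stop("informative_features must be >= 1")
  if (k > n_features) stop("informative_features (", k,
                           ") exceeds n_features (", n_features, ")")
  if (is.null(effect_sizes)) {
    effect_sizes <- seq(1.5, 0.5, length.out = k) * (-1)^(seq_len(k) - 1)
  }
  if (length(effect_sizes) != k) stop("effect_sizes must have length ", k)
  if (survival_range[1] <= 0) stop("survival_range minimum must be > 0")
  if (survival_range[2] <= survival_range[1]) stop("survival_range must increase")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 informative_features = as.integer(k),
                 effect_sizes = as.numeric(effect_sizes),
                 link = link, noise_sd = noise_sd,
                 survival_range = as.numeric(survival_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Nonlinear response: Gaussian bump centred off the origin plus a weak linear
## term. The bump contributes curvature a kernel regressor can exploit while
## the linear term keeps a modest monotone component.
nonlinear_link_value <- function(x, effects) {
  as.numeric(crossprod(x, effects) * 0.5) +
    as.numeric(exp(-(x - 1)^2 / 2) %*% effects * 2)
}

#' Simulate a cohort with known ground truth
#'
#' Expression values are i.i.d. standard normal. The latent survival score is
#' a linear (or Gaussian-bump nonlinear) combination of the planted features;
#' the noiseless score is min-max mapped onto `survival_range`, Gaussian noise
#' in years is added, and the result is clipped back into the range. With
#' `noise_sd = 0` nothing is ever clipped, so a single planted linear feature
#' correlates perfectly with survival.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `cohort` (a [cohort()]) and `truth` (list of
#'   `informative_ids`, `effect_sizes`, and the affine map used).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; p <- spec$n_features; k <- spec$informative_features
    feature_ids <- sprintf("mir-sim-%04d", seq_len(p))
    sample_ids <- sprintf("S%04d", seq_len(n))
    X <- matrix(stats::rnorm(p * n), nrow = p, ncol = n,
                dimnames = list(feature_ids, sample_ids))
    idx <- seq_len(k)   # planted features occupy the first k rows
    Z <- X[idx, , drop = FALSE]
    latent <- switch(spec$link,
      linear = as.numeric(crossprod(Z, spec$effect_sizes)),
      nonlinear_rbf = vapply(seq_len(n), function(j) {
        nonlinear_link_value(Z[, j], spec$effect_sizes)
      }, numeric(1)))
    lo <- spec$survival_range[1]; hi <- spec$survival_range[2]
    rng <- range(latent)
    if (diff(rng) == 0) {
      mapped <- rep((lo + hi) / 2, n); a <- 0; b <- (lo + hi) / 2
    } else {
      a <- (hi - lo) / diff(rng); b <- lo - a * rng[1]
      mapped <- a * latent + b
    }
    y <- mapped + stats::rnorm(n, sd = spec$noise_sd)
    y <- pmin(pmax(y, lo), hi)
    names(y) <- sample_ids
    list(cohort = cohort(X, y),
         truth = list(informative_ids = feature_ids[idx],
                      effect_sizes = spec$effect_sizes,
                      affine_map = c(scale = a, offset = b)))
  })
}

## Clinical table for a simulated cohort, in the dialect read_clinical_tsv
## expects; survival is converted back to integer days.
simulated_clinical_table <- function(cohort, days_per_year = 365.25) {
  data.frame(sample_id = names(cohort$survival_years),
             days_to_death = as.integer(round(cohort$survival_years * days_per_year)),
             received_therapy = "TRUE",
             vital_status = "dead",
             stringsAsFactors = FALSE)
}

#' Write a fixture suite of synthetic cohorts
#'
#' Writes a small (40 samples x 30 features, 3 planted) and a full-scale
#' (247 x 470, 10 planted) fixture, each as paired expression + clinical TSVs,
#' plus a JSON manifest recording seeds, ground-truth feature ids and effect
#' sizes. Re-running with the same seed reproduces the files byte for byte.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; each fixture derives its own sub-seed.
#' @return The manifest, invisibly; also written to `manifest.json`.
#' @export
write_fixture_suite <- function(outdir, seed = 1L) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output directory ", outdir)
  }
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  specs <- list(
    small = synthetic_spec(n_samples = 40, n_features = 30,
                           informative_features = 3, noise_sd = 0.5,
                           seed = derive_seed(seed, "fixture-small")),
    full_scale = synthetic_spec(seed = derive_seed(seed, "fixture-full")))
  manifest <- list(master_seed = seed, fixtures = list())
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    sim <- simulate_cohort(sp)
    expr_path <- file.path(outdir, paste0(nm, "_expression.tsv"))
    clin_path <- file.path(outdir, paste0(nm, "_clinical.tsv"))
    write_expression_tsv(sim$cohort$expression, expr_path)
    atomic_write(clin_path, function(tmp) {
      utils::write.table(simulated_clinical_table(sim$cohort), tmp,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    manifest$fixtures[[nm]] <- list(
      expression = basename(expr_path), clinical = basename(clin_path),
      n_samples = sp$n_samples, n_features = sp$n_features,
      seed = sp$seed, link = sp$link, noise_sd = sp$noise_sd,
      survival_range = sp$survival_range,
      informative_ids = sim$truth$informative_ids,
      effect_sizes = sim$truth$effect_sizes,
      affine_map = as.list(sim$truth$affine_map))
  }
  write_json_report(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
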