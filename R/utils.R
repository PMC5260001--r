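#' @keywords internal
"_PACKAGE"

## Shared internal helpers: seeded evaluation, seed derivation, atomic writes.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded helpers do not perturb the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a named sub-seed from a master seed
#'
#' A single user-supplied seed fans out to independent, documented sub-seeds
#' (folds, population, simulation, ...) so each component is reproducible in
#' isolation. The derivation is a fixed affine hash of the label, kept inside
#' 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param label character tag naming the consumer.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1L, "folds")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587)
}

## Write a file atomically: write to a temp path in the same directory, then
## rename. Failure paths never leave a partial final artifact.
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  ok <- TRUE
  invisible(path)
}

## Consistent JSON dialect for all reports.
write_json_report <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
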