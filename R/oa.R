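## Two-level orthogonal arrays by the Sylvester/Hadamard doubling
## construction. These drive both the intelligent crossover and the
## main-effect-difference feature ranking.

#' Build a two-level orthogonal array
#'
#' Returns the smallest Sylvester-type array with at least `n_factors`
#' columns: `N` rows (a power of two, `N >= n_factors + 1`), entries 1/2,
#' every column balanced, and every ordered level pair occurring exactly
#' `N/4` times in every column pair.
#'
#' @param n_factors number of two-level factors (>= 1).
#' @return An `orthogonal_array` matrix (`N` rows x `n_factors` columns,
#'   entries in `{1, 2}`).
#' @export
build_orthogonal_array <- function(n_factors) {
  if (n_factors < 1) stop("n_factors must be >= 1")
  N <- 2L
  while (N < n_factors + 1L) N <- N * 2L
  H <- matrix(1, 1, 1)
  while (nrow(H) < N) H <- rbind(cbind(H, H), cbind(H, -H))
  oa <- ifelse(H[, -1, drop = FALSE] > 0, 1L, 2L)   # drop the all-ones column
  structure(oa[, seq_len(n_factors), drop = FALSE], class = "orthogonal_array")
}

#' Check orthogonal-array invariants by enumeration
#'
#' Verifies column balance (equal counts of levels 1 and 2) and pairwise
#' orthogonality (each ordered level combination appearing exactly `N/4`
#' times for every column pair).
#'
#' @param oa an array from [build_orthogonal_array()].
#' @return `TRUE` if all invariants hold, otherwise `FALSE`.
#' @export
validate_orthogonal_array <- function(oa) {
  N <- nrow(oa)
  if (!all(oa %in% c(1L, 2L))) return(FALSE)
  if (bitwAnd(N, N - 1L) != 0L) return(FALSE)           # power of two
  if (N < ncol(oa) + 1L) return(FALSE)
  for (j in seq_len(ncol(oa))) {
    if (sum(oa[, j] == 1L) != N / 2) return(FALSE)
  }
  if (ncol(oa) >= 2) {
    for (a in seq_len(ncol(oa) - 1)) for (b in seq((a + 1), ncol(oa))) {
      combos <- table(factor(oa[, a], levels = 1:2), factor(oa[, b], levels = 1:2))
      if (!all(combos == N / 4)) return(FALSE)
    }
  }
  TRUE
}
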