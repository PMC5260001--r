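## Inheritable bi-objective combinatorial GA (IBCGA).
##
## A stage-wise sweep over the number of selected features r: each stage runs
## a steady-state GA whose crossover is the orthogonal-array "intelligent"
## operator (children assembled from estimated per-gene main effects), and
## each stage's final population is inherited into the next stage with one
## extra feature gene switched on per individual.

#' IBCGA run parameters
#'
#' Defaults are the standard published configuration of the algorithm:
#' stages r = 10..50, population 50, crossover probability 0.8, mutation
#' probability 0.05, 60 generations per stage, 2-way tournaments.
#'
#' @param r_start,r_end first and last feature-count stages.
#' @param N_pop population size.
#' @param P_c crossover probability (fraction of the pool crossed per
#'   generation).
#' @param P_m mutation probability (fraction of individuals mutated).
#' @param G_max generations per stage.
#' @param tournament_size individuals per selection tournament.
#' @param seed master seed for the whole run.
#' @return An `ibcga_params` list.
#' @export
ibcga_params <- function(r_start = 10, r_end = 50, N_pop = 50, P_c = 0.8,
                         P_m = 0.05, G_max = 60, tournament_size = 2,
                         seed = 1L) {
  stopifnot(r_start >= 1, r_end >= r_start, N_pop >= 2,
            P_c > 0, P_c < 1, P_m > 0, P_m < 1, G_max >= 0,
            tournament_size >= 2)
  structure(list(r_start = as.integer(r_start), r_end = as.integer(r_end),
                 N_pop = as.integer(N_pop), P_c = P_c, P_m = P_m,
                 G_max = as.integer(G_max),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "ibcga_params")
}

#' Initialise a stage-r population
#'
#' Every chromosome gets exactly `r` randomly placed feature genes set to 1
#' and uniform 4-bit hyperparameter genes.
#'
#' @param n_features chromosome length.
#' @param r number of selected features per chromosome.
#' @param n_pop population size.
#' @param seed optional seed; by default draws from the current RNG stream.
#' @return List of [chromosome()]s.
#' @export
init_population <- function(n_features, r, n_pop, seed = NULL) {
  if (r > n_features) stop("r (", r, ") exceeds n_features (", n_features, ")")
  gen <- function() {
    lapply(seq_len(n_pop), function(i) {
      f <- integer(n_features)
      f[sample.int(n_features, r)] <- 1L
      chromosome(f, sample.int(16, 3) - 1L)
    })
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Tournament selection
#'
#' Forms a mating pool of `length(population)` winners of independent
#' `tournament_size`-way tournaments (contestants sampled with replacement);
#' fitness ties go to the lexicographically smaller chromosome.
#'
#' @param population list of chromosomes.
#' @param fitnesses numeric fitness per individual.
#' @param tournament_size contestants per tournament (default 2).
#' @return Integer vector of selected indices (the mating pool).
#' @export
tournament_select <- function(population, fitnesses, tournament_size = 2) {
  n <- length(population)
  stopifnot(length(fitnesses) == n)
  vapply(seq_len(n), function(i) {
    cand <- sample.int(n, tournament_size, replace = TRUE)
    best <- cand[1]
    for (j in cand[-1]) {
      if (fitnesses[j] > fitnesses[best] ||
          (fitnesses[j] == fitnesses[best] &&
           chrom_less(population[[j]], population[[best]]))) {
        best <- j
      }
    }
    best
  }, integer(1))
}

## ---- orthogonal-array crossover ------------------------------------------

## Factorisation of two parents: positions where the feature genes differ
## (each its own factor, randomly grouped when beyond the cap) plus one
## factor per differing 4-bit hyperparameter gene.
crossover_factors <- function(p1, p2, cap = 31) {
  diff_f <- which(p1$f != p2$f)
  diff_hp <- which(p1$hp != p2$hp)
  budget <- cap - length(diff_hp)
  if (budget < 1 && length(diff_f)) budget <- 1
  factors <- list()
  if (length(diff_f)) {
    if (length(diff_f) <= budget) {
      groups <- as.list(diff_f)
    } else {
      lab <- sample(rep(seq_len(budget), length.out = length(diff_f)))
      groups <- split(diff_f, lab)
    }
    factors <- lapply(groups, function(g) list(type = "f", pos = as.integer(g)))
  }
  for (g in diff_hp) factors[[length(factors) + 1]] <- list(type = "hp", pos = g)
  factors
}

## Instantiate one OA row: level 1 takes parent 1's genes for that factor,
## level 2 parent 2's; then repair the feature count to exactly r by random
## flips restricted to positions where the parents differ.
instantiate_row <- function(levels, factors, p1, p2, r) {
  f <- p1$f; hp <- p1$hp
  for (j in seq_along(factors)) {
    if (levels[j] == 2L) {
      fac <- factors[[j]]
      if (fac$type == "f") f[fac$pos] <- p2$f[fac$pos] else hp[fac$pos] <- p2$hp[fac$pos]
    }
  }
  repair_count(chromosome(f, hp), which(p1$f != p2$f), r)
}

repair_count <- function(chrom, flex_pos, r) {
  excess <- sum(chrom$f) - r
  if (excess > 0) {
    ones <- intersect(flex_pos, which(chrom$f == 1L))
    drop <- if (length(ones) == 1) ones else sample(ones, excess)
    chrom$f[drop] <- 0L
  } else if (excess < 0) {
    zeros <- intersect(flex_pos, which(chrom$f == 0L))
    add <- if (length(zeros) == 1) zeros else sample(zeros, -excess)
    chrom$f[add] <- 1L
  }
  chrom
}

#' Orthogonal-array intelligent crossover
#'
#' Factors are the gene positions where the parents differ (feature genes
#' individually, capped by random grouping; each differing hyperparameter
#' gene as one factor). Every row of the corresponding orthogonal array is
#' instantiated as a candidate chromosome, repaired to exactly `r` selected
#' features and evaluated; per-factor main effects (mean fitness at level 1
#' minus level 2) assemble child 1 from each factor's better level, while
#' child 2 is the best evaluated row.
#'
#' @param p1,p2 parent chromosomes, both with `r` selected features.
#' @param cohort,folds,grid,standardize,cache fitness-evaluation context
#'   (see [evaluate_fitness()]).
#' @param r stage feature count.
#' @param factor_cap maximum number of OA factors (surplus differing
#'   positions are randomly grouped; default 31, i.e. a 32-row array).
#' @return List `(child1, child2)` with attribute `n_evaluations`.
#' @export
oa_crossover <- function(p1, p2, cohort, folds, grid, r,
                         standardize = TRUE, cache = NULL, factor_cap = 31) {
  factors <- crossover_factors(p1, p2, cap = factor_cap)
  if (!length(factors)) {
    out <- list(child1 = p1, child2 = p2)
    attr(out, "n_evaluations") <- 0L
    return(out)
  }
  oa <- build_orthogonal_array(length(factors))
  cands <- lapply(seq_len(nrow(oa)), function(i) {
    instantiate_row(oa[i, ], factors, p1, p2, r)
  })
  fits <- vapply(cands, function(ch) {
    evaluate_fitness(ch, cohort, folds, grid, standardize, cache)$fitness
  }, numeric(1))

  ## child 2: best evaluated row (lexicographic tie-break)
  best <- 1L
  for (i in seq_along(cands)[-1]) {
    if (fits[i] > fits[best] ||
        (fits[i] == fits[best] && chrom_less(cands[[i]], cands[[best]]))) best <- i
  }

  ## child 1: per-factor better level, ties to the lexicographically
  ## smaller parent's level
  f <- p1$f; hp <- p1$hp
  p1_smaller <- chrom_less(p1, p2)
  for (j in seq_along(factors)) {
    med_j <- mean(fits[oa[, j] == 1L]) - mean(fits[oa[, j] == 2L])
    take2 <- med_j < 0 || (med_j == 0 && !p1_smaller)
    if (take2) {
      fac <- factors[[j]]
      if (fac$type == "f") f[fac$pos] <- p2$f[fac$pos] else hp[fac$pos] <- p2$hp[fac$pos]
    }
  }
  child1 <- repair_count(chromosome(f, hp), which(p1$f != p2$f), r)
  out <- list(child1 = child1, child2 = cands[[best]])
  attr(out, "n_evaluations") <- length(cands)
  out
}

#' Count-preserving mutation
#'
#' Swaps `n_swaps` randomly chosen selected feature genes with unselected
#' genes (keeping the stage count `r` intact) and flips each 4-bit
#' hyperparameter gene bit with probability 1/4. A single swap keeps the
#' mutant close to its parent, so a newly introduced good gene is judged in
#' a context the selection can reward.
#'
#' @param chrom a chromosome.
#' @param n_swaps swaps per call (default 1), capped by the number of
#'   selected and unselected genes.
#' @param hp_bit_prob per-bit flip probability for the hyperparameter genes
#'   (default 1/16, i.e. under one flipped bit per mutant, so a mutant's
#'   feature change is usually judged at its parent's hyperparameters).
#' @return The mutated chromosome.
#' @export
swap_mutate <- function(chrom, n_swaps = 1, hp_bit_prob = 1 / 16) {
  ones <- which(chrom$f == 1L)
  zeros <- which(chrom$f == 0L)
  if (length(ones) && length(zeros)) {
    k <- min(length(ones), length(zeros), max(1L, as.integer(n_swaps)))
    i <- if (length(ones) == 1) ones else sample(ones, k)
    j <- if (length(zeros) == 1) zeros else sample(zeros, k)
    chrom$f[i] <- 0L
    chrom$f[j] <- 1L
  }
  for (g in 1:3) {
    flips <- which(stats::runif(4) < hp_bit_prob)
    if (length(flips)) {
      chrom$hp[g] <- as.integer(bitwXor(chrom$hp[g], sum(2L^(flips - 1L))))
    }
  }
  chrom
}

## Index of the fittest individual, lexicographic tie-break.
best_index <- function(population, fits) {
  best <- 1L
  for (i in seq_along(population)[-1]) {
    if (fits[i] > fits[best] ||
        (fits[i] == fits[best] && chrom_less(population[[i]], population[[best]]))) {
      best <- i
    }
  }
  best
}

#' Run one IBCGA stage
#'
#' `G_max` generations of evaluate, tournament selection, orthogonal-array
#' crossover of `P_c * N_pop` parents, and count-preserving mutation of
#' `P_m * N_pop` individuals (the best individual is exempt and is re-seeded
#' into the population if crossover displaced it). Returns the best-ever
#' individual of the stage as the stage solution.
#'
#' @param population list of chromosomes, all with `r` selected features.
#' @param r stage feature count.
#' @param cohort,folds,grid,standardize,cache fitness context.
#' @param params [ibcga_params()].
#' @param cross_folds fold assignment used to score crossover candidates
#'   (defaults to `folds`; a coarser assignment cuts crossover cost).
#' @param factor_cap see [oa_crossover()].
#' @param refine_elite after the generation loop, refine the elite's three
#'   hyperparameter genes over the grid (features fixed), so stage solutions
#'   are reported at comparable hyperparameter quality. `TRUE` or `"cd"`:
#'   coordinate descent, one gene at a time (cheap); `"joint"`: full joint
#'   (C, gamma) sweep plus a nu sweep per cycle (for cohorts where single
#'   evaluations are cheap); `FALSE`/`"none"`: off.
#' @return List with `solution` (a `stage_solution`), `population` (final)
#'   and `trace` (per-generation best fitness data.frame).
#' @export
run_stage <- function(population, r, cohort, folds, grid, params,
                      standardize = TRUE, cache = NULL, cross_folds = folds,
                      factor_cap = 31, refine_elite = TRUE) {
  n_pop <- length(population)
  eval_all <- function(pop) {
    vapply(pop, function(ch) {
      evaluate_fitness(ch, cohort, folds, grid, standardize, cache)$fitness
    }, numeric(1))
  }
  fits <- eval_all(population)
  bi <- best_index(population, fits)
  best_chrom <- population[[bi]]
  best_fit <- fits[bi]
  trace <- data.frame(r = r, generation = 0L, best = fits[bi],
                      best_ever = best_fit)

  ## Steady-state generational scheme: the tournament pool chooses crossover
  ## parents, children displace the worst individuals, mutation perturbs a few
  ## non-elite slots in place. The population itself persists between
  ## generations, so moderately fit explorers survive long enough for the
  ## orthogonal-array crossover to screen the genes they carry.
  for (gen in seq_len(params$G_max)) {
    pool <- tournament_select(population, fits, params$tournament_size)

    n_par <- floor(params$P_c * n_pop)
    n_par <- n_par - n_par %% 2L
    if (n_par >= 2) {
      parents <- sample(pool, n_par)
      ## pair distinct chromosomes where possible: crossover of identical
      ## parents is a no-op and wastes the operator's evaluation budget
      sig <- vapply(population[parents], chrom_signature, character(1))
      for (k in seq(1, n_par, by = 2)) {
        if (sig[k] == sig[k + 1]) {
          later <- seq(k + 2, length.out = max(0, n_par - k - 1))
          alt <- later[sig[later] != sig[k]]
          if (length(alt)) {
            j <- alt[1]
            tmp <- parents[k + 1]; parents[k + 1] <- parents[j]; parents[j] <- tmp
            tmp <- sig[k + 1]; sig[k + 1] <- sig[j]; sig[j] <- tmp
          }
        }
      }
      children <- vector("list", n_par)
      for (k in seq(1, n_par, by = 2)) {
        ch <- oa_crossover(population[[parents[k]]], population[[parents[k + 1]]],
                           cohort, cross_folds, grid, r,
                           standardize, cache, factor_cap)
        children[[k]] <- ch$child1
        children[[k + 1]] <- ch$child2
      }
      ## children replace the currently worst individuals (the best is safe)
      worst <- order(fits, decreasing = FALSE)
      worst <- setdiff(worst, best_index(population, fits))[seq_len(n_par)]
      for (k in seq_len(n_par)) {
        population[[worst[k]]] <- children[[k]]
        fits[worst[k]] <- evaluate_fitness(children[[k]], cohort, folds, grid,
                                           standardize, cache)$fitness
      }
    }

    ## mutation in place on randomly chosen non-best slots
    bi <- best_index(population, fits)
    eligible <- setdiff(seq_len(n_pop), bi)
    n_mut <- min(max(0L, as.integer(round(params$P_m * n_pop))), length(eligible))
    if (n_mut > 0) {
      targets <- if (length(eligible) == 1) eligible else sample(eligible, n_mut)
      for (i in targets) {
        population[[i]] <- swap_mutate(population[[i]])
        fits[i] <- evaluate_fitness(population[[i]], cohort, folds, grid,
                                    standardize, cache)$fitness
      }
    }

    bi <- best_index(population, fits)
    if (fits[bi] > best_fit ||
        (fits[bi] == best_fit && chrom_less(population[[bi]], best_chrom))) {
      best_chrom <- population[[bi]]
      best_fit <- fits[bi]
    }
    trace <- rbind(trace, data.frame(r = r, generation = gen, best = fits[bi],
                                     best_ever = best_fit))
  }

  ## memetic elite refinement: coordinate descent of the elite's three
  ## hyperparameter genes (features fixed), so every stage solution X_r is
  ## reported at comparable hyperparameter quality and stage fitnesses
  ## reflect feature sets rather than hyperparameter luck
  if (!identical(refine_elite, FALSE) && !identical(refine_elite, "none")) {
    mode <- if (isTRUE(refine_elite)) "cd" else match.arg(refine_elite,
                                                          c("cd", "joint"))
    try_hp <- function(hp) {
      cand <- best_chrom
      cand$hp <- hp
      f <- evaluate_fitness(cand, cohort, folds, grid, standardize,
                            cache)$fitness
      if (f > best_fit || (f == best_fit && chrom_less(cand, best_chrom))) {
        best_chrom <<- cand
        best_fit <<- f
        TRUE
      } else FALSE
    }
    for (cycle in 1:3) {
      improved <- FALSE
      if (mode == "cd") {
        ## one gene at a time through its 16 values
        for (g in 1:3) for (v in 0:15) {
          if (v != best_chrom$hp[g]) {
            hp <- best_chrom$hp; hp[g] <- v
            improved <- try_hp(hp) || improved
          }
        }
      } else {
        ## pairwise joint sweeps: the hyperparameters interact along ridges
        ## that one-gene descent cannot follow
        for (iC in 0:15) for (ig in 0:15) {
          improved <- try_hp(c(iC, ig, best_chrom$hp[3])) || improved
        }
        for (ig in 0:15) for (inu in 0:15) {
          improved <- try_hp(c(best_chrom$hp[1], ig, inu)) || improved
        }
        for (iC in 0:15) for (inu in 0:15) {
          improved <- try_hp(c(iC, best_chrom$hp[2], inu)) || improved
        }
      }
      if (!improved) break
    }
    ## the refined elite re-enters the population
    sigs <- vapply(population, chrom_signature, character(1))
    if (!chrom_signature(best_chrom) %in% sigs) {
      population[[sample.int(n_pop, 1)]] <- best_chrom
    }
  }

  solution <- structure(
    list(r = r, chromosome = best_chrom,
         fitness = evaluate_fitness(best_chrom, cohort, folds, grid,
                                    standardize, cache)),
    class = "stage_solution")
  list(solution = solution, population = population, trace = trace)
}

#' Inherit a population into the next stage
#'
#' Flips one randomly chosen feature gene from 0 to 1 in every chromosome,
#' taking each from `r` to `r + 1` selected features; previously selected
#' genes stay selected.
#'
#' @param population list of chromosomes with equal selected-feature counts.
#' @return The inherited population.
#' @export
inherit_population <- function(population) {
  lapply(population, function(ch) {
    zeros <- which(ch$f == 0L)
    if (!length(zeros)) stop("cannot inherit: all feature genes already selected")
    i <- if (length(zeros) == 1) zeros else sample(zeros, 1)
    ch$f[i] <- 1L
    ch
  })
}

#' Run the full IBCGA sweep
#'
#' Executes the stage-wise sweep r = `r_start`..`r_end`: initialise at
#' `r_start`, run each stage for `G_max` generations, inherit the final
#' population into the next stage, and collect one stage solution `X_r` per
#' stage plus the overall best. Fully deterministic given `params$seed`.
#'
#' @param cohort a [cohort()].
#' @param params [ibcga_params()].
#' @param grid [hyperparam_grid()].
#' @param n_folds folds for the cross-validated fitness (default 10).
#' @param folds optional explicit [make_folds()] assignment overriding
#'   `n_folds` (e.g. to share folds across runs).
#' @param standardize z-score features per training fold.
#' @param crossover_cv_folds optional smaller fold count used only to score
#'   crossover candidates (cuts crossover cost; `NULL` reuses the main folds).
#' @param factor_cap OA factor cap for crossover.
#' @param refine_elite see [run_stage()]; on by default.
#' @param verbose print per-stage progress.
#' @return An `ibcga_result`: list with `stages` (stage solutions), the
#'   `overall_best` stage solution, `trace`, `folds`, `params`, `grid`.
#' @export
run_ibcga <- function(cohort, params = ibcga_params(), grid = hyperparam_grid(),
                      n_folds = 10, standardize = TRUE,
                      crossover_cv_folds = NULL, factor_cap = 31,
                      refine_elite = TRUE, folds = NULL, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(params, "ibcga_params"))
  n_features <- nrow(cohort$expression)
  if (params$r_end > n_features) stop("r_end exceeds the number of features")
  n <- ncol(cohort$expression)
  if (is.null(folds)) {
    folds <- make_folds(n, n_folds, derive_seed(params$seed, "folds"))
  } else if (length(folds) != n) {
    stop("supplied folds do not match the cohort size")
  }
  cross_folds <- if (is.null(crossover_cv_folds)) folds else {
    make_folds(n, crossover_cv_folds, derive_seed(params$seed, "crossover-folds"))
  }
  cache <- new.env(parent = emptyenv())
  with_seed(derive_seed(params$seed, "ga-stream"), {
    population <- init_population(n_features, params$r_start, params$N_pop)
    stages <- vector("list", params$r_end - params$r_start + 1L)
    traces <- list()
    for (r in seq(params$r_start, params$r_end)) {
      t0 <- Sys.time()
      st <- run_stage(population, r, cohort, folds, grid, params,
                      standardize, cache, cross_folds, factor_cap, refine_elite)
      stages[[r - params$r_start + 1L]] <- st$solution
      traces[[length(traces) + 1L]] <- st$trace
      population <- st$population
      if (verbose) {
        message(sprintf("[stage r=%d] best fitness %.4f (%.1fs)", r,
                        st$solution$fitness$fitness,
                        as.numeric(Sys.time() - t0, units = "secs")))
      }
      if (r < params$r_end) population <- inherit_population(population)
    }
    fit_vals <- vapply(stages, function(s) s$fitness$fitness, numeric(1))
    bi <- 1L
    for (i in seq_along(stages)[-1]) {
      if (fit_vals[i] > fit_vals[bi] ||
          (fit_vals[i] == fit_vals[bi] &&
           chrom_less(stages[[i]]$chromosome, stages[[bi]]$chromosome))) bi <- i
    }
    structure(list(stages = stages, overall_best = stages[[bi]],
                   trace = do.call(rbind, traces), folds = folds,
                   params = params, grid = grid, standardize = standardize),
              class = "ibcga_result")
  })
}

#' @export
print.stage_solution <- function(x, ...) {
  cat(sprintf("X_%d: fitness %.4f (%d features)\n", x$r, x$fitness$fitness,
              sum(x$chromosome$f)))
  invisible(x)
}

#' @export
print.ibcga_result <- function(x, ...) {
  cat("IBCGA sweep: stages r =", x$params$r_start, "..", x$params$r_end, "\n")
  cat(sprintf("overall best: r = %d, pooled r = %.4f, MAE = %.3f years\n",
              x$overall_best$r, x$overall_best$fitness$fitness,
              x$overall_best$fitness$mae_years))
  invisible(x)
}

#' Selected feature ids of a stage solution
#' @param solution a `stage_solution`.
#' @param cohort the cohort it was fitted on.
#' @return Character vector of feature ids.
#' @export
selected_features <- function(solution, cohort) {
  rownames(cohort$expression)[solution$chromosome$f == 1L]
}
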