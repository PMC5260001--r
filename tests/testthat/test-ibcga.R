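test_that("initial populations carry exactly r selected genes", {
  pop <- init_population(470, 10, 50, seed = 1)
  expect_length(pop, 50)
  expect_true(all(vapply(pop, function(c) sum(c$f), numeric(1)) == 10))
  expect_true(all(vapply(pop, function(c) all(c$hp %in% 0:15), logical(1))))

  expect_identical(init_population(30, 4, 5, seed = 9),
                   init_population(30, 4, 5, seed = 9))
  pop_all <- init_population(8, 8, 3, seed = 2)
  expect_true(all(vapply(pop_all, function(c) sum(c$f), numeric(1)) == 8))
  expect_error(init_population(5, 6, 3, seed = 1), "exceeds")
})

test_that("tournament selection favours the dominant individual", {
  pop <- init_population(10, 3, 20, seed = 5)
  fits <- rep(0.1, 20); fits[7] <- 0.9
  set.seed(11)
  # the dominant individual wins every tournament that samples it, so over
  # many pools its share must exceed the uniform share 1/N_pop
  share <- mean(replicate(50, mean(tournament_select(pop, fits) == 7)))
  expect_gt(share, 1 / 20)
  # and with two individuals it fills most of the pool (expected share 3/4)
  pop2 <- pop[1:2]
  share2 <- mean(replicate(50, mean(tournament_select(pop2, c(0.1, 0.9)) == 2)))
  expect_gt(share2, 0.5)

  set.seed(12)
  equal_pool <- tournament_select(pop, rep(0.5, 20))
  expect_true(all(equal_pool %in% 1:20))

  set.seed(13); a <- tournament_select(pop, fits)
  set.seed(13); b <- tournament_select(pop, fits)
  expect_identical(a, b)
})

test_that("OA crossover respects the stage constraint and degenerate parents", {
  sim <- toy_cohort(n = 30, p = 10, k = 1, noise_sd = 0, seed = 61)
  folds <- make_folds(30, 5, seed = 6)
  g <- hyperparam_grid()
  p1 <- chrom_for(c(1, 2, 3), 10)
  same <- oa_crossover(p1, p1, sim$cohort, folds, g, r = 3)
  expect_identical(same$child1, p1)
  expect_equal(attr(same, "n_evaluations"), 0L)

  # equal-count parents differ in an even number of feature genes; two feature
  # positions plus one differing hyperparameter gene give 3 factors -> L4 array
  p2 <- chrom_for(c(1, 2, 3), 10, hp = c(12, 8, 7))
  p3 <- chrom_for(c(1, 2, 4), 10, hp = c(12, 8, 6))
  set.seed(14)
  ch <- oa_crossover(p2, p3, sim$cohort, folds, g, r = 3)
  expect_equal(attr(ch, "n_evaluations"), 4L)
  expect_equal(sum(ch$child1$f), 3)
  expect_equal(sum(ch$child2$f), 3)
})

test_that("crossover children inherit the informative feature from either parent", {
  hits <- vapply(1:20, function(s) {
    sim <- toy_cohort(n = 30, p = 8, k = 1, noise_sd = 0, seed = 600 + s)
    folds <- make_folds(30, 5, seed = s)
    inf <- which(rownames(sim$cohort$expression) %in% sim$truth$informative_ids)
    others <- setdiff(1:8, inf)
    p_with <- chrom_for(c(inf, others[1]), 8)
    p_without <- chrom_for(others[2:3], 8)
    set.seed(s)
    ch <- oa_crossover(p_with, p_without, sim$cohort, folds, hyperparam_grid(), r = 2)
    ch$child1$f[inf] == 1L
  }, logical(1))
  expect_equal(sum(hits), 20)
})

test_that("mutation preserves the selected-feature count", {
  set.seed(15)
  ch <- chrom_for(c(2, 5), 6)
  for (i in 1:20) {
    m <- swap_mutate(ch)
    expect_equal(sum(m$f), 2)
    expect_true(all(m$hp %in% 0:15))
  }
  full <- chrom_for(1:4, 4)
  m <- swap_mutate(full)
  expect_equal(m$f, full$f)   # no zeros to swap with

  set.seed(16); a <- swap_mutate(ch)
  set.seed(16); b <- swap_mutate(ch)
  expect_identical(a, b)
})

test_that("stages maintain the count invariant, elitism and G_max semantics", {
  sim <- toy_cohort(n = 30, p = 8, k = 2, noise_sd = 0.3, seed = 71)
  folds <- make_folds(30, 5, seed = 7)
  params <- ibcga_params(r_start = 2, r_end = 2, N_pop = 8, G_max = 4, seed = 3)
  pop <- init_population(8, 2, 8, seed = 3)

  set.seed(17)
  st <- run_stage(pop, 2, sim$cohort, folds, hyperparam_grid(), params)
  expect_true(all(vapply(st$population, function(c) sum(c$f), numeric(1)) == 2))
  expect_equal(sum(st$solution$chromosome$f), 2)
  expect_true(all(diff(st$trace$best_ever) >= 0))
  # elite hp refinement may lift the reported solution above the search trace
  expect_gte(st$solution$fitness$fitness, max(st$trace$best_ever))

  # G_max = 0: the stage solution is the best of the initial population;
  # elite hp refinement may only improve it, never change its feature set
  params0 <- ibcga_params(r_start = 2, r_end = 2, N_pop = 8, G_max = 0, seed = 3)
  st0 <- run_stage(pop, 2, sim$cohort, folds, hyperparam_grid(), params0,
                   refine_elite = FALSE)
  init_fits <- vapply(pop, function(c) {
    evaluate_fitness(c, sim$cohort, folds)$fitness
  }, numeric(1))
  expect_equal(st0$solution$fitness$fitness, max(init_fits))
  st0r <- run_stage(pop, 2, sim$cohort, folds, hyperparam_grid(), params0,
                    refine_elite = TRUE)
  expect_gte(st0r$solution$fitness$fitness, st0$solution$fitness$fitness)
  expect_identical(st0r$solution$chromosome$f, st0$solution$chromosome$f)
})

test_that("inheritance adds exactly one new gene and keeps the old ones", {
  pop <- init_population(12, 4, 6, seed = 21)
  set.seed(18)
  pop2 <- inherit_population(pop)
  for (i in seq_along(pop)) {
    expect_equal(sum(pop2[[i]]$f), 5)
    expect_true(all(pop2[[i]]$f[pop[[i]]$f == 1L] == 1L))
  }
  one_zero <- chromosome(c(1, 1, 0, 1), c(0, 0, 0))
  set.seed(19)
  expect_equal(inherit_population(list(one_zero))[[1]]$f, rep(1L, 4))
  full <- chromosome(rep(1, 4), c(0, 0, 0))
  expect_error(inherit_population(list(full)), "cannot inherit")
})

test_that("the full sweep returns one solution per stage, deterministically", {
  sim <- toy_cohort(n = 30, p = 10, k = 2, noise_sd = 0.3, seed = 81)
  params <- ibcga_params(r_start = 2, r_end = 5, N_pop = 6, G_max = 2, seed = 7)
  res <- run_ibcga(sim$cohort, params, n_folds = 5, crossover_cv_folds = 3)
  expect_length(res$stages, 4)
  expect_equal(vapply(res$stages, function(s) s$r, numeric(1)), 2:5)
  expect_equal(vapply(res$stages, function(s) sum(s$chromosome$f), numeric(1)), 2:5)
  best_fit <- res$overall_best$fitness$fitness
  expect_true(all(vapply(res$stages, function(s) s$fitness$fitness, numeric(1))
                  <= best_fit))

  res2 <- run_ibcga(sim$cohort, params, n_folds = 5, crossover_cv_folds = 3)
  expect_identical(res$overall_best$chromosome, res2$overall_best$chromosome)
  expect_identical(res$trace, res2$trace)
  expect_error(run_ibcga(sim$cohort, ibcga_params(r_start = 2, r_end = 50)),
               "exceeds")
})

test_that("a small sweep recovers planted features", {
  recovered <- vapply(1:10, function(s) {
    sim <- toy_cohort(n = 40, p = 30, k = 3, noise_sd = 0.3, seed = 700 + s)
    params <- ibcga_params(r_start = 3, r_end = 3, N_pop = 12, G_max = 5,
                           seed = s)
    res <- run_ibcga(sim$cohort, params, n_folds = 5, crossover_cv_folds = 3)
    sel <- selected_features(res$overall_best, sim$cohort)
    length(intersect(sel, sim$truth$informative_ids))
  }, numeric(1))
  expect_gte(sum(recovered >= 2), 8)
})
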