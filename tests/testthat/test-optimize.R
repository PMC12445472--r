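# negative squared distance to a fixed feasible target: unique maximiser
known_maximizer_objective <- function(target) {
  function(Xm) -rowSums(sweep(Xm, 2L, target)^2)
}

test_that("default optimizer configuration matches the reference settings", {
  cfg <- optimizer_config()
  expect_identical(cfg$population, 30L)
  expect_identical(cfg$max_iterations, 1000L)
  expect_equal(cfg$de_mutation_F, 0.8)
  expect_equal(cfg$de_crossover_CR, 0.9)
  expect_equal(cfg$pso_c1, 2)
  expect_equal(cfg$pso_c2, 2)
  expect_equal(cfg$pso_inertia_start, 0.9)
  expect_equal(cfg$pso_inertia_end, 0.4)
  expect_equal(entropy_params()$alpha, 0.01)
})

test_that("repair produces valid threshold vectors from arbitrary reals", {
  rc <- repair_candidate(c(120.4, 30.2, 10.9, 200.1), 256L)
  expect_identical(rc$t, c(30L, 120L))
  expect_identical(rc$v, c(11L, 200L))

  expect_identical(repair_candidate(c(50, 50, 10, 20), 256L)$t, c(50L, 51L))
  rc3 <- repair_candidate(c(-5, 300, 17, 90), 256L)
  expect_identical(rc3$t, c(1L, 254L))

  # cascade at the top of the range falls back to a downward sweep
  rc4 <- repair_candidate(c(254, 254, 254, 1, 2, 3), 256L)
  expect_identical(rc4$t, c(252L, 253L, 254L))

  expect_error(repair_candidate(c(1, 2, 3), 256L), "even length")
  expect_error(repair_candidate(rep(1, 8), 5L), "cannot fit")

  # repair is total: random garbage always yields a valid vector
  set.seed(5)
  for (i in 1:50) {
    raw <- runif(6, -100, 400)
    rc <- repair_candidate(raw, 64L)
    expect_true(all(rc$t >= 1L & rc$t <= 62L))
    expect_true(!is.unsorted(rc$t, strictly = TRUE))
    expect_true(!is.unsorted(rc$v, strictly = TRUE))
  }
})

test_that("exhaustive search enumerates the candidate space and finds the optimum", {
  # L = 4, k = 1: exactly 4 candidates; constant objective -> lexicographic min
  calls <- 0L
  counter <- function(Xm) { calls <<- calls + nrow(Xm); rep(1, nrow(Xm)) }
  res <- exhaustive_search(counter, 1L, 4L)
  expect_identical(calls, 4L)
  expect_identical(res$best_X$t, 1L)
  expect_identical(res$best_X$v, 1L)

  expect_error(exhaustive_search(counter, 3L, 256L, cap = 1e6), "cap")

  # dominance over random sampling on a real objective
  H <- make_random_histogram(16L, 120L, seed = 17)
  f <- fitness_objective(H, 2L, entropy_params(mode = "quantum"))
  best <- exhaustive_search(f, 2L, 16L)
  set.seed(18)
  rand <- t(replicate(1000, c(sort(sample(1:14, 2)), sort(sample(1:14, 2)))))
  expect_true(all(f(rand) <= best$best_fitness + 1e-12))
  expect_equal(f(matrix(c(best$best_X$t, best$best_X$v), 1)), best$best_fitness)
})

test_that("PSO and DE recover a known unique maximiser", {
  target <- c(40, 90, 30, 100)
  obj <- known_maximizer_objective(target)
  hits_pso <- 0L; hits_de <- 0L
  for (seed in 1:20) {
    cfg <- optimizer_config(seed = seed, max_iterations = 300)
    rp <- pso_optimize(obj, 2L, 256L, cfg)
    rd <- de_optimize(obj, 2L, 256L, cfg)
    if (all(c(rp$best_X$t, rp$best_X$v) == target)) hits_pso <- hits_pso + 1L
    if (all(c(rd$best_X$t, rd$best_X$v) == target)) hits_de <- hits_de + 1L
  }
  expect_gte(hits_pso, 19L)
  expect_gte(hits_de, 19L)
})

test_that("stagnation and degenerate-operator rules behave as specified", {
  const <- function(Xm) rep(0, nrow(Xm))
  cfg <- optimizer_config(population = 1L, stagnation_patience = 1L, seed = 1)
  res <- pso_optimize(const, 1L, 32L, cfg)
  expect_lte(res$iterations, 2L)

  # F = 0, CR = 0: DE population never changes, best stays the initial best
  H <- make_random_histogram(16L, 60L, seed = 4)
  f <- fitness_objective(H, 1L, entropy_params(mode = "classical"))
  cfg0 <- optimizer_config(de_mutation_F = 0, de_crossover_CR = 0,
                           seed = 3, max_iterations = 50,
                           stagnation_patience = 10L)
  r0 <- de_optimize(f, 1L, 16L, cfg0)
  # initial best: re-evaluate the seeded initial population directly
  set.seed(3)
  init <- matrix(runif(30 * 2, 1, 14), 30, 2)
  init_fit <- f(cbind(pmin(pmax(round(init[, 1]), 1), 14),
                      pmin(pmax(round(init[, 2]), 1), 14)))
  expect_equal(r0$best_fitness, max(init_fit))
  expect_true(all(r0$trace$best_fitness == max(init_fit)))
  expect_identical(r0$iterations, 10L)   # stagnation patience fires exactly
})

test_that("optimizer runs are reproducible and traces are monotone", {
  H <- make_random_histogram(32L, 200L, seed = 23)
  f <- fitness_objective(H, 2L, entropy_params(mode = "quantum"))
  for (fn in list(pso_optimize, de_optimize)) {
    a <- fn(f, 2L, 32L, optimizer_config(seed = 11, max_iterations = 150))
    b <- fn(f, 2L, 32L, optimizer_config(seed = 11, max_iterations = 150))
    expect_identical(a$best_X, b$best_X)
    expect_identical(a$best_fitness, b$best_fitness)
    expect_identical(a$trace, b$trace)
    expect_true(all(diff(a$trace$best_fitness) >= 0))
    # reported best re-evaluates to itself
    expect_equal(f(matrix(c(a$best_X$t, a$best_X$v), 1)), a$best_fitness)
  }
})

test_that("metaheuristics match the exhaustive optimum at small scale", {
  # L = 16, k = 1 keeps this fast; the acceptance suite runs the L = 32, k = 2
  # configuration
  H <- make_random_histogram(16L, 100L, seed = 29)
  for (mode in c("classical", "quantum")) {
    f <- fitness_objective(H, 1L, entropy_params(mode = mode))
    opt <- exhaustive_search(f, 1L, 16L)$best_fitness
    hits <- 0L
    for (seed in 1:10) {
      cfg <- optimizer_config(seed = seed, max_iterations = 200)
      if (abs(pso_optimize(f, 1L, 16L, cfg)$best_fitness - opt) < 1e-9)
        hits <- hits + 1L
    }
    expect_gte(hits, 9L)
  }
})

test_that("optimizer results expose tidy, glance and trace exports", {
  H <- make_random_histogram(16L, 80L, seed = 31)
  f <- fitness_objective(H, 1L, entropy_params(mode = "classical"))
  res <- pso_optimize(f, 1L, 16L, optimizer_config(seed = 2, max_iterations = 50))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "best_fitness"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$best_fitness, res$best_fitness)
  dir <- withr::local_tempdir()
  p <- write_trace(res, file.path(dir, "trace.csv"))
  expect_identical(nrow(utils::read.csv(p)), nrow(td))
  expect_s3_class(autoplot(res), "ggplot")
})
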