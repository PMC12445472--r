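#' Optimizer configuration
#'
#' Defaults reproduce the reference experimental setup: population 30,
#' at most 1000 iterations, DE mutation factor `F = 0.8` and crossover rate
#' `CR = 0.9`, PSO cognitive/social coefficients `c1 = c2 = 2` with inertia
#' decreasing linearly from 0.9 to 0.4 over the iteration budget. The
#' stagnation patience (stop after this many iterations without global-best
#' improvement) is this package's termination rule; the original study reports
#' iteration counts but not its stopping criterion.
#'
#' @param population Swarm/population size.
#' @param max_iterations Iteration budget.
#' @param de_mutation_F DE scale factor.
#' @param de_crossover_CR DE binomial crossover rate in `[0, 1]`.
#' @param pso_c1,pso_c2 PSO cognitive and social coefficients.
#' @param pso_inertia_start,pso_inertia_end Linear inertia schedule endpoints.
#' @param stagnation_patience Iterations without improvement before stopping.
#' @param seed Integer RNG seed; every run is reproducible from it.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(population = 30L, max_iterations = 1000L,
                             de_mutation_F = 0.8, de_crossover_CR = 0.9,
                             pso_c1 = 2, pso_c2 = 2,
                             pso_inertia_start = 0.9, pso_inertia_end = 0.4,
                             stagnation_patience = 100L, seed = 1L) {
  abort_if(population < 1L || max_iterations < 1L || stagnation_patience < 1L,
           "population, max_iterations and stagnation_patience must be positive")
  abort_if(de_crossover_CR < 0 || de_crossover_CR > 1, "CR must lie in [0, 1]")
  structure(list(population = as.integer(population),
                 max_iterations = as.integer(max_iterations),
                 de_mutation_F = de_mutation_F,
                 de_crossover_CR = de_crossover_CR,
                 pso_c1 = pso_c1, pso_c2 = pso_c2,
                 pso_inertia_start = pso_inertia_start,
                 pso_inertia_end = pso_inertia_end,
                 stagnation_patience = as.integer(stagnation_patience),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Repair a raw real-valued candidate into a valid threshold vector
#'
#' Rounds each half (rows then columns) to integers, clips to `[1, L-2]`,
#' sorts ascending, and resolves duplicates by incrementing upward with
#' cascade (falling back to a downward sweep at the top of the range), so
#' repair is total on any even-length real vector.
#'
#' @param raw Numeric vector of length `2k`: `(t raw | v raw)`.
#' @param L Number of gray levels.
#' @return A `threshold_vector`.
#' @export
repair_candidate <- function(raw, L = 256L) {
  abort_if(length(raw) %% 2L != 0L || length(raw) == 0L,
           "raw candidate must have positive even length 2k")
  k <- length(raw) %/% 2L
  abort_if(k > L - 2L, sprintf("cannot fit %d distinct thresholds in [1, %d]", k, L - 2L))
  fix <- function(z) repair_half(z, L)
  threshold_vector(fix(raw[seq_len(k)]), fix(raw[k + seq_len(k)]), L = L)
}

repair_half <- function(z, L) {
  z <- sort(pmin(pmax(round(z), 1L), L - 2L))
  k <- length(z)
  for (i in seq_len(k)[-1L]) if (z[i] <= z[i - 1L]) z[i] <- z[i - 1L] + 1L
  if (z[k] > L - 2L) {                     # cascaded past the top: sweep down
    z[k] <- L - 2L
    for (i in rev(seq_len(k - 1L))) if (z[i] >= z[i + 1L]) z[i] <- z[i + 1L] - 1L
  }
  as.integer(z)
}

# matrix version: row-wise repair of an n x 2k matrix (used in inner loops)
repair_matrix <- function(Xm, L) {
  k <- ncol(Xm) %/% 2L
  out <- matrix(0L, nrow(Xm), ncol(Xm))
  for (r in seq_len(nrow(Xm))) {
    out[r, seq_len(k)] <- repair_half(Xm[r, seq_len(k)], L)
    out[r, k + seq_len(k)] <- repair_half(Xm[r, k + seq_len(k)], L)
  }
  out
}

new_optimizer_result <- function(method, best_row, best_fit, iterations, trace,
                                 k, L, seed) {
  best_row <- as.integer(best_row)
  structure(list(
    method = method,
    best_X = threshold_vector(best_row[seq_len(k)], best_row[k + seq_len(k)], L),
    best_fitness = best_fit,
    iterations = as.integer(iterations),
    trace = tibble::tibble(iteration = seq_along(trace), best_fitness = trace),
    seed = seed
  ), class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("<optimizer_result> %s: k = %d, best fitness = %.6g after %d iterations\n",
              x$method, x$best_X$k, x$best_fitness, x$iterations))
  cat(sprintf("  t* = (%s), v* = (%s)\n",
              paste(x$best_X$t, collapse = ", "),
              paste(x$best_X$v, collapse = ", ")))
  invisible(x)
}

#' @rdname optimizer_result_methods
#' @param x,object An `optimizer_result`.
#' @param ... Unused.
#' @export
tidy.optimizer_result <- function(x, ...) x$trace

#' Broom-style accessors for optimizer results
#'
#' `tidy()` returns the convergence trace (iteration, best-so-far fitness);
#' `glance()` a one-row summary; `autoplot()` the convergence curve.
#'
#' @name optimizer_result_methods
#' @export
glance.optimizer_result <- function(x, ...) {
  tibble::tibble(method = x$method, k = x$best_X$k,
                 best_fitness = x$best_fitness, iterations = x$iterations,
                 t_star = paste(x$best_X$t, collapse = ","),
                 v_star = paste(x$best_X$v, collapse = ","),
                 seed = x$seed)
}

#' @rdname optimizer_result_methods
#' @export
autoplot.optimizer_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Iteration", y = "Best fitness",
                  title = sprintf("%s convergence (k = %d)", object$method,
                                  object$best_X$k)) +
    ggplot2::theme_minimal()
}

# shared candidate bookkeeping: lexicographic comparison for deterministic ties
lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0L && d[nz[1L]] < 0
}

# evaluate a population matrix: repair, score, return list(repaired, fitness)
eval_population <- function(pos, objective, L) {
  rep_m <- repair_matrix(pos, L)
  list(X = rep_m, fit = objective(rep_m))
}

#' Particle swarm optimization over threshold vectors
#'
#' Global-best PSO on continuous positions in `[1, L-2]^(2k)`; candidates are
#' evaluated through [repair_candidate()] so every scored vector is feasible.
#' Velocities are clamped to half the feasible span per dimension and
#' positions reflect at the bounds. Stops at the iteration budget or after
#' `stagnation_patience` iterations without global-best improvement.
#'
#' @param objective Vectorised fitness: takes an `n x 2k` integer matrix of
#'   repaired candidates (rows `t | v`), returns `n` fitness values. Build one
#'   with [fitness_objective()].
#' @param k Number of thresholds per axis.
#' @param L Number of gray levels.
#' @param config An [optimizer_config()].
#' @return An `optimizer_result`.
#' @export
pso_optimize <- function(objective, k, L, config = optimizer_config()) {
  n <- config$population; d <- 2L * k
  lo <- 1; hi <- L - 2
  vmax <- (L - 3) / 2
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  pos <- matrix(runif(n * d, lo, hi), n, d)
  vel <- matrix(runif(n * d, -vmax, vmax), n, d)
  ev <- eval_population(pos, objective, L)
  pbest_pos <- pos; pbest_fit <- ev$fit; pbest_X <- ev$X
  g <- which.max(pbest_fit)
  gbest_fit <- pbest_fit[g]; gbest_pos <- pbest_pos[g, ]; gbest_X <- pbest_X[g, ]

  trace <- numeric(config$max_iterations)
  stall <- 0L; iter <- 0L
  for (it in seq_len(config$max_iterations)) {
    iter <- it
    wi <- config$pso_inertia_start +
      (config$pso_inertia_end - config$pso_inertia_start) *
      (it - 1) / max(1, config$max_iterations - 1)
    r1 <- matrix(runif(n * d), n, d); r2 <- matrix(runif(n * d), n, d)
    vel <- wi * vel +
      config$pso_c1 * r1 * (pbest_pos - pos) +
      config$pso_c2 * r2 * sweep(-pos, 2L, -gbest_pos)
    vel <- pmin(pmax(vel, -vmax), vmax)
    pos <- pos + vel
    # reflect at bounds and damp the offending velocity component
    under <- pos < lo; over <- pos > hi
    pos[under] <- 2 * lo - pos[under]; pos[over] <- 2 * hi - pos[over]
    pos <- pmin(pmax(pos, lo), hi)   # guard against double reflection
    vel[under | over] <- -vel[under | over]

    ev <- eval_population(pos, objective, L)
    imp <- ev$fit > pbest_fit
    pbest_fit[imp] <- ev$fit[imp]
    pbest_pos[imp, ] <- pos[imp, ]
    pbest_X[imp, ] <- ev$X[imp, ]
    g <- which.max(pbest_fit)
    improved <- pbest_fit[g] > gbest_fit ||
      (pbest_fit[g] == gbest_fit && lex_less(pbest_X[g, ], gbest_X))
    if (pbest_fit[g] > gbest_fit) stall <- 0L else stall <- stall + 1L
    if (improved) {
      gbest_fit <- pbest_fit[g]; gbest_pos <- pbest_pos[g, ]
      gbest_X <- pbest_X[g, ]
    }
    trace[it] <- gbest_fit
    if (stall >= config$stagnation_patience) break
  }
  new_optimizer_result("PSO", gbest_X, gbest_fit, iter, trace[seq_len(iter)],
                       k, L, config$seed)
}

#' Differential evolution over threshold vectors
#'
#' DE/rand/1/bin on the same continuous search space, repair rule, bounds and
#' termination contract as [pso_optimize()]: mutation `a + F (b - c)` over
#' distinct random members, binomial crossover with rate `CR` (one guaranteed
#' mutant coordinate), greedy selection of the better of trial and target.
#'
#' @inheritParams pso_optimize
#' @return An `optimizer_result`.
#' @export
de_optimize <- function(objective, k, L, config = optimizer_config()) {
  n <- config$population; d <- 2L * k
  lo <- 1; hi <- L - 2
  Fm <- config$de_mutation_F; CR <- config$de_crossover_CR
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  pos <- matrix(runif(n * d, lo, hi), n, d)
  ev <- eval_population(pos, objective, L)
  fit <- ev$fit; Xint <- ev$X
  g <- which.max(fit)
  gbest_fit <- fit[g]; gbest_X <- Xint[g, ]

  trace <- numeric(config$max_iterations)
  stall <- 0L; iter <- 0L
  for (it in seq_len(config$max_iterations)) {
    iter <- it
    trial <- pos
    for (i in seq_len(n)) {
      idx <- if (n >= 4L) sample(seq_len(n)[-i], 3L) else
        sample(seq_len(n), 3L, replace = TRUE)
      mutant <- pos[idx[1L], ] + Fm * (pos[idx[2L], ] - pos[idx[3L], ])
      mutant <- pmin(pmax(mutant, lo), hi)
      jrand <- sample.int(d, 1L)
      cross <- runif(d) < CR
      if (CR > 0) cross[jrand] <- TRUE  # CR = 0 disables crossover entirely
      trial[i, cross] <- mutant[cross]
    }
    ev <- eval_population(trial, objective, L)
    take <- ev$fit > fit
    pos[take, ] <- trial[take, ]
    fit[take] <- ev$fit[take]
    Xint[take, ] <- ev$X[take, ]
    g <- which.max(fit)
    if (fit[g] > gbest_fit) {
      gbest_fit <- fit[g]; gbest_X <- Xint[g, ]
      stall <- 0L
    } else {
      if (fit[g] == gbest_fit && lex_less(Xint[g, ], gbest_X)) gbest_X <- Xint[g, ]
      stall <- stall + 1L
    }
    trace[it] <- gbest_fit
    if (stall >= config$stagnation_patience) break
  }
  new_optimizer_result("DE", gbest_X, gbest_fit, iter, trace[seq_len(iter)],
                       k, L, config$seed)
}

#' Exhaustive search over all admissible threshold vectors
#'
#' Enumerates every strictly increasing `k`-subset of `[1, L-2]` for rows and
#' columns and returns the true global maximum — the small-scale oracle
#' against which the metaheuristics are validated. Ties in fitness resolve to
#' the lexicographically smallest `(t | v)` vector.
#'
#' @inheritParams pso_optimize
#' @param cap Refuse instances with more than this many candidates.
#' @return An `optimizer_result` with a single-entry trace.
#' @export
exhaustive_search <- function(objective, k, L, cap = 1e7) {
  n_half <- choose(L - 2L, k)
  n_cand <- n_half^2
  abort_if(n_cand > cap,
           sprintf("exhaustive search refused: %.3g candidates exceed the cap of %.3g",
                   n_cand, cap))
  halves <- t(combn(seq_len(L - 2L), k))        # each row sorted ascending
  # all (row-half, col-half) pairs; col index varies fastest within a row
  # block so the enumeration order itself is lexicographic in (t | v)
  grid_t <- halves[rep(seq_len(n_half), each = n_half), , drop = FALSE]
  grid_v <- halves[rep(seq_len(n_half), times = n_half), , drop = FALSE]
  best_fit <- -Inf; best_row <- NULL
  chunk <- 200000L
  for (start in seq(1L, n_cand, by = chunk)) {
    sel <- start:min(n_cand, start + chunk - 1L)
    Xm <- cbind(grid_t[sel, , drop = FALSE], grid_v[sel, , drop = FALSE])
    f <- objective(Xm)
    j <- which.max(f)
    if (f[j] > best_fit) {       # first occurrence wins: lexicographic tie-break
      best_fit <- f[j]; best_row <- Xm[j, ]
    }
  }
  new_optimizer_result("exhaustive", best_row, best_fit, 1L, best_fit, k, L,
                       NA_integer_)
}

#' Build the vectorised entropy objective for a histogram
#'
#' Returns the fitness closure the optimizers consume: it accepts an
#' `n x 2k` matrix of repaired integer candidates and returns `n` fitness
#' values, each identical to [renyi_fitness()] on the corresponding
#' [threshold_vector()].
#'
#' @param H A `joint_histogram`.
#' @param k Number of thresholds per axis.
#' @param params An [entropy_params()].
#' @return A function `(matrix) -> numeric`.
#' @export
fitness_objective <- function(H, k, params = entropy_params()) {
  make_fitness_closure(H, k, params)
}

#' Export a convergence trace as CSV
#' @param result An `optimizer_result`.
#' @param path Output CSV path (columns `iteration`, `best_fitness`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
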