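test_that("diagonal partition tiles both axes exactly", {
  rects <- partition_diagonal(256L, threshold_vector(100, 120, 256L))
  expect_equal(rects$r_lo, c(0L, 101L))
  expect_equal(rects$r_hi, c(100L, 255L))
  expect_equal(rects$c_lo, c(0L, 121L))
  expect_equal(rects$c_hi, c(120L, 255L))

  # smallest admissible case: L = 4, k = 2
  r4 <- partition_diagonal(4L, threshold_vector(c(1, 2), c(1, 2), 4L))
  expect_equal(r4$r_lo, c(0L, 2L, 3L))
  expect_equal(r4$r_hi, c(1L, 2L, 3L))

  # tiling property across random thresholds
  set.seed(21)
  for (i in 1:20) {
    L <- sample(c(8L, 16L, 64L), 1)
    k <- sample(1:3, 1)
    t <- sort(sample(1:(L - 2L), k)); v <- sort(sample(1:(L - 2L), k))
    rr <- partition_diagonal(L, threshold_vector(t, v, L))
    covered_rows <- unlist(Map(seq, rr$r_lo, rr$r_hi))
    covered_cols <- unlist(Map(seq, rr$c_lo, rr$c_hi))
    expect_identical(sort(covered_rows), 0:(L - 1L))
    expect_identical(sort(covered_cols), 0:(L - 1L))
  }

  expect_error(threshold_vector(c(2, 2), c(1, 3), 16L), "strictly increasing")
  expect_error(threshold_vector(0, 5, 16L), "strictly increasing")
  expect_error(threshold_vector(15, 5, 16L), "strictly increasing")
})

test_that("classical Renyi entropy matches analytic and brute-force values", {
  # uniform histogram, single full rectangle: 2 ln L for every alpha
  full <- function(L) tibble::tibble(i = 1L, r_lo = 0L, r_hi = L - 1L,
                                     c_lo = 0L, c_hi = L - 1L)
  for (L in c(4L, 16L)) for (a in c(0.01, 0.5, 2, 10)) {
    v <- classical_renyi(make_uniform_histogram(L), full(L),
                         entropy_params(alpha = a, mode = "classical"))$total
    expect_lt(abs(v - 2 * log(L)), 1e-9)
  }

  # single occupied cell with w = 1: entropy 0
  H1 <- make_random_histogram(8L, 1L, seed = 2)
  v1 <- classical_renyi(H1, full(8L),
                        entropy_params(alpha = 0.5, mode = "classical",
                                       empty_cell_policy = "occupied_only"))$total
  expect_equal(v1, 0)

  # brute-force agreement on random histograms and partitions
  set.seed(31)
  for (i in 1:10) {
    H <- make_random_histogram(16L, sample(20:200, 1), seed = i)
    t <- sort(sample(1:14, 2)); v <- sort(sample(1:14, 2))
    rects <- partition_diagonal(16L, threshold_vector(t, v, 16L))
    for (a in c(0.01, 2)) {
      got <- classical_renyi(H, rects,
                             entropy_params(alpha = a, mode = "classical"))
      want <- vapply(1:3, function(j)
        oracle_cr_rect(H$weights, rects$r_lo[j], rects$r_hi[j],
                       rects$c_lo[j], rects$c_hi[j], a), numeric(1))
      expect_equal(got$per_rectangle, want, tolerance = 1e-12)
      expect_equal(got$total, sum(want), tolerance = 1e-12)
    }
  }
})

test_that("classical Renyi entropy approaches Shannon entropy as alpha -> 1", {
  for (seed in 1:100) {
    H <- make_random_histogram(16L, sample(10:256, 1), seed = seed)
    full <- tibble::tibble(i = 1L, r_lo = 0L, r_hi = 15L, c_lo = 0L, c_hi = 15L)
    w <- H$weights[H$weights > 0]
    shannon <- -sum(w * log(w))
    for (a in c(1 - 1e-3, 1 + 1e-3)) {
      cr <- classical_renyi(H, full,
                            entropy_params(alpha = a, mode = "classical"))$total
      expect_lt(abs(cr - shannon), 1e-3 * max(1, shannon))
    }
  }
})

test_that("quantum subsystems encode FRQI amplitude sums and rank-one rho", {
  # all-zero-weight rectangle of A cells under all_cells: C = A, S = 0
  H <- make_random_histogram(16L, 1L, seed = 7)   # mass in one cell somewhere
  occ <- which(H$counts > 0, arr.ind = TRUE)
  # choose a rectangle avoiding the occupied cell
  rect <- list(r_lo = if (occ[1] > 8) 0L else 8L,
               r_hi = if (occ[1] > 8) 7L else 15L,
               c_lo = 0L, c_hi = 15L)
  qs <- quantum_subsystem(H, rect, entropy_params(mode = "quantum"))
  A <- (rect$r_hi - rect$r_lo + 1L) * 16L
  expect_equal(qs$C, A)
  expect_equal(qs$S, 0)
  expect_equal(sum(diag(qs$rho)), A^2, tolerance = 1e-12)

  # single cell with w = 1: theta = pi/2, C = 0, S = 1, rho = diag(0, 1)
  H1 <- joint_histogram(matrix(5L, 1, 1), L = 1L)
  qs1 <- quantum_subsystem(H1, list(r_lo = 0L, r_hi = 0L, c_lo = 0L, c_hi = 0L),
                           entropy_params(mode = "quantum"))
  expect_equal(qs1$C, cos(pi / 2))
  expect_equal(qs1$S, 1)
  expect_equal(qs1$rho, matrix(c(0, 0, 0, 1), 2, 2), tolerance = 1e-15)

  # rho is rank one: nonzero eigenvalue C^2 + S^2, the other 0
  for (seed in 1:10) {
    Hr <- make_random_histogram(16L, 80L, seed = seed)
    qs <- quantum_subsystem(Hr, list(r_lo = 2L, r_hi = 9L, c_lo = 1L, c_hi = 12L),
                            entropy_params(mode = "quantum"))
    ev <- sort(eigen(qs$rho, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(ev[1], qs$C^2 + qs$S^2, tolerance = 1e-9)
    expect_lt(abs(ev[2]), 1e-9 * max(1, ev[1]))
  }
})

test_that("quantum Renyi entropy equals its rank-one closed form", {
  for (seed in 1:25) {
    H <- make_random_histogram(16L, sample(5:256, 1), seed = seed)
    t <- sort(sample(1:14, 2)); v <- sort(sample(1:14, 2))
    rects <- partition_diagonal(16L, threshold_vector(t, v, 16L))
    for (a in c(0.01, 0.5, 2)) {
      p <- entropy_params(alpha = a, mode = "quantum")
      got <- quantum_renyi(H, rects, p)$per_rectangle
      want <- vapply(1:3, function(j)
        oracle_qr_rect(H$weights, rects$r_lo[j], rects$r_hi[j],
                       rects$c_lo[j], rects$c_hi[j], a), numeric(1))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }

  # unit-trace normalisation collapses every pure subsystem to zero entropy
  H <- make_random_histogram(16L, 50L, seed = 3)
  rects <- partition_diagonal(16L, threshold_vector(7, 7, 16L))
  p_unit <- entropy_params(alpha = 0.5, mode = "quantum",
                           rho_normalization = "unit_trace")
  expect_equal(quantum_renyi(H, rects, p_unit)$per_rectangle, c(0, 0),
               tolerance = 1e-12)

  # 1x1 grid with w = 1: s = 1, entropy 0 under the literal form
  H1 <- joint_histogram(matrix(4L, 1, 1), L = 1L)
  r1 <- tibble::tibble(i = 1L, r_lo = 0L, r_hi = 0L, c_lo = 0L, c_hi = 0L)
  expect_equal(quantum_renyi(H1, r1,
                             entropy_params(alpha = 0.5, mode = "quantum"))$total,
               0, tolerance = 1e-12)
})

test_that("entropy parameters reject invalid alpha", {
  expect_error(entropy_params(alpha = 1), "alpha")
  expect_error(entropy_params(alpha = 0), "alpha")
  expect_error(entropy_params(alpha = -2), "alpha")
})

test_that("fitness dispatches, penalises degenerate candidates, and matches the oracle", {
  H <- make_random_histogram(16L, 90L, seed = 13)
  for (mode in c("classical", "quantum")) {
    p <- entropy_params(alpha = 0.01, mode = mode)
    for (seed in 1:10) {
      set.seed(seed)
      t <- sort(sample(1:14, 2)); v <- sort(sample(1:14, 2))
      X <- threshold_vector(t, v, 16L)
      expect_equal(renyi_fitness(H, X, p),
                   oracle_fitness(H, t, v, 0.01, mode), tolerance = 1e-10)
    }
  }

  # occupied_only: an all-empty rectangle fires the penalty
  Hs <- make_random_histogram(16L, 2L, seed = 1)   # sparse: empty rects easy
  p_occ <- entropy_params(mode = "quantum", empty_cell_policy = "occupied_only")
  fits <- sapply(1:14, function(t1)
    renyi_fitness(Hs, threshold_vector(t1, t1, 16L), p_occ))
  expect_true(any(fits == PENALTY_SENTINEL))
  expect_true(all(fits[fits != PENALTY_SENTINEL] > PENALTY_SENTINEL))

  # rectangle-order invariance: fitness equals the sum over shuffled rects
  rects <- partition_diagonal(16L, threshold_vector(c(4, 9), c(5, 10), 16L))
  p <- entropy_params(alpha = 0.5, mode = "classical")
  a <- classical_renyi(H, rects, p)$total
  b <- classical_renyi(H, rects[c(3, 1, 2), ], p)$total
  expect_identical(a, b)
})

test_that("vectorised objective agrees with the direct fitness on every policy", {
  H <- make_random_histogram(32L, 300L, seed = 8)
  combos <- expand.grid(mode = c("classical", "quantum"),
                        policy = c("all_cells", "occupied_only"),
                        norm = c("literal", "unit_trace"),
                        stringsAsFactors = FALSE)
  set.seed(99)
  Xm <- t(replicate(25, c(sort(sample(1:30, 2)), sort(sample(1:30, 2)))))
  for (i in seq_len(nrow(combos))) {
    p <- entropy_params(alpha = 0.01, mode = combos$mode[i],
                        empty_cell_policy = combos$policy[i],
                        rho_normalization = combos$norm[i])
    f <- fitness_objective(H, 2L, p)
    direct <- vapply(seq_len(nrow(Xm)), function(j)
      renyi_fitness(H, threshold_vector(Xm[j, 1:2], Xm[j, 3:4], 32L), p),
      numeric(1))
    expect_equal(f(Xm), direct, tolerance = 1e-9,
                 label = paste(combos[i, ], collapse = "/"))
  }
})
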