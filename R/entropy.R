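#' Threshold vector for diagonal-rectangle partitioning
#'
#' `k` row thresholds `t1 < ... < tk` acting on histogram rows (intensity)
#' and `k` column thresholds `v1 < ... < vk` acting on columns (local mean).
#' Thresholds live in `[1, L-2]` so no class interval is degenerate.
#'
#' @param t Integer vector of row thresholds, strictly increasing.
#' @param v Integer vector of column thresholds, strictly increasing.
#' @param L Number of gray levels.
#' @return A `threshold_vector` list with `t`, `v`, `k`, `L`.
#' @export
threshold_vector <- function(t, v, L = 256L) {
  t <- as.integer(t); v <- as.integer(v); L <- as.integer(L)
  abort_if(length(t) != length(v), "t and v must have equal length k")
  abort_if(length(t) == 0L, "at least one threshold is required")
  ok <- function(z) all(z >= 1L & z <= L - 2L) && !is.unsorted(z, strictly = TRUE)
  abort_if(!ok(t) || !ok(v),
           sprintf("thresholds must be strictly increasing within [1, %d]", L - 2L))
  structure(list(t = t, v = v, k = length(t), L = L),
            class = "threshold_vector")
}

#' @export
print.threshold_vector <- function(x, ...) {
  cat(sprintf("<threshold_vector> k = %d, t = (%s | v = %s), L = %d\n",
              x$k, paste(x$t, collapse = ", "),
              paste(x$v, collapse = ", "), x$L))
  invisible(x)
}

#' Entropy objective parameters
#'
#' @param alpha Renyi order, positive and not 1. Default 0.01, the setting
#'   used throughout the reference experiments.
#' @param mode `"classical"` (cell-weight Renyi entropy) or `"quantum"`
#'   (density-operator Renyi entropy).
#' @param empty_cell_policy `"all_cells"` sums over every grid cell of a
#'   rectangle, zero-weight cells included (each contributes cos 0 = 1 to the
#'   quantum amplitude); `"occupied_only"` restricts to cells with positive
#'   counts.
#' @param rho_normalization `"literal"` uses the rank-one density operator
#'   exactly as assembled from the amplitude sums (trace C^2 + S^2, generally
#'   not 1); `"unit_trace"` rescales it to trace one, which collapses the
#'   quantum entropy of any pure subsystem to 0 and exists for study only.
#' @return An `entropy_params` list.
#' @export
entropy_params <- function(alpha = 0.01,
                           mode = c("classical", "quantum"),
                           empty_cell_policy = c("all_cells", "occupied_only"),
                           rho_normalization = c("literal", "unit_trace")) {
  abort_if(!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha == 1,
           "alpha must be a positive real different from 1")
  structure(list(alpha = alpha,
                 mode = match.arg(mode),
                 empty_cell_policy = match.arg(empty_cell_policy),
                 rho_normalization = match.arg(rho_normalization)),
            class = "entropy_params")
}

#' Penalty assigned to degenerate threshold candidates
#'
#' A finite large negative sentinel returned by [renyi_fitness()] whenever a
#' rectangle carries no entropy mass, so maximizers reject the candidate
#' without tripping over infinities.
#' @export
PENALTY_SENTINEL <- -1e12

#' Partition the histogram diagonal into rectangles
#'
#' Splits `[0, L-1]^2` along the main diagonal: rectangle 1 is
#' `[0, t1] x [0, v1]`, rectangle i is `[t(i-1)+1, ti] x [v(i-1)+1, vi]`, and
#' rectangle k+1 runs to `L-1` on both axes. Row ranges tile `[0, L-1]`
#' exactly and likewise column ranges; off-diagonal mass is not represented
#' (and never scored).
#'
#' @param L Number of gray levels.
#' @param X A `threshold_vector`.
#' @return A tibble with one row per rectangle: `i`, `r_lo`, `r_hi`,
#'   `c_lo`, `c_hi` (inclusive 0-based gray-level bounds).
#' @export
partition_diagonal <- function(L, X) {
  stopifnot(inherits(X, "threshold_vector"))
  abort_if(X$L != L, "threshold vector was built for a different L")
  r_hi <- c(X$t, L - 1L)
  c_hi <- c(X$v, L - 1L)
  tibble::tibble(
    i = seq_len(X$k + 1L),
    r_lo = c(0L, X$t + 1L), r_hi = r_hi,
    c_lo = c(0L, X$v + 1L), c_hi = c_hi
  )
}

# sum of FUN(weights) over one rectangle, honouring the empty-cell policy
rect_cells <- function(H, r_lo, r_hi, c_lo, c_hi, policy) {
  w <- H$weights[(r_lo + 1L):(r_hi + 1L), (c_lo + 1L):(c_hi + 1L), drop = FALSE]
  if (policy == "occupied_only") w <- w[w > 0] # drop zero-count cells
  w
}

#' Classical Renyi entropy of a diagonal partition
#'
#' Per rectangle, `CR_a = (1 / (1 - a)) * ln(sum of w(x, y)^a)` over the
#' rectangle's cells, using the globally normalised weights; the total is the
#' sum over rectangles. A rectangle with zero weight-power sum has no defined
#' entropy: the per-rectangle value is `-Inf` and callers such as
#' [renyi_fitness()] convert that into the penalty sentinel.
#'
#' @param H A `joint_histogram`.
#' @param rects Rectangle tibble from [partition_diagonal()].
#' @param params An `entropy_params` with `mode = "classical"`.
#' @return List with `per_rectangle` (numeric vector) and `total`.
#' @export
classical_renyi <- function(H, rects, params = entropy_params(mode = "classical")) {
  abort_if(params$mode != "classical", "params$mode must be 'classical'")
  a <- params$alpha
  per <- vapply(seq_len(nrow(rects)), function(j) {
    w <- rect_cells(H, rects$r_lo[j], rects$r_hi[j],
                    rects$c_lo[j], rects$c_hi[j], params$empty_cell_policy)
    s <- sum(w^a)                      # 0^a = 0 for a > 0: zero cells drop out
    if (s <= 0) -Inf else log(s) / (1 - a)
  }, numeric(1))
  list(per_rectangle = per, total = sum(per))
}

#' Quantum subsystem of one diagonal rectangle
#'
#' FRQI-style encoding: each histogram cell carries an angle
#' `theta = (pi / 2) * w(x, y)`; the subsystem amplitude sums are
#' `C = sum(cos theta)` and `S = sum(sin theta)` over the rectangle's cells,
#' and the (unnormalised, rank-one) density operator is the outer product of
#' `(C, S)` with itself, with trace `C^2 + S^2`.
#'
#' @param H A `joint_histogram`.
#' @param rect One-row slice of the [partition_diagonal()] tibble (or any
#'   list with `r_lo`, `r_hi`, `c_lo`, `c_hi`).
#' @param params An `entropy_params`.
#' @return List with `C`, `S`, and the 2x2 matrix `rho`.
#' @export
quantum_subsystem <- function(H, rect, params = entropy_params(mode = "quantum")) {
  w <- rect_cells(H, rect$r_lo, rect$r_hi, rect$c_lo, rect$c_hi,
                  params$empty_cell_policy)
  theta <- (pi / 2) * w
  C <- sum(cos(theta)); S <- sum(sin(theta))
  rho <- outer(c(C, S), c(C, S))
  if (params$rho_normalization == "unit_trace") {
    tr <- C^2 + S^2
    if (tr > 0) rho <- rho / tr
  }
  list(C = C, S = S, rho = rho)
}

# trace(rho^a) through the spectral decomposition of the symmetric 2x2 rho,
# with the 0^a = 0 convention; tiny negative eigenvalues from floating-point
# cancellation are clamped to zero.
trace_power <- function(rho, a) {
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < .Machine$double.eps * max(abs(ev), 1)] <- 0
  sum(ev[ev > 0]^a)
}

#' Quantum Renyi entropy of a diagonal partition
#'
#' Per rectangle, `QR_a = (1 / (1 - a)) * ln(trace(rho^a))` with `rho` from
#' [quantum_subsystem()]; the trace power is evaluated through the spectral
#' decomposition of the 2x2 operator (rank one, so the nonzero eigenvalue is
#' `C^2 + S^2` under the literal normalisation). Totals sum over rectangles.
#' An empty subsystem (`C^2 + S^2 = 0`) yields `-Inf`, converted to the
#' penalty sentinel by [renyi_fitness()].
#'
#' @inheritParams classical_renyi
#' @return List with `per_rectangle` and `total`.
#' @export
quantum_renyi <- function(H, rects, params = entropy_params(mode = "quantum")) {
  abort_if(params$mode != "quantum", "params$mode must be 'quantum'")
  a <- params$alpha
  per <- vapply(seq_len(nrow(rects)), function(j) {
    qs <- quantum_subsystem(H, rects[j, ], params)
    tp <- trace_power(qs$rho, a)
    if (tp <= 0) -Inf else log(tp) / (1 - a)
  }, numeric(1))
  list(per_rectangle = per, total = sum(per))
}

#' Entropy fitness of a threshold candidate
#'
#' Partitions the histogram with [partition_diagonal()] and scores it with
#' the classical or quantum Renyi entropy according to `params$mode`.
#' Candidates producing any rectangle without entropy mass return the finite
#' penalty sentinel `-1e12` so population maximizers discard them safely.
#'
#' @param H A `joint_histogram`.
#' @param X A `threshold_vector`.
#' @param params An `entropy_params`.
#' @return A single finite numeric fitness value.
#' @export
renyi_fitness <- function(H, X, params = entropy_params()) {
  rects <- partition_diagonal(H$L, X)
  res <- if (params$mode == "quantum") quantum_renyi(H, rects, params)
         else classical_renyi(H, rects, params)
  if (!is.finite(res$total)) PENALTY_SENTINEL else res$total
}

# Vectorised fitness closure used by the optimizers and exhaustive search.
#
# Precomputes 2D prefix sums of w^alpha (classical) or of cos/sin of the cell
# angles (quantum), so one candidate costs k+1 O(1) rectangle lookups. Takes
# an n x 2k matrix of repaired integer candidates (t | v rows) and returns n
# fitness values identical to renyi_fitness() on each row.
make_fitness_closure <- function(H, k, params = entropy_params()) {
  L <- H$L
  a <- params$alpha
  occupied <- params$empty_cell_policy == "occupied_only"
  psum <- function(m) {         # padded prefix-sum table, (L+1) x (L+1)
    p <- matrix(0, L + 1L, L + 1L)
    p[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
    p
  }
  if (params$mode == "classical") {
    Pw <- psum(H$weights^a)     # 0^a = 0 handles empty cells for both policies
    tabs <- list(Pw)
  } else {
    theta <- (pi / 2) * H$weights
    cosm <- cos(theta); sinm <- sin(theta)
    if (occupied) {             # zero-weight cells contribute nothing
      mask <- H$counts > 0L
      cosm <- cosm * mask; sinm <- sinm * mask
    }
    tabs <- list(psum(cosm), psum(sinm))
  }
  rect_sum <- function(p, rlo, rhi, clo, chi) {
    # inclusive 0-based bounds -> padded 1-based prefix table
    p[cbind(rhi + 2L, chi + 2L)] - p[cbind(rlo + 1L, chi + 2L)] -
      p[cbind(rhi + 2L, clo + 1L)] + p[cbind(rlo + 1L, clo + 1L)]
  }
  unit_trace <- params$rho_normalization == "unit_trace"
  function(Xm) {
    if (is.null(dim(Xm))) Xm <- matrix(Xm, nrow = 1L)
    n <- nrow(Xm)
    t_lo <- cbind(0L, Xm[, seq_len(k), drop = FALSE] + 1L)
    t_hi <- cbind(Xm[, seq_len(k), drop = FALSE], L - 1L)
    v_lo <- cbind(0L, Xm[, k + seq_len(k), drop = FALSE] + 1L)
    v_hi <- cbind(Xm[, k + seq_len(k), drop = FALSE], L - 1L)
    total <- numeric(n)
    bad <- logical(n)
    for (i in seq_len(k + 1L)) {
      if (params$mode == "classical") {
        s <- rect_sum(tabs[[1L]], t_lo[, i], t_hi[, i], v_lo[, i], v_hi[, i])
        # prefix-sum cancellation can leave tiny negatives on empty rectangles
        s[s < 0] <- 0
      } else {
        C <- rect_sum(tabs[[1L]], t_lo[, i], t_hi[, i], v_lo[, i], v_hi[, i])
        S <- rect_sum(tabs[[2L]], t_lo[, i], t_hi[, i], v_lo[, i], v_hi[, i])
        tr <- C^2 + S^2
        s <- numeric(n)
        s[tr > 0] <- if (unit_trace) 1 else tr[tr > 0]^a
      }
      pos <- s > 0
      bad <- bad | !pos
      total[pos] <- total[pos] + log(s[pos])
    }
    ifelse(bad, PENALTY_SENTINEL, total / (1 - a))
  }
}
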