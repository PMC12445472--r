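# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's fast paths (prefix sums, closures) and recompute
# everything cell by cell.

# local mean by explicit window scan
oracle_local_mean <- function(px, L = 256L) {
  M <- nrow(px); N <- ncol(px)
  out <- matrix(0L, M, N)
  for (m in seq_len(M)) for (n in seq_len(N)) {
    rs <- max(1, m - 1):min(M, m + 1)
    cs <- max(1, n - 1):min(N, n + 1)
    out[m, n] <- floor(mean(px[rs, cs]) + 0.5)
  }
  out
}

# classical Renyi entropy of one rectangle by direct summation
oracle_cr_rect <- function(w, rlo, rhi, clo, chi, alpha) {
  s <- 0
  for (x in rlo:rhi) for (y in clo:chi) {
    wx <- w[x + 1L, y + 1L]
    if (wx > 0) s <- s + wx^alpha
  }
  if (s <= 0) -Inf else log(s) / (1 - alpha)
}

# quantum Renyi closed form: rank-one rho has eigenvalues {C^2 + S^2, 0}
oracle_qr_rect <- function(w, rlo, rhi, clo, chi, alpha,
                           occupied_only = FALSE, counts = NULL) {
  C <- 0; S <- 0
  for (x in rlo:rhi) for (y in clo:chi) {
    if (occupied_only && counts[x + 1L, y + 1L] == 0L) next
    th <- (pi / 2) * w[x + 1L, y + 1L]
    C <- C + cos(th); S <- S + sin(th)
  }
  s <- C^2 + S^2
  if (s <= 0) -Inf else (alpha / (1 - alpha)) * log(s)
}

# full-fitness oracle: partition + per-rectangle sums, penalty on emptiness
oracle_fitness <- function(H, tvec, vvec, alpha, mode,
                           occupied_only = FALSE) {
  L <- H$L
  rlo <- c(0L, tvec + 1L); rhi <- c(tvec, L - 1L)
  clo <- c(0L, vvec + 1L); chi <- c(vvec, L - 1L)
  per <- vapply(seq_along(rlo), function(i) {
    if (mode == "classical") {
      oracle_cr_rect(H$weights, rlo[i], rhi[i], clo[i], chi[i], alpha)
    } else {
      oracle_qr_rect(H$weights, rlo[i], rhi[i], clo[i], chi[i], alpha,
                     occupied_only, H$counts)
    }
  }, numeric(1))
  if (any(!is.finite(per))) -1e12 else sum(per)
}

# exact two-sided Wilcoxon p by enumerating all 2^n sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  min(1, 2 * mean(w_plus <= w_obs))
}

random_gray_image <- function(M, N, L = 256L, seed = 1L) {
  set.seed(seed)
  gray_image(matrix(sample(0:(L - 1L), M * N, replace = TRUE), M, N), L = L)
}
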