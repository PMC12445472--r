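#' Nine-metric segmentation quality report
#'
#' Compares a processed image against a reference and returns one row of
#' nine complementary quality metrics:
#'
#' * `psnr` — peak signal-to-noise ratio, `10 log10((L-1)^2 / MSE)` dB,
#'   capped at 100 dB when MSE = 0.
#' * `ssim` — mean structural similarity over 8x8 sliding windows with the
#'   standard stabilisation constants `(0.01 (L-1))^2`, `(0.03 (L-1))^2`.
#' * `ambe` — absolute mean brightness error `|mean(ref) - mean(proc)|`
#'   (the one metric where lower is better).
#' * `cii` — contrast improvement index: ratio of mean 3x3 local contrast
#'   `(max - min) / (max + min + eps)` of processed to reference.
#' * `sd` — population standard deviation of the processed image.
#' * `edge_density` — fraction of pixels whose Sobel gradient magnitude
#'   exceeds Otsu's threshold of the magnitude image.
#' * `rec` — relative entropy change: `|H(proc) - H(ref)| / max(H(ref), eps)`
#'   on 1D Shannon intensity entropies.
#' * `sf` — spatial frequency, `sqrt(RF^2 + CF^2)` of the RMS first
#'   differences along rows and columns.
#' * `cir` — contrast improvement ratio between 3x3 local-contrast maps,
#'   `sum((c - c~)^2) / sum(c^2)` over windows where the reference contrast
#'   `c` is positive.
#'
#' @param reference A `gray_image`.
#' @param processed A `gray_image` of identical shape.
#' @return A one-row tibble with the nine metrics.
#' @examples
#' a <- gray_image(matrix(sample(0:255, 64, TRUE), 8, 8))
#' compute_metrics(a, a)
#' @export
compute_metrics <- function(reference, processed) {
  abort_if(!identical(dim(reference), dim(processed)),
           "reference and processed images must have identical shape")
  L <- levels_of(reference)
  ref <- as_pixel_matrix(reference) * 1.0
  prc <- as_pixel_matrix(processed) * 1.0
  eps <- 1e-9

  mse <- mean((ref - prc)^2)
  psnr <- if (mse == 0) 100 else 10 * log10((L - 1)^2 / mse)

  cref <- local_contrast_map(ref)
  cprc <- local_contrast_map(prc)
  pos <- cref > 0

  h_ref <- shannon_1d(ref, L)

  tibble::tibble(
    psnr = psnr,
    ssim = ssim_mean(ref, prc, L),
    ambe = abs(mean(ref) - mean(prc)),
    cii = (mean(cprc) + eps) / (mean(cref) + eps),
    sd = sqrt(mean((prc - mean(prc))^2)),
    edge_density = edge_density(prc),
    rec = abs(shannon_1d(prc, L) - h_ref) / max(h_ref, eps),
    sf = spatial_frequency(prc),
    cir = if (any(pos)) sum((cref[pos] - cprc[pos])^2) / sum(cref[pos]^2) else 0
  )
}

shannon_1d <- function(px, L) {
  p <- tabulate(px + 1L, nbins = L) / length(px)
  p <- p[p > 0]
  -sum(p * log(p))
}

spatial_frequency <- function(px) {
  M <- nrow(px); N <- ncol(px)
  rf2 <- if (N > 1) sum((px[, -1, drop = FALSE] - px[, -N, drop = FALSE])^2) / (M * N) else 0
  cf2 <- if (M > 1) sum((px[-1, , drop = FALSE] - px[-M, , drop = FALSE])^2) / (M * N) else 0
  sqrt(rf2 + cf2)
}

# in-bounds 3x3 window minima / maxima via shifted comparisons
local_window_extrema <- function(px, which = c("max", "min")) {
  which <- match.arg(which)
  M <- nrow(px); N <- ncol(px)
  acc <- px
  f <- if (which == "max") pmax else pmin
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(M, M + dr)
    cs <- max(1, 1 + dc):min(N, N + dc)
    acc[rs, cs] <- f(acc[rs, cs], px[rs - dr, cs - dc])
  }
  acc
}

local_contrast_map <- function(px, eps = 1e-9) {
  mx <- local_window_extrema(px, "max")
  mn <- local_window_extrema(px, "min")
  (mx - mn) / (mx + mn + eps)
}

# Sobel gradient magnitude (replicated borders), then Otsu threshold on a
# 256-bin magnitude histogram; edge density = fraction above threshold.
edge_density <- function(px) {
  M <- nrow(px); N <- ncol(px)
  pad <- px[c(1, seq_len(M), M), c(1, seq_len(N), N), drop = FALSE]
  sh <- function(dr, dc) pad[seq_len(M) + 1 + dr, seq_len(N) + 1 + dc, drop = FALSE]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  g <- sqrt(gx^2 + gy^2)
  if (max(g) == 0) return(0)
  thr <- otsu_threshold(g)
  mean(g > thr)
}

# Otsu's between-class-variance maximiser on a 256-bin histogram of a
# non-negative continuous map; returns a threshold on the map's scale.
otsu_threshold <- function(g, nbins = 256L) {
  lo <- min(g); hi <- max(g)
  if (hi <= lo) return(lo)
  bin <- pmin(floor((g - lo) / (hi - lo) * nbins), nbins - 1L)
  p <- tabulate(bin + 1L, nbins = nbins) / length(g)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 1L))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  kstar <- which.max(sigma_b) - 1L
  lo + (kstar + 0.5) / nbins * (hi - lo)
}

# mean SSIM over fully contained 8x8 sliding windows (whole image if smaller),
# computed with prefix sums of x, y, x^2, y^2, xy.
ssim_mean <- function(x, y, L, win = 8L) {
  C1 <- (0.01 * (L - 1))^2
  C2 <- (0.03 * (L - 1))^2
  M <- nrow(x); N <- ncol(x)
  w <- min(win, M, N)
  n <- w * w
  ps <- function(m) {
    p <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    p[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
    p
  }
  wsum <- function(p) {
    p[(w + 1L):(M + 1L), (w + 1L):(N + 1L), drop = FALSE] -
      p[1L:(M - w + 1L), (w + 1L):(N + 1L), drop = FALSE] -
      p[(w + 1L):(M + 1L), 1L:(N - w + 1L), drop = FALSE] +
      p[1L:(M - w + 1L), 1L:(N - w + 1L), drop = FALSE]
  }
  sx <- wsum(ps(x)); sy <- wsum(ps(y))
  sxx <- wsum(ps(x * x)); syy <- wsum(ps(y * y)); sxy <- wsum(ps(x * y))
  mx <- sx / n; my <- sy / n
  vx <- sxx / n - mx^2; vy <- syy / n - my^2
  cxy <- sxy / n - mx * my
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)   # guard fp cancellation
  ssim <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(ssim)
}

#' Serialize a metrics report to JSON
#' @param report One-row tibble from [compute_metrics()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
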