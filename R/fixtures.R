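#' Synthetic piecewise-constant image specification
#'
#' Describes a reproducible test image: horizontally banded constant-intensity
#' classes (spatially contiguous blocks, so 3x3 local means stay informative,
#' mimicking the spatial coherence of real photographs that 2D-histogram
#' methods exploit) plus additive rounded Gaussian noise clipped to the gray
#' range.
#'
#' @param size `c(M, N)` image dimensions.
#' @param class_means Strictly increasing gray levels, one per class, at
#'   least 2 levels apart.
#' @param class_fractions Positive class proportions summing to 1; equal by
#'   default.
#' @param noise_sigma Gaussian noise standard deviation in gray levels.
#' @param seed Integer RNG seed.
#' @param L Number of gray levels.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(size = c(128L, 128L), class_means = c(60L, 128L, 200L),
                         class_fractions = NULL, noise_sigma = 8,
                         seed = 1L, L = 256L) {
  class_means <- as.integer(class_means)
  abort_if(is.unsorted(class_means, strictly = TRUE),
           "class_means must be strictly increasing")
  abort_if(any(diff(class_means) < 2L),
           "class means must be at least 2 gray levels apart")
  abort_if(any(class_means < 0L) || any(class_means > L - 1L),
           "class means must lie in [0, L-1]")
  class_fractions <- class_fractions %||%
    rep(1 / length(class_means), length(class_means))
  abort_if(length(class_fractions) != length(class_means),
           "one fraction per class is required")
  abort_if(any(class_fractions <= 0) || abs(sum(class_fractions) - 1) > 1e-9,
           "fractions must be positive and sum to 1")
  abort_if(noise_sigma < 0, "noise_sigma must be non-negative")
  structure(list(size = as.integer(size), class_means = class_means,
                 class_fractions = class_fractions, noise_sigma = noise_sigma,
                 seed = as.integer(seed), L = as.integer(L)),
            class = "fixture_spec")
}

#' Generate a synthetic piecewise-constant image with ground truth
#'
#' Classes occupy contiguous horizontal row bands whose sizes respect the
#' class fractions to within one row; each pixel then receives rounded
#' `N(0, sigma^2)` noise clipped to `[0, L-1]`. The true class of every pixel
#' is returned as a label map, enabling threshold-recovery scoring.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `image` (a `gray_image`), `labels` (integer matrix of
#'   1-based true class indices), and `spec`.
#' @examples
#' fx <- make_piecewise_image(fixture_spec(size = c(32, 32), noise_sigma = 0))
#' @export
make_piecewise_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  M <- spec$size[1]; N <- spec$size[2]
  nc <- length(spec$class_means)
  # cumulative row boundaries: fractions respected to within one row
  bounds <- round(cumsum(spec$class_fractions) * M)
  bounds[nc] <- M
  row_class <- rep(seq_len(nc), times = diff(c(0L, bounds)))
  labels <- matrix(row_class, M, N)
  clean <- matrix(spec$class_means[row_class], M, N)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  noisy <- if (spec$noise_sigma > 0) {
    clean + round_half_up(matrix(rnorm(M * N, 0, spec$noise_sigma), M, N))
  } else clean
  noisy <- pmin(pmax(noisy, 0L), spec$L - 1L)
  list(image = gray_image(noisy, L = spec$L), labels = labels, spec = spec)
}

#' Uniform joint histogram
#'
#' One count in every cell, so every weight is `1 / L^2` — the analytic
#' fixture for which the single-rectangle classical Renyi entropy equals
#' `2 ln L` for every admissible order.
#'
#' @param L Number of gray levels (at least 2).
#' @return A `joint_histogram`.
#' @export
make_uniform_histogram <- function(L) {
  abort_if(L < 2L, "L must be at least 2")
  joint_histogram(matrix(1L, L, L), L = as.integer(L))
}

#' Random sparse joint histogram
#'
#' Uniformly chosen occupied cells with positive integer counts; the
#' property-test workhorse.
#'
#' @param L Number of gray levels.
#' @param occupied_cells Number of cells with positive counts, in `[1, L^2]`.
#' @param seed Integer RNG seed.
#' @param max_count Counts are drawn uniformly from `1:max_count`.
#' @return A `joint_histogram`.
#' @export
make_random_histogram <- function(L, occupied_cells, seed = 1L, max_count = 20L) {
  L <- as.integer(L)
  abort_if(occupied_cells < 1L || occupied_cells > L * L,
           "occupied_cells must lie in [1, L^2]")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  counts <- matrix(0L, L, L)
  cells <- sample.int(L * L, occupied_cells)
  counts[cells] <- sample.int(max_count, occupied_cells, replace = TRUE)
  joint_histogram(counts, L = L)
}

#' Write a fixture image, its label map and spec to disk
#'
#' @param fx Result of [make_piecewise_image()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the three files (`<name>.png`,
#'   `<name>_labels.csv`, `<name>_spec.json`).
#' @return The image path, invisibly.
#' @export
write_fixture <- function(fx, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  write_gray_image(fx$image, img_path)
  utils::write.table(fx$labels, file.path(dir, paste0(name, "_labels.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(fx$spec),
                       file.path(dir, paste0(name, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(img_path)
}
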