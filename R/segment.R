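#' Reconstruct a segmented image from row thresholds
#'
#' Class 1 collects pixels with `f <= t1`, class `i` those with
#' `t(i-1) < f <= ti`, and the last class runs to `L-1` — each threshold
#' belongs to the class below it, mirroring exactly how
#' [partition_diagonal()] assigns histogram rows to diagonal rectangles, so
#' the classes scored by the objective are the classes rendered in the
#' output. Every pixel lands in exactly one class; each class is replaced by
#' the rounded mean of its members; empty classes produce no output level.
#'
#' @param img A `gray_image`.
#' @param row_thresholds Strictly increasing integer thresholds in `[1, L-2]`.
#' @return A `segmented_image`: a `gray_image` with attributes
#'   `class_means` (integer vector, `NA` for empty classes) and
#'   `class_bounds` (the thresholds used).
#' @examples
#' img <- gray_image(matrix(c(40, 60, 150, 220), 2, 2))
#' seg <- apply_thresholds(img, 100)
#' @export
apply_thresholds <- function(img, row_thresholds) {
  L <- levels_of(img)
  tv <- as.integer(row_thresholds)
  abort_if(length(tv) == 0L, "at least one threshold is required")
  abort_if(any(tv < 1L | tv > L - 2L) || is.unsorted(tv, strictly = TRUE),
           sprintf("thresholds must be strictly increasing within [1, %d]", L - 2L))
  px <- as_pixel_matrix(img)
  # class index per pixel: 1 + number of thresholds strictly below f
  cls <- findInterval(px, tv + 0.5) + 1L     # class i = [t(i-1)+1, ti]
  means <- rep(NA_integer_, length(tv) + 1L)
  out <- px
  for (i in seq_along(means)) {
    sel <- cls == i
    if (any(sel)) {
      means[i] <- as.integer(round_half_up(mean(px[sel])))
      out[sel] <- means[i]
    }
  }
  structure(gray_image(out, L = L),
            class_means = means, class_bounds = tv,
            class = c("segmented_image", "gray_image", "matrix", "array"))
}

#' @export
print.segmented_image <- function(x, ...) {
  m <- attr(x, "class_means")
  cat(sprintf("<segmented_image> %d x %d, %d classes (means: %s), thresholds (%s)\n",
              nrow(x), ncol(x), sum(!is.na(m)),
              paste(m[!is.na(m)], collapse = ", "),
              paste(attr(x, "class_bounds"), collapse = ", ")))
  invisible(x)
}

#' Contrast enhancement hook
#'
#' Optional pre-segmentation enhancement. `"identity"` passes the image
#' through unchanged; `"global_equalization"` applies histogram equalization
#' via the cumulative distribution (single-level images are returned
#' unchanged, the map being undefined there); `"clahe"` applies contrast-
#' limited adaptive histogram equalization via EBImage.
#'
#' @param img A `gray_image`.
#' @param strategy One of `"identity"`, `"global_equalization"`, `"clahe"`.
#' @return An enhanced `gray_image`, same shape and `L`.
#' @export
enhance_contrast <- function(img,
                             strategy = c("identity", "global_equalization",
                                          "clahe")) {
  strategy <- match.arg(strategy)
  L <- levels_of(img)
  px <- as_pixel_matrix(img)
  out <- switch(strategy,
    identity = px,
    global_equalization = {
      h <- tabulate(px + 1L, nbins = L)
      cdf <- cumsum(h)
      cdf_min <- min(cdf[cdf > 0])
      if (cdf_min == length(px)) px   # single gray level: map is 0/0
      else {
        lut <- round_half_up((cdf - cdf_min) / (length(px) - cdf_min) * (L - 1L))
        matrix(lut[px + 1L], nrow(px), ncol(px))
      }
    },
    clahe = {
      abort_if(!requireNamespace("EBImage", quietly = TRUE),
               "the 'clahe' strategy requires the EBImage package")
      # EBImage works on [0,1] intensities with x as (width, height)
      e <- EBImage::clahe(t(px) / (L - 1L), nx = 8, ny = 8)
      t(round_half_up(pmin(pmax(e, 0), 1) * (L - 1L)))
    }
  )
  gray_image(out, L = L)
}

#' End-to-end multilevel segmentation
#'
#' The full pipeline: optional contrast enhancement, 3x3 local-mean image,
#' joint 2D histogram, entropy-fitness maximization over the `2k` threshold
#' coordinates, and class-mean reconstruction using the optimal row
#' thresholds. Column thresholds shape the fitness only — an asymmetry
#' inherent to the diagonal-rectangle objective, preserved deliberately.
#'
#' @param img A `gray_image`.
#' @param k Number of thresholds.
#' @param params An [entropy_params()]; its `mode` selects the classical or
#'   quantum objective.
#' @param config An [optimizer_config()].
#' @param method `"pso"`, `"de"`, or `"exhaustive"`.
#' @param enhance Enhancement strategy passed to [enhance_contrast()].
#' @return A `segmentation` list: `segmented` (the `segmented_image`),
#'   `optimizer` (the `optimizer_result`), `enhanced` (the image actually
#'   segmented), and `meta` (stage timings, method, parameters).
#' @examples
#' img <- gray_image(matrix(rep(c(50, 200), each = 32), 8, 8))
#' res <- segment_image(img, k = 1, method = "exhaustive",
#'                      params = entropy_params(mode = "classical"))
#' @export
segment_image <- function(img, k,
                          params = entropy_params(),
                          config = optimizer_config(),
                          method = c("pso", "de", "exhaustive"),
                          enhance = "identity") {
  method <- match.arg(method)
  L <- levels_of(img)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  work <- enhance_contrast(img, enhance)
  timings["enhance"] <- tic() - t0

  t0 <- tic()
  means <- local_mean_image(work)
  H <- build_joint_histogram(work, means)
  timings["histogram"] <- tic() - t0

  t0 <- tic()
  objective <- fitness_objective(H, k, params)
  opt <- switch(method,
    pso = pso_optimize(objective, k, L, config),
    de = de_optimize(objective, k, L, config),
    exhaustive = exhaustive_search(objective, k, L)
  )
  timings["optimize"] <- tic() - t0

  t0 <- tic()
  seg <- apply_thresholds(work, opt$best_X$t)
  timings["segment"] <- tic() - t0

  structure(list(
    segmented = seg,
    optimizer = opt,
    enhanced = work,
    meta = list(method = method, entropy_mode = params$mode,
                alpha = params$alpha, k = k, enhance = enhance,
                seed = config$seed, timings = timings)
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s-%s, k = %d, alpha = %g, enhance = %s\n",
              toupper(x$meta$method),
              if (x$meta$entropy_mode == "quantum") "QR" else "CR",
              x$meta$k, x$meta$alpha, x$meta$enhance))
  print(x$optimizer)
  invisible(x)
}

#' @rdname segmentation_methods
#' @param x,object A `segmentation`.
#' @param ... Unused.
#' @export
glance.segmentation <- function(x, ...) {
  dplyr::mutate(glance(x$optimizer),
                entropy_mode = x$meta$entropy_mode,
                alpha = x$meta$alpha, enhance = x$meta$enhance,
                n_levels = length(unique(as.vector(x$segmented))))
}

#' Accessors and plots for segmentation results
#'
#' `glance()` summarises the run in one row; `autoplot()` shows the
#' segmented image as a gray raster.
#'
#' @name segmentation_methods
#' @export
autoplot.segmentation <- function(object, ...) {
  px <- as_pixel_matrix(object$segmented)
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- px[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, levels_of(object$segmented) - 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "level", x = NULL, y = NULL) +
    ggplot2::theme_void()
}
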