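#' Rank competing methods on one metric
#'
#' Rank 1 is best. Direction follows the metric (AMBE is lower-is-better,
#' the other eight higher-is-better): ranks order methods by mean metric
#' value; methods tied on the mean are ordered by lower variance; any
#' remaining ties break by method-name order for determinism.
#'
#' @param values Named list, one numeric vector of per-image metric values
#'   per method; equal lengths.
#' @param higher_is_better `TRUE` for every metric except AMBE.
#' @return A tibble with `method`, `mean`, `variance`, `rank`.
#' @export
rank_methods <- function(values, higher_is_better = TRUE) {
  abort_if(length(values) == 0L || any(lengths(values) == 0L),
           "every method needs at least one metric value")
  abort_if(length(unique(lengths(values))) != 1L,
           "per-method value lists must have equal length")
  means <- vapply(values, mean, numeric(1))
  vars <- vapply(values, function(v) if (length(v) > 1L) var(v) else 0, numeric(1))
  key_mean <- if (higher_is_better) -means else means
  ord <- order(key_mean, vars, names(values))  # best first
  rk <- integer(length(values))
  rk[ord] <- seq_along(values)
  tibble::tibble(method = names(values), mean = unname(means),
                 variance = unname(vars), rank = rk)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Drops zero differences, ranks absolute differences with average ranks for
#' ties, and reports `W = min(W+, W-)` (the smaller of the positive- and
#' negative-difference rank sums). The two-sided p-value is exact for up to
#' 25 nonzero pairs — computed from the full null distribution of the rank
#' sum — and uses the normal approximation with tie correction above that.
#'
#' @param a,b Equal-length paired numeric samples.
#' @return A list with `W`, `p_value`, `n` (nonzero pairs), and `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
#' @export
wilcoxon_signed_rank <- function(a, b) {
  abort_if(length(a) != length(b), "paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  abort_if(n < 5L, "fewer than 5 nonzero differences: test refused")
  r <- rank(abs(d))                       # average ranks for ties
  w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= 25L) {
    # exact null distribution of W+ by convolution over the (doubled,
    # tie-averaged) ranks: coefficient c[s] = #subsets with doubled-rank sum s
    r2 <- as.integer(round(2 * r))
    coef <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), coef[seq_len(length(coef) - ri)])
      coef <- coef + shifted
    }
    probs <- coef / 2^n
    # P(W+ <= W) with W on the original scale -> doubled scale
    p <- min(1, 2 * sum(probs[seq_len(as.integer(round(2 * W)) + 1L)]))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu + 0.25) / sqrt(sigma2)   # slight continuity correction
    p <- min(1, 2 * pnorm(z))
    method <- "normal_approx"
  }
  list(W = W, p_value = p, n = n, method = method)
}

benchmark_method_grid <- function() {
  tibble::tibble(
    method = c("PSO-CR", "DE-CR", "PSO-QR", "DE-QR"),
    optimizer = c("pso", "de", "pso", "de"),
    entropy = c("classical", "classical", "quantum", "quantum")
  )
}

metric_directions <- function() {
  c(psnr = TRUE, ssim = TRUE, ambe = FALSE, cii = TRUE, sd = TRUE,
    edge_density = TRUE, rec = TRUE, sf = TRUE, cir = TRUE)
}

#' Run the four-method comparative benchmark
#'
#' Executes [segment_image()] for every (image, k, method) combination of the
#' four optimizer-entropy pairs (PSO-CR, DE-CR, PSO-QR, DE-QR), computes the
#' nine quality metrics of each run against its reference, and aggregates
#' per-(k, metric) rank tables with variance tie-breaking, overall ranks
#' (sum of the nine per-metric ranks; 9 best, 36 worst for four methods),
#' pairwise Wilcoxon signed-rank tables, and mean iteration/fitness
#' summaries. Per-image failures are recorded and skipped.
#'
#' @param images Named list of `gray_image` objects (or paths readable by
#'   [load_gray_image()]).
#' @param ks Integer vector of threshold counts, e.g. `c(2, 4, 7)`.
#' @param alpha Renyi order for both entropy modes.
#' @param config Base [optimizer_config()]; each run derives its own seed
#'   from `config$seed` and the grid position for independence.
#' @param enhance Enhancement strategy for every run.
#' @param compare_to `"enhanced"` scores runs against the image actually
#'   segmented; `"original"` scores against the raw input.
#' @return A `comparison_table`: list of tibbles `rows` (per-run metrics and
#'   optimizer summary), `ranks` (per k/metric/method), `overall` (OR per
#'   k/method), `wilcoxon` (pairwise tests per k/metric), `failures`.
#' @export
run_benchmark <- function(images, ks = c(2L, 4L, 7L),
                          alpha = 0.01,
                          config = optimizer_config(),
                          enhance = "identity",
                          compare_to = c("enhanced", "original")) {
  compare_to <- match.arg(compare_to)
  if (is.null(names(images)))
    names(images) <- sprintf("img%02d", seq_along(images))
  grid <- benchmark_method_grid()
  rows <- list(); failures <- list()
  run_id <- 0L
  for (img_name in names(images)) {
    img <- images[[img_name]]
    if (is.character(img)) img <- load_gray_image(img)
    for (k in ks) {
      for (j in seq_len(nrow(grid))) {
        run_id <- run_id + 1L
        cfg <- config
        cfg$seed <- as.integer((config$seed + run_id * 7919L) %% .Machine$integer.max)
        res <- tryCatch({
          params <- entropy_params(alpha = alpha, mode = grid$entropy[j])
          sg <- segment_image(img, k, params = params, config = cfg,
                              method = grid$optimizer[j], enhance = enhance)
          ref <- if (compare_to == "enhanced") sg$enhanced else img
          met <- compute_metrics(ref, sg$segmented)
          dplyr::bind_cols(
            tibble::tibble(image = img_name, method = grid$method[j], k = k,
                           best_fitness = sg$optimizer$best_fitness,
                           iterations = sg$optimizer$iterations,
                           t_star = paste(sg$optimizer$best_X$t, collapse = ",")),
            met)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            tibble::tibble(image = img_name, method = grid$method[j], k = k,
                           error = conditionMessage(res))
        } else {
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  rows <- dplyr::bind_rows(rows)
  abort_if(nrow(rows) == 0L, "every benchmark run failed")
  dirs <- metric_directions()

  ranks <- tidyr::expand_grid(k = ks, metric = names(dirs)) |>
    purrr::pmap(function(k, metric) {
      sub <- rows[rows$k == k, ]
      vals <- split(sub[[metric]], sub$method)[unique(sub$method)]
      rk <- rank_methods(vals, higher_is_better = dirs[[metric]])
      dplyr::mutate(rk, k = k, metric = metric, .before = 1)
    }) |> dplyr::bind_rows()

  overall <- ranks |>
    dplyr::group_by(.data$k, .data$method) |>
    dplyr::summarise(OR = sum(.data$rank), .groups = "drop")

  pairs <- combn(grid$method, 2L)
  wil <- list()
  for (k in ks) {
    sub <- rows[rows$k == k, ]
    for (metric in names(dirs)) for (p in seq_len(ncol(pairs))) {
      m1 <- pairs[1L, p]; m2 <- pairs[2L, p]
      a <- sub[[metric]][sub$method == m1]
      b <- sub[[metric]][sub$method == m2]
      wt <- tryCatch(wilcoxon_signed_rank(a, b), error = function(e) NULL)
      if (!is.null(wt)) {
        wil[[length(wil) + 1L]] <- tibble::tibble(
          k = k, metric = metric, method_a = m1, method_b = m2,
          W = wt$W, p_value = wt$p_value, n = wt$n)
      }
    }
  }

  summary_tbl <- rows |>
    dplyr::group_by(.data$k, .data$method) |>
    dplyr::summarise(mean_iterations = mean(.data$iterations),
                     mean_fitness = mean(.data$best_fitness),
                     .groups = "drop")

  structure(list(rows = rows, ranks = ranks, overall = overall,
                 wilcoxon = dplyr::bind_rows(wil), summary = summary_tbl,
                 failures = dplyr::bind_rows(failures)),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d runs, %d failures\n",
              nrow(x$rows), nrow(x$failures)))
  cat("Overall ranks (lower is better):\n")
  print(tidyr::pivot_wider(x$overall, names_from = "method", values_from = "OR"))
  invisible(x)
}

#' @rdname comparison_table_methods
#' @param x,object A `comparison_table`.
#' @param ... Unused.
#' @export
tidy.comparison_table <- function(x, ...) x$rows

#' Accessors and plots for benchmark tables
#'
#' `tidy()` returns the per-run metric rows; `glance()` the per-(k, method)
#' overall-rank table; `autoplot()` boxplots of a chosen metric by method.
#'
#' @name comparison_table_methods
#' @export
glance.comparison_table <- function(x, ...) x$overall

#' @rdname comparison_table_methods
#' @param metric Metric column to plot (default `"psnr"`).
#' @export
autoplot.comparison_table <- function(object, metric = "psnr", ...) {
  ggplot2::ggplot(object$rows,
                  ggplot2::aes(x = .data$method, y = .data[[metric]],
                               fill = .data$method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Export benchmark tables as CSV files
#' @param ct A `comparison_table`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(ct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("rows", "ranks", "overall", "wilcoxon", "summary")) {
    utils::write.csv(ct[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  quart <- ct$rows |>
    tidyr::pivot_longer(dplyr::all_of(names(metric_directions())),
                        names_to = "metric") |>
    dplyr::group_by(.data$k, .data$method, .data$metric) |>
    dplyr::summarise(q1 = quantile(.data$value, 0.25),
                     median = median(.data$value),
                     q3 = quantile(.data$value, 0.75), .groups = "drop")
  utils::write.csv(quart, file.path(dir, "metric_quartiles.csv"),
                   row.names = FALSE)
  invisible(dir)
}
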