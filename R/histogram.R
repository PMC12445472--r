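#' Joint intensity/local-mean histogram
#'
#' The L x L joint histogram `h(x, y)` counting pixels whose intensity is `x`
#' and whose rounded 3x3 local mean is `y`. Rows index intensity, columns
#' index local mean; both axes are 0-based gray levels. Normalised weights
#' `w(x, y) = h(x, y) / (M * N)` drive both entropy objectives.
#'
#' @param counts L x L matrix of non-negative integer counts.
#' @param L Number of gray levels; inferred from `counts` when omitted.
#' @return A `joint_histogram` with elements `counts`, `weights`, `total`,
#'   `Sf` (occupied intensity levels), `Sg` (occupied mean levels), `L`.
#' @export
joint_histogram <- function(counts, L = nrow(counts)) {
  counts <- as.matrix(counts)
  L <- as.integer(L)
  abort_if(nrow(counts) != L || ncol(counts) != L,
           "counts must be a square L x L matrix")
  abort_if(anyNA(counts) || any(counts < 0) || any(counts != floor(counts)),
           "counts must be non-negative integers")
  total <- sum(counts)
  abort_if(total <= 0, "histogram must contain at least one observation")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, weights = counts / total, total = total,
         Sf = which(rowSums(counts) > 0L) - 1L,
         Sg = which(colSums(counts) > 0L) - 1L,
         L = L),
    class = "joint_histogram"
  )
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf(
    "<joint_histogram> L = %d, total = %d, occupied cells = %d, |Sf| = %d, |Sg| = %d\n",
    x$L, x$total, sum(x$counts > 0L), length(x$Sf), length(x$Sg)))
  invisible(x)
}

#' Build the joint histogram of an image and its local means
#'
#' @param img A `gray_image`.
#' @param means Its `local_mean_image()`; computed when omitted.
#' @return A `joint_histogram`.
#' @examples
#' img <- gray_image(matrix(c(0, 0, 0, 255), 2, 2))
#' H <- build_joint_histogram(img)
#' @export
build_joint_histogram <- function(img, means = local_mean_image(img)) {
  L <- levels_of(img)
  abort_if(!identical(dim(img), dim(means)),
           "image and local-mean image must have identical shape")
  abort_if(levels_of(means) != L, "image and means disagree on L")
  x <- as.vector(as_pixel_matrix(img))
  y <- as.vector(as_pixel_matrix(means))
  counts <- matrix(tabulate(x * L + y + 1L, nbins = L * L),
                   nrow = L, ncol = L, byrow = TRUE)
  joint_histogram(counts, L = L)
}

#' Export a joint histogram as CSV plus a JSON sidecar
#'
#' Writes the raw counts as an L-row by L-column CSV (no headers) and a
#' `<path>.json` sidecar recording `L` and the pixel total, so histograms can
#' be archived and reloaded without the source image.
#'
#' @param H A `joint_histogram`.
#' @param path Output CSV path.
#' @param M,N Optional source-image dimensions for the sidecar.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(H, path, M = NA_integer_, N = NA_integer_) {
  utils::write.table(H$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(M = M, N = N, L = H$L, total = H$total),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a histogram written by [write_histogram()]
#' @param path CSV path previously written by [write_histogram()].
#' @return A `joint_histogram`.
#' @export
read_histogram <- function(path) {
  counts <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(counts) <- NULL
  joint_histogram(counts)
}
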