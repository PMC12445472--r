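#' Grayscale image container
#'
#' Wraps an integer pixel matrix as a `gray_image`, the unit every pipeline
#' stage consumes. Pixels are gray levels in `[0, L-1]`; `L` defaults to 256
#' (8-bit) but is configurable so reduced-gray-level oracles stay cheap.
#'
#' @param pixels Integer matrix (rows M, columns N) of gray levels.
#' @param L Number of gray levels (default 256).
#' @return A `gray_image`: the pixel matrix with attributes `L`.
#' @examples
#' img <- gray_image(matrix(c(0, 0, 0, 255), 2, 2))
#' @export
gray_image <- function(pixels, L = 256L) {
  pixels <- as.matrix(pixels)
  abort_if(length(pixels) == 0L, "image must contain at least one pixel")
  abort_if(anyNA(pixels), "image contains missing values")
  abort_if(any(pixels != floor(pixels)), "pixel values must be integers")
  L <- as.integer(L)
  abort_if(L < 2L, "L must be at least 2")
  abort_if(any(pixels < 0) || any(pixels > L - 1L),
           sprintf("pixel values must lie in [0, %d]", L - 1L))
  storage.mode(pixels) <- "integer"
  structure(pixels, L = L, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, L = %d, range [%d, %d]\n",
              nrow(x), ncol(x), levels_of(x), min(x), max(x)))
  invisible(x)
}

#' Number of gray levels of an image or histogram
#' @param x A `gray_image` or `joint_histogram`.
#' @return Integer `L`.
#' @export
levels_of <- function(x) as.integer(attr(x, "L"))

as_pixel_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "L") <- NULL
  y
}

#' Read a grayscale image from disk
#'
#' Reads PNG, TIFF and PGM/PPM rasters into a `gray_image`. Multi-channel
#' images are collapsed by Rec. 601 luma weighting (0.299, 0.587, 0.114);
#' sub-byte or 16-bit sample depths are rescaled to `[0, 255]`.
#'
#' @param path Path to an image file; format inferred from the extension.
#' @return A `gray_image` with `L = 256`.
#' @export
load_gray_image <- function(path) {
  abort_if(!file.exists(path), sprintf("cannot read image: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = ,
    ppm  = ,
    pnm  = read_pnm(path),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  )
  abort_if(length(arr) == 0L, "zero-area image")
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]  # gray (+alpha): keep the gray channel
    }
  }
  # png/tiff readers normalise samples to [0,1] whatever the bit depth
  gray_image(round_half_up(pmin(pmax(arr, 0), 1) * 255))
}

# Minimal PNM reader (P2/P5 gray, P3/P6 color); no installed R package
# handles the format. Returns values normalised to [0,1] like png::readPNG.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  abort_if(!magic %in% c("P2", "P3", "P5", "P6"),
           sprintf("not a supported PNM file: %s", path))
  tokens <- character(0)
  # header tokens: width, height, maxval; '#' starts a comment to end of line
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    abort_if(length(ch) == 0L, "truncated PNM header")
    if (ch == "#") {
      repeat {
        c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || c2 == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || !grepl("[0-9]", c2)) break
        tok <- paste0(tok, c2)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  abort_if(w < 1L || h < 1L, "zero-area image")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  nvals <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval > 255L) {
      readBin(con, "integer", n = nvals, size = 2L, signed = FALSE,
              endian = "big")
    } else {
      readBin(con, "integer", n = nvals, size = 1L, signed = FALSE)
    }
  } else {
    scan(con, what = integer(), n = nvals, quiet = TRUE)
  }
  abort_if(length(vals) < nvals, "truncated PNM pixel data")
  if (nch == 3L) {
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    vals <- 0.299 * m[, 1] + 0.587 * m[, 2] + 0.114 * m[, 3]
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image to disk
#'
#' @param img A `gray_image` (L = 256).
#' @param path Output path; `.png`, `.tif`/`.tiff`, or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  img <- gray_image(img, L = levels_of(img))
  norm <- as_pixel_matrix(img) / (levels_of(img) - 1L)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(norm, path),
    tif  = ,
    tiff = tiff::writeTIFF(norm, path),
    pgm  = {
      con <- file(path, "wb")
      on.exit(close(con))
      writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
                eos = NULL)
      writeBin(as.integer(t(as_pixel_matrix(img))), con, size = 1L)
    },
    stop(sprintf("unsupported output format: .%s", ext), call. = FALSE)
  )
  invisible(path)
}

#' 3x3 local-mean image
#'
#' For every pixel, the arithmetic mean of its 3x3 neighbourhood (centre
#' included) restricted to in-bounds pixels — 4 neighbours at corners, 6 on
#' edges, 9 in the interior — rounded half-up to an integer gray bin. This is
#' the second axis of the joint 2D histogram.
#'
#' @param img A `gray_image`.
#' @return A `gray_image` of rounded local means, same shape and `L`.
#' @export
local_mean_image <- function(img) {
  L <- levels_of(img)
  px <- as_pixel_matrix(img)
  M <- nrow(px); N <- ncol(px)
  acc <- matrix(0, M, N)
  cnt <- matrix(0L, M, N)
  for (dr in -1:1) {
    rs <- max(1, 1 + dr):min(M, M + dr)      # destination rows
    src_r <- rs - dr
    for (dc in -1:1) {
      cs <- max(1, 1 + dc):min(N, N + dc)
      src_c <- cs - dc
      acc[rs, cs] <- acc[rs, cs] + px[src_r, src_c]
      cnt[rs, cs] <- cnt[rs, cs] + 1L
    }
  }
  gray_image(round_half_up(acc / cnt), L = L)
}
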