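#' Read an 8-bit raster image
#'
#' Reads a PNG (or TIFF, if the tiff package is installed) file and returns
#' either an RGB array (H x W x 3, integers in `[0, 255]`) or, for
#' single-channel files, a [grey_image]. Alpha channels are dropped.
#'
#' @param path Path to a `.png` / `.tif(f)` file.
#' @return An integer H x W x 3 array or a [grey_image].
#' @export
read_image <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, " (PNG and TIFF are supported)",
         call. = FALSE)
  )
  px <- round_half_up(raw * 255)
  if (length(dim(px)) == 2) {
    return(grey_image(px, provenance = path))
  }
  if (dim(px)[3] >= 3) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1) {
    return(grey_image(px[, , 1], provenance = path))
  }
  storage.mode(px) <- "integer"
  attr(px, "provenance") <- path
  px
}

#' Write a greyscale image to PNG
#'
#' @param img A [grey_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is_grey_image(img))
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' Convert an RGB image to greyscale (CCIR 601 luma)
#'
#' Applies the luma weighting `Y = 0.299 R + 0.587 G + 0.114 B`, rounds
#' half-up and clamps to `[0, 255]`. A greyscale input passes through
#' unchanged.
#'
#' @param img An H x W x 3 integer array in `[0, 255]`, or a [grey_image]
#'   (returned as-is).
#' @return A [grey_image].
#' @export
#' @examples
#' rgb <- array(0L, c(2, 2, 3)); rgb[, , 1] <- 255L
#' to_greyscale(rgb)  # pure red -> 76
to_greyscale <- function(img) {
  if (is_grey_image(img)) return(img)
  if (is.matrix(img)) return(grey_image(img))
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("`img` must be an H x W x 3 array or a grey_image", call. = FALSE)
  }
  check_8bit(img)
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  out <- grey_image(matrix(clamp255(round_half_up(y)), dim(img)[1], dim(img)[2]),
                    provenance = attr(img, "provenance") %||% "rgb array")
  add_provenance(out, "to_greyscale(ccir601)")
}

#' Mean absolute pixel difference between two images
#'
#' The image-similarity score used to match candidate images to a reference
#' set: the mean over all pixels (and channels, for RGB inputs) of the
#' absolute intensity difference.
#'
#' @param a,b Two images (matrices or arrays) of identical shape.
#' @return A non-negative scalar.
#' @export
mean_abs_diff <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  mean(abs(as.numeric(a) - as.numeric(b)))
}

#' Rank candidate images by similarity to a reference set
#'
#' Scores every candidate by its average [mean_abs_diff()] over all
#' reference images and returns the `k` best matches.
#'
#' @param candidates,references Lists of same-shape images.
#' @param k Number of matches to return (`k <= length(candidates)`).
#' @return A tibble with columns `index`, `score`, ordered by ascending
#'   score (ties broken by candidate index).
#' @export
select_matched <- function(candidates, references, k = length(candidates)) {
  if (length(references) == 0) stop("empty reference set", call. = FALSE)
  stopifnot(length(candidates) >= 1, k >= 1, k <= length(candidates))
  scores <- purrr::map_dbl(
    candidates,
    function(cand) mean(purrr::map_dbl(references, mean_abs_diff, a = cand))
  )
  ord <- order(scores, seq_along(scores))[seq_len(k)]
  tibble::tibble(index = ord, score = scores[ord])
}

#' Monotone contrast transforms
#'
#' Global contrast manipulations used for robustness checks. All are
#' monotone in pixel intensity, so they preserve the order in which pixels
#' enter a filtration; each output is rounded half-up and clamped once.
#'
#' * `gamma`: `Y' = 255 (Y/255)^gamma` (`params$gamma > 0`).
#' * `linear_stretch`: affine map of `[params$lo, params$hi]` onto
#'   `[0, 255]`, clamped.
#' * `percentile_stretch`: `linear_stretch` with `lo`/`hi` taken at
#'   `params$p_lo` / `params$p_hi` quantiles of the image histogram.
#'
#' @param img A [grey_image].
#' @param kind One of `"gamma"`, `"linear_stretch"`, `"percentile_stretch"`.
#' @param params Named list of parameters for the chosen kind.
#' @return A transformed [grey_image] of the same dimensions.
#' @export
#' @examples
#' img <- grey_image(matrix(128L, 4, 4))
#' contrast_transform(img, "gamma", list(gamma = 2))  # 128 -> 64
contrast_transform <- function(img, kind = c("gamma", "linear_stretch",
                                             "percentile_stretch"),
                               params = list()) {
  stopifnot(is_grey_image(img))
  kind <- match.arg(kind)
  y <- as.numeric(img)
  out <- switch(kind,
    gamma = {
      g <- params$gamma %||% stop("gamma transform needs params$gamma")
      if (g <= 0) stop("gamma must be > 0", call. = FALSE)
      255 * (y / 255)^g
    },
    linear_stretch = {
      lo <- params$lo %||% min(y)
      hi <- params$hi %||% max(y)
      if (lo >= hi) stop("stretch bounds must satisfy lo < hi", call. = FALSE)
      (y - lo) / (hi - lo) * 255
    },
    percentile_stretch = {
      p_lo <- params$p_lo %||% 0.02
      p_hi <- params$p_hi %||% 0.98
      q <- stats::quantile(y, c(p_lo, p_hi), names = FALSE)
      if (q[1] >= q[2]) stop("stretch bounds must satisfy lo < hi", call. = FALSE)
      (y - q[1]) / (q[2] - q[1]) * 255
    })
  res <- grey_image(matrix(clamp255(round_half_up(out)), nrow(img), ncol(img)),
                    provenance = attr(img, "provenance"))
  add_provenance(res, sprintf("contrast_transform(%s)", kind))
}
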