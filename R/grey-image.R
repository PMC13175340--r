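#' Greyscale image objects
#'
#' A `grey_image` is an integer matrix of pixel intensities in `[0, 255]`
#' (rows = image rows, columns = image columns) carrying a provenance
#' attribute that records the source and any transforms applied. It is the
#' object all filtrations are built from.
#'
#' @param x An integer-valued matrix with entries in `[0, 255]`.
#' @param provenance Character vector describing where the pixels came from.
#' @return A `grey_image` object.
#' @export
#' @examples
#' img <- grey_image(matrix(0L, 8, 8))
grey_image <- function(x, provenance = "matrix") {
  if (!is.matrix(x) || nrow(x) < 1 || ncol(x) < 1) {
    stop("`x` must be a matrix with at least one row and column", call. = FALSE)
  }
  check_8bit(x)
  storage.mode(x) <- "integer"
  structure(x, class = c("grey_image", class(matrix())),
            provenance = as.character(provenance))
}

check_8bit <- function(x) {
  rng <- range(x)
  if (anyNA(x) || rng[1] < 0 || rng[2] > 255 || any(x != round(x))) {
    stop(sprintf(
      "pixel values must be 8-bit integers in [0, 255]; observed range [%s, %s]",
      format(rng[1]), format(rng[2])), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %d x %d, values in [%d, %d]\n",
              nrow(x), ncol(x), min(x), max(x)))
  cat("provenance:", paste(attr(x, "provenance"), collapse = " | "), "\n")
  invisible(x)
}

is_grey_image <- function(x) inherits(x, "grey_image")

# round-half-up, the single rounding rule used by every intensity transform
round_half_up <- function(x) floor(x + 0.5)

clamp255 <- function(x) pmin(pmax(x, 0), 255)

add_provenance <- function(img, tag) {
  attr(img, "provenance") <- c(attr(img, "provenance"), tag)
  img
}
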