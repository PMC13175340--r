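#' Topological feature map of dimension-1 cycles
#'
#' Overlays a square grid of non-overlapping windows (default 50 x 50
#' pixels) on the image and summarises the dimension-1 cycle
#' representatives per window:
#'
#' * `density`: number of cycles anchored in the window. Each cycle is
#'   anchored in exactly one window — the one containing the centroid of
#'   its representative's bounding box — so cycles are never
#'   double-counted.
#' * `max_persistence`: largest persistence among cycles whose
#'   representative touches the window (0 if none).
#' * `max_perimeter`: largest representative pixel count among cycles
#'   touching the window (0 if none).
#'
#' Right/bottom edge windows may be smaller than `window` when the image
#' size is not a multiple of the window size; they are kept.
#'
#' @param pairs A `persistence_pairs` tibble with dimension-1
#'   representatives (from [persistence()]).
#' @param shape Image dimensions `c(H, W)`; defaults to the shape recorded
#'   in `pairs`.
#' @param kind One of `"density"`, `"max_persistence"`, `"max_perimeter"`.
#' @param window Window side in pixels (default 50, minimum 2).
#' @return A `feature_map`: a `ceiling(H/window) x ceiling(W/window)`
#'   numeric matrix with attributes `kind`, `window`, `source`, `shape`.
#' @export
feature_map <- function(pairs, shape = attr(pairs, "shape"),
                        kind = c("density", "max_persistence", "max_perimeter"),
                        window = 50) {
  kind <- match.arg(kind)
  stopifnot(window >= 2, length(shape) == 2)
  gr <- ceiling(shape[1] / window)
  gc <- ceiling(shape[2] / window)
  m <- matrix(0, gr, gc)
  d1 <- pairs[pairs$dim == 1, , drop = FALSE]
  for (i in seq_len(nrow(d1))) {
    rep1 <- d1$representative[[i]]
    if (is.null(rep1)) {
      stop(sprintf("dimension-1 pair %d has no representative", i),
           call. = FALSE)
    }
    if (kind == "density") {
      ctr_r <- mean(range(rep1[, "row"]))
      ctr_c <- mean(range(rep1[, "col"]))
      wi <- ceiling(ctr_r / window); wj <- ceiling(ctr_c / window)
      m[wi, wj] <- m[wi, wj] + 1
    } else {
      cells <- unique(cbind(ceiling(rep1[, "row"] / window),
                            ceiling(rep1[, "col"] / window)))
      val <- if (kind == "max_persistence") d1$persistence[i]
             else nrow(unique(rep1))              # distinct perimeter pixels
      m[cells] <- pmax(m[cells], val)
    }
  }
  new_feature_map(m, kind, window,
                  source = attr(pairs, "direction") %||% "unknown",
                  shape = as.integer(shape))
}

new_feature_map <- function(m, kind, window, source, shape) {
  structure(m, class = c("feature_map", class(matrix())),
            kind = kind, window = window, source = source, shape = shape)
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s (%s), %d x %d windows of %d px\n",
              attr(x, "kind"), attr(x, "source"), nrow(x), ncol(x),
              attr(x, "window")))
  invisible(x)
}

#' Composite feature map over both filtrations
#'
#' Combines the BW and WB maps of the same kind: densities add cellwise,
#' maxima (persistence, perimeter) take the cellwise maximum.
#'
#' @param bw,wb `feature_map`s of the same kind, window and grid shape.
#' @return A `feature_map` with `source = "composite"`.
#' @export
composite_map <- function(bw, wb) {
  if (!identical(attr(bw, "kind"), attr(wb, "kind")) ||
      !identical(dim(bw), dim(wb)) ||
      !identical(attr(bw, "window"), attr(wb, "window"))) {
    stop("feature maps must share kind, window and grid shape", call. = FALSE)
  }
  m <- if (attr(bw, "kind") == "density") unclass(bw) + unclass(wb)
       else pmax(unclass(bw), unclass(wb))
  new_feature_map(matrix(m, nrow(bw), ncol(bw)), attr(bw, "kind"),
                  attr(bw, "window"), "composite", attr(bw, "shape"))
}

#' Feature maps for an image, both filtrations and their composite
#'
#' Convenience wrapper: runs [persistence()] in both directions and returns
#' the composite [feature_map()] of the requested kind.
#'
#' @inheritParams feature_map
#' @param img A [grey_image].
#' @return A composite `feature_map`.
#' @export
image_feature_map <- function(img, kind = c("density", "max_persistence",
                                            "max_perimeter"), window = 50) {
  kind <- match.arg(kind)
  p_bw <- persistence(build_filtration(img, "BW"))
  p_wb <- persistence(build_filtration(img, "WB"))
  composite_map(feature_map(p_bw, dim(img), kind, window),
                feature_map(p_wb, dim(img), kind, window))
}
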