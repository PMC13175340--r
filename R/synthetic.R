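#' Synthetic scene specifications with known topological ground truth
#'
#' A scene is a constant light background carrying dark axis-aligned
#' primitives rasterised with hard edges, so every birth and death level is
#' an exact integer and the full bar list of both filtrations can be
#' written down in advance:
#'
#' * `disk(row, col, radius, intensity)` — filled disk; one BW component,
#'   one WB hole.
#' * `annulus(row, col, r_inner, r_outer, intensity)` — dark ring with
#'   interior at background intensity; adds a BW hole and a WB interior
#'   component on top of the disk-like bars.
#' * `rectangle(row1, col1, row2, col2, intensity)` — filled rectangle.
#' * `stripe(from, to, intensity, orientation)` — dark band spanning the
#'   full image width (`orientation = "horizontal"`, rows `from:to`) or
#'   height (`"vertical"`), i.e. a frame-touching shape that breaks
#'   Alexander duality.
#'
#' Primitives must be darker than the background, must not touch the frame
#' (stripes excepted) and must keep at least one background pixel between
#' each other; specs violating this are refused because their ground truth
#' would be ambiguous.
#'
#' @param shape Image dimensions `c(H, W)`.
#' @param primitives List of primitive descriptions built with [disk()],
#'   [annulus()], [rectangle()], [stripe()].
#' @param background Background intensity (default 255).
#' @param n_speckles Number of 2x2 dark texture squares scattered over free
#'   background (default 0).
#' @param speckle_intensity Intensity of the speckle squares (default 0).
#' @param speckle_regions Optional list of regions with their own speckle
#'   counts, each `list(row1, col1, row2, col2, n)`; overrides `n_speckles`
#'   and gives a texture whose cycle density varies by region.
#' @param noise_sd Gaussian pixel noise (default 0; any positive value
#'   invalidates the exact ground truth, which is then flagged).
#' @param seed Integer seed driving speckle placement and noise.
#' @return A `scene_spec` list.
#' @export
#' @examples
#' sp <- scene_spec(c(32, 32), list(disk(16, 16, 5, 0)))
#' sc <- render_scene(sp)
#' sc$truth$counts
scene_spec <- function(shape, primitives = list(), background = 255,
                       n_speckles = 0, speckle_intensity = 0,
                       speckle_regions = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 4),
            background >= 0, background <= 255,
            n_speckles >= 0, noise_sd >= 0)
  for (p in primitives) {
    if (p$intensity >= background) {
      stop("primitive intensity must be below the background intensity",
           call. = FALSE)
    }
  }
  if (is.null(speckle_regions) && n_speckles > 0) {
    speckle_regions <- list(list(row1 = 2, col1 = 2, row2 = shape[1] - 2,
                                 col2 = shape[2] - 2, n = n_speckles))
  }
  total <- sum(vapply(speckle_regions, function(r) r$n, 0))
  structure(list(shape = as.integer(shape), primitives = primitives,
                 background = as.integer(background),
                 n_speckles = as.integer(total),
                 speckle_intensity = as.integer(speckle_intensity),
                 speckle_regions = speckle_regions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param row,col Centre pixel of the primitive.
#' @param radius,r_inner,r_outer Radii in pixels.
#' @param intensity Primitive intensity in `[0, 255]`.
#' @export
disk <- function(row, col, radius, intensity = 0) {
  stopifnot(radius >= 1)
  list(type = "disk", row = row, col = col, radius = radius,
       intensity = as.integer(intensity))
}

#' @rdname scene_spec
#' @export
annulus <- function(row, col, r_inner, r_outer, intensity = 0) {
  stopifnot(r_inner >= 1.5, r_outer >= r_inner + 2)
  list(type = "annulus", row = row, col = col, r_inner = r_inner,
       r_outer = r_outer, intensity = as.integer(intensity))
}

#' @rdname scene_spec
#' @param row1,col1,row2,col2 Corner pixels of the rectangle (inclusive).
#' @export
rectangle <- function(row1, col1, row2, col2, intensity = 0) {
  stopifnot(row2 >= row1, col2 >= col1)
  list(type = "rectangle", row1 = row1, col1 = col1, row2 = row2,
       col2 = col2, intensity = as.integer(intensity))
}

#' @rdname scene_spec
#' @param from,to First and last row (or column) of the band, inclusive.
#' @param orientation `"horizontal"` (spans all columns) or `"vertical"`.
#' @export
stripe <- function(from, to, intensity = 0,
                   orientation = c("horizontal", "vertical")) {
  stopifnot(to >= from)
  list(type = "stripe", from = from, to = to,
       intensity = as.integer(intensity), orientation = match.arg(orientation))
}

rasterize_primitive <- function(p, shape) {
  H <- shape[1]; W <- shape[2]
  rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))
  switch(p$type,
    disk = (rr - p$row)^2 + (cc - p$col)^2 <= p$radius^2,
    annulus = {
      d2 <- (rr - p$row)^2 + (cc - p$col)^2
      d2 <= p$r_outer^2 & d2 > p$r_inner^2
    },
    rectangle = rr >= p$row1 & rr <= p$row2 & cc >= p$col1 & cc <= p$col2,
    stripe = if (p$orientation == "horizontal") {
      rr >= p$from & rr <= p$to
    } else {
      cc >= p$from & cc <= p$to
    })
}

annulus_interior <- function(p, shape) {
  H <- shape[1]; W <- shape[2]
  rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))
  (rr - p$row)^2 + (cc - p$col)^2 <= p$r_inner^2
}

# dilate a mask by one pixel (8-neighbourhood), used for separation checks
dilate1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-H, ]
  out[-H, ] <- out[-H, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -W]
  out[, -W] <- out[, -W] | m[, -1]
  out
}

#' Render a synthetic scene
#'
#' Draws the image described by a [scene_spec()] and returns it together
#' with its exact topological ground truth: the complete list of expected
#' persistence bars for both filtrations and the expected unmatched-bar
#' counts of the duality matching.
#'
#' @param spec A `scene_spec`.
#' @return A list of class `topo_scene` with elements `image`
#'   ([grey_image]), `truth` (list: `bars` tibble with columns `direction`,
#'   `dim`, `birth`, `death`, `essential`; `counts` tibble;
#'   `n_unmatched_wb1_bw0`, `n_unmatched_bw1_wb0`; `exact` flag) and
#'   `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  B <- spec$background
  img <- matrix(B, H, W)
  occupied <- matrix(FALSE, H, W)   # primitives + interiors, for separation

  masks <- list()
  for (p in spec$primitives) {
    m <- rasterize_primitive(p, spec$shape)
    full <- if (p$type == "annulus") m | annulus_interior(p, spec$shape) else m
    if (!any(m)) stop("primitive rasterises to no pixels", call. = FALSE)
    if (p$type == "stripe") {
      lim <- if (p$orientation == "horizontal") H else W
      if (p$from <= 1 || p$to >= lim) {
        stop("stripe must leave background on both sides of the band",
             call. = FALSE)
      }
    }
    if (p$type != "stripe") {
      touches <- any(full[1, ]) || any(full[H, ]) || any(full[, 1]) ||
        any(full[, W])
      if (touches) {
        stop("non-stripe primitive touches the image frame; ground truth would be ambiguous",
             call. = FALSE)
      }
    }
    if (any(dilate1(full) & occupied)) {
      stop("primitives overlap or touch; ground truth would be ambiguous",
           call. = FALSE)
    }
    occupied <- occupied | dilate1(full)
    img[m] <- p$intensity
    masks[[length(masks) + 1L]] <- m
  }

  # speckle texture: seeded non-overlapping 2x2 dark squares, per region
  if (spec$n_speckles > 0) {
    speckle_anchors <- withr::with_seed(spec$seed, {
      anchors <- matrix(NA_integer_, 0, 2)
      for (reg in spec$speckle_regions) {
        r_lo <- max(reg$row1, 2); r_hi <- min(reg$row2, H - 2)
        c_lo <- max(reg$col1, 2); c_hi <- min(reg$col2, W - 2)
        placed <- 0; tries <- 0
        while (placed < reg$n && tries < 200 * reg$n) {
          tries <- tries + 1
          r <- sample(r_lo:r_hi, 1); c <- sample(c_lo:c_hi, 1)
          if (any(occupied[(r - 1):(r + 2), (c - 1):(c + 2)])) next
          occupied[(r - 1):(r + 2), (c - 1):(c + 2)] <- TRUE
          anchors <- rbind(anchors, c(r, c))
          placed <- placed + 1
        }
        if (placed < reg$n) {
          stop("could not place all speckles without overlap", call. = FALSE)
        }
      }
      anchors
    })
    for (i in seq_len(nrow(speckle_anchors))) {
      r <- speckle_anchors[i, 1]; c <- speckle_anchors[i, 2]
      img[r:(r + 1), c:(c + 1)] <- spec$speckle_intensity
    }
  }

  exact <- spec$noise_sd == 0
  if (!exact) {
    img <- withr::with_seed(spec$seed + 1L, {
      clamp255(round_half_up(img + stats::rnorm(length(img), 0, spec$noise_sd)))
    })
    img <- matrix(img, H, W)
  }

  truth <- scene_truth(spec, masks)
  list_out <- list(image = grey_image(img, provenance = "render_scene"),
                   truth = truth, spec = spec)
  class(list_out) <- "topo_scene"
  list_out
}

#' @export
print.topo_scene <- function(x, ...) {
  cat(sprintf("<topo_scene> %d x %d, %d primitive(s), %d speckle(s)%s\n",
              x$spec$shape[1], x$spec$shape[2], length(x$spec$primitives),
              x$spec$n_speckles,
              if (x$truth$exact) "" else " [noisy: ground truth inexact]"))
  invisible(x)
}

# expected bar list for a validated spec (exact only when noise_sd == 0)
scene_truth <- function(spec, masks) {
  B <- spec$background
  prim <- spec$primitives
  n_sp <- spec$n_speckles
  isp <- spec$speckle_intensity

  bars <- tibble::tibble(direction = character(), dim = integer(),
                         birth = numeric(), death = numeric(),
                         essential = logical())
  add <- function(direction, dim, birth, death, essential = FALSE) {
    bars <<- dplyr::bind_rows(bars, tibble::tibble(
      direction = direction, dim = dim, birth = birth, death = death,
      essential = essential))
  }

  dark_units <- c(purrr::map_dbl(prim, "intensity"),
                  rep(isp, n_sp))                 # one per component
  if (length(dark_units) == 0) {
    add("BW", 0L, B, 255, TRUE)
    add("WB", 0L, 255 - B, 255, TRUE)
  } else {
    # BW dim 0: every dark unit born at its intensity, dies when the
    # background connects everything at level B; the darkest unit (ties:
    # smallest row-major anchor) is the essential class.
    ess_idx <- essential_unit(spec, masks)
    for (i in seq_along(dark_units)) {
      if (i == ess_idx) add("BW", 0L, dark_units[i], 255, TRUE)
      else add("BW", 0L, dark_units[i], B, FALSE)
    }
    add("WB", 0L, 255 - B, 255, TRUE)            # background
  }

  for (p in prim) {
    if (p$type == "annulus") {
      add("BW", 1L, p$intensity, B)              # interior hole
      add("WB", 0L, 255 - B, 255 - p$intensity)  # interior component
      add("WB", 1L, 255 - B, 255 - p$intensity)  # ring as hole in light
    } else if (p$type == "stripe") {
      # a full-span band splits the background; the cut heals when the
      # stripe itself enters the reverse filtration
      add("WB", 0L, 255 - B, 255 - p$intensity)
    } else {
      add("WB", 1L, 255 - B, 255 - p$intensity)  # enclosed dark shape
    }
  }
  for (i in seq_len(n_sp)) add("WB", 1L, 255 - B, 255 - isp)

  n_stripes <- sum(purrr::map_chr(prim, "type") == "stripe")
  counts <- dplyr::count(bars, .data$direction, .data$dim, name = "n")
  list(bars = bars, counts = counts,
       n_unmatched_wb1_bw0 = if (length(dark_units) == 0) 1L
                             else n_stripes + as.integer(B < 255),
       n_unmatched_bw1_wb0 = 1L + n_stripes,
       exact = spec$noise_sd == 0)
}

# which dark unit carries the essential BW class: minimal intensity, ties
# by smallest row-major pixel index (the elder rule's anchor order)
essential_unit <- function(spec, masks) {
  H <- spec$shape[1]; W <- spec$shape[2]
  units <- list()
  for (i in seq_along(masks)) units[[i]] <- masks[[i]]
  n_prim <- length(units)
  ints <- purrr::map_dbl(spec$primitives, "intensity")
  if (spec$n_speckles > 0) {
    # regenerate anchors deterministically is awkward here; speckles share
    # one intensity, so only their anchor order can matter on an intensity
    # tie with a primitive -- conservatively recompute from the spec seed
    # is not needed for counts: the essential flag only moves between bars
    # of identical (birth, death) in that case.
    ints <- c(ints, rep(spec$speckle_intensity, spec$n_speckles))
  }
  anchors <- purrr::map_dbl(units, function(m) min(which(t(m))))
  if (spec$n_speckles > 0) {
    anchors <- c(anchors, rep(Inf, spec$n_speckles))
  }
  order(ints, anchors)[1]
}
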