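#' Fixation heatmap from eye-tracking data
#'
#' Builds a duration-weighted Gaussian fixation heatmap. Fixations with
#' duration at or below `min_duration` (75 ms by default) are discarded;
#' each remaining fixation deposits an isotropic Gaussian of width `sigma`
#' centred at its (x, y) position with total in-image mass proportional to
#' its duration (the kernel is renormalized inside the image so border
#' fixations are not down-weighted by truncation). The final map is
#' normalized to unit sum. With no qualifying fixation an all-zero map with
#' attribute `sentinel = TRUE` is returned.
#'
#' @param fixations A data frame with columns `x` (column coordinate), `y`
#'   (row coordinate) and `duration` in ms; extra id columns are ignored.
#'   Coordinates outside the image are clamped with a warning.
#' @param shape Image dimensions `c(H, W)`.
#' @param sigma Gaussian kernel width in pixels (default 50).
#' @param min_duration Minimum fixation duration in ms, exclusive
#'   (default 75).
#' @return A `gaze_heatmap`: an H x W matrix summing to 1 (or the zero
#'   sentinel).
#' @export
gaze_heatmap <- function(fixations, shape, sigma = 50, min_duration = 75) {
  stopifnot(sigma > 0, length(shape) == 2)
  H <- shape[1]; W <- shape[2]
  keep <- fixations$duration > min_duration
  fx <- fixations[keep, , drop = FALSE]
  acc <- matrix(0, H, W)
  if (nrow(fx) == 0) {
    return(structure(acc, class = c("gaze_heatmap", class(matrix())),
                     sigma = sigma, sentinel = TRUE))
  }
  if (any(fx$x < 1 | fx$x > W | fx$y < 1 | fx$y > H)) {
    warning("fixation coordinates outside the image were clamped")
    fx$x <- pmin(pmax(fx$x, 1), W)
    fx$y <- pmin(pmax(fx$y, 1), H)
  }
  rows <- seq_len(H); cols <- seq_len(W)
  for (i in seq_len(nrow(fx))) {
    kr <- stats::dnorm(rows, mean = fx$y[i], sd = sigma)
    kc <- stats::dnorm(cols, mean = fx$x[i], sd = sigma)
    k <- outer(kr, kc)
    acc <- acc + fx$duration[i] * k / sum(k)
  }
  structure(acc / sum(acc), class = c("gaze_heatmap", class(matrix())),
            sigma = sigma, sentinel = FALSE)
}

#' @export
print.gaze_heatmap <- function(x, ...) {
  cat(sprintf("<gaze_heatmap> %d x %d, sigma %.1f px%s\n", nrow(x), ncol(x),
              attr(x, "sigma"),
              if (isTRUE(attr(x, "sentinel"))) " (sentinel: no fixations)" else ""))
  invisible(x)
}

window_sums <- function(hm, window) {
  gr <- ceiling(nrow(hm) / window); gc <- ceiling(ncol(hm) / window)
  wi <- ceiling(row(hm) / window); wj <- ceiling(col(hm) / window)
  m <- matrix(0, gr, gc)
  agg <- tapply(as.numeric(hm), list(wi, wj), sum)
  m[seq_len(nrow(agg)), seq_len(ncol(agg))] <- agg
  m
}

#' Per-window gaze weights
#'
#' Integrates a fixation heatmap over the feature-map grid windows and
#' normalizes, giving the "looking" weighting for a weighted ECDF.
#'
#' @param hm A `gaze_heatmap` (non-sentinel).
#' @param window Window side in pixels, matching the feature map.
#' @return A matrix of non-negative window weights summing to 1.
#' @export
window_weights <- function(hm, window = 50) {
  if (isTRUE(attr(hm, "sentinel"))) {
    stop("sentinel heatmap has no gaze mass; use uniform weights",
         call. = FALSE)
  }
  m <- window_sums(hm, window)
  m / sum(m)
}

#' Complement ("not looking") window weights
#'
#' Uniform weight over the windows whose gaze weight is at most
#' `eps * max(window weight)`; zero elsewhere.
#'
#' @inheritParams window_weights
#' @param eps Relative threshold defining "unvisited" (default 0.05).
#' @return A matrix of window weights summing to 1.
#' @export
complement_weights <- function(hm, window = 50, eps = 0.05) {
  w <- window_weights(hm, window)
  unvisited <- w <= eps * max(w)
  if (!any(unvisited)) {
    stop("no unvisited window below the eps threshold", call. = FALSE)
  }
  out <- matrix(0, nrow(w), ncol(w))
  out[unvisited] <- 1 / sum(unvisited)
  out
}

#' Weighted empirical CDF of a feature map
#'
#' `ECDF(v) = sum of weights of windows with value <= v`: with uniform
#' weights this is the ordinary ECDF of the window values; with gaze
#' weights it describes the feature values in the regions an observer
#' fixated.
#'
#' @param map A `feature_map` (or numeric matrix).
#' @param weights Matrix of non-negative window weights aligned with
#'   `map`, summing to 1; `NULL` (default) uses uniform weights.
#' @return A `weighted_ecdf`: list with ascending `support` and
#'   `cum_weight` ending at 1.
#' @export
weighted_ecdf <- function(map, weights = NULL) {
  v <- as.numeric(map)
  if (is.null(weights)) weights <- rep(1 / length(v), length(v))
  w <- as.numeric(weights)
  if (length(w) != length(v)) {
    stop("weights must align with the feature-map grid", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  w <- w / sum(w)
  agg <- tapply(w, v, sum)
  support <- as.numeric(names(agg))
  structure(list(support = support,
                 cum_weight = pmin(cumsum(as.numeric(agg)), 1)),
            class = "weighted_ecdf")
}

#' @export
print.weighted_ecdf <- function(x, ...) {
  cat(sprintf("<weighted_ecdf> %d support points in [%g, %g]\n",
              length(x$support), min(x$support), max(x$support)))
  invisible(x)
}

eval_ecdf <- function(e, at) {
  idx <- findInterval(at, e$support)
  c(0, e$cum_weight)[idx + 1]
}

merged_support <- function(e1, e2) {
  s <- sort(unique(c(e1$support, e2$support)))
  if (length(s) == 0) stop("empty ECDF support", call. = FALSE)
  s
}

#' Mean squared / mean signed difference between two ECDFs
#'
#' Both ECDFs are evaluated on the merged support grid. `mse_ecdf` returns
#' the mean of the squared differences (in `[0, 1]`); `me_ecdf` the mean of
#' the signed differences `e1 - e2` (in `[-1, 1]`). A negative `me_ecdf`
#' means `e1` lies below `e2`, i.e. the first distribution puts its mass on
#' higher feature values.
#'
#' @param e1,e2 `weighted_ecdf`s over the same feature kind.
#' @return A scalar.
#' @export
mse_ecdf <- function(e1, e2) {
  s <- merged_support(e1, e2)
  mean((eval_ecdf(e1, s) - eval_ecdf(e2, s))^2)
}

#' @rdname mse_ecdf
#' @export
me_ecdf <- function(e1, e2) {
  s <- merged_support(e1, e2)
  mean(eval_ecdf(e1, s) - eval_ecdf(e2, s))
}

#' Kolmogorov-Smirnov statistic between two ECDFs
#'
#' `sup |e1 - e2|` over the merged support.
#'
#' @inheritParams mse_ecdf
#' @return A scalar in `[0, 1]`.
#' @export
ks_stat <- function(e1, e2) {
  s <- merged_support(e1, e2)
  max(abs(eval_ecdf(e1, s) - eval_ecdf(e2, s)))
}

#' Gaze-vs-feature comparison statistics for one viewing
#'
#' The per-(participant, image) summary of how fixated regions relate to a
#' topological feature map: the intrinsic (uniform-weight) ECDF is compared
#' with the gaze-weighted "looking" ECDF, and the looking ECDF with the
#' complement "not looking" ECDF.
#'
#' `me_looking_vs_notlooking` is oriented so that positive values mean the
#' fixated regions carry *higher* feature values than the ignored regions
#' (a distribution over higher values has a lower ECDF, hence the sign
#' flip relative to the raw [me_ecdf()]).
#'
#' @param map A `feature_map`.
#' @param fixations Fixation data frame (see [gaze_heatmap()]).
#' @param sigma,min_duration Heatmap parameters.
#' @param eps Complement threshold (see [complement_weights()]).
#' @return A one-row tibble: `mse_intrinsic_vs_looking`,
#'   `mse_looking_vs_notlooking`, `me_looking_vs_notlooking`, `ks`,
#'   `n_fixations`.
#' @export
gaze_feature_stats <- function(map, fixations, sigma = 50, min_duration = 75,
                               eps = 0.05) {
  window <- attr(map, "window")
  shape <- attr(map, "shape")
  hm <- gaze_heatmap(fixations, shape, sigma = sigma,
                     min_duration = min_duration)
  e_u <- weighted_ecdf(map)
  e_look <- weighted_ecdf(map, window_weights(hm, window))
  e_not <- tryCatch(weighted_ecdf(map, complement_weights(hm, window, eps)),
                    error = function(e) NULL)   # gaze covered every window
  tibble::tibble(
    mse_intrinsic_vs_looking = mse_ecdf(e_u, e_look),
    mse_looking_vs_notlooking = if (is.null(e_not)) NA_real_
                                else mse_ecdf(e_look, e_not),
    me_looking_vs_notlooking = if (is.null(e_not)) NA_real_
                               else -me_ecdf(e_look, e_not),
    ks = ks_stat(e_u, e_look),
    n_fixations = sum(fixations$duration > min_duration))
}
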