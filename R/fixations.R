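#' Simulate fixations biased toward high-feature regions
#'
#' Draws `n` fixations over the image underlying a feature map. Each
#' fixation first picks a grid window with probability proportional to
#' `(1 + map value)^bias` — `bias = 0` is spatially uniform over windows,
#' large `bias` concentrates on the argmax window — then a uniform pixel
#' position inside that window, and a uniform duration in
#' `[min_dur, max_dur]` ms.
#'
#' @param map A `feature_map` (carries the window size and image shape).
#' @param n Number of fixations.
#' @param bias Non-negative window-preference exponent.
#' @param min_dur,max_dur Duration range in ms (`max_dur > min_dur > 0`).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A tibble of fixations: `x`, `y`, `duration`, `participant`,
#'   `image`, `session`.
#' @export
simulate_fixations <- function(map, n, bias = 0, min_dur = 100,
                               max_dur = 400, seed = 1L) {
  stopifnot(n >= 1, bias >= 0, min_dur > 0, max_dur > min_dur)
  window <- attr(map, "window")
  shape <- attr(map, "shape")
  vals <- as.numeric(map)
  if (all(vals == 0) && bias > 0) {
    warning("all-zero feature map: falling back to uniform window choice")
  }
  prob <- (1 + vals)^bias
  prob <- prob / sum(prob)
  withr::with_seed(seed, {
    win <- sample.int(length(vals), n, replace = TRUE, prob = prob)
    wi <- (win - 1) %% nrow(map) + 1          # grid row
    wj <- (win - 1) %/% nrow(map) + 1         # grid col
    r_lo <- (wi - 1) * window + 1
    r_hi <- pmin(wi * window, shape[1])
    c_lo <- (wj - 1) * window + 1
    c_hi <- pmin(wj * window, shape[2])
    tibble::tibble(
      x = c_lo + stats::runif(n) * (c_hi - c_lo),
      y = r_lo + stats::runif(n) * (r_hi - r_lo),
      duration = stats::runif(n, min_dur, max_dur),
      participant = "sim", image = "synthetic", session = 1L)
  })
}
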