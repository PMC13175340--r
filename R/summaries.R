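#' Betti curve of a set of persistence pairs
#'
#' Counts, at every filtration level `f = 0..255`, the bars of the chosen
#' dimension alive at `f`. Bars are right-open intervals `[birth, death)`;
#' the essential dimension-0 class counts through level 255 inclusive.
#'
#' @param pairs A `persistence_pairs` tibble (or any tibble with `dim`,
#'   `birth`, `death`, `essential` columns).
#' @param dim Homology dimension, 0 or 1.
#' @return A `betti_curve` tibble with columns `level` (0..255) and `beta`.
#' @export
betti_curve <- function(pairs, dim = 0) {
  p <- pairs[pairs$dim == dim, , drop = FALSE]
  lv <- 0:255
  beta <- integer(256)
  if (nrow(p) > 0) {
    death_eff <- ifelse(p$essential, 256, p$death)   # essential: alive at 255
    for (i in seq_len(nrow(p))) {
      alive <- lv >= p$birth[i] & lv < death_eff[i]
      beta <- beta + alive
    }
  }
  structure(tibble::tibble(level = lv, beta = as.integer(beta)),
            class = c("betti_curve", class(tibble::tibble())),
            hom_dim = dim)
}

#' Integrated Betti curve (area under the curve)
#'
#' The discrete integral `sum_f beta(f)` over the 256 levels, which equals
#' the total persistence of all bars of that dimension under the right-open
#' convention (the essential bar contributing `256 - birth`).
#'
#' @param curve A `betti_curve`.
#' @return A non-negative scalar.
#' @export
integrated_betti <- function(curve) {
  sum(as.numeric(curve$beta))
}

#' Persistence landscape
#'
#' Each bar `(b, d)` contributes a tent function
#' `max(0, min(f - b, d - f))`; layer `k` of the landscape is the k-th
#' largest tent height at each level. Bars with persistence at or below
#' `min_persistence` are discarded first (the group-level summaries use a
#' threshold of 5 intensity steps). Essential dimension-0 bars enter with
#' death capped at 255.
#'
#' @param pairs A `persistence_pairs` tibble.
#' @param dim Homology dimension, 0 or 1.
#' @param min_persistence Discard bars with `death - birth <=` this value
#'   (default 5).
#' @return A `persistence_landscape`: a layers x 256 matrix of tent heights
#'   evaluated on the integer grid 0..255 (zero rows trimmed; possibly zero
#'   layers), with attribute `levels`.
#' @export
landscape <- function(pairs, dim = 0, min_persistence = 5) {
  if (min_persistence < 0) stop("min_persistence must be >= 0", call. = FALSE)
  p <- pairs[pairs$dim == dim, , drop = FALSE]
  p <- p[(p$death - p$birth) > min_persistence, , drop = FALSE]
  lv <- 0:255
  if (nrow(p) == 0) {
    return(new_landscape(matrix(0, 0, 256), dim))
  }
  tents <- vapply(seq_len(nrow(p)), function(i) {
    pmax(0, pmin(lv - p$birth[i], p$death[i] - lv))
  }, numeric(256))                               # 256 x nbars
  layers <- apply(tents, 1, sort, decreasing = TRUE)
  layers <- matrix(layers, ncol = 256)           # nbars x 256
  keep <- rowSums(layers) > 0
  new_landscape(layers[keep, , drop = FALSE], dim)
}

new_landscape <- function(m, hom_dim = NA) {
  structure(m, class = c("persistence_landscape", class(matrix())),
            levels = 0:255, hom_dim = hom_dim)
}

#' @export
print.persistence_landscape <- function(x, ...) {
  cat(sprintf("<persistence_landscape> %d layer(s) on levels 0..255, area %.2f\n",
              nrow(x), landscape_area(x)))
  invisible(x)
}

# trapezoid integral of each row over the unit-spaced level grid
trapz_rows <- function(m) {
  if (nrow(m) == 0 || ncol(m) < 2) return(numeric(nrow(m)))
  k <- ncol(m)
  rowSums((m[, -1, drop = FALSE] + m[, -k, drop = FALSE]) / 2)
}

#' Total area beneath a persistence landscape (its L1 norm)
#'
#' @param ls A `persistence_landscape`.
#' @return Sum over layers of the trapezoid integral of the layer.
#' @export
landscape_area <- function(ls) {
  sum(trapz_rows(ls))
}

pad_layers <- function(a, b) {
  k <- max(nrow(a), nrow(b))
  pad <- function(m) rbind(m, matrix(0, k - nrow(m), ncol(m)))
  list(pad(a), pad(b))
}

#' Layer-wise average of persistence landscapes
#'
#' Pointwise arithmetic mean of each layer across a list of landscapes,
#' missing layers treated as zero.
#'
#' @param landscapes Nonempty list of `persistence_landscape` objects.
#' @return A `persistence_landscape`.
#' @export
average_landscape <- function(landscapes) {
  if (length(landscapes) == 0) stop("empty landscape list", call. = FALSE)
  k <- max(vapply(landscapes, nrow, 0L), 1L)
  acc <- matrix(0, k, 256)
  for (ls in landscapes) {
    if (nrow(ls) > 0) acc[seq_len(nrow(ls)), ] <- acc[seq_len(nrow(ls)), ] + ls
  }
  new_landscape(acc / length(landscapes), attr(landscapes[[1]], "hom_dim"))
}

#' L1 distance between two persistence landscapes
#'
#' `sum_k integral |lambda_k^1 - lambda_k^2|`, layers padded with zero.
#'
#' @param ls1,ls2 `persistence_landscape` objects.
#' @return A non-negative scalar; equals [landscape_area()] of either
#'   argument when the other is empty.
#' @export
l1_distance <- function(ls1, ls2) {
  p <- pad_layers(ls1, ls2)
  sum(trapz_rows(abs(p[[1]] - p[[2]])))
}

#' Permutation test for a group difference in mean landscapes
#'
#' Test statistic: the L1 distance between the two group-mean landscapes.
#' Group labels are permuted `n_perm` times;
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param group_a,group_b Nonempty lists of `persistence_landscape`s.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @return A `landscape_permtest` object; see [tidy()] and [glance()].
#' @export
landscape_permutation_test <- function(group_a, group_b, n_perm = 10000,
                                       seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  all_ls <- c(group_a, group_b)
  na <- length(group_a)
  observed <- l1_distance(average_landscape(group_a),
                          average_landscape(group_b))
  stat <- function(idx_a) {
    l1_distance(average_landscape(all_ls[idx_a]),
                average_landscape(all_ls[-idx_a]))
  }
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat(sample(length(all_ls), na))
    }, numeric(1))
  })
  p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  structure(list(statistic = observed, p.value = p, n_perm = n_perm,
                 n_a = na, n_b = length(group_b), seed = seed,
                 perm_stats = perm),
            class = "landscape_permtest")
}

#' @export
print.landscape_permtest <- function(x, ...) {
  cat(sprintf(
    "Landscape permutation test: L1(mean A, mean B) = %.3f, p = %.4g (%d permutations, n = %d vs %d)\n",
    x$statistic, x$p.value, x$n_perm, x$n_a, x$n_b))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.landscape_permtest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 method = "landscape L1 permutation test",
                 n_perm = x$n_perm, n_a = x$n_a, n_b = x$n_b)
}

#' @export
glance.landscape_permtest <- function(x, ...) tidy(x)

#' Hedges' g effect size
#'
#' Bias-corrected standardized mean difference:
#' `g = J (mean(x) - mean(y)) / s_pooled` with
#' `J = 1 - 3 / (4 (n_x + n_y) - 9)`.
#'
#' @param x,y Numeric samples of size at least 2 each.
#' @return A scalar; antisymmetric in its arguments.
#' @export
hedges_g <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  j <- 1 - 3 / (4 * (nx + ny) - 9)
  j * (mean(x) - mean(y)) / sqrt(sp2)
}
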