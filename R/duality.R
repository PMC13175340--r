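#' Alexander-duality-violation statistic of an image
#'
#' For the V-construction cubical filtrations of an image, every
#' dimension-1 class of one filtration corresponds injectively to a
#' dimension-0 class of the reverse filtration, except for cycles that
#' comprise or interact with the image frame. The violation statistic
#' compares the integrated Betti curves across the dual pairing:
#'
#' `ADV_BW = (b0_BW - b1_WB) / mean(b0_BW, b1_WB)`
#'
#' where `b0_BW` is the area under the dimension-0 Betti curve of the BW
#' filtration and `b1_WB` the area under the dimension-1 Betti curve of the
#' WB filtration; `ADV_WB` swaps the roles. Both lie in `[0, 2]`: 0 means
#' perfect duality, 2 maximal violation (e.g. a constant image, whose
#' reverse filtration has no holes at all).
#'
#' @param img A [grey_image].
#' @return An `adv_result`: a one-row tibble with columns `adv_bw`,
#'   `adv_wb`, `b0_bw`, `b1_wb`, `b0_wb`, `b1_bw`.
#' @export
#' @examples
#' adv(grey_image(matrix(128L, 8, 8)))  # constant image: adv_bw = 2
adv <- function(img) {
  if (!is_grey_image(img)) img <- grey_image(img)
  p_bw <- persistence(build_filtration(img, "BW"), representatives = FALSE)
  p_wb <- persistence(build_filtration(img, "WB"), representatives = FALSE)
  b0_bw <- integrated_betti(betti_curve(p_bw, 0))
  b1_bw <- integrated_betti(betti_curve(p_bw, 1))
  b0_wb <- integrated_betti(betti_curve(p_wb, 0))
  b1_wb <- integrated_betti(betti_curve(p_wb, 1))
  adv_one <- function(b0, b1) {
    if (b0 + b1 == 0) stop("both Betti areas are zero", call. = FALSE)
    (b0 - b1) / mean(c(b0, b1))
  }
  out <- tibble::tibble(
    adv_bw = adv_one(b0_bw, b1_wb),
    adv_wb = adv_one(b0_wb, b1_bw),
    b0_bw = b0_bw, b1_wb = b1_wb, b0_wb = b0_wb, b1_bw = b1_bw)
  structure(out, class = c("adv_result", class(out)))
}

#' Match dual persistence pairs across filtrations
#'
#' Pairs each dimension-1 bar of one filtration with a dimension-0 bar of
#' the reverse filtration. Matching is greedy by descending persistence and
#' requires (i) equal persistence and (ii) spatial overlap: the
#' dimension-0 anchor vertex must fall inside the (1-pixel-expanded)
#' bounding box of the dimension-1 cycle representative. Unmatched bars on
#' either side are reported; for scenes whose shapes avoid the frame these
#' are at most the essential background class, and each frame-touching
#' component adds exactly one.
#'
#' @param pairs_dim1 `persistence_pairs` of one filtration (dimension-1
#'   rows with representatives are used).
#' @param pairs_dim0_rev `persistence_pairs` of the reverse filtration of
#'   the same image (dimension-0 rows are used).
#' @return A list of class `dual_matching`: `matched` (tibble of index
#'   pairs with persistence), `unmatched_dim1`, `unmatched_dim0` (tibbles).
#' @export
match_dual_pairs <- function(pairs_dim1, pairs_dim0_rev) {
  dir1 <- attr(pairs_dim1, "direction")
  dir0 <- attr(pairs_dim0_rev, "direction")
  if (!is.null(dir1) && !is.null(dir0) && identical(dir1, dir0)) {
    stop("pair sets must come from opposite filtration directions",
         call. = FALSE)
  }
  d1 <- pairs_dim1[pairs_dim1$dim == 1, , drop = FALSE]
  d0 <- pairs_dim0_rev[pairs_dim0_rev$dim == 0, , drop = FALSE]
  d1 <- d1[order(-d1$persistence), , drop = FALSE]
  used0 <- rep(FALSE, nrow(d0))
  m_i1 <- integer(0); m_i0 <- integer(0)
  for (i in seq_len(nrow(d1))) {
    rep1 <- d1$representative[[i]]
    if (is.null(rep1)) {
      stop("dimension-1 pair without representative; rerun persistence() with representatives = TRUE",
           call. = FALSE)
    }
    box <- c(range(rep1[, "row"]) + c(-1, 1), range(rep1[, "col"]) + c(-1, 1))
    cand <- which(!used0 &
                    d0$persistence == d1$persistence[i] &
                    d0$anchor_row >= box[1] & d0$anchor_row <= box[2] &
                    d0$anchor_col >= box[3] & d0$anchor_col <= box[4])
    if (length(cand) > 0) {
      used0[cand[1]] <- TRUE
      m_i1 <- c(m_i1, i); m_i0 <- c(m_i0, cand[1])
    }
  }
  matched <- tibble::tibble(
    birth_dim1 = d1$birth[m_i1], death_dim1 = d1$death[m_i1],
    birth_dim0 = d0$birth[m_i0], death_dim0 = d0$death[m_i0],
    persistence = d1$persistence[m_i1])
  structure(list(
    matched = matched,
    unmatched_dim1 = d1[setdiff(seq_len(nrow(d1)), m_i1),
                        c("birth", "death", "persistence", "essential")],
    unmatched_dim0 = d0[!used0,
                        c("birth", "death", "persistence", "essential")]),
    class = "dual_matching")
}

#' @export
print.dual_matching <- function(x, ...) {
  cat(sprintf(
    "<dual_matching> %d matched, %d unmatched dim-1, %d unmatched dim-0\n",
    nrow(x$matched), nrow(x$unmatched_dim1), nrow(x$unmatched_dim0)))
  invisible(x)
}

#' Grid-partition identity at one filtration level
#'
#' At any level `f` the connected components of the level set (pixels with
#' BW value `<= f`) and of its complement (the reverse filtration at
#' `f' = 254 - f`) partition the pixel grid, so their counts add up:
#' `n_partitions = beta0(f) + beta0'(f')`.
#'
#' Partition counts come from direct 4-connected component labelling of the
#' two pixel sets; the Betti numbers come from the persistence pairs of the
#' two filtrations, so the identity genuinely cross-checks the two routes.
#'
#' @param img A [grey_image].
#' @param f Filtration level, `0 <= f <= 254`.
#' @param pairs_bw,pairs_wb Optional precomputed `persistence_pairs` for
#'   the two directions (recomputed when omitted).
#' @return A one-row tibble with `f`, `f_dual`, `n_partitions`,
#'   `beta0_at_f`, `beta0_rev_at_fdual` and logical `identity_holds`.
#' @export
partition_check <- function(img, f, pairs_bw = NULL, pairs_wb = NULL) {
  if (!is_grey_image(img)) img <- grey_image(img)
  if (f < 0 || f > 254) stop("f must be in [0, 254]", call. = FALSE)
  mask <- unclass(img) <= f
  n_part <- label4_count_cpp(mask) + label4_count_cpp(!mask)
  if (is.null(pairs_bw)) {
    pairs_bw <- persistence(build_filtration(img, "BW"), representatives = FALSE)
  }
  if (is.null(pairs_wb)) {
    pairs_wb <- persistence(build_filtration(img, "WB"), representatives = FALSE)
  }
  f_dual <- 254 - f
  b0 <- betti_curve(pairs_bw, 0)$beta[f + 1]
  b0r <- betti_curve(pairs_wb, 0)$beta[f_dual + 1]
  tibble::tibble(f = f, f_dual = f_dual,
                 n_partitions = n_part,
                 beta0_at_f = b0, beta0_rev_at_fdual = b0r,
                 identity_holds = n_part == b0 + b0r)
}
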