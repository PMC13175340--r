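#' Pipeline configuration
#'
#' Bundles the tunable parameters of the per-image pipeline with their
#' defaults: 50-pixel feature-map windows, a landscape persistence
#' threshold of 5 intensity steps, a 50-pixel gaze kernel, a complement
#' threshold of 0.05 and 10000 label permutations.
#'
#' @param window Feature-map window side in pixels.
#' @param min_persistence Landscape persistence threshold.
#' @param sigma Gaze-kernel width in pixels.
#' @param eps Complement ("not looking") relative threshold.
#' @param n_perm Permutations for group landscape tests.
#' @param seed Integer seed for all randomized steps.
#' @param out_dir Optional output directory; when set, [run_batch()] writes
#'   its tables there together with a JSON echo of this configuration.
#' @return A `topo_config` list.
#' @export
topo_config <- function(window = 50, min_persistence = 5, sigma = 50,
                        eps = 0.05, n_perm = 10000, seed = 1L,
                        out_dir = NULL) {
  stopifnot(window >= 2, min_persistence >= 0, sigma > 0, eps >= 0,
            n_perm >= 1)
  structure(list(window = window, min_persistence = min_persistence,
                 sigma = sigma, eps = eps, n_perm = n_perm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "topo_config")
}

image_summary_row <- function(img, id, config) {
  p_bw <- persistence(build_filtration(img, "BW"), representatives = FALSE)
  p_wb <- persistence(build_filtration(img, "WB"), representatives = FALSE)
  b0_bw <- integrated_betti(betti_curve(p_bw, 0))
  b1_bw <- integrated_betti(betti_curve(p_bw, 1))
  b0_wb <- integrated_betti(betti_curve(p_wb, 0))
  b1_wb <- integrated_betti(betti_curve(p_wb, 1))
  mp <- config$min_persistence
  tibble::tibble(
    image = id,
    n_dim0_bw = sum(p_bw$dim == 0), n_dim1_bw = sum(p_bw$dim == 1),
    n_dim0_wb = sum(p_wb$dim == 0), n_dim1_wb = sum(p_wb$dim == 1),
    b0_bw = b0_bw, b1_bw = b1_bw, b0_wb = b0_wb, b1_wb = b1_wb,
    area_dim0_bw = landscape_area(landscape(p_bw, 0, mp)),
    area_dim1_bw = landscape_area(landscape(p_bw, 1, mp)),
    adv_bw = (b0_bw - b1_wb) / mean(c(b0_bw, b1_wb)),
    adv_wb = (b0_wb - b1_bw) / mean(c(b0_wb, b1_bw)))
}

#' Run the full per-image pipeline over a batch of images
#'
#' For every image: both filtrations, persistence, Betti areas, landscape
#' areas (at the configured threshold) and the two duality-violation
#' statistics. When a two-level `groups` factor is supplied, a group
#' comparison table is added: Mann-Whitney U (via [stats::wilcox.test()])
#' and Hedges' g on the scalar summaries, and the landscape permutation
#' test per dimension on the BW filtration.
#'
#' @param images List of [grey_image]s (or paths readable by
#'   [read_image()]). Unreadable entries are skipped with a warning; the
#'   call errors only if all fail.
#' @param config A [topo_config()].
#' @param groups Optional vector with one label per image, two levels.
#' @return A list: `per_image` tibble and (when `groups` is given)
#'   `group_comparison` tibble. Written as CSV (plus `config.json`) under
#'   `config$out_dir` when set.
#' @export
run_batch <- function(images, config = topo_config(), groups = NULL) {
  ids <- names(images) %||% as.character(seq_along(images))
  rows <- list()
  ok <- logical(length(images))
  for (i in seq_along(images)) {
    row <- tryCatch({
      img <- images[[i]]
      if (is.character(img)) img <- to_greyscale(read_image(img))
      if (!is_grey_image(img)) img <- grey_image(img)
      image_summary_row(img, ids[i], config)
    }, error = function(e) {
      warning(sprintf("skipping image '%s': %s", ids[i], conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) { rows[[length(rows) + 1L]] <- row; ok[i] <- TRUE }
  }
  if (!any(ok)) stop("no image could be processed", call. = FALSE)
  per_image <- dplyr::bind_rows(rows)

  comparison <- NULL
  if (!is.null(groups)) {
    g <- factor(groups[ok])
    if (nlevels(g) != 2) stop("`groups` must have exactly two levels",
                              call. = FALSE)
    lv <- levels(g)
    scalar_cmp <- purrr::map_dfr(
      c("adv_bw", "adv_wb", "area_dim0_bw", "area_dim1_bw"),
      function(v) {
        x <- per_image[[v]][g == lv[1]]; y <- per_image[[v]][g == lv[2]]
        wt <- stats::wilcox.test(x, y, exact = FALSE)
        tibble::tibble(measure = v, u_statistic = unname(wt$statistic),
                       p_mann_whitney = wt$p.value,
                       hedges_g = tryCatch(hedges_g(x, y),
                                           error = function(e) NA_real_))
      })
    perm_p <- purrr::map_dfr(c(0L, 1L), function(d) {
      ls_of <- function(img) {
        p <- persistence(build_filtration(img, "BW"), representatives = FALSE)
        landscape(p, d, config$min_persistence)
      }
      imgs <- images[ok]
      imgs <- purrr::map(imgs, function(im) {
        if (is.character(im)) im <- to_greyscale(read_image(im))
        if (!is_grey_image(im)) im <- grey_image(im)
        im
      })
      ga <- purrr::map(imgs[g == lv[1]], ls_of)
      gb <- purrr::map(imgs[g == lv[2]], ls_of)
      pt <- landscape_permutation_test(ga, gb, n_perm = config$n_perm,
                                       seed = config$seed)
      tibble::tibble(measure = sprintf("landscape_dim%d_bw", d),
                     u_statistic = NA_real_, p_mann_whitney = NA_real_,
                     hedges_g = NA_real_, l1_statistic = pt$statistic,
                     p_permutation = pt$p.value)
    })
    comparison <- dplyr::bind_rows(scalar_cmp, perm_p)
  }

  out <- list(per_image = per_image, group_comparison = comparison,
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(per_image, file.path(config$out_dir, "per_image.csv"))
    if (!is.null(comparison)) {
      readr::write_csv(comparison,
                       file.path(config$out_dir, "group_comparison.csv"))
    }
    jsonlite::write_json(config[setdiff(names(config), "out_dir")],
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Compare the duality-violation statistic between two image groups
#'
#' @param group_a,group_b Lists of [grey_image]s.
#' @return A tibble with Mann-Whitney U and Hedges' g for `adv_bw` and
#'   `adv_wb`.
#' @export
adv_compare <- function(group_a, group_b) {
  val <- function(g) dplyr::bind_rows(purrr::map(g, adv))
  a <- val(group_a); b <- val(group_b)
  purrr::map_dfr(c("adv_bw", "adv_wb"), function(v) {
    wt <- stats::wilcox.test(a[[v]], b[[v]], exact = FALSE)
    tibble::tibble(measure = v, u_statistic = unname(wt$statistic),
                   p_mann_whitney = wt$p.value,
                   hedges_g = tryCatch(hedges_g(a[[v]], b[[v]]),
                                       error = function(e) NA_real_))
  })
}
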