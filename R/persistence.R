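#' Build a cubical filtration of a greyscale image
#'
#' Constructs the V-construction cubical complex of an image: one vertex
#' per pixel, edges between 4-neighbours, squares on 2x2 pixel blocks,
#' every cell entering the filtration at the maximum value of its vertices.
#' The BW (black-to-white) direction filters on raw intensity, so dark
#' pixels enter first; WB (white-to-black) filters on `255 - Y`.
#'
#' @param img A [grey_image] (plain integer matrices are accepted and
#'   validated).
#' @param direction `"BW"` or `"WB"`.
#' @return A `cubical_filtration` object: the direction-applied vertex
#'   values plus metadata. Levels run over the 256 intensity steps 0..255.
#' @export
#' @examples
#' f <- build_filtration(grey_image(matrix(7L, 1, 1)), "WB")
#' f$values  # 248
build_filtration <- function(img, direction = c("BW", "WB")) {
  direction <- match.arg(direction)
  if (!is_grey_image(img)) img <- grey_image(img)
  vals <- unclass(img)
  attr(vals, "provenance") <- NULL
  if (direction == "WB") vals <- 255L - vals
  structure(list(values = vals, direction = direction, dim = dim(vals)),
            class = "cubical_filtration")
}

#' @export
print.cubical_filtration <- function(x, ...) {
  cat(sprintf("<cubical_filtration> %s, %d x %d pixels, 256 levels\n",
              x$direction, x$dim[1], x$dim[2]))
  invisible(x)
}

new_persistence_pairs <- function(df, direction, shape) {
  structure(df, class = c("persistence_pairs", class(df)),
            direction = direction, shape = shape)
}

#' Persistent homology of a cubical filtration
#'
#' Computes dimension-0 and dimension-1 persistence pairs. Dimension 0 is
#' obtained by an ascending union-find pass with the elder rule (at a merge
#' the component born earlier survives; ties broken by the lexicographic
#' (row, col) position of the component's minimal vertex). Dimension 1 uses
#' the planar-duality descending pass over the dual square grid, which
#' pairs each hole's closing edge with the square value at which the hole
#' fills. Zero-persistence pairs are discarded. The single essential
#' dimension-0 class has its death capped at 255 and is flagged.
#'
#' Each dimension-1 pair carries a cycle representative: a closed loop of
#' 4-neighbour edges present at the birth level, recorded as an ordered
#' matrix of (row, col) vertices. Dimension-0 representatives are the
#' anchor vertex of the component at birth.
#'
#' @param filt A `cubical_filtration` from [build_filtration()].
#' @param representatives Compute dimension-1 cycle representatives?
#' @return A `persistence_pairs` tibble with columns `dim`, `birth`,
#'   `death`, `essential`, `anchor_row`, `anchor_col`, `persistence` and a
#'   list-column `representative` (NULL for dimension 0), ordered by
#'   (dim, birth, death, anchor).
#' @export
#' @examples
#' img <- grey_image(matrix(c(0, 0, 0, 0, 255, 0, 0, 0, 0), 3, 3))
#' persistence(build_filtration(img, "BW"))  # one component + one hole
persistence <- function(filt, representatives = TRUE) {
  stopifnot(inherits(filt, "cubical_filtration"))
  res <- cubical_pairs_cpp(filt$values, representatives)
  d0 <- tibble::as_tibble(res$dim0)
  d0$dim <- 0L
  d0$representative <- purrr::map2(d0$anchor_row, d0$anchor_col,
                                   ~cbind(row = .x, col = .y))
  d1 <- tibble::as_tibble(res$dim1)
  d1$dim <- 1L
  d1$essential <- FALSE
  d1$representative <- if (representatives && nrow(d1) > 0) {
    lapply(res$dim1_reps, function(m) {
      colnames(m) <- c("row", "col")
      m
    })
  } else {
    rep(list(NULL), nrow(d1))
  }
  out <- dplyr::bind_rows(d0, d1)
  out$persistence <- out$death - out$birth
  out <- out[order(out$dim, out$birth, out$death,
                   out$anchor_row, out$anchor_col), ]
  out <- out[, c("dim", "birth", "death", "essential", "persistence",
                 "anchor_row", "anchor_col", "representative")]
  new_persistence_pairs(out, filt$direction, filt$dim)
}

#' Reference persistence by boundary-matrix reduction
#'
#' Textbook Z/2 boundary-matrix reduction over the full cubical complex,
#' used as an independent oracle for [persistence()] in the test-suite.
#' Cells are ordered by (value, dimension, enumeration index); the standard
#' left-to-right column reduction yields (birth cell, death cell) pairs.
#' Only small instances are accepted.
#'
#' @param filt A `cubical_filtration`.
#' @param max_cells Guard on the total cell count (default 10000).
#' @return A tibble with columns `dim`, `birth`, `death`, `essential`,
#'   zero-persistence pairs removed, essential deaths capped at 255.
#' @export
oracle_persistence <- function(filt, max_cells = 10000) {
  stopifnot(inherits(filt, "cubical_filtration"))
  v <- filt$values
  H <- nrow(v); W <- ncol(v)
  n_v <- H * W
  n_e <- H * (W - 1) + (H - 1) * W
  n_s <- max(H - 1, 0) * max(W - 1, 0)
  if (n_v + n_e + n_s > max_cells) {
    stop("instance too large for the reduction oracle", call. = FALSE)
  }
  vid <- function(r, c) (r - 1) * W + c
  vv <- as.numeric(t(v))                         # pixel value by row-major id

  # enumerate cells: value, dim, boundary (ids within each dim enumeration)
  cell_val <- numeric(0); cell_dim <- integer(0); bdry <- list()
  # vertices
  for (r in seq_len(H)) for (c in seq_len(W)) {
    cell_val <- c(cell_val, v[r, c]); cell_dim <- c(cell_dim, 0L)
    bdry[[length(bdry) + 1L]] <- integer(0)
  }
  # edges: horizontal then vertical, row-major; record global edge index
  edge_of <- new.env()
  ne <- 0L
  add_edge <- function(a, b) {
    ne <<- ne + 1L
    cell_val <<- c(cell_val, max(vv[a], vv[b]))
    cell_dim <<- c(cell_dim, 1L)
    bdry[[length(bdry) + 1L]] <<- c(a, b)
    assign(paste(sort(c(a, b)), collapse = "-"), n_v + ne, envir = edge_of)
  }
  if (W > 1) for (r in seq_len(H)) for (c in seq_len(W - 1)) {
    add_edge(vid(r, c), vid(r, c + 1))
  }
  if (H > 1) for (r in seq_len(H - 1)) for (c in seq_len(W)) {
    add_edge(vid(r, c), vid(r + 1, c))
  }
  # squares
  if (H > 1 && W > 1) for (r in seq_len(H - 1)) for (c in seq_len(W - 1)) {
    corners <- c(vid(r, c), vid(r, c + 1), vid(r + 1, c), vid(r + 1, c + 1))
    cell_val <- c(cell_val, max(vv[corners])); cell_dim <- c(cell_dim, 2L)
    e <- function(a, b) get(paste(sort(c(a, b)), collapse = "-"), envir = edge_of)
    bdry[[length(bdry) + 1L]] <- c(
      e(corners[1], corners[2]), e(corners[3], corners[4]),
      e(corners[1], corners[3]), e(corners[2], corners[4]))
  }

  m <- length(cell_val)
  ord <- order(cell_val, cell_dim, seq_len(m))   # filtration order, faces first
  pos <- integer(m); pos[ord] <- seq_len(m)      # cell id -> column index

  cols <- vector("list", m)
  for (j in seq_len(m)) cols[[j]] <- sort(pos[bdry[[ord[j]]]])
  low_of <- integer(m)                           # low value -> owning column
  pair_of <- integer(m)                          # column -> its low (0 = none)
  for (j in seq_len(m)) {
    cur <- cols[[j]]
    while (length(cur) > 0) {
      lw <- cur[length(cur)]
      j2 <- low_of[lw]
      if (j2 == 0L) break
      cur <- sort(c(setdiff(cur, cols[[j2]]), setdiff(cols[[j2]], cur)))
    }
    cols[[j]] <- cur
    if (length(cur) > 0) {
      lw <- cur[length(cur)]
      low_of[lw] <- j
      pair_of[j] <- lw
    }
  }

  births <- numeric(0); deaths <- numeric(0); dims <- integer(0); ess <- logical(0)
  death_cols <- which(pair_of > 0L)
  for (j in death_cols) {
    i <- pair_of[j]
    b <- cell_val[ord[i]]; d <- cell_val[ord[j]]
    if (d > b) {
      births <- c(births, b); deaths <- c(deaths, d)
      dims <- c(dims, cell_dim[ord[i]]); ess <- c(ess, FALSE)
    }
  }
  # essentials: positive (zero-column) cells that are nobody's birth
  is_birth <- logical(m); is_birth[pair_of[pair_of > 0L]] <- TRUE
  for (j in seq_len(m)) {
    if (length(cols[[j]]) == 0 && !is_birth[j] && cell_dim[ord[j]] < 2L) {
      births <- c(births, cell_val[ord[j]]); deaths <- c(deaths, 255)
      dims <- c(dims, cell_dim[ord[j]]); ess <- c(ess, TRUE)
    }
  }
  out <- tibble::tibble(dim = dims, birth = births, death = deaths,
                        essential = ess)
  out[order(out$dim, out$birth, out$death), ]
}
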