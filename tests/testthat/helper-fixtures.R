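# shared fixtures: all built in code at test time

# the 3x3 "ring": dark border, light centre -- one component, one hole
ring3 <- function() {
  m <- matrix(0L, 3, 3); m[2, 2] <- 255L
  grey_image(m)
}

random_small_image <- function(n = 8, values = 0:7) {
  grey_image(matrix(sample(values, n * n, replace = TRUE), n, n))
}

# canonical multiset form of a pair table for cross-implementation checks
bar_multiset <- function(pairs) {
  df <- data.frame(dim = as.integer(pairs$dim),
                   birth = as.numeric(pairs$birth),
                   death = as.numeric(pairs$death),
                   essential = pairs$essential)
  df <- df[order(df$dim, df$birth, df$death, df$essential), ]
  rownames(df) <- NULL
  df
}

# single-bar landscape for landscape-algebra tests
one_bar_landscape <- function(b, d, dim = 0, min_persistence = 0) {
  pairs <- tibble::tibble(dim = as.integer(dim), birth = b, death = d,
                          essential = FALSE)
  landscape(pairs, dim = dim, min_persistence = min_persistence)
}

# a standard busy synthetic scene: disks + annulus + speckle texture
demo_scene <- function(shape = c(64, 64), n_speckles = 6, seed = 7L,
                       stripes = 0) {
  prims <- list(disk(14, 14, 5, 0), disk(14, 46, 4, 40),
                annulus(46, 44, 3, 6, 20), rectangle(40, 10, 50, 22, 10))
  if (stripes > 0) {
    rows <- seq(26, 34, length.out = stripes)
    for (i in seq_len(stripes)) {
      prims[[length(prims) + 1L]] <- stripe(round(rows[i]), round(rows[i]) + 1,
                                            intensity = 5 * i)
    }
  }
  scene_spec(shape, prims, n_speckles = n_speckles, seed = seed)
}
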