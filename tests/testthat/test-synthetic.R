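scene_bars_observed <- function(sc) {
  p_bw <- persistence(build_filtration(sc$image, "BW"), representatives = FALSE)
  p_wb <- persistence(build_filtration(sc$image, "WB"), representatives = FALSE)
  df <- rbind(cbind(direction = "BW", bar_multiset(p_bw)),
              cbind(direction = "WB", bar_multiset(p_wb)))
  df <- df[order(df$direction, df$dim, df$birth, df$death, df$essential), ]
  rownames(df) <- NULL
  df
}

scene_bars_expected <- function(sc) {
  df <- as.data.frame(sc$truth$bars)
  df$dim <- as.integer(df$dim)
  df$birth <- as.numeric(df$birth); df$death <- as.numeric(df$death)
  df <- df[order(df$direction, df$dim, df$birth, df$death, df$essential),
           c("direction", "dim", "birth", "death", "essential")]
  rownames(df) <- NULL
  df
}

test_that("rendered scenes match their predicted bar lists exactly", {
  specs <- list(
    scene_spec(c(32, 32), list(disk(16, 16, 5, 0))),
    scene_spec(c(32, 32), list(annulus(16, 16, 3, 6, 20))),
    scene_spec(c(48, 48), list(disk(12, 12, 4, 0), disk(12, 36, 4, 60),
                               rectangle(30, 8, 40, 20, 30))),
    demo_scene(),
    demo_scene(stripes = 2),
    scene_spec(c(40, 40), list(), n_speckles = 10, seed = 5L)
  )
  for (sp in specs) {
    sc <- render_scene(sp)
    expect_identical(scene_bars_observed(sc), scene_bars_expected(sc))
  }
})

test_that("three dark disks on white give the documented bar counts", {
  sc <- render_scene(scene_spec(c(32, 32), list(disk(8, 8, 3, 0),
                                                disk(8, 24, 3, 0),
                                                disk(24, 16, 3, 0))))
  p_bw <- persistence(build_filtration(sc$image, "BW"))
  p_wb <- persistence(build_filtration(sc$image, "WB"))
  d0 <- p_bw[p_bw$dim == 0, ]
  expect_identical(nrow(d0), 3L)                     # one per disk
  expect_identical(sum(d0$essential), 1L)
  expect_true(all(d0$death[!d0$essential] == 255))   # merge when white enters
  d1w <- p_wb[p_wb$dim == 1, ]
  expect_identical(nrow(d1w), 3L)                    # each disk a hole in white
  expect_true(all(d1w$persistence == 255))
})

test_that("an annulus produces the ring hole with predictable levels", {
  sc <- render_scene(scene_spec(c(32, 32), list(annulus(16, 16, 3, 6, 40))))
  p_bw <- persistence(build_filtration(sc$image, "BW"))
  d1 <- p_bw[p_bw$dim == 1, ]
  expect_identical(nrow(d1), 1L)
  expect_identical(d1$birth, 40L)    # hole appears with the ring
  expect_identical(d1$death, 255L)   # fills when the interior enters
})

test_that("an empty spec renders a constant image with a single essential class", {
  sc <- render_scene(scene_spec(c(16, 16)))
  expect_true(all(sc$image == 255))
  expect_identical(scene_bars_observed(sc), scene_bars_expected(sc))
  expect_identical(sum(sc$truth$bars$essential), 2L)  # one per direction
})

test_that("ambiguous specs are refused", {
  expect_error(render_scene(scene_spec(c(32, 32), list(disk(10, 10, 4, 0),
                                                       disk(12, 12, 4, 0)))),
               "overlap")
  expect_error(render_scene(scene_spec(c(32, 32), list(disk(3, 16, 4, 0)))),
               "frame")
  expect_error(scene_spec(c(32, 32), list(disk(16, 16, 4, 255))),
               "below the background")
  expect_error(render_scene(scene_spec(c(16, 16), n_speckles = 200)),
               "speckles")
})

test_that("frame-touching stripes change the unmatched-duality count by exactly k", {
  base <- render_scene(demo_scene())
  count_unmatched <- function(sc) {
    p_bw <- persistence(build_filtration(sc$image, "BW"))
    p_wb <- persistence(build_filtration(sc$image, "WB"))
    m <- match_dual_pairs(p_wb, p_bw)
    nrow(m$unmatched_dim1) + nrow(m$unmatched_dim0)
  }
  u0 <- count_unmatched(base)
  expect_identical(u0, base$truth$n_unmatched_wb1_bw0)
  for (k in 1:3) {
    sck <- render_scene(demo_scene(stripes = k))
    expect_identical(count_unmatched(sck), u0 + k)
    expect_identical(sck$truth$n_unmatched_wb1_bw0, u0 + k)
  }
})

test_that("simulated fixations are deterministic and respect the bias", {
  fm <- pixtopo:::new_feature_map(matrix(c(0, 0, 9, 0), 2, 2), "density",
                                  10, "composite", c(20L, 20L))
  f1 <- simulate_fixations(fm, 50, bias = 1, seed = 9)
  f2 <- simulate_fixations(fm, 50, bias = 1, seed = 9)
  expect_identical(f1, f2)
  expect_true(all(f1$duration > 100 & f1$duration < 400))

  # large bias concentrates on the argmax window (grid row 1, col 2)
  fb <- simulate_fixations(fm, 100, bias = 50, seed = 2)
  expect_true(all(fb$x > 10 & fb$y <= 10.5))

  expect_warning(
    simulate_fixations(pixtopo:::new_feature_map(matrix(0, 2, 2), "density",
                                                 10, "composite", c(20L, 20L)),
                       10, bias = 2, seed = 1),
    "uniform")
})

test_that("unbiased fixations are uniform over windows", {
  fm <- pixtopo:::new_feature_map(matrix(c(5, 1, 3, 7), 2, 2), "density",
                                  25, "composite", c(50L, 50L))
  fx <- simulate_fixations(fm, 10000, bias = 0, seed = 4)
  counts <- table(paste(ceiling(round(fx$y) / 25), ceiling(round(fx$x) / 25)))
  expect_identical(length(counts), 4L)
  gof <- suppressWarnings(stats::chisq.test(as.numeric(counts)))
  expect_gt(gof$p.value, 0.001)
})
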