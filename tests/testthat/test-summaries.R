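bars <- function(...) {
  v <- c(...)
  if (length(v) == 0) {
    return(tibble::tibble(dim = integer(), birth = numeric(),
                          death = numeric(), essential = logical()))
  }
  m <- matrix(v, ncol = 2, byrow = TRUE)
  tibble::tibble(dim = 0L, birth = m[, 1], death = m[, 2], essential = FALSE)
}

test_that("Betti curves count alive bars with right-open intervals", {
  bc <- betti_curve(bars(10, 20), 0)
  expect_identical(bc$beta, as.integer(0:255 >= 10 & 0:255 < 20))

  const <- persistence(build_filtration(grey_image(matrix(5L, 3, 3)), "BW"))
  expect_true(all(betti_curve(const, 0)$beta[6:256] == 1))
  expect_true(all(betti_curve(const, 0)$beta[1:5] == 0))

  strip <- grey_image(matrix(c(0L, 255L, 0L, 255L, 0L), 1, 5))
  b0 <- betti_curve(persistence(build_filtration(strip, "BW")), 0)
  expect_identical(b0$beta[1], 3L)      # level 0
  expect_identical(b0$beta[256], 1L)    # level 255
})

test_that("integrated Betti equals the total persistence of the bars", {
  expect_identical(integrated_betti(betti_curve(bars(0, 10), 0)), 10)
  expect_identical(integrated_betti(betti_curve(bars(), 0)), 0)
  expect_identical(integrated_betti(betti_curve(bars(0, 10, 5, 15), 0)), 20)
  # conservation on real pair sets, essential bar counting 256 - birth
  set.seed(61)
  p <- persistence(build_filtration(random_small_image(8, 0:7), "BW"))
  for (d in 0:1) {
    pd <- p[p$dim == d, ]
    len <- ifelse(pd$essential, 256 - pd$birth, pd$death - pd$birth)
    expect_equal(integrated_betti(betti_curve(p, d)), sum(len))
  }
})

test_that("landscapes are nested tent stacks with the persistence threshold", {
  ls1 <- one_bar_landscape(0, 10)
  expect_identical(nrow(ls1), 1L)
  expect_identical(max(ls1), 5)
  expect_identical(which.max(ls1[1, ]) - 1L, 5L)       # peak at f = 5

  expect_identical(nrow(landscape(bars(0, 4), 0, min_persistence = 5)), 0L)
  expect_identical(nrow(landscape(bars(0, 5), 0, min_persistence = 5)), 0L)
  expect_identical(nrow(landscape(bars(0, 6), 0, min_persistence = 5)), 1L)

  two <- landscape(bars(0, 10, 2, 8), 0, min_persistence = 0)
  expect_identical(nrow(two), 2L)
  expect_identical(two[2, 6], 3)                        # layer 2 peak at f = 5
  expect_true(all(two[1, ] >= two[2, ]))                # nesting
  expect_error(landscape(bars(0, 10), 0, min_persistence = -1), ">= 0")
})

test_that("landscape area follows the closed form and matches the L1 distance to empty", {
  empty <- landscape(bars(), 0)
  expect_identical(landscape_area(empty), 0)
  for (bd in list(c(0, 10), c(10, 30), c(100, 200))) {
    ls <- one_bar_landscape(bd[1], bd[2])
    expect_equal(landscape_area(ls), (bd[2] - bd[1])^2 / 4)
    expect_equal(l1_distance(ls, empty), landscape_area(ls))
  }
  # additivity for non-interacting bars
  ls2 <- landscape(bars(0, 10, 100, 130), 0, min_persistence = 0)
  expect_equal(landscape_area(ls2), 25 + 225)
})

test_that("average landscapes are pointwise layer means and averaging is linear", {
  ls <- one_bar_landscape(0, 10)
  same <- average_landscape(list(ls, ls, ls))
  expect_equal(unclass(same), unclass(ls), ignore_attr = TRUE)

  empty <- landscape(bars(), 0)
  half <- average_landscape(list(ls, empty))
  expect_equal(max(half), 2.5)
  expect_equal(landscape_area(half), landscape_area(ls) / 2)

  scaled <- pixtopo:::new_landscape(unclass(ls) * 3)
  expect_equal(unclass(average_landscape(list(scaled))),
               3 * unclass(average_landscape(list(ls))), ignore_attr = TRUE)
  expect_error(average_landscape(list()), "empty")
})

test_that("L1 distance is a symmetric pseudometric on landscapes", {
  a <- one_bar_landscape(0, 50)
  b <- one_bar_landscape(100, 180)
  expect_identical(l1_distance(a, a), 0)
  expect_equal(l1_distance(a, b), l1_distance(b, a))
  expect_equal(l1_distance(a, b),
               landscape_area(a) + landscape_area(b))   # disjoint supports
})

test_that("the landscape permutation test separates groups and respects the null", {
  # clearly separated persistence ranges
  ga <- lapply(1:10, function(i) one_bar_landscape(0, 100 + i))
  gb <- lapply(1:10, function(i) one_bar_landscape(0, 20 + i))
  sep <- landscape_permutation_test(ga, gb, n_perm = 999, seed = 5)
  expect_lte(sep$p.value, 0.05)

  # identical groups: observed statistic 0, p at the top of its range
  null <- landscape_permutation_test(ga, ga[sample(10)], n_perm = 499, seed = 5)
  expect_gte(null$p.value, 0.9)

  # scaling both groups leaves ranks, hence p, unchanged under a fixed seed
  dbl <- function(g) lapply(g, function(l) pixtopo:::new_landscape(unclass(l) * 2))
  sep2 <- landscape_permutation_test(dbl(ga), dbl(gb), n_perm = 999, seed = 5)
  expect_identical(sep2$p.value, sep$p.value)
  expect_equal(sep2$statistic, 2 * sep$statistic)

  expect_error(landscape_permutation_test(ga, gb, n_perm = 0), "n_perm")
  expect_error(landscape_permutation_test(list(), gb), "nonempty")

  td <- tidy(sep)
  expect_identical(td$p.value, sep$p.value)
  expect_identical(glance(sep)$statistic, sep$statistic)
})

test_that("Hedges' g applies the small-sample correction", {
  expect_equal(hedges_g(c(1, 2, 3), c(0, 2, 4)), 0)
  # x = {0,0,1,1}, y = {1,1,2,2}: raw d = -sqrt(3), J = 1 - 3/23
  expect_equal(hedges_g(c(0, 0, 1, 1), c(1, 1, 2, 2)),
               -sqrt(3) * (1 - 3 / 23), tolerance = 1e-12)
  expect_equal(hedges_g(c(0, 0, 1, 1), c(1, 1, 2, 2)),
               -1.5061, tolerance = 1e-4)
  x <- rnorm(8); y <- rnorm(6)
  expect_equal(hedges_g(x, y), -hedges_g(y, x))
  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled variance")
})
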