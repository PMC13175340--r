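test_that("filtration orientation: BW keeps raw values, WB reverses them", {
  one <- grey_image(matrix(7L, 1, 1))
  expect_identical(build_filtration(one, "BW")$values[1, 1], 7L)
  expect_identical(build_filtration(one, "WB")$values[1, 1], 248L)

  p <- persistence(build_filtration(one, "BW"))
  expect_identical(nrow(p), 1L)
  expect_identical(p$birth, 7L)
  expect_true(p$essential)
})

test_that("constant and near-trivial images have the expected bars", {
  const <- persistence(build_filtration(grey_image(matrix(0L, 2, 2)), "BW"))
  expect_identical(nrow(const), 1L)
  expect_identical(const$dim, 0L)
  expect_identical(const$birth, 0L)
  expect_true(const$essential)

  # dark ring, light centre: one essential component and one hole [0, 255)
  p <- persistence(build_filtration(ring3(), "BW"))
  expect_identical(bar_multiset(p),
                   data.frame(dim = c(0L, 1L), birth = c(0, 0),
                              death = c(255, 255),
                              essential = c(TRUE, FALSE)))

  # alternating strip: three components born 0, two merge at 255
  strip <- grey_image(matrix(c(0L, 255L, 0L, 255L, 0L), 1, 5))
  p5 <- persistence(build_filtration(strip, "BW"))
  d0 <- p5[p5$dim == 0, ]
  expect_identical(nrow(d0), 3L)
  expect_true(all(d0$birth == 0))
  expect_identical(sum(d0$essential), 1L)
  expect_true(all(d0$death[!d0$essential] == 255))
})

test_that("dimension-1 representatives are closed loops at birth enclosing unentered pixels", {
  # even-odd point-in-polygon for the (possibly pinched) contour
  inside_polygon <- function(loop, pr, pc) {
    nxt <- rbind(loop[-1, , drop = FALSE], loop[1, , drop = FALSE])
    crossings <- 0
    for (k in seq_len(nrow(loop))) {
      r1 <- loop[k, 1]; c1 <- loop[k, 2]; r2 <- nxt[k, 1]; c2 <- nxt[k, 2]
      if (c1 == c2 && c1 > pc) {                  # vertical segment to the right
        lo <- min(r1, r2); hi <- max(r1, r2)
        if (pr > lo && pr < hi) crossings <- crossings + 1
      }
    }
    crossings %% 2 == 1
  }
  set.seed(21)
  for (i in 1:25) {
    img <- random_small_image(10, values = 0:5)
    f <- build_filtration(img, sample(c("BW", "WB"), 1))
    p <- persistence(f)
    d1 <- p[p$dim == 1, ]
    for (j in seq_len(nrow(d1))) {
      loop <- d1$representative[[j]]
      expect_gte(nrow(loop), 4)
      nxt <- rbind(loop[-1, , drop = FALSE], loop[1, , drop = FALSE])
      step <- abs(loop - nxt)
      expect_true(all(rowSums(step) == 1))      # consecutive = 4-neighbours
      vals <- f$values[loop]
      evals <- pmax(vals, vals[c(2:length(vals), 1)])
      expect_true(all(evals <= d1$birth[j]))    # all loop edges present at birth
      # the loop must enclose at least one pixel not yet in the complex:
      # probe at half-pixel offsets so rays never graze vertices
      late <- which(f$values > d1$birth[j], arr.ind = TRUE)
      enclosed <- any(vapply(seq_len(nrow(late)), function(k) {
        inside_polygon(loop, late[k, 1] + 0.25, late[k, 2] + 0.25)
      }, logical(1)))
      expect_true(enclosed)
    }
  }
})

test_that("Euler identity holds at every level: V - E + S = beta0 - beta1", {
  set.seed(31)
  for (i in 1:10) {
    img <- random_small_image(8, values = 0:6)
    f <- build_filtration(img, "BW")
    p <- persistence(f, representatives = FALSE)
    b0 <- betti_curve(p, 0); b1 <- betti_curve(p, 1)
    v <- f$values
    H <- nrow(v); W <- ncol(v)
    ev <- pmax(v[, -W], v[, -1])                 # horizontal edge values
    eh <- pmax(v[-H, ], v[-1, ])                 # vertical edge values
    sq <- pmax(pmax(v[-H, -W], v[-H, -1]), pmax(v[-1, -W], v[-1, -1]))
    for (f_lev in 0:6) {
      euler <- sum(v <= f_lev) - (sum(ev <= f_lev) + sum(eh <= f_lev)) +
        sum(sq <= f_lev)
      expect_identical(euler,
                       b0$beta[f_lev + 1] - b1$beta[f_lev + 1])
    }
  }
})

test_that("dimension-0 bar count equals the number of local-minimum plateaus", {
  count_min_plateaus <- function(v) {
    H <- nrow(v); W <- ncol(v)
    n <- 0L
    seen <- matrix(FALSE, H, W)
    for (s in which(!seen)) {
      if (seen[s]) next
      # flood the constant-value plateau containing s
      val <- v[s]
      stack <- s; members <- integer(0); is_min <- TRUE
      while (length(stack)) {
        cur <- stack[[1]]; stack <- stack[-1]
        if (seen[cur]) next
        r <- (cur - 1) %% H + 1; c <- (cur - 1) %/% H + 1
        if (v[cur] != val) next
        seen[cur] <- TRUE; members <- c(members, cur)
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- r + d[1]; cc <- c + d[2]
          if (rr < 1 || rr > H || cc < 1 || cc > W) next
          nb <- (cc - 1) * H + rr
          if (v[nb] == val) { if (!seen[nb]) stack <- c(stack, nb) }
          else if (v[nb] < val) is_min <- FALSE
        }
      }
      if (is_min) n <- n + 1L
    }
    n
  }
  set.seed(41)
  for (i in 1:10) {
    img <- random_small_image(7, values = 0:4)
    p <- persistence(build_filtration(img, "BW"), representatives = FALSE)
    expect_identical(sum(p$dim == 0), count_min_plateaus(unclass(img)))
  }
})

test_that("persistence output ordering and direction metadata are stable", {
  img <- ring3()
  p1 <- persistence(build_filtration(img, "BW"))
  p2 <- persistence(build_filtration(img, "BW"))
  expect_identical(as.data.frame(p1[, 1:7]), as.data.frame(p2[, 1:7]))
  expect_identical(attr(p1, "direction"), "BW")
  expect_identical(attr(p1, "shape"), c(3L, 3L))
})
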