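test_that("reclassification is a pure relabeling and composes", {
  g <- land_grid(matrix(c(1, 2, 3, 4, 2, 1), 2, 3), cell_size = 1000)
  ident <- c(`1` = 1, `2` = 2, `3` = 3, `4` = 4)
  expect_equal(reclassify(g, ident)$values, g$values)
  # collapse 4 vegetation inputs to 3 habitat classes
  # (humid + littoral -> primary 0, degraded -> 1, other -> matrix 2)
  collapse <- c(`1` = 0, `2` = 0, `3` = 1, `4` = 2)
  out <- reclassify(g, collapse)
  expect_setequal(unique(as.vector(out$values)), c(0, 1, 2))
  # two compatible mappings equal the composed mapping
  first <- c(`1` = 10, `2` = 10, `3` = 30, `4` = 40)
  second <- c(`10` = 0, `30` = 1, `40` = 2)
  composed <- c(`1` = 0, `2` = 0, `3` = 1, `4` = 2)
  expect_equal(reclassify(reclassify(g, first), second)$values,
               reclassify(g, composed)$values)
  expect_error(reclassify(g, c(`1` = 0)), "2")
})

test_that("reclassify preserves nodata and georeferencing", {
  m <- matrix(c(1, NA, 2, 1), 2, 2)
  g <- land_grid(m, cell_size = 500, origin = c(10, 20))
  out <- reclassify(g, c(`1` = 5, `2` = 6))
  expect_true(is.na(out$values[2, 1]))
  expect_true(same_georef(out, g))
})

test_that("distance-to-features equals the brute-force minimum and is Lipschitz", {
  tmpl <- land_grid(matrix(0, 20, 20), cell_size = 1000)
  set.seed(4)
  pts <- data.frame(x = runif(5, 0, 20000), y = runif(5, 0, 20000))
  out <- distance_to_features(tmpl, pts)
  cc <- cell_centers(tmpl)
  brute <- matrix(Inf, 20, 20)
  for (k in 1:5)
    brute <- pmin(brute, sqrt((cc$x - pts$x[k])^2 + (cc$y - pts$y[k])^2))
  expect_equal(out$values, brute, tolerance = 1e-9)
  # 1-Lipschitz: orthogonal neighbors differ by <= cell size, diagonal by
  # <= cell size * sqrt(2)
  dx <- abs(diff(t(out$values))); dy <- abs(diff(out$values))
  expect_true(all(dx <= 1000 + 1e-9) && all(dy <= 1000 + 1e-9))
  dd <- abs(out$values[-1, -1] - out$values[-20, -20])
  expect_true(all(dd <= 1000 * sqrt(2) + 1e-9))
})

test_that("a feature at a cell center gives that cell distance zero", {
  tmpl <- land_grid(matrix(0, 3, 5), cell_size = 1000)
  out <- distance_to_features(tmpl, data.frame(x = 1500, y = 1500))
  expect_equal(out$values[2, 2], 0)   # center of cell (row 2, col 2)
  expect_equal(out$values[2, 3], 1000)
  expect_equal(out$values[2, 5], 3000)
  expect_error(distance_to_features(tmpl, data.frame(x = numeric(), y = numeric())),
               "feature")
})

test_that("TPI matches the naive per-cell loop oracle", {
  set.seed(6)
  dem <- land_grid(matrix(rnorm(100, 1000, 100), 10, 10), cell_size = 1000)
  dem$values[4, 7] <- NA
  out <- topographic_position_index(dem)
  v <- dem$values
  for (i in 1:10) for (j in 1:10) {
    if (is.na(v[i, j])) { expect_true(is.na(out$values[i, j])); next }
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= 10 && j2 >= 1 && j2 <= 10 && !is.na(v[i2, j2]))
        nb <- c(nb, v[i2, j2])
    }
    expect_equal(out$values[i, j], v[i, j] - mean(nb), tolerance = 1e-12)
  }
})

test_that("TPI of a flat DEM is zero and simple contrasts are exact", {
  flat <- land_grid(matrix(750, 6, 6), cell_size = 1000)
  expect_true(all(topographic_position_index(flat)$values == 0))
  m <- matrix(4, 3, 3); m[2, 2] <- 10
  peak <- land_grid(m, cell_size = 1000)
  expect_equal(topographic_position_index(peak)$values[2, 2], 6)
})

test_that("TPI on a linear ramp sums to ~0 over the interior", {
  ramp <- land_grid(matrix(rep(seq(0, 900, length.out = 10), each = 10), 10, 10),
                    cell_size = 1000)
  tpi <- topographic_position_index(ramp)
  expect_lt(abs(sum(tpi$values[2:9, 2:9])), 1e-9)
})

test_that("rasterized lines flag exactly the intersected cells", {
  tmpl <- land_grid(matrix(0, 5, 5), cell_size = 1000)
  # horizontal segment across the middle row (y = 2500 is row 3)
  horiz <- data.frame(line = 1, x = c(200, 4800), y = c(2500, 2500))
  out <- rasterize_lines(tmpl, horiz)
  expect_equal(out$values[3, ], rep(1, 5))
  expect_equal(sum(out$values), 5)
  expect_warning(rasterize_lines(tmpl, NULL), "empty")
  suppressWarnings(expect_true(all(rasterize_lines(tmpl, NULL)$values == 0)))
})

test_that("diagonal rasterization matches a dense point-sampling oracle", {
  tmpl <- land_grid(matrix(0, 5, 5), cell_size = 1000)
  seg <- data.frame(line = 1, x = c(300, 4700), y = c(600, 4100))
  out <- rasterize_lines(tmpl, seg)
  t <- seq(0, 1, length.out = 5000)
  px <- seg$x[1] + t * diff(seg$x); py <- seg$y[1] + t * diff(seg$y)
  idx <- locate_cells(tmpl, px, py)
  oracle <- matrix(0, 5, 5)
  oracle[unique(idx)] <- 1
  expect_equal(out$values, oracle)
})
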