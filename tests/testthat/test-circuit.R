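# hand-built grid_graph for closed-form circuit laws
manual_graph <- function(n, edges_i, edges_j, edge_res, focal) {
  structure(list(n_nodes = n, edges_i = edges_i, edges_j = edges_j,
                 diagonal = rep(FALSE, length(edges_i)),
                 node_id = matrix(seq_len(n), 1, n), focal = focal,
                 comp = rep(1L, n), cell_size = 1, origin = c(0, 0),
                 nodata = -9999, edge_res = edge_res),
            class = "grid_graph")
}

test_that("grid graph edges follow the average-resistance 8-neighbor scheme", {
  g <- land_grid(matrix(1, 1, 2), cell_size = 1)
  loc <- data.frame(name = c("a", "b"), x = c(0.5, 1.5), y = 0.5)
  gr <- build_grid_graph(g, loc)
  expect_equal(length(gr$edges_i), 1)
  expect_equal(gr$edge_res, 1)

  g2 <- land_grid(matrix(1, 2, 2), cell_size = 1)
  gr2 <- build_grid_graph(g2, data.frame(name = c("a", "b"),
                                         x = c(0.5, 1.5), y = c(0.5, 1.5)))
  expect_equal(length(gr2$edges_i), 6)
  expect_equal(sort(gr2$edge_res), sort(c(1, 1, 1, 1, sqrt(2), sqrt(2))))

  g3 <- land_grid(matrix(c(2, 4), 1, 2), cell_size = 1)
  gr3 <- build_grid_graph(g3, loc)
  expect_equal(gr3$edge_res, 3)
  g4 <- land_grid(matrix(c(2, NA, NA, 4), 2, 2), cell_size = 1)
  gr4 <- build_grid_graph(g4, data.frame(name = c("a", "b"),
                                         x = c(0.5, 1.5), y = c(1.5, 0.5)))
  expect_equal(gr4$edge_res, 3 * sqrt(2))
})

test_that("localities on nodata cells are rejected by name", {
  g <- land_grid(matrix(c(1, NA, 1, 1), 2, 2), cell_size = 1)
  loc <- data.frame(name = c("ok", "bad"), x = c(0.5, 0.5), y = c(1.5, 0.5))
  expect_error(build_grid_graph(g, loc), "bad")
})

test_that("series and parallel resistor laws hold exactly", {
  series <- land_grid(matrix(1, 1, 3), cell_size = 1)
  loc <- data.frame(name = c("a", "b"), x = c(0.5, 2.5), y = 0.5)
  expect_equal(effective_resistance(build_grid_graph(series, loc), "a", "b"), 2,
               tolerance = 1e-12)
  # two disjoint unit-resistance paths a-x-b and a-y-b, each path totalling 2
  par <- manual_graph(4, c(1, 3, 1, 4), c(3, 2, 4, 2), rep(1, 4),
                      c(a = 1, b = 2))
  expect_equal(effective_resistance(par, "a", "b"), 1, tolerance = 1e-12)
  # single two-edge parallel pair
  par2 <- manual_graph(2, c(1, 1), c(2, 2), c(1, 1), c(a = 1, b = 2))
  expect_equal(effective_resistance(par2, "a", "b"), 0.5, tolerance = 1e-12)
})

test_that("effective resistance matches the dense pseudoinverse oracle", {
  set.seed(13)
  for (rep in 1:3) {
    g <- land_grid(matrix(runif(36, 1, 100), 6, 6), cell_size = 1)
    if (rep == 3) g$values[c(8, 21)] <- NA   # keep <= 100 nodes, add holes
    loc <- data.frame(name = c("a", "b"), x = c(0.5, 5.5), y = c(0.5, 5.5))
    gr <- build_grid_graph(g, loc)
    got <- effective_resistance(gr, "a", "b")
    want <- oracle_effective_resistance(g, c(6, 1), c(1, 6))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("the resistance matrix reuses one solve consistently across pairs", {
  set.seed(14)
  g <- land_grid(matrix(runif(64, 1, 50), 8, 8), cell_size = 1)
  loc <- data.frame(name = c("a", "b", "c", "d"),
                    x = c(0.5, 7.5, 0.5, 7.5), y = c(0.5, 0.5, 7.5, 7.5))
  gr <- build_grid_graph(g, loc)
  R <- resistance_matrix(gr)
  for (pr in list(c("a", "b"), c("a", "d"), c("b", "c")))
    expect_equal(R[pr[1], pr[2]], effective_resistance(gr, pr[1], pr[2]),
                 tolerance = 1e-9)
  # linearity: scaling all cell resistances scales the matrix
  g2 <- land_grid(g$values * 7, cell_size = 1)
  R2 <- resistance_matrix(build_grid_graph(g2, loc))
  expect_equal(unclass(R2), unclass(R) * 7, tolerance = 1e-9)
})

test_that("uniform surfaces rank-order focal pairs like Euclidean distance", {
  g <- land_grid(matrix(1, 3, 12), cell_size = 1)
  # distinct pairwise separations (2, 4, 5, 6, 9, 11) avoid midrank ties
  loc <- data.frame(name = letters[1:4], x = c(0.5, 2.5, 6.5, 11.5), y = 1.5)
  R <- resistance_matrix(build_grid_graph(g, loc))
  E <- euclidean_matrix(loc)
  expect_equal(cor(pair_vector(R), pair_vector(E), method = "spearman"), 1)
})

test_that("effective resistance is a metric and obeys Rayleigh monotonicity", {
  set.seed(15)
  for (rep in 1:5) {
    g <- land_grid(matrix(runif(36, 1, 20), 6, 6), cell_size = 1)
    loc <- data.frame(name = c("a", "b", "c"),
                      x = c(0.5, 5.5, 2.5), y = c(0.5, 5.5, 3.5))
    R <- resistance_matrix(build_grid_graph(g, loc))
    expect_true(all(pair_vector(R) > 0))
    expect_lte(R["a", "b"], R["a", "c"] + R["c", "b"] + 1e-12)
    # raise one random cell's resistance: no pairwise resistance decreases
    g2 <- g; cell <- sample(36, 1)
    g2$values[cell] <- g2$values[cell] * 10
    R2 <- resistance_matrix(build_grid_graph(g2, loc))
    expect_true(all(pair_vector(R2) >= pair_vector(R) - 1e-10))
  }
})

test_that("disconnected focal pairs yield an explicit infinite marker", {
  m <- matrix(1, 3, 3); m[, 2] <- NA
  g <- land_grid(m, cell_size = 1)
  loc <- data.frame(name = c("l", "r"), x = c(0.5, 2.5), y = 1.5)
  gr <- build_grid_graph(g, loc)
  expect_identical(effective_resistance(gr, "l", "r"), Inf)
  R <- resistance_matrix(gr)
  expect_identical(R["l", "r"], Inf)
})

test_that("current maps satisfy Kirchhoff conservation and symmetric splits", {
  series <- land_grid(matrix(1, 1, 3), cell_size = 1)
  loc <- data.frame(name = c("a", "b"), x = c(0.5, 2.5), y = 0.5)
  cm <- current_map(build_grid_graph(series, loc))
  expect_equal(cm$values[1, ], c(1, 1, 1), tolerance = 1e-12)
  # interior nodes of two disjoint parallel paths each carry half the current
  par <- manual_graph(4, c(1, 3, 1, 4), c(3, 2, 4, 2), rep(1, 4),
                      c(a = 1, b = 2))
  cmp <- current_map(par)
  expect_equal(as.vector(cmp$values), c(1, 1, 0.5, 0.5), tolerance = 1e-12)
  # conservation audit on a two-class 8x8 surface: for every focal pair the
  # net current at each non-focal node is ~0 (checked via L v = b residual)
  cls <- gen_categorical_landscape(8, 8, 2, smoothness = 2, seed = 5)
  surf <- apply_categorical(cls, categorical_spec("h", c(`0` = 1, `1` = 40)))
  loc2 <- place_localities(cls, 3, class = 0, min_sep_cells = 2, seed = 2)
  gr <- build_grid_graph(surf, loc2)
  L <- landres:::.graph_laplacian(gr)
  sol <- landres:::.solve_component(gr, L, unname(gr$focal),
                                    want_potentials = TRUE)
  for (i in 1:2) for (j in (i + 1):3) {
    v <- sol$V[, i] - sol$V[, j]
    net <- as.numeric(L %*% v)
    b <- rep(0, gr$n_nodes)
    b[gr$focal[i]] <- 1; b[gr$focal[j]] <- -1
    expect_lt(max(abs(net - b)), 1e-10)
  }
})
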