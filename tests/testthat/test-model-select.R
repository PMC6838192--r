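test_that("subsample size is the floor of the fraction with a floor of 3", {
  expect_equal(subsample_size(18, 0.75), 13L)
  expect_equal(subsample_size(4, 0.75), 3L)
  expect_equal(subsample_size(100, 0.75), 75L)
  expect_error(subsample_size(4, 0.5), "too small")
  expect_error(subsample_size(18, 1.2), "fraction")
  expect_error(subsample_size(3, 0.75), ">= 4")
})

# fixed small model set used by several blocks
select_fixture <- function(seed = 51, n_loc = 12) {
  scen <- tiny_scenario(seed = seed, n_loc = n_loc, rows = 20)
  d <- gen_genetic_distances(scen)
  euclid <- euclidean_matrix(scen$localities)
  list(scen = scen, genetic = d$genetic, true_R = d$resistance, euclid = euclid)
}

test_that("a single-model set is degenerate: rank 1, weight 1, pi_hat 1", {
  fx <- select_fixture()
  bs <- bootstrap_select(list(only = fx$true_R), fx$genetic, c(only = 4L),
                         n_iterations = 20, seed = 1)
  expect_equal(bs$table$avg_rank, 1)
  expect_equal(bs$table$omega_bar, 1)
  expect_equal(bs$table$pi_hat, 1)
})

test_that("bootstrap selection favors the generating surface and is reproducible", {
  fx <- select_fixture()
  models <- list(true_surface = fx$true_R, euclidean = fx$euclid)
  Kv <- c(true_surface = 4L, euclidean = 2L)
  bs1 <- bootstrap_select(models, fx$genetic, Kv, n_iterations = 200, seed = 7)
  bs2 <- bootstrap_select(models, fx$genetic, Kv, n_iterations = 200, seed = 7)
  expect_identical(bs1$table, bs2$table)
  tab <- bs1$table
  expect_equal(sum(tab$pi_hat), 1, tolerance = 1e-12)
  expect_true(all(tab$omega_bar >= 0 & tab$omega_bar <= 1))
  expect_true(all(tab$avg_rank >= 1 & tab$avg_rank <= 2))
  # AICc penalizes the K = 4 surface hard at 9-locality subsamples, so a
  # clear win here reflects genuine signal, not bookkeeping
  expect_gt(tab$pi_hat[tab$surface == "true_surface"], 0.9)
})

test_that("identical duplicate models resolve by the deterministic tie-break", {
  fx <- select_fixture(52)
  bs <- bootstrap_select(list(alpha = fx$true_R, beta = fx$true_R),
                         fx$genetic, c(alpha = 4L, beta = 4L),
                         n_iterations = 50, seed = 2)
  tab <- bs$table
  # equal AICc every iteration; lexical order always puts alpha first
  expect_equal(tab$pi_hat[tab$surface == "alpha"], 1)
  expect_equal(tab$pi_hat[tab$surface == "beta"], 0)
  expect_equal(sum(tab$pi_hat), 1)
  expect_equal(tab$avg_rank[tab$surface == "alpha"], 1)
})

test_that("Spearman correlation uses midranks and hits the antitone bound", {
  fx <- select_fixture(53)
  expect_equal(spearman_correlation(fx$true_R, fx$true_R), 1)
  rev_m <- max(fx$true_R) - unclass(fx$true_R)
  diag(rev_m) <- 0
  rev <- pairwise_matrix(rev_m, kind = "resistance")
  expect_equal(spearman_correlation(fx$true_R, rev), -1)
  # hand-computed midrank fixture with one tie:
  # pair vectors a = (1, 2, 2) -> midranks (1, 2.5, 2.5); b = (10, 30, 20)
  # -> ranks (1, 3, 2); Pearson of the rank vectors = 1.5/sqrt(3)
  a <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  b <- a
  a[1, 2] <- a[2, 1] <- 1; a[1, 3] <- a[3, 1] <- 2; a[2, 3] <- a[3, 2] <- 2
  b[1, 2] <- b[2, 1] <- 10; b[1, 3] <- b[3, 1] <- 30; b[2, 3] <- b[3, 2] <- 20
  got <- spearman_correlation(pairwise_matrix(a, kind = "resistance"),
                              pairwise_matrix(b, kind = "resistance"))
  expect_equal(got, 1.5 / sqrt(3), tolerance = 1e-12)
})

test_that("composite candidacy needs pi_hat above Euclidean and the 1% floor", {
  mk <- function(pi) {
    structure(list(table = data.frame(
      surface = names(pi), K = 3L, avg_rank = 1, omega_bar = pi,
      pi_hat = unname(pi))), class = "bootstrap_summary")
  }
  expect_setequal(
    composite_candidates(mk(c(A = 0.56, B = 0.44, euclidean = 0)), "euclidean"),
    c("A", "B"))
  expect_equal(
    composite_candidates(mk(c(A = 0.995, B = 0.005, euclidean = 0)), "euclidean"),
    "A")
  expect_length(
    composite_candidates(mk(c(A = 0.0, B = 0.0, euclidean = 1.0)), "euclidean"),
    0)
  expect_error(composite_candidates(mk(c(A = 1)), "euclidean"), "null")
})

test_that("a dominating model's pi_hat converges to 1 with more iterations", {
  fx <- select_fixture(54)
  # strengthen domination: noise-free response equal to the true predictor
  rv <- pair_vector(fx$true_R)
  yv <- (rv - mean(rv)) / sd(rv)
  n <- nrow(fx$true_R)
  y <- matrix(0, n, n, dimnames = dimnames(fx$true_R))
  idx <- combn(n, 2)
  y[t(idx)] <- yv; y[t(idx[2:1, ])] <- yv
  y <- pairwise_matrix(y, kind = "genetic")
  models <- list(true_surface = fx$true_R, euclidean = fx$euclid)
  Kv <- c(true_surface = 4L, euclidean = 2L)
  bs <- bootstrap_select(models, y, Kv, n_iterations = 150, seed = 3)
  expect_equal(bs$table$pi_hat[bs$table$surface == "true_surface"], 1)
})
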