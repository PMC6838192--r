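test_that("MLPE incidence structure has two unit entries per pair", {
  Z <- mlpe_design(c("A", "B", "C"))
  expect_equal(unname(Z), rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
  Z8 <- mlpe_design(paste0("P", 1:8))
  expect_true(all(rowSums(Z8) == 2))
  M <- tcrossprod(Z8)
  expect_true(all(diag(M) == 2))
  expect_true(all(M[upper.tri(M)] %in% c(0, 1)))
  expect_error(mlpe_design(c("A", "B")), "3")
})

# deterministic pairwise fixture over 4 localities
fixture_pair_matrices <- function(seed = 31) {
  set.seed(seed)
  loc <- data.frame(name = c("A", "B", "C", "D"),
                    x = runif(4, 0, 1e4), y = runif(4, 0, 1e4))
  x <- euclidean_matrix(loc)
  xv <- pair_vector(x)
  Z <- mlpe_design(loc$name)
  u <- rnorm(4, 0, 0.1)
  yv <- 0.1 + 0.002 * scale(xv)[, 1] + as.numeric(Z %*% u) + rnorm(6, 0, 0.03)
  y <- matrix(0, 4, 4, dimnames = list(loc$name, loc$name))
  idx <- combn(4, 2)
  y[t(idx)] <- yv; y[t(idx[2:1, ])] <- yv
  list(y = pairwise_matrix(y, kind = "genetic"), x = x)
}

test_that("fitted log-likelihood matches the dense multivariate-normal oracle", {
  fx <- fixture_pair_matrices()
  fit <- fit_mlpe(fx$y, fx$x)
  mu <- fit$beta0 + fit$beta1 * fit$x_std
  ll <- oracle_mlpe_loglik(fit$y, mu, fit$Z, fit$sigma_u2, fit$sigma_e2)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("the sigma_u^2 = 0 boundary of the profile equals the OLS likelihood", {
  fx <- fixture_pair_matrices(32)
  yv <- pair_vector(fx$y); xv <- pair_vector(fx$x)
  xs <- (xv - mean(xv)) / sd(xv)
  Z <- mlpe_design(rownames(fx$y))
  eig <- eigen(tcrossprod(Z), symmetric = TRUE)
  prof <- landres:::.mlpe_profile(as.numeric(crossprod(eig$vectors, yv)),
                                  crossprod(eig$vectors, cbind(1, xs)),
                                  pmax(eig$values, 0))
  expect_equal(prof(0)$loglik, as.numeric(logLik(lm(yv ~ xs))),
               tolerance = 1e-6)
  # and the ML fit can never fall below that boundary
  fit <- fit_mlpe(fx$y, fx$x)
  expect_gte(fit$loglik, prof(0)$loglik - 1e-9)
})

test_that("beta1 is invariant to affine rescaling of the raw predictor", {
  fx <- fixture_pair_matrices(33)
  f1 <- fit_mlpe(fx$y, fx$x)
  x2 <- pairwise_matrix(unclass(fx$x) * 3.7, kind = "euclidean")
  f2 <- fit_mlpe(fx$y, x2)
  expect_equal(f1$beta1, f2$beta1, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("MLPE recovers the generating slope over replicates", {
  set.seed(41)
  loc <- data.frame(name = sprintf("P%02d", 1:18),
                    x = runif(18, 0, 1e5), y = runif(18, 0, 1e5))
  x <- euclidean_matrix(loc)
  xv <- pair_vector(x); xs <- (xv - mean(xv)) / sd(xv)
  Z <- mlpe_design(loc$name)
  idx <- combn(18, 2)
  est <- replicate(200, {
    yv <- 0.2 + 0.8 * xs + as.numeric(Z %*% rnorm(18, 0, 0.05)) +
      rnorm(153, 0, 0.05)
    y <- matrix(0, 18, 18, dimnames = list(loc$name, loc$name))
    y[t(idx)] <- yv; y[t(idx[2:1, ])] <- yv
    fit_mlpe(pairwise_matrix(y, kind = "genetic"), x)$beta1
  })
  expect_lt(abs(mean(est) - 0.8), 0.05)
})

test_that("infinite resistance entries are refused, not imputed", {
  fx <- fixture_pair_matrices(34)
  xb <- unclass(fx$x); xb[1, 2] <- xb[2, 1] <- Inf
  expect_error(fit_mlpe(fx$y, pairwise_matrix(xb, kind = "resistance")),
               "non-finite")
})

test_that("AICc follows the small-sample formula on the population count", {
  expect_equal(aicc(-10, K = 2, n_eff = 18), 24.8)
  expect_gt(aicc(-10, K = 5, n_eff = 18), aicc(-10, K = 3, n_eff = 18))
  expect_equal(aicc(-10, K = 2, n_eff = 1e9), 2 * 10 + 2 * 2, tolerance = 1e-6)
  expect_error(aicc(-10, K = 17, n_eff = 18), "undefined")
})

test_that("the surface K convention reproduces the model-table bookkeeping", {
  cat3 <- categorical_spec("cover", c(`0` = 1, `1` = 50, `2` = 300))
  cat2 <- categorical_spec("rivers", c(`0` = 1, `1` = 100))
  cont <- continuous_spec("village", "monomolecular", 2, 500)
  expect_equal(surface_K(cat3), 4L)
  expect_equal(surface_K(cat2), 3L)
  expect_equal(surface_K(cont), 3L)
  expect_equal(surface_K("euclidean"), 2L)
  expect_equal(surface_K(composite_spec(list(cat3, cont))), 7L)
})

test_that("Akaike weights behave under symmetry, shift and degeneracy", {
  expect_equal(unname(akaike_weights(c(100, 100))), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(round(unname(w), 3), c(0.731, 0.269))
  expect_equal(unname(akaike_weights(42)), 1)
  set.seed(9)
  ws <- akaike_weights(runif(6, 50, 80))
  expect_equal(sum(ws), 1, tolerance = 1e-12)
  expect_gte(max(ws), 1 / 6)
})

test_that("mlpe_fit methods are mutually consistent", {
  fx <- fixture_pair_matrices(35)
  fit <- fit_mlpe(fx$y, fx$x, K = 3)
  expect_equal(unname(coef(fit)), c(fit$beta0, fit$beta1))
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(predict(fit), fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(6L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 2))
  expect_output(print(summary(fit)), "var components")
})
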