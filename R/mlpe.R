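#' Pair-to-population incidence structure for the MLPE model
#'
#' One row per unordered pair of localities (in [pair_vector()] order), with
#' unit entries in the two columns of the pair's populations. With random
#' population effects `u ~ N(0, sigma_u^2 I)`, `Zu` induces the MLPE
#' covariance: `Var(y_p) = 2 sigma_u^2 + sigma_e^2` and
#' `Cov(y_p, y_q) = sigma_u^2 x (number of shared populations)`.
#'
#' @param localities ordered character vector of locality names (>= 3).
#' @return p x n incidence matrix, p = n(n-1)/2.
#' @export
mlpe_design <- function(localities) {
  n <- length(localities)
  if (n < 3L) stop("MLPE needs >= 3 localities (model unidentifiable below)")
  idx <- utils::combn(n, 2L)
  p <- ncol(idx)
  Z <- matrix(0, p, n, dimnames = list(NULL, localities))
  Z[cbind(seq_len(p), idx[1L, ])] <- 1
  Z[cbind(seq_len(p), idx[2L, ])] <- 1
  Z
}

# profile log-likelihood machinery: with V = sigma_e^2 (I + lambda ZZ'),
# beta and sigma_e^2 have closed forms given lambda. One symmetric
# eigendecomposition of ZZ' serves every lambda.
.mlpe_profile <- function(ty, TX, lam_eigs) {
  p <- length(ty)
  function(lambda) {
    w <- 1 / (1 + lambda * lam_eigs)
    A <- crossprod(TX, w * TX)
    b <- crossprod(TX, w * ty)
    beta <- solve(A, b)
    r <- ty - TX %*% beta
    s2 <- sum(w * r^2) / p
    ll <- -0.5 * (p * log(2 * pi * s2) + p + sum(log1p(lambda * lam_eigs)))
    list(loglik = ll, beta = as.numeric(beta), sigma_e2 = s2,
         sigma_u2 = lambda * s2)
  }
}

#' Fit a maximum-likelihood population-effects (MLPE) mixed model
#'
#' Regresses pairwise genetic distance on one pairwise predictor (effective
#' resistance or Euclidean distance) while accounting for the
#' non-independence of pairs that share a population. The model is
#' `y = beta0 + beta1 * x_std + Z u + e` with `u ~ N(0, sigma_u^2 I_n)` over
#' populations, `e ~ N(0, sigma_e^2 I_p)` over pairs, and Z the
#' [mlpe_design()] incidence. Fitting is by maximum likelihood (not REML):
#' beta and `sigma_e^2` are profiled out analytically and the variance ratio
#' `lambda = sigma_u^2 / sigma_e^2` is optimized in one dimension, always
#' comparing the interior optimum against the `lambda = 0` boundary (the OLS
#' limit) and keeping the better.
#'
#' The predictor is standardized internally (z-score over pairs), so
#' `beta1` is in genetic-distance units per SD of the predictor and is
#' invariant to affine rescaling of the raw predictor.
#'
#' @param y `pairwise_matrix` of genetic distances.
#' @param x `pairwise_matrix` predictor over the same localities (no
#'   infinite entries: disconnected landscapes are refused, not imputed).
#' @param K parameter count used for AICc, following the surface convention
#'   of [surface_K()] (default 2, the Euclidean-null convention).
#' @param n_eff effective sample size for AICc; defaults to the number of
#'   populations (pairwise observations are not independent).
#' @return object of class `mlpe_fit`.
#' @export
fit_mlpe <- function(y, x, K = 2, n_eff = NULL) {
  if (!setequal(rownames(y), rownames(x))) stop("locality sets differ")
  x <- restrict_pairwise(x, rownames(y))
  yv <- pair_vector(y); xv <- pair_vector(x)
  if (any(!is.finite(xv)))
    stop("predictor contains non-finite entries (disconnected localities?)")
  if (any(!is.finite(yv))) stop("response contains non-finite entries")
  n <- nrow(y); p <- length(yv)
  xsd <- stats::sd(xv)
  if (xsd == 0) stop("predictor has zero variance across pairs")
  xs <- (xv - mean(xv)) / xsd
  Z <- mlpe_design(rownames(y))
  M <- tcrossprod(Z)
  eig <- eigen(M, symmetric = TRUE)
  X <- cbind(`(Intercept)` = 1, x_std = xs)
  ty <- crossprod(eig$vectors, yv)
  TX <- crossprod(eig$vectors, X)
  prof <- .mlpe_profile(as.numeric(ty), TX, pmax(eig$values, 0))

  at0 <- prof(0)
  opt <- stats::optimize(function(lg) prof(exp(lg))$loglik,
                         interval = c(-12, 12), maximum = TRUE, tol = 1e-9)
  atopt <- prof(exp(opt$maximum))
  best <- if (atopt$loglik > at0$loglik) atopt else at0

  n_eff <- if (is.null(n_eff)) n else n_eff
  fit <- structure(
    list(beta0 = best$beta[1], beta1 = best$beta[2],
         sigma_u2 = best$sigma_u2, sigma_e2 = best$sigma_e2,
         loglik = best$loglik, K = K, n_pops = n, n_pairs = p,
         n_eff = n_eff,
         localities = rownames(y), y = yv, x_std = xs,
         x_center = mean(xv), x_scale = xsd, Z = Z),
    class = "mlpe_fit")
  fit$aicc <- if (n_eff > K + 1) aicc(fit) else NA_real_
  fit
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 loglik + 2K + 2K(K+1) / (n - K - 1)` with effective sample
#' size n = number of populations (not pairs): pairwise observations are
#' non-independent, and the population count is the replication unit.
#'
#' @param fit an `mlpe_fit`, or a numeric log-likelihood.
#' @param K parameter count (ignored when `fit` is an `mlpe_fit`).
#' @param n_eff effective sample size (ignored when `fit` is an `mlpe_fit`).
#' @return AICc value.
#' @export
aicc <- function(fit, K = NULL, n_eff = NULL) {
  if (inherits(fit, "mlpe_fit")) {
    ll <- fit$loglik; K <- fit$K; n_eff <- fit$n_eff
  } else ll <- fit
  if (n_eff <= K + 1)
    stop("AICc undefined: effective sample size ", n_eff,
         " must exceed K + 1 = ", K + 1)
  -2 * ll + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Parameter count (K) of a resistance surface for AICc
#'
#' The convention reconciling a bootstrap model-selection table: the
#' Euclidean-distance null has K = 2; a categorical surface has K = number
#' of categories + 1; a continuous transformation has K = 3 (shape, maximum,
#' + 1); a composite is the sum of its components.
#'
#' @param spec a `resistance_spec`/`composite_spec`, or the string
#'   `"euclidean"` for the null model.
#' @return integer K.
#' @export
surface_K <- function(spec) {
  if (is.character(spec) && identical(tolower(spec), "euclidean")) return(2L)
  stopifnot(inherits(spec, "resistance_spec"))
  if (spec$kind == "composite")
    return(sum(vapply(spec$components, surface_K, integer(1))))
  if (spec$kind == "categorical") length(spec$values) + 1L else 3L
}

#' Akaike weights from AICc values
#'
#' `w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2))` with
#' `Delta_m = AICc_m - min(AICc)`.
#'
#' @param aicc_values numeric vector (names kept).
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat("MLPE mixed model (ML fit)\n")
  cat(sprintf("  %d populations, %d pairs\n", x$n_pops, x$n_pairs))
  cat(sprintf("  beta0 = %.4f, beta1 = %.4f (per SD of predictor)\n",
              x$beta0, x$beta1))
  cat(sprintf("  sigma_u^2 = %.5f, sigma_e^2 = %.5f\n", x$sigma_u2, x$sigma_e2))
  cat(sprintf("  logLik = %.3f, K = %d, AICc = %s\n", x$loglik, x$K,
              ifelse(is.na(x$aicc), "NA", sprintf("%.3f", x$aicc))))
  invisible(x)
}

#' @export
summary.mlpe_fit <- function(object, ...) {
  out <- object[c("beta0", "beta1", "sigma_u2", "sigma_e2", "loglik", "K",
                  "aicc", "n_pops", "n_pairs")]
  out$icc <- 2 * object$sigma_u2 / (2 * object$sigma_u2 + object$sigma_e2)
  class(out) <- "summary.mlpe_fit"
  out
}

#' @export
print.summary.mlpe_fit <- function(x, ...) {
  cat(sprintf(
    "MLPE fit: beta0 = %.4f, beta1 = %.4f\n  var components: sigma_u^2 = %.5f, sigma_e^2 = %.5f (pair ICC = %.3f)\n  logLik = %.3f, K = %d, AICc = %s (n = %d populations, %d pairs)\n",
    x$beta0, x$beta1, x$sigma_u2, x$sigma_e2, x$icc, x$loglik, x$K,
    ifelse(is.na(x$aicc), "NA", sprintf("%.3f", x$aicc)), x$n_pops, x$n_pairs))
  invisible(x)
}

#' @export
coef.mlpe_fit <- function(object, ...)
  c(beta0 = object$beta0, beta1 = object$beta1)

#' @export
logLik.mlpe_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n_pairs,
            class = "logLik")
}

#' @param newdata optional `pairwise_matrix` of the raw predictor; default
#'   the training pairs.
#' @rdname fit_mlpe
#' @export
predict.mlpe_fit <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$x_std
        else (pair_vector(newdata) - object$x_center) / object$x_scale
  object$beta0 + object$beta1 * xs
}

#' @export
residuals.mlpe_fit <- function(object, ...)
  object$y - (object$beta0 + object$beta1 * object$x_std)

#' @export
fitted.mlpe_fit <- function(object, ...)
  object$beta0 + object$beta1 * object$x_std

#' @export
simulate.mlpe_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  mu <- object$beta0 + object$beta1 * object$x_std
  n <- object$n_pops; p <- object$n_pairs
  out <- replicate(nsim, {
    u <- stats::rnorm(n, 0, sqrt(object$sigma_u2))
    mu + as.numeric(object$Z %*% u) + stats::rnorm(p, 0, sqrt(object$sigma_e2))
  })
  as.data.frame(out)
}
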