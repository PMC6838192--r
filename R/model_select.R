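#' Bootstrap subsample size
#'
#' `floor(fraction * n)` localities, e.g. 75% of 18 localities = 13. At
#' least 3 localities must remain for the MLPE model to be identifiable.
#'
#' @param n_localities total localities (>= 4).
#' @param fraction subsample fraction in (0, 1).
#' @return integer subsample size.
#' @export
subsample_size <- function(n_localities, fraction = 0.75) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (n_localities < 4L) stop("need >= 4 localities")
  k <- as.integer(floor(fraction * n_localities))
  if (k < 3L) stop("subsample of ", k, " localities is too small (< 3)")
  k
}

#' Bootstrap AICc model selection across optimized surfaces
#'
#' Per iteration, a fraction of the localities is sampled without
#' replacement; every model's pre-optimized distance matrix is restricted
#' to the induced pairs and refit by MLPE (no re-optimization); AICc ranks
#' (1 = best) and Akaike weights are computed; results are aggregated into
#' the average rank, the average weight (omega-bar) and the top-model
#' frequency (pi-hat). AICc ties are broken by smaller K, then model name.
#'
#' @param models named list of `pairwise_matrix` predictors (the optimized
#'   resistance surfaces plus the Euclidean null), all over the same
#'   localities.
#' @param genetic `pairwise_matrix` of genetic distances.
#' @param K named integer vector of parameter counts, one per model.
#' @param n_iterations bootstrap iterations (paper-scale default 10000).
#' @param fraction locality fraction per iteration.
#' @param seed integer seed.
#' @return object of class `bootstrap_summary`: data.frame `table` with
#'   columns `surface`, `K`, `avg_rank`, `omega_bar`, `pi_hat`, plus run
#'   metadata.
#' @export
bootstrap_select <- function(models, genetic, K, n_iterations = 10000,
                             fraction = 0.75, seed = 1) {
  if (length(models) < 1L) stop("need >= 1 model")
  nms <- names(models)
  if (is.null(nms) || any(!nzchar(nms))) stop("models must be named")
  if (!all(nms %in% names(K))) stop("K must be named for every model")
  K <- K[nms]
  locs <- rownames(genetic)
  for (m in models)
    if (!setequal(rownames(m), locs)) stop("all matrices must share one locality set")
  n <- length(locs)
  k_sub <- subsample_size(n, fraction)
  M <- length(models)
  # tie-break order: smaller K first, then lexical name
  tie_order <- order(K, nms)

  ranks_sum <- stats::setNames(numeric(M), nms)
  w_sum <- stats::setNames(numeric(M), nms)
  top_cnt <- stats::setNames(numeric(M), nms)
  dropped <- 0L

  .with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      sub <- sample(locs, k_sub)
      res <- tryCatch({
        av <- vapply(nms, function(nm) {
          fit <- fit_mlpe(restrict_pairwise(genetic, sub),
                          restrict_pairwise(models[[nm]], sub),
                          K = K[[nm]])
          aicc(fit)
        }, numeric(1))
        av
      }, error = function(e) NULL)
      if (is.null(res)) { dropped <- dropped + 1L; next }
      # deterministic rank: AICc, then smaller K, then name
      ord <- order(res, match(seq_len(M), tie_order))
      rk <- integer(M); rk[ord] <- seq_len(M)
      ranks_sum <- ranks_sum + rk
      w_sum <- w_sum + akaike_weights(res)
      top_cnt[ord[1]] <- top_cnt[ord[1]] + 1
    }
  })
  used <- n_iterations - dropped
  if (dropped > 0.01 * n_iterations)
    stop("more than 1% of bootstrap iterations failed (", dropped, " of ",
         n_iterations, ")")
  tab <- data.frame(surface = nms, K = as.integer(K),
                    avg_rank = ranks_sum / used,
                    omega_bar = w_sum / used,
                    pi_hat = top_cnt / used, row.names = NULL)
  tab <- tab[order(tab$avg_rank), ]
  structure(list(table = tab, n_iterations = n_iterations,
                 subsample_size = k_sub, dropped = dropped, seed = seed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "Bootstrap model selection: %d iterations, %d localities per subsample (%d dropped)\n",
    x$n_iterations, x$subsample_size, x$dropped))
  tab <- x$table
  tab$avg_rank <- round(tab$avg_rank, 3)
  tab$omega_bar <- round(tab$omega_bar, 4)
  tab$pi_hat <- round(tab$pi_hat, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation between two pairwise matrices
#'
#' Rank correlation (midrank ties) over the unordered-pair vectors; used to
#' assess redundancy between top single surfaces before building composites.
#'
#' @param a,b `pairwise_matrix` objects over the same localities.
#' @return Spearman's rho.
#' @export
spearman_correlation <- function(a, b) {
  if (!setequal(rownames(a), rownames(b))) stop("locality sets differ")
  b <- restrict_pairwise(b, rownames(a))
  av <- pair_vector(a); bv <- pair_vector(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("constant pair vector; rank correlation undefined")
  stats::cor(av, bv, method = "spearman")
}

#' Surfaces eligible for composite construction
#'
#' Returns surfaces whose top-model frequency exceeds both the Euclidean
#' null's and the 1% floor (`pi_hat > pi_hat(euclidean)` and
#' `pi_hat > 0.01`).
#'
#' @param summary a `bootstrap_summary`.
#' @param euclidean_name name of the Euclidean null model in the summary.
#' @return character vector of surface names (possibly empty).
#' @export
composite_candidates <- function(summary, euclidean_name = "euclidean") {
  tab <- summary$table
  if (!euclidean_name %in% tab$surface)
    stop("Euclidean null '", euclidean_name, "' not in summary")
  pe <- tab$pi_hat[tab$surface == euclidean_name]
  sel <- tab$surface[tab$pi_hat > pe & tab$pi_hat > 0.01 &
                     tab$surface != euclidean_name]
  as.character(sel)
}

#' Write a bootstrap summary as CSV (model-selection table layout)
#' @param summary a `bootstrap_summary`.
#' @param path file path.
#' @export
write_selection_csv <- function(summary, path) {
  utils::write.csv(summary$table, path, row.names = FALSE)
  invisible(path)
}
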