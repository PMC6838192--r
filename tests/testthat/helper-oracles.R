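# Independent oracles used across tests. These deliberately re-derive each
# quantity by a different route than the package (explicit loops, dense
# algebra) so agreement is evidence, not tautology.

# Weir & Cockerham (1984) theta via explicit per-population loops.
# tab: genotype_table; pops: labels to include (NULL = all).
oracle_wc_theta <- function(tab, pops = NULL) {
  keep <- if (is.null(pops)) rep(TRUE, length(tab$ids)) else tab$pops %in% pops
  A <- B <- C <- 0
  for (l in seq_along(tab$loci)) {
    g <- tab$alleles[keep, l, , drop = FALSE]
    pop <- tab$pops[keep]
    ok <- !is.na(g[, 1, 1])
    g1 <- g[ok, 1, 1]; g2 <- g[ok, 1, 2]; pp <- pop[ok]
    pls <- unique(pp)
    r <- length(pls)
    if (r < 2) next
    n_i <- sapply(pls, function(q) sum(pp == q))
    alleles <- unique(c(g1, g2))
    if (length(alleles) < 2) next
    n_bar <- mean(n_i)
    n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in alleles) {
      p_i <- h_i <- numeric(r)
      for (q in seq_len(r)) {
        rows <- pp == pls[q]
        p_i[q] <- (sum(g1[rows] == al) + sum(g2[rows] == al)) / (2 * n_i[q])
        h_i[q] <- sum((g1[rows] == al) != (g2[rows] == al)) / n_i[q]
      }
      p_bar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / sum(n_i)
      a <- n_bar / n_c *
        (s2 - 1 / (n_bar - 1) *
           (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
      b <- n_bar / (n_bar - 1) *
        (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
           (2 * n_bar - 1) / (4 * n_bar) * h_bar)
      cc <- h_bar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  A / (A + B + C)
}

# random small genotype table for property tests
random_genotype_table <- function(n_pops = 3, n_ind = 5, n_loci = 3,
                                  n_alleles = 4, miss_rate = 0.1) {
  n <- n_pops * n_ind
  a <- array(sample.int(n_alleles, n * n_loci * 2, replace = TRUE),
             dim = c(n, n_loci, 2))
  drop <- matrix(runif(n * n_loci) < miss_rate, n, n_loci)
  for (l in seq_len(n_loci)) {
    a[drop[, l], l, 1] <- NA_integer_
    a[drop[, l], l, 2] <- NA_integer_
  }
  genotype_table(paste0("i", 1:n), rep(paste0("p", 1:n_pops), each = n_ind), a)
}

# Moore-Penrose pseudoinverse via eigendecomposition (dense Laplacian oracle)
oracle_pinv <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
}

# dense 8-neighbor Laplacian built cell-by-cell from a land_grid (NA skipped)
oracle_grid_laplacian <- function(grid) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  id <- matrix(NA_integer_, nr, nc)
  id[!is.na(v)] <- seq_len(sum(!is.na(v)))
  n <- sum(!is.na(v))
  L <- matrix(0, n, n)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc || is.na(v[i2, j2])) next
      er <- (v[i, j] + v[i2, j2]) / 2
      if (di != 0 && dj != 0) er <- er * sqrt(2)
      L[id[i, j], id[i2, j2]] <- -1 / er
    }
  }
  diag(L) <- -rowSums(L)
  list(L = L, id = id)
}

# effective resistance between two cells from the dense pseudoinverse
oracle_effective_resistance <- function(grid, cell_a, cell_b) {
  o <- oracle_grid_laplacian(grid)
  a <- o$id[cell_a[1], cell_a[2]]; b <- o$id[cell_b[1], cell_b[2]]
  e <- rep(0, nrow(o$L)); e[a] <- 1; e[b] <- -1
  drop(t(e) %*% oracle_pinv(o$L) %*% e)
}

# dense multivariate-normal log density with MLPE covariance
oracle_mlpe_loglik <- function(y, mu, Z, sigma_u2, sigma_e2) {
  V <- sigma_u2 * tcrossprod(Z) + sigma_e2 * diag(length(y))
  r <- y - mu
  -0.5 * (length(y) * log(2 * pi) + determinant(V)$modulus[1] +
            drop(t(r) %*% solve(V) %*% r))
}

# a small fully-connected scenario for reuse (kept tiny for speed)
tiny_scenario <- function(seed = 3, n_loc = 8, rows = 20)
  synthetic_scenario(grid_rows = rows, grid_cols = rows, n_localities = n_loc,
                     seed = seed)
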