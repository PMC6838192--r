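#' Diploid multi-locus genotype table
#'
#' Stores diploid genotypes for a set of individuals grouped into
#' populations. Alleles are positive integers; missing data is `NA` (written
#' as 0 in CSV, the usual microsatellite convention).
#'
#' @param ids character vector of individual ids.
#' @param pops character vector of population labels, same length.
#' @param alleles integer array of dim (n_individuals, n_loci, 2).
#' @param loci optional locus names.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(ids, pops, alleles, loci = NULL) {
  stopifnot(length(dim(alleles)) == 3L, dim(alleles)[3] == 2L,
            dim(alleles)[1] == length(ids), length(pops) == length(ids))
  if (any(!nzchar(pops)) || anyNA(pops)) stop("population labels must be nonempty")
  if (any(alleles <= 0, na.rm = TRUE)) stop("alleles must be positive integers")
  if (is.null(loci)) loci <- paste0("loc", seq_len(dim(alleles)[2]))
  # an individual is genotyped at a locus only if both allele slots are present
  half <- xor(is.na(alleles[, , 1, drop = FALSE]), is.na(alleles[, , 2, drop = FALSE]))
  if (any(half)) stop("half-missing genotypes found; both alleles must be present or both missing")
  structure(list(ids = as.character(ids), pops = as.character(pops),
                 alleles = alleles, loci = as.character(loci)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals, %d populations, %d loci\n",
              length(x$ids), length(unique(x$pops)), length(x$loci)))
  invisible(x)
}

#' Read / write genotypes as CSV (two columns per locus)
#'
#' Format: `id,population,<locus>.1,<locus>.2,...`; missing alleles are 0.
#'
#' @param path file path.
#' @return a `genotype_table` (read) or `path` (write).
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  n_loci <- (ncol(df) - 2L) %/% 2L
  a <- array(NA_integer_, dim = c(nrow(df), n_loci, 2L))
  for (l in seq_len(n_loci)) {
    a[, l, 1] <- as.integer(df[[2L + 2L * l - 1L]])
    a[, l, 2] <- as.integer(df[[2L + 2L * l]])
  }
  a[a == 0L] <- NA_integer_
  loci <- unique(sub("\\.[12]$", "", names(df)[-(1:2)]))
  genotype_table(df[[1]], df[[2]], a, loci = loci)
}

#' @rdname read_genotypes_csv
#' @param table a `genotype_table`.
#' @export
write_genotypes_csv <- function(table, path) {
  a <- table$alleles
  a[is.na(a)] <- 0L
  cols <- list(id = table$ids, population = table$pops)
  for (l in seq_along(table$loci)) {
    cols[[paste0(table$loci[l], ".1")]] <- a[, l, 1]
    cols[[paste0(table$loci[l], ".2")]] <- a[, l, 2]
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

# Per-locus Weir & Cockerham (1984) variance components for one locus.
# geno: n x 2 matrix of alleles (rows = individuals), pop: factor.
# Returns list(a, b, c): vectors over alleles (components summed over alleles
# downstream). Individuals missing at this locus are dropped locus-wise.
.wc_locus_components <- function(geno, pop) {
  keep <- !is.na(geno[, 1])
  geno <- geno[keep, , drop = FALSE]
  pop <- factor(pop[keep])
  r <- nlevels(pop)
  n_i <- as.vector(table(pop))
  if (r < 2L || any(n_i < 1L)) return(NULL)
  alleles <- sort(unique(as.vector(geno)))
  if (length(alleles) < 2L) return(NULL)        # monomorphic: undefined
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  a <- b <- c_ <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    al <- alleles[k]
    cnt <- (geno[, 1] == al) + (geno[, 2] == al)       # allele copies per ind
    het <- (geno[, 1] == al) != (geno[, 2] == al)      # heterozygous for al
    p_i <- tapply(cnt, pop, sum) / (2 * n_i)
    h_i <- tapply(het, pop, mean)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a[k] <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b[k] <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    c_[k] <- h_bar / 2
  }
  list(a = a, b = b, c = c_)
}

#' Weir-Cockerham F_ST (theta)
#'
#' Multi-locus, multi-allele theta of Weir & Cockerham (1984): per allele and
#' locus the among-population (a), among-individual (b) and within-individual
#' (c) variance components are accumulated and theta = sum(a) / sum(a + b + c).
#' Negative estimates are reported as-is (not truncated at zero). A locus
#' missing in an individual drops that individual from that locus only.
#'
#' @param table a `genotype_table`.
#' @param pops optional character vector of population labels to restrict to
#'   (e.g. two labels for a pairwise estimate); default uses all populations.
#' @return theta estimate (scalar).
#' @export
weir_cockerham_fst <- function(table, pops = NULL) {
  keep <- if (is.null(pops)) rep(TRUE, length(table$ids)) else table$pops %in% pops
  if (!is.null(pops)) {
    miss <- setdiff(pops, unique(table$pops))
    if (length(miss)) stop("unknown populations: ", paste(miss, collapse = ", "))
  }
  pop <- table$pops[keep]
  cnt <- table(pop)
  if (length(cnt) < 2L) stop("need >= 2 populations")
  if (any(cnt < 2L))
    stop("populations with < 2 individuals: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  A <- B <- C <- 0
  any_locus <- FALSE
  for (l in seq_along(table$loci)) {
    comp <- .wc_locus_components(table$alleles[keep, l, , drop = TRUE], pop)
    if (is.null(comp)) next
    any_locus <- TRUE
    A <- A + sum(comp$a); B <- B + sum(comp$b); C <- C + sum(comp$c)
  }
  if (!any_locus)
    stop("F_ST undefined: no polymorphic locus shared by the requested populations")
  denom <- A + B + C
  if (denom == 0)
    stop("F_ST undefined: zero total variance across loci")
  A / denom
}

#' Pairwise F_ST matrix over all populations
#'
#' @param table a `genotype_table`.
#' @return a `pairwise_matrix` of kind `"genetic"`, populations in order of
#'   first appearance.
#' @export
pairwise_fst_matrix <- function(table) {
  pops <- unique(table$pops)
  if (length(pops) < 2L) stop("need >= 2 populations")
  cnt <- table(table$pops)
  if (any(cnt < 2L))
    stop("populations with < 2 individuals: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  n <- length(pops)
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- weir_cockerham_fst(table, pops = c(pops[i], pops[j]))
    m[i, j] <- m[j, i] <- v
  }
  pairwise_matrix(m, kind = "genetic")
}

#' Pairwise Euclidean distance matrix from projected coordinates
#'
#' @param localities data.frame with columns `name`, `x`, `y` (meters,
#'   projected planar coordinates).
#' @return a `pairwise_matrix` of kind `"euclidean"`.
#' @export
euclidean_matrix <- function(localities) {
  if (anyDuplicated(localities$name))
    stop("duplicate locality names")
  d <- as.matrix(stats::dist(cbind(localities$x, localities$y)))
  dimnames(d) <- list(localities$name, localities$name)
  pairwise_matrix(d, kind = "euclidean")
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of pairwise genetic distance on pairwise Euclidean
#' distance over the n(n-1)/2 unordered pairs. Reports slope, intercept,
#' Pearson r and r^2 (the proportion of variance in genetic distance
#' explained by geographic distance alone).
#'
#' @param genetic,euclidean `pairwise_matrix` objects over the same
#'   localities.
#' @return object of class `ibd_result`: list with `slope`, `intercept`,
#'   `pearson_r`, `r_squared`, `n_pairs`.
#' @export
ibd_regression <- function(genetic, euclidean) {
  if (!setequal(rownames(genetic), rownames(euclidean)))
    stop("locality sets differ")
  if (nrow(genetic) < 3L) stop("need >= 3 localities")
  euclidean <- restrict_pairwise(euclidean, rownames(genetic))
  y <- pair_vector(genetic); x <- pair_vector(euclidean)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a distance matrix; IBD regression undefined")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r, r_squared = r^2, n_pairs = length(y)),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "Isolation-by-distance regression (%d pairs)\n  slope = %.4g per m, intercept = %.4g\n  Pearson r = %.3f, r^2 = %.1f%% of variance explained\n",
    x$n_pairs, x$slope, x$intercept, x$pearson_r, 100 * x$r_squared))
  invisible(x)
}
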