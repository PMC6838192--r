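#' Generate a spatially autocorrelated categorical landscape
#'
#' Smooths i.i.d. Gaussian noise with a separable Gaussian kernel of the
#' given length scale, then thresholds the smoothed field at
#' class-proportion quantiles, yielding patchy class maps resembling habitat
#' rasters (class 0, 1, ..., n_classes - 1).
#'
#' @param rows,cols grid dimensions.
#' @param n_classes number of classes (>= 2).
#' @param smoothness kernel length scale in cells (> 0); larger = bigger
#'   patches.
#' @param seed integer seed; identical arguments give identical grids.
#' @param proportions target class proportions (default equal); thresholds
#'   are the corresponding quantiles of the smoothed field.
#' @param cell_size cell size in meters.
#' @return `land_grid` of integer class labels, all classes present.
#' @export
gen_categorical_landscape <- function(rows, cols, n_classes, smoothness = 8,
                                      seed = 1,
                                      proportions = rep(1 / n_classes, n_classes),
                                      cell_size = 1000) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (smoothness <= 0) stop("smoothness must be > 0")
  if (rows * cols < n_classes)
    stop("grid has fewer cells than classes; infeasible request")
  stopifnot(length(proportions) == n_classes, all(proportions > 0))
  proportions <- proportions / sum(proportions)
  field <- .with_seed(seed, {
    noise <- matrix(stats::rnorm(rows * cols), rows, cols)
    .gaussian_blur(noise, smoothness)
  })
  qs <- stats::quantile(field, cumsum(proportions)[-n_classes], names = FALSE)
  cls <- matrix(findInterval(field, unique(qs)), rows, cols)
  # guarantee every class appears even under quantile ties on tiny grids
  missing <- setdiff(seq_len(n_classes) - 1L, unique(as.vector(cls)))
  if (length(missing)) {
    ord <- order(field)
    take <- .with_seed(.sub_seed(seed, 1), sample(ord, length(missing)))
    cls[take] <- missing
  }
  land_grid(cls, cell_size = cell_size)
}

# separable Gaussian blur with edge renormalization (kernel mass inside the
# grid sums to 1 at every cell)
.gaussian_blur <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  blur1 <- function(mm) {
    n <- ncol(mm)
    out <- matrix(0, nrow(mm), n); den <- out
    for (d in -half:half) {
      src <- seq_len(n) + d
      ok <- src >= 1L & src <= n
      w <- k[d + half + 1L]
      out[, ok] <- out[, ok] + w * mm[, src[ok], drop = FALSE]
      den[, ok] <- den[, ok] + w
    }
    out / den
  }
  t(blur1(t(blur1(m))))
}

#' Generate a distance-to-source continuous landscape
#'
#' Places `n_sources` random source cells and assigns every cell the planar
#' distance (meters) from its center to the nearest source center (the
#' synthetic analogue of a distance-to-nearest-village layer).
#'
#' @param rows,cols grid dimensions.
#' @param n_sources number of source points (>= 1).
#' @param seed integer seed.
#' @param cell_size cell size in meters.
#' @return `land_grid` of distances, 0 at source cells.
#' @export
gen_continuous_landscape <- function(rows, cols, n_sources = 4, seed = 1,
                                     cell_size = 1000) {
  if (n_sources < 1L) stop("n_sources must be >= 1")
  cells <- .with_seed(seed, sample.int(rows * cols, n_sources))
  tmpl <- land_grid(matrix(0, rows, cols), cell_size = cell_size)
  cc <- cell_centers(tmpl)
  pts <- data.frame(x = cc$x[cells], y = cc$y[cells])
  distance_to_features(tmpl, pts)
}

#' Synthetic study scenario
#'
#' Bundles the generative conditions of one synthetic landscape-genetics
#' study: a spatially autocorrelated categorical landscape, localities
#' placed in the lowest-resistance class with a minimum separation of 3
#' cells, a true resistance surface, and the MLPE noise model that turns
#' true resistance distances into observed genetic distances.
#'
#' @param grid_rows,grid_cols landscape dimensions.
#' @param cell_size cell size (meters).
#' @param n_localities number of sampling localities (>= 3).
#' @param true_spec the generating `resistance_spec` (default a 3-class
#'   categorical surface with values 1 / 50 / 300).
#' @param beta0,beta1 intercept and slope (per SD of resistance distance) of
#'   the genetic-distance model.
#' @param sigma_u population random-effect SD (>= 0).
#' @param sigma_e pair residual SD (> 0).
#' @param seed integer seed driving landscape, localities and noise.
#' @return object of class `synthetic_scenario` with elements `landscape`
#'   (class grid), `localities` (name/x/y data.frame) and the parameters.
#' @export
synthetic_scenario <- function(grid_rows = 40, grid_cols = 40, cell_size = 1000,
                               n_localities = 18,
                               true_spec = categorical_spec(
                                 "habitat", c(`0` = 1, `1` = 50, `2` = 300)),
                               beta0 = 0.2, beta1 = 0.8,
                               sigma_u = 0.05, sigma_e = 0.05, seed = 1) {
  if (n_localities < 3L) stop("need >= 3 localities")
  if (sigma_u < 0 || sigma_e <= 0) stop("require sigma_u >= 0 and sigma_e > 0")
  landscape <- gen_categorical_landscape(grid_rows, grid_cols,
                                         n_classes = length(true_spec$values),
                                         smoothness = max(2, grid_rows / 8),
                                         seed = .sub_seed(seed, 11),
                                         cell_size = cell_size)
  localities <- place_localities(landscape, n_localities,
                                 class = as.numeric(true_spec$fixed),
                                 min_sep_cells = 3,
                                 seed = .sub_seed(seed, 12))
  structure(list(landscape = landscape, localities = localities,
                 true_spec = true_spec, beta0 = beta0, beta1 = beta1,
                 sigma_u = sigma_u, sigma_e = sigma_e, seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> %d x %d landscape, %d localities\n  truth: %s surface; beta0 = %g, beta1 = %g, sigma_u = %g, sigma_e = %g, seed = %d\n",
    nrow(x$landscape$values), ncol(x$landscape$values), nrow(x$localities),
    x$true_spec$kind, x$beta0, x$beta1, x$sigma_u, x$sigma_e, x$seed))
  invisible(x)
}

#' Place sampling localities on a categorical landscape
#'
#' Samples cells of the requested class (by default the lowest-resistance
#' habitat class) with a minimum pairwise separation, mimicking sampling
#' restricted to primary-habitat sites.
#'
#' @param landscape class `land_grid`.
#' @param n number of localities.
#' @param class class label localities must fall on.
#' @param min_sep_cells minimum pairwise center separation in cell units.
#' @param seed integer seed.
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
place_localities <- function(landscape, n, class = 0, min_sep_cells = 3,
                             seed = 1) {
  ok <- which(landscape$values == class)
  if (length(ok) < n) stop("not enough cells of class ", class)
  cc <- cell_centers(landscape)
  min_d <- min_sep_cells * landscape$cell_size
  chosen <- .with_seed(seed, {
    cand <- sample(ok)
    sel <- integer(0)
    for (c0 in cand) {
      if (length(sel) &&
          min(sqrt((cc$x[sel] - cc$x[c0])^2 + (cc$y[sel] - cc$y[c0])^2)) < min_d)
        next
      sel <- c(sel, c0)
      if (length(sel) == n) break
    }
    sel
  })
  if (length(chosen) < n)
    stop("could not place ", n, " localities at separation >= ",
         min_sep_cells, " cells; landscape too fragmented")
  data.frame(name = sprintf("P%02d", seq_len(n)),
             x = cc$x[chosen], y = cc$y[chosen])
}

#' Generate MLPE-structured genetic distances from a scenario
#'
#' Computes true resistance distances from the scenario's generating surface
#' via the circuit solver, standardizes them over pairs, and draws
#' `y_ij = beta0 + beta1 * R_std_ij + u_i + u_j + e_ij` with
#' `u ~ N(0, sigma_u^2)` per locality and `e ~ N(0, sigma_e^2)` per pair.
#' Values are generic distances (F_ST-like) and are not clamped to `[0, 1]`,
#' keeping the generative model exactly invertible by the MLPE fit.
#'
#' @param scenario a `synthetic_scenario`.
#' @return list with `genetic` and `resistance` `pairwise_matrix` objects.
#' @export
gen_genetic_distances <- function(scenario) {
  res_grid <- build_resistance(scenario$true_spec, scenario$landscape)
  graph <- build_grid_graph(res_grid, scenario$localities)
  R <- resistance_matrix(graph)
  rv <- pair_vector(R)
  if (any(!is.finite(rv)))
    stop("disconnected localities on the true surface; cannot generate distances")
  rs <- if (stats::sd(rv) > 0) (rv - mean(rv)) / stats::sd(rv) else rv * 0
  n <- nrow(R)
  yv <- .with_seed(.sub_seed(scenario$seed, 21), {
    u <- stats::rnorm(n, 0, scenario$sigma_u)
    e <- stats::rnorm(length(rv), 0, scenario$sigma_e)
    Z <- mlpe_design(rownames(R))
    scenario$beta0 + scenario$beta1 * rs + as.numeric(Z %*% u) + e
  })
  y <- matrix(0, n, n, dimnames = dimnames(R))
  y[lower.tri(y)] <- 0   # fill from pair vector below
  idx <- utils::combn(n, 2L)
  y[cbind(idx[1, ], idx[2, ])] <- yv
  y[cbind(idx[2, ], idx[1, ])] <- yv
  list(genetic = pairwise_matrix(y, kind = "genetic"),
       resistance = R)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per locus an ancestral allele frequency `p ~ Uniform(0.1, 0.9)` is drawn;
#' each population's frequency is Beta-distributed around it with
#' differentiation parameter theta
#' (`Beta(p (1-theta)/theta, (1-p)(1-theta)/theta)`), and diploid genotypes
#' are binomial draws. The expected Weir-Cockerham estimate is approximately
#' theta, making this the estimator-validation workhorse.
#'
#' @param n_pops number of populations.
#' @param n_ind_per_pop individuals per population (>= 2).
#' @param n_loci number of biallelic loci.
#' @param theta differentiation parameter in (0, 1).
#' @param seed integer seed.
#' @return a `genotype_table` (populations "P01", "P02", ...).
#' @export
gen_genotypes_balding_nichols <- function(n_pops, n_ind_per_pop, n_loci,
                                          theta, seed = 1) {
  if (!is.numeric(theta) || theta <= 0 || theta >= 1)
    stop("theta must lie strictly in (0, 1)")
  if (n_ind_per_pop < 2L) stop("need >= 2 individuals per population")
  n_ind <- n_pops * n_ind_per_pop
  pops <- rep(sprintf("P%02d", seq_len(n_pops)), each = n_ind_per_pop)
  a <- .with_seed(seed, {
    arr <- array(NA_integer_, dim = c(n_ind, n_loci, 2L))
    for (l in seq_len(n_loci)) {
      p <- stats::runif(1, 0.1, 0.9)
      shp <- (1 - theta) / theta
      pk <- stats::rbeta(n_pops, p * shp, (1 - p) * shp)
      pk <- pmin(pmax(pk, 1e-9), 1 - 1e-9)
      for (k in seq_len(n_pops)) {
        rows <- which(pops == sprintf("P%02d", k))
        # allele 1 with frequency pk, allele 2 otherwise, slot-wise
        arr[rows, l, 1] <- ifelse(stats::runif(length(rows)) < pk[k], 1L, 2L)
        arr[rows, l, 2] <- ifelse(stats::runif(length(rows)) < pk[k], 1L, 2L)
      }
    }
    arr
  })
  genotype_table(sprintf("I%04d", seq_len(n_ind)), pops, a)
}

#' Write a scenario's inputs to disk as plain-text files
#'
#' Emits the landscape (`landscape.asc`), localities (`localities.csv`),
#' genetic distances (`genetic.csv`) and true resistance distances
#' (`true_resistance.csv`) of a synthetic scenario.
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asc(scenario$landscape, file.path(dir, "landscape.asc"))
  utils::write.csv(scenario$localities, file.path(dir, "localities.csv"),
                   row.names = FALSE)
  d <- gen_genetic_distances(scenario)
  write_pairwise_csv(d$genetic, file.path(dir, "genetic.csv"))
  write_pairwise_csv(d$resistance, file.path(dir, "true_resistance.csv"))
  invisible(dir)
}
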