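#' Genetic-algorithm configuration
#'
#' Real-coded GA with tournament selection, BLX-alpha blend crossover,
#' Gaussian mutation scaled to each gene's range, and elitism. The search
#' stops after `stagnation_limit` generations without improvement or at
#' `max_generations`. All randomness flows from one seeded stream, so a
#' fixed seed reproduces the whole trace.
#'
#' @param population_size individuals per generation (>= 4); default
#'   `max(20, 10 * n_genes)`, set at run time when `NULL`.
#' @param max_generations hard cap on generations.
#' @param stagnation_limit generations without fitness improvement before
#'   stopping.
#' @param crossover_rate,mutation_rate probabilities in `[0, 1]`.
#' @param blx_alpha BLX-alpha blend parameter.
#' @param mutation_sd_frac mutation SD as a fraction of each gene's range.
#' @param elitism_count individuals copied unchanged each generation.
#' @param tournament_size tournament selection size.
#' @param improve_tol minimum fitness gain counting as an improvement for
#'   the stagnation clock (log-likelihood units).
#' @param seed integer seed.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = NULL, max_generations = 200,
                      stagnation_limit = 25, crossover_rate = 0.8,
                      mutation_rate = 0.2, blx_alpha = 0.5,
                      mutation_sd_frac = 0.1, elitism_count = 2,
                      tournament_size = 3, improve_tol = 1e-6, seed = 1) {
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            is.null(population_size) || population_size >= 4)
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 stagnation_limit = stagnation_limit,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, blx_alpha = blx_alpha,
                 mutation_sd_frac = mutation_sd_frac,
                 elitism_count = elitism_count,
                 tournament_size = tournament_size,
                 improve_tol = improve_tol, seed = seed),
            class = "ga_config")
}

# generic real-coded GA maximizer; fitness_fn takes a gene vector and
# returns a scalar (non-finite = worst). Deterministic given config$seed.
.ga_maximize <- function(fitness_fn, lower, upper, config) {
  ng <- length(lower)
  np <- if (is.null(config$population_size)) max(20L, 10L * ng)
        else config$population_size
  rng <- upper - lower
  .with_seed(config$seed, {
    pop <- matrix(stats::runif(np * ng, lower, upper), np, ng, byrow = TRUE)
    fit <- apply(pop, 1L, fitness_fn)
    fit[!is.finite(fit)] <- -Inf
    best_fit <- max(fit); best_gene <- pop[which.max(fit), ]
    trace <- best_fit
    stagnant <- 0L
    for (gen in seq_len(config$max_generations)) {
      newpop <- matrix(0, np, ng)
      # elitism
      elite <- order(fit, decreasing = TRUE)[seq_len(config$elitism_count)]
      newpop[seq_along(elite), ] <- pop[elite, , drop = FALSE]
      i <- length(elite)
      while (i < np) {
        # tournament selection of two parents
        pick <- function() {
          cand <- sample.int(np, config$tournament_size)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (stats::runif(1) < config$crossover_rate) {
          # BLX-alpha blend
          lo <- pmin(p1, p2); hi <- pmax(p1, p2)
          d <- hi - lo
          c1 <- stats::runif(ng, lo - config$blx_alpha * d,
                             hi + config$blx_alpha * d)
          c2 <- stats::runif(ng, lo - config$blx_alpha * d,
                             hi + config$blx_alpha * d)
        } else { c1 <- p1; c2 <- p2 }
        for (child in list(c1, c2)) {
          if (i >= np) break
          mut <- stats::runif(ng) < config$mutation_rate
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, config$mutation_sd_frac * rng[mut])
          child <- pmin(pmax(child, lower), upper)
          i <- i + 1L
          newpop[i, ] <- child
        }
      }
      pop <- newpop
      fit <- apply(pop, 1L, fitness_fn)
      fit[!is.finite(fit)] <- -Inf
      improved <- max(fit) > best_fit + config$improve_tol
      if (max(fit) > best_fit) {
        best_fit <- max(fit); best_gene <- pop[which.max(fit), ]
      }
      stagnant <- if (improved) 0L else stagnant + 1L
      trace <- c(trace, max(best_fit, trace[length(trace)]))
      if (stagnant >= config$stagnation_limit) break
    }
    list(gene = best_gene, fitness = best_fit, trace = trace,
         generations = length(trace) - 1L)
  })
}

# gene bounds per spec template
.gene_bounds <- function(spec) {
  if (spec$kind == "categorical") {
    ng <- length(spec$values) - 1L
    list(lower = rep(0.01, ng), upper = rep(3500, ng),
         names = setdiff(names(spec$values), spec$fixed))
  } else {
    list(lower = c(0.01, 0.01), upper = c(14, 3500),
         names = c("shape", "maximum"))
  }
}

# rebuild a spec from a gene vector
.spec_from_genes <- function(spec, genes) {
  if (spec$kind == "categorical") {
    v <- spec$values
    v[setdiff(names(v), spec$fixed)] <- genes
    categorical_spec(spec$name, v, fixed = spec$fixed)
  } else {
    continuous_spec(spec$name, spec$transformation, genes[1], genes[2])
  }
}

# MLPE log-likelihood fitness for a candidate resistance surface, with
# memoization on the rounded gene vector (circuit solves dominate cost)
.make_surface_fitness <- function(template_specs, layers, tmpl_graph, genetic) {
  cache <- new.env(parent = emptyenv())
  splits <- cumsum(vapply(template_specs,
                          function(s) length(.gene_bounds(s)$lower), integer(1)))
  function(genes) {
    key <- paste(round(genes, 4), collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch({
      start <- c(1L, utils::head(splits, -1) + 1L)
      comps <- lapply(seq_along(template_specs), function(k) {
        s <- .spec_from_genes(template_specs[[k]], genes[start[k]:splits[k]])
        build_resistance(s, layers[[k]])
      })
      surf <- if (length(comps) == 1L) comps[[1]] else combine_composite(comps)
      graph <- graph_set_resistance(tmpl_graph, surf)
      R <- resistance_matrix(graph)
      if (any(!is.finite(pair_vector(R)))) -Inf
      else fit_mlpe(genetic, R)$loglik
    }, error = function(e) -Inf)
    cache[[key]] <- val
    val
  }
}

#' Optimize a resistance surface by genetic algorithm
#'
#' Searches the parameter space of one surface (free categorical class
#' values, or shape and maximum of a continuous transformation) to maximize
#' the MLPE log-likelihood of pairwise genetic distance regressed on the
#' candidate's effective-resistance distances. K is constant within one
#' surface's search, so log-likelihood and AICc rank candidates
#' identically; AICc enters only when surfaces are compared.
#'
#' @param layer landscape `land_grid` (class grid for categorical, raw
#'   continuous layer otherwise).
#' @param template a `resistance_spec` giving the surface family; its
#'   numeric values are the search's starting template, not constraints.
#' @param genetic `pairwise_matrix` of genetic distances.
#' @param localities data.frame `name`, `x`, `y`.
#' @param config a [ga_config()].
#' @return list with `spec` (best `resistance_spec`), `fit` (its refitted
#'   `mlpe_fit`, with K from [surface_K()]), `resistance` (its
#'   `pairwise_matrix`), `trace` (best fitness per generation) and
#'   `generations`.
#' @export
optimize_surface <- function(layer, template, genetic, localities,
                             config = ga_config()) {
  if (any(!is.finite(pair_vector(genetic))))
    stop("genetic matrix contains non-finite entries")
  bounds <- .gene_bounds(template)
  tmpl_graph <- graph_template(layer, localities)
  fitness <- .make_surface_fitness(list(template), list(layer), tmpl_graph,
                                   genetic)
  res <- .ga_maximize(fitness, bounds$lower, bounds$upper, config)
  if (!is.finite(res$fitness))
    stop("no candidate produced a connected surface; optimization failed")
  spec <- .spec_from_genes(template, res$gene)
  surf <- build_resistance(spec, layer)
  R <- resistance_matrix(graph_set_resistance(tmpl_graph, surf))
  fit <- fit_mlpe(genetic, R, K = surface_K(spec))
  list(spec = spec, fit = fit, resistance = R, trace = res$trace,
       generations = res$generations)
}

#' Jointly optimize a composite resistance surface
#'
#' Concatenates the gene vectors of the component surfaces and optimizes
#' them jointly; each candidate is combined by cellwise sum
#' ([combine_composite()]) before the circuit solve.
#'
#' @param layers named list of landscape `land_grid`s, one per component.
#' @param templates list of component `resistance_spec`s (same order).
#' @inheritParams optimize_surface
#' @return as [optimize_surface()], with `spec` a `composite_spec`.
#' @export
optimize_composite <- function(layers, templates, genetic, localities,
                               config = ga_config()) {
  if (length(templates) < 2L) stop("a composite needs >= 2 components")
  bl <- lapply(templates, .gene_bounds)
  lower <- unlist(lapply(bl, `[[`, "lower"))
  upper <- unlist(lapply(bl, `[[`, "upper"))
  tmpl_graph <- graph_template(layers[[1]], localities)
  fitness <- .make_surface_fitness(templates, layers, tmpl_graph, genetic)
  res <- .ga_maximize(fitness, lower, upper, config)
  if (!is.finite(res$fitness))
    stop("no candidate produced a connected surface; optimization failed")
  splits <- cumsum(vapply(templates,
                          function(s) length(.gene_bounds(s)$lower), integer(1)))
  start <- c(1L, utils::head(splits, -1) + 1L)
  comps <- lapply(seq_along(templates), function(k)
    .spec_from_genes(templates[[k]], res$gene[start[k]:splits[k]]))
  spec <- composite_spec(comps)
  surfs <- lapply(seq_along(comps), function(k)
    build_resistance(comps[[k]], layers[[k]]))
  surf <- combine_composite(surfs)
  R <- resistance_matrix(graph_set_resistance(tmpl_graph, surf))
  fit <- fit_mlpe(genetic, R, K = surface_K(spec))
  list(spec = spec, fit = fit, resistance = R, trace = res$trace,
       generations = res$generations)
}

#' Replicate optimization runs and report convergence agreement
#'
#' Runs the same optimization under several seeds and reports the pairwise
#' Pearson correlation between the replicate best-surface resistance
#' matrices; replicate agreement below `threshold` is flagged, following
#' the practice of running each optimization at least twice.
#'
#' @param run_fn function(seed) returning a list with a `resistance`
#'   `pairwise_matrix` (e.g. a closure over [optimize_surface()]).
#' @param seeds integer vector of seeds (>= 2).
#' @param threshold minimum pairwise Pearson r considered converged.
#' @return list with `correlations` (matrix), `min_r`, `converged`, `runs`.
#' @export
replicate_runs <- function(run_fn, seeds, threshold = 0.95) {
  if (length(seeds) < 2L) stop("need >= 2 replicate seeds")
  runs <- lapply(seeds, run_fn)
  vecs <- vapply(runs, function(r) pair_vector(r$resistance),
                 numeric(length(pair_vector(runs[[1]]$resistance))))
  cm <- stats::cor(vecs)
  dimnames(cm) <- list(paste0("seed", seeds), paste0("seed", seeds))
  min_r <- min(cm[upper.tri(cm)])
  list(correlations = cm, min_r = min_r,
       converged = min_r >= threshold, runs = runs)
}
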