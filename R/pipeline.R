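#' Bundle a demo synthetic study to disk
#'
#' Generates a self-contained 18-locality synthetic study mirroring the
#' full workflow's input structure: a 3-class categorical habitat layer
#' (the generating surface), a distance-to-points layer, a TPI layer and
#' two binary line layers as competing candidate surfaces, plus localities
#' and MLPE-structured genetic distances. Sized so the full pipeline
#' completes quickly on one CPU at 1,000 bootstrap iterations.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param grid_rows,grid_cols landscape size.
#' @param n_localities number of sampling localities.
#' @return the scenario, invisibly; files written under `dir`.
#' @export
make_demo <- function(dir, seed = 1, grid_rows = 40, grid_cols = 40,
                      n_localities = 18) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scen <- synthetic_scenario(grid_rows = grid_rows, grid_cols = grid_cols,
                             n_localities = n_localities, seed = seed)
  write_scenario(scen, dir)
  nr <- grid_rows; nc <- grid_cols; cs <- scen$landscape$cell_size
  village <- gen_continuous_landscape(nr, nc, n_sources = 5,
                                      seed = .sub_seed(seed, 31),
                                      cell_size = cs)
  write_asc(village, file.path(dir, "village_distance.asc"))
  dem <- .with_seed(.sub_seed(seed, 32), {
    base <- .gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), nr / 10)
    land_grid(1000 + 500 * base, cell_size = cs)
  })
  write_asc(topographic_position_index(dem), file.path(dir, "tpi.asc"))
  lines_df <- .with_seed(.sub_seed(seed, 33), {
    mk <- function(id) {
      nvert <- 4L
      data.frame(line = id,
                 x = sort(stats::runif(nvert, 0, nc * cs)),
                 y = stats::runif(nvert, 0, nr * cs))
    }
    rbind(mk(1L), mk(2L), mk(3L))
  })
  rivers <- rasterize_lines(scen$landscape, lines_df)
  write_asc(rivers, file.path(dir, "rivers.asc"))
  roads_df <- .with_seed(.sub_seed(seed, 34), {
    data.frame(line = rep(1:2, each = 3L),
               x = stats::runif(6, 0, nc * cs), y = stats::runif(6, 0, nr * cs))
  })
  write_asc(rasterize_lines(scen$landscape, roads_df),
            file.path(dir, "roads.asc"))
  meta <- list(seed = seed, grid_rows = grid_rows, grid_cols = grid_cols,
               n_localities = n_localities,
               true_surface = "habitat",
               true_values = as.list(scen$true_spec$values),
               beta0 = scen$beta0, beta1 = scen$beta1,
               sigma_u = scen$sigma_u, sigma_e = scen$sigma_e)
  jsonlite::write_json(meta, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(scen)
}

# checkpoint helper: run `fn` only if `files` are absent from the run dir
.stage <- function(run_dir, name, files, fn, log) {
  paths <- file.path(run_dir, files)
  if (all(file.exists(paths))) {
    log(sprintf("[%s] checkpoint present, skipping", name))
    return(invisible(FALSE))
  }
  log(sprintf("[%s] running", name))
  tryCatch(fn(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  invisible(TRUE)
}

#' Run the full inference pipeline on a demo-style study directory
#'
#' Stage order encodes the selection protocol: IBD regression, single-
#' surface GA optimization (habitat categorical; village-distance
#' monomolecular and ricker with the better kept; TPI ricker; rivers and
#' roads categorical), Spearman correlation among winners, bootstrap
#' selection over singles, composite optimization from the surfaces that
#' beat the Euclidean null, a second bootstrap including the composite, and
#' the current map of the top model. Each stage checkpoints its outputs in
#' `run_dir`; a rerun skips completed stages.
#'
#' @param study_dir directory produced by [make_demo()] (or with the same
#'   file layout).
#' @param run_dir output directory for artifacts.
#' @param seed integer seed for GA and bootstrap stages.
#' @param n_iterations bootstrap iterations.
#' @param ga ga settings from [ga_config()] (its seed field is overridden
#'   stage-wise from `seed`).
#' @param quiet suppress progress messages.
#' @return invisible list with the main results (ibd, singles table,
#'   final table, top model name).
#' @export
run_full_pipeline <- function(study_dir, run_dir, seed = 1,
                              n_iterations = 1000, ga = ga_config(),
                              quiet = FALSE) {
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(msg) if (!quiet) message(msg)
  habitat <- read_asc(file.path(study_dir, "landscape.asc"))
  village <- read_asc(file.path(study_dir, "village_distance.asc"))
  tpi <- read_asc(file.path(study_dir, "tpi.asc"))
  rivers <- read_asc(file.path(study_dir, "rivers.asc"))
  roads <- read_asc(file.path(study_dir, "roads.asc"))
  localities <- utils::read.csv(file.path(study_dir, "localities.csv"))
  genetic <- read_pairwise_csv(file.path(study_dir, "genetic.csv"),
                               kind = "genetic")
  euclid <- euclidean_matrix(localities)

  # 1. isolation by distance
  .stage(run_dir, "ibd", "ibd.json", function() {
    r <- ibd_regression(genetic, euclid)
    jsonlite::write_json(unclass(r), file.path(run_dir, "ibd.json"),
                         auto_unbox = TRUE, digits = NA)
  }, log)

  # 2. single-surface optimization
  singles_def <- list(
    habitat = list(layer = habitat,
                   template = categorical_spec("habitat",
                     c(`0` = 1, `1` = 100, `2` = 100))),
    village = list(layer = village,
                   template = continuous_spec("village", "monomolecular", 3, 100),
                   also = continuous_spec("village", "ricker", 3, 100)),
    tpi = list(layer = tpi,
               template = continuous_spec("tpi", "ricker", 3, 100),
               also = continuous_spec("tpi", "monomolecular", 3, 100)),
    rivers = list(layer = rivers,
                  template = categorical_spec("rivers", c(`0` = 1, `1` = 100))),
    roads = list(layer = roads,
                 template = categorical_spec("roads", c(`0` = 1, `1` = 100))))
  opt <- list()
  for (nm in names(singles_def)) {
    d <- singles_def[[nm]]
    mat_file <- sprintf("opt_%s.csv", nm)
    spec_file <- sprintf("opt_%s.yaml", nm)
    .stage(run_dir, paste0("optimize_", nm), c(mat_file, spec_file), function() {
      cfg <- ga; cfg$seed <- .sub_seed(seed, 100 + match(nm, names(singles_def)))
      res <- optimize_surface(d$layer, d$template, genetic, localities, cfg)
      if (!is.null(d$also)) {
        cfg2 <- cfg; cfg2$seed <- .sub_seed(cfg$seed, 1)
        res2 <- optimize_surface(d$layer, d$also, genetic, localities, cfg2)
        if (res2$fit$loglik > res$fit$loglik) res <- res2
      }
      write_pairwise_csv(res$resistance, file.path(run_dir, mat_file))
      write_spec_yaml(res$spec, file.path(run_dir, spec_file))
      utils::write.csv(data.frame(generation = seq_along(res$trace) - 1L,
                                  best_loglik = res$trace),
                       file.path(run_dir, sprintf("trace_%s.csv", nm)),
                       row.names = FALSE)
    }, log)
    opt[[nm]] <- list(
      resistance = read_pairwise_csv(file.path(run_dir, mat_file),
                                     kind = "resistance"),
      spec = read_spec_yaml(file.path(run_dir, spec_file)))
  }

  # 3. bootstrap selection over singles + Euclidean null
  models <- c(lapply(opt, `[[`, "resistance"), list(euclidean = euclid))
  Kv <- c(vapply(opt, function(o) surface_K(o$spec), integer(1)),
          euclidean = 2L)
  .stage(run_dir, "select_singles", "selection_singles.csv", function() {
    bs <- bootstrap_select(models, genetic, Kv, n_iterations = n_iterations,
                           seed = .sub_seed(seed, 200))
    write_selection_csv(bs, file.path(run_dir, "selection_singles.csv"))
  }, log)
  singles_tab <- utils::read.csv(file.path(run_dir, "selection_singles.csv"))
  bs_singles <- structure(list(table = singles_tab), class = "bootstrap_summary")
  cand <- composite_candidates(bs_singles, "euclidean")

  # 4. Spearman correlations among candidate surfaces
  .stage(run_dir, "spearman", "spearman.csv", function() {
    if (length(cand) >= 2L) {
      cmb <- utils::combn(cand, 2L)
      rho <- vapply(seq_len(ncol(cmb)), function(k)
        spearman_correlation(opt[[cmb[1, k]]]$resistance,
                             opt[[cmb[2, k]]]$resistance), numeric(1))
      df <- data.frame(surface_a = cmb[1, ], surface_b = cmb[2, ], rho = rho)
    } else df <- data.frame(surface_a = character(), surface_b = character(),
                            rho = numeric())
    utils::write.csv(df, file.path(run_dir, "spearman.csv"), row.names = FALSE)
  }, log)

  # 5. composite optimization from the candidates
  has_composite <- length(cand) >= 2L
  if (has_composite) {
    .stage(run_dir, "composite", c("opt_composite.csv", "opt_composite.yaml"),
           function() {
      cfg <- ga; cfg$seed <- .sub_seed(seed, 300)
      res <- optimize_composite(
        lapply(cand, function(nm) singles_def[[nm]]$layer),
        lapply(cand, function(nm) opt[[nm]]$spec),
        genetic, localities, cfg)
      write_pairwise_csv(res$resistance, file.path(run_dir, "opt_composite.csv"))
      write_spec_yaml(res$spec, file.path(run_dir, "opt_composite.yaml"))
    }, log)
  }

  # 6. final bootstrap: composite vs its components vs Euclidean
  .stage(run_dir, "select_final", "selection_final.csv", function() {
    if (has_composite) {
      comp_R <- read_pairwise_csv(file.path(run_dir, "opt_composite.csv"),
                                  kind = "resistance")
      comp_spec <- read_spec_yaml(file.path(run_dir, "opt_composite.yaml"))
      fm <- c(list(composite = comp_R),
              lapply(opt[cand], `[[`, "resistance"), list(euclidean = euclid))
      fK <- c(composite = surface_K(comp_spec),
              vapply(opt[cand], function(o) surface_K(o$spec), integer(1)),
              euclidean = 2L)
    } else { fm <- models; fK <- Kv }
    bs <- bootstrap_select(fm, genetic, fK, n_iterations = n_iterations,
                           seed = .sub_seed(seed, 400))
    write_selection_csv(bs, file.path(run_dir, "selection_final.csv"))
  }, log)
  final_tab <- utils::read.csv(file.path(run_dir, "selection_final.csv"))
  top <- final_tab$surface[which.max(final_tab$pi_hat)]

  # 7. current map of the top model
  .stage(run_dir, "currentmap", "current_map.asc", function() {
    surf_R_file <- if (top == "euclidean") NULL
                   else if (top == "composite") "opt_composite.yaml"
                   else sprintf("opt_%s.yaml", top)
    if (is.null(surf_R_file)) {
      # Euclidean top model: uniform surface
      surf <- land_grid(matrix(1, nrow(habitat$values), ncol(habitat$values)),
                        habitat$cell_size, habitat$origin)
    } else {
      spec <- read_spec_yaml(file.path(run_dir, surf_R_file))
      layer_list <- list(habitat = habitat, village = village, tpi = tpi,
                         rivers = rivers, roads = roads)
      surf <- if (spec$kind == "composite") build_resistance(spec, layer_list)
              else build_resistance(spec, layer_list[[spec$name]])
    }
    cm <- current_map(build_grid_graph(surf, localities))
    write_asc(cm, file.path(run_dir, "current_map.asc"))
  }, log)

  manifest <- list(seed = seed, n_iterations = n_iterations,
                   study_dir = normalizePath(study_dir),
                   top_model = top,
                   composite_candidates = cand,
                   version = as.character(utils::packageVersion("landres")))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(ibd = jsonlite::read_json(file.path(run_dir, "ibd.json")),
                 singles = singles_tab, final = final_tab, top_model = top))
}
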