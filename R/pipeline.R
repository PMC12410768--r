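#' Pipeline configuration
#'
#' Collects all tunables of the end-to-end synthetic pipeline in one
#' serializable list. A run's effective configuration is written next to
#' its outputs, and all stage seeds are derived from the single root seed
#' (see [stage_seed()]).
#'
#' @param output_dir directory for all stage artifacts.
#' @param seed root seed.
#' @param n_cells,class_proportions,n_clusters,target_buildings,max_cells
#'   synthetic landscape and survey-design settings.
#' @param chains,iterations,warmup,adapt MCMC settings (defaults follow the
#'   study: 3 chains x 5000 iterations, 500 warm-up discarded).
#' @param thin,block_size prediction settings.
#' @param train_fraction,cv_repeats,distance_breaks,n_perm evaluation
#'   settings.
#' @param areas_nx,areas_ny,zone_every aggregation block layout.
#' @return object of class `bupop_config` (a named list).
#' @export
pipeline_config <- function(output_dir = tempfile("bupop_run_"), seed = 1L,
                            n_cells = 4000, class_proportions = c(0.15, 0.25, 0.60),
                            n_clusters = 60, target_buildings = 80,
                            max_cells = 600,
                            chains = 3, iterations = 5000, warmup = 500,
                            adapt = 500,
                            thin = 1L, block_size = 10000L,
                            train_fraction = 0.8, cv_repeats = 1,
                            distance_breaks = c(0, 10), n_perm = 999,
                            areas_nx = 4, areas_ny = 4, zone_every = 2) {
  cfg <- as.list(environment())
  class(cfg) <- "bupop_config"
  cfg
}

pipeline_artifacts <- function(cfg) {
  files <- c(grid = "grid.csv", clusters = "clusters.csv",
             truth = "truth.csv", draws = "draws.csv",
             cell_summary = "cell_summary.csv", areas = "areas.csv",
             zones = "zones.csv", metrics = "metrics_full.csv",
             moran = "moran.csv", manifest = "manifest.json")
  stats::setNames(file.path(cfg$output_dir, files), names(files))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the requested stages in order on a synthetic landscape:
#' `simulate` (landscape, ground truth, stratified cluster sample),
#' `prepare` (model-ready tables; standardization is carried by the grid
#' constants), `fit` (MCMC), `predict` (gridded posterior predictive),
#' `aggregate` (block areas and zones), `evaluate` (in-sample residual
#' metrics and Moran's I on residuals). Each stage writes CSV artifacts and
#' the run manifest records seeds, file hashes and timings; re-running with
#' an identical configuration reproduces identical artifacts and hashes.
#'
#' @param config a `bupop_config`.
#' @param stages ordered subset of
#'   `c("simulate","prepare","fit","predict","aggregate","evaluate")`.
#' @return the manifest (invisibly readable from `manifest.json`), as a
#'   list; stage results are attached in the `results` element.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "prepare", "fit", "predict",
                                    "aggregate", "evaluate")) {
  stopifnot(inherits(config, "bupop_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_artifacts(config)
  res <- list()
  timings <- list()
  state <- new.env(parent = emptyenv())

  need <- function(stage, artifact, loader) {
    stop_if(!file.exists(paths[[artifact]]),
            "stage '", stage, "' requires artifact '", paths[[artifact]],
            "'; run its producing stage first")
    loader(paths[[artifact]])
  }
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    v
  }

  for (stage in stages) {
    if (stage == "simulate") {
      clock("simulate", {
        grid <- generate_grid(config$n_cells, config$class_proportions,
                              seed = stage_seed(config$seed, "simulate"))
        sim <- simulate_truth(grid, default_truth("cell"),
                              seed = stage_seed(config$seed, "simulate") + 1L)
        state$grid <- sim$grid
        state$truth <- sim$truth
        state$clusters <- sample_clusters(sim$grid, config$n_clusters,
                                          config$target_buildings,
                                          config$max_cells,
                                          seed = stage_seed(config$seed, "clusters"))
        utils::write.csv(sim$grid[, setdiff(names(sim$grid), "cells")],
                         paths[["grid"]], row.names = FALSE)
        tcsv <- with(state$truth, data.frame(
          class = 1:3, alpha_B = alpha_B, beta_B = beta_B, sigma_B = sigma_B,
          alpha_D = alpha_D, sigma_D = sigma_D))
        tcsv$beta_D <- paste(state$truth$beta_D, collapse = ";")
        utils::write.csv(tcsv, paths[["truth"]], row.names = FALSE)
        utils::write.csv(state$clusters[, setdiff(names(state$clusters), "cells")],
                         paths[["clusters"]], row.names = FALSE)
      })
    } else if (stage == "prepare") {
      # the simulate stage already emits standardized, model-ready tables;
      # this stage validates them and persists the constants
      clock("prepare", {
        stop_if(is.null(state$grid), "prepare requires the simulate stage")
        const <- attr(state$grid, "constants")
        utils::write.csv(cbind(covariate = rownames(const), const),
                         file.path(config$output_dir, "standardization.csv"),
                         row.names = FALSE)
      })
    } else if (stage == "fit") {
      clock("fit", {
        stop_if(is.null(state$clusters),
                "fit requires cluster data; run the simulate stage first")
        state$fit <- fit_microcensus(state$clusters, chains = config$chains,
                                     iterations = config$iterations,
                                     warmup = config$warmup,
                                     adapt = config$adapt,
                                     seed = stage_seed(config$seed, "fit"))
        utils::write.csv(
          cbind(chain = state$fit$chain, as.data.frame(draws_matrix(state$fit))),
          paths[["draws"]], row.names = FALSE)
        diag <- fit_diagnostics(state$fit)
        jsonlite::write_json(
          list(min_ess_bulk = diag$min_ess_bulk,
               divergences = diag$divergences, ebfmi = diag$ebfmi),
          file.path(config$output_dir, "diagnostics.json"),
          auto_unbox = TRUE, digits = NA, na = "null")
      })
    } else if (stage == "predict") {
      clock("predict", {
        stop_if(is.null(state$fit),
                "predict requires a fitted model; run the fit stage first")
        state$pred <- predict_cells(state$fit, state$grid,
                                    seed = stage_seed(config$seed, "predict"),
                                    thin = config$thin,
                                    block_size = config$block_size)
        utils::write.csv(state$pred$summary, paths[["cell_summary"]],
                         row.names = FALSE)
      })
    } else if (stage == "aggregate") {
      clock("aggregate", {
        stop_if(is.null(state$pred),
                "aggregate requires predictions; run the predict stage first")
        blocks <- make_block_areas(state$grid, config$areas_nx,
                                   config$areas_ny, config$zone_every)
        amap <- assign_cells(state$grid, blocks$areas)
        zmap <- assign_cells(state$grid, blocks$zones)
        state$areas <- aggregate_draws(state$pred, amap)
        state$zones <- aggregate_draws(state$pred, zmap)
        utils::write.csv(state$areas, paths[["areas"]], row.names = FALSE)
        utils::write.csv(state$zones, paths[["zones"]], row.names = FALSE)
      })
    } else if (stage == "evaluate") {
      clock("evaluate", {
        stop_if(is.null(state$fit),
                "evaluate requires a fitted model; run the fit stage first")
        pin <- predict_clusters(state$fit, state$clusters, newdata = TRUE,
                                seed = stage_seed(config$seed, "evaluate"))
        mb <- residual_metrics(state$clusters$B_obs, pin$B_rep)
        mp <- residual_metrics(state$clusters$P_obs, pin$P_rep)
        state$metrics <- rbind(cbind(outcome = "building", mb),
                               cbind(outcome = "population", mp))
        utils::write.csv(state$metrics, paths[["metrics"]], row.names = FALSE)
        resid <- state$clusters$P_obs - rowMeans(pin$P_rep)
        state$moran <- morans_i(resid,
                                cbind(state$clusters$cx, state$clusters$cy),
                                breaks = config$distance_breaks,
                                n_perm = config$n_perm,
                                seed = stage_seed(config$seed, "evaluate") + 1L)
        mo <- do.call(rbind, lapply(state$moran$bands, function(b)
          data.frame(lower = b$band[1], upper = b$band[2],
                     global_i = b$global_i, p_value = b$p_value)))
        utils::write.csv(mo, paths[["moran"]], row.names = FALSE)
      })
    }
  }
  files <- setdiff(list.files(config$output_dir, full.names = TRUE),
                   paths[["manifest"]])  # the manifest cannot hash itself
  manifest <- list(config = unclass(config)[setdiff(names(config), "")],
                   stages = stages, timings = timings,
                   seeds = sapply(c("simulate", "clusters", "fit", "predict",
                                    "aggregate", "evaluate"),
                                  function(st) stage_seed(config$seed, st)),
                   hashes = as.list(tools::md5sum(files)),
                   version = as.character(utils::packageVersion("bupop")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  manifest$results <- as.list(state)
  invisible(manifest)
}
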