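#' Build the quadrat frame from raw inputs
#'
#' Assembles the analysis table (one row per quadrat): terrain altitude
#' and convexity, the nine kriged soil properties plus fertility PC1,
#' CWM and single-trait FDis per trait, multivariate FDis, and
#' aboveground carbon storage.
#'
#' @param stems validated stem table (quadrats will be assigned).
#' @param traits validated trait table.
#' @param egrid an [elevation_grid()].
#' @param soil_samples soil sample data.frame.
#' @param grid a [plot_grid()].
#' @param variogram_family `"spherical"` or `"exponential"`.
#' @param fdis_standardize standardization of the multivariate FDis.
#' @param carbon_fraction carbon fraction of dry biomass.
#' @param impute_wd impute missing wood densities?
#' @return list with `quadrat_frame` (data.frame), `variograms`,
#'   `soil_pca`, `carbon` (full [quadrat_carbon()] result).
#' @export
build_quadrat_frame <- function(stems, traits, egrid, soil_samples, grid,
                                variogram_family = "spherical",
                                fdis_standardize = "zscore",
                                carbon_fraction = 0.5, impute_wd = TRUE) {
  stems <- assign_quadrats(stems, grid)
  terr <- convexity(egrid)
  soil <- krige_soil(soil_samples, grid, family = variogram_family)
  pca <- soil_pca(soil$table)
  comm <- community_matrix(stems, grid)
  fun <- functional_summary(comm, traits, fdis_standardize = fdis_standardize)
  carb <- quadrat_carbon(stems, traits, grid,
                         carbon_fraction = carbon_fraction,
                         impute_wd = impute_wd)
  qf <- data.frame(terr,
                   soil$table[match(terr$quadrat_id, soil$table$quadrat_id),
                              -1, drop = FALSE],
                   soil_pc1 = pca$scores[, 1],
                   fun[match(terr$quadrat_id, fun$quadrat_id), -1, drop = FALSE],
                   c_storage = carb$quadrat$c_storage[
                     match(terr$quadrat_id, carb$quadrat$quadrat_id)])
  rownames(qf) <- NULL
  list(quadrat_frame = qf, variograms = soil$models, soil_pca = pca,
       carbon = carb)
}

# default SEM specifications on the quadrat frame: environment drives the
# three leaf-trait summaries, which (with environment) drive carbon;
# leaf-trait summaries share correlated errors (common unmodelled causes)
.default_sem_edges <- function(middle) {
  env <- c("convexity", "soil_pc1")
  rbind(
    expand.grid(from = env, to = middle, stringsAsFactors = FALSE),
    expand.grid(from = c(env, middle), to = "c_storage",
                stringsAsFactors = FALSE))
}

.default_sem_error_cov <- function(middle) {
  cmb <- utils::combn(middle, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

#' Run the full statistical layer on a quadrat frame
#'
#' Pearson correlation tables (all variables vs carbon storage; trait
#' summaries vs the two environmental axes), the seven stepwise
#' regression variants (environment / dominance / diversity and their
#' combinations), LMG partitioning of the all-variables final model, and
#' the two pruned recursive path models (functional dominance and
#' functional diversity of the leaf traits as mediators).
#'
#' @param qf a quadrat frame from [build_quadrat_frame()].
#' @param alpha pruning threshold for path models.
#' @return list with `correlations_c`, `correlations_env`, `stepwise`
#'   (named list of [stepwise_ols()] fits), `importance`
#'   ([lmg_partition()] or NULL if the final model exceeds 12 regressors),
#'   `sem_dominance`, `sem_diversity` (each a [prune_path_model()]
#'   result).
#' @export
analyze_quadrat_frame <- function(qf, alpha = 0.05) {
  env <- c("convexity", "soil_pc1")
  cwm_v <- paste0(.trait_names, "_cwm")
  fdis_v <- c(paste0(.trait_names, "_fdis"), "multi_fdis")
  correlations_c <- pearson_table(qf, c(env, cwm_v, fdis_v), "c_storage")
  correlations_env <- pearson_table(qf, c(cwm_v, fdis_v), env)

  specs <- list(
    environment = env,
    dominance = cwm_v,
    diversity = fdis_v,
    environment_dominance = c(env, cwm_v),
    environment_diversity = c(env, fdis_v),
    dominance_diversity = c(cwm_v, fdis_v),
    all = c(env, cwm_v, fdis_v))
  stepwise <- lapply(specs, function(cand) stepwise_ols("c_storage", cand, qf))

  groups <- c(stats::setNames(rep("environment", length(env)), env),
              stats::setNames(rep("dominance", length(cwm_v)), cwm_v),
              stats::setNames(rep("diversity", length(fdis_v)), fdis_v))
  retained <- stepwise$all$retained
  importance <- if (length(retained) >= 1 && length(retained) <= 12)
    lmg_partition("c_storage", retained, qf, groups = groups) else NULL

  leaf_cwm <- c("la_cwm", "ldmc_cwm", "sla_cwm")
  leaf_fdis <- c("la_fdis", "ldmc_fdis", "sla_fdis")
  sem_dom <- prune_path_model(
    path_model(.default_sem_edges(leaf_cwm),
               error_cov = .default_sem_error_cov(leaf_cwm)), qf, alpha)
  sem_div <- prune_path_model(
    path_model(.default_sem_edges(leaf_fdis),
               error_cov = .default_sem_error_cov(leaf_fdis)), qf, alpha)

  list(correlations_c = correlations_c, correlations_env = correlations_env,
       stepwise = stepwise, importance = importance,
       sem_dominance = sem_dom, sem_diversity = sem_div)
}

#' Read a pipeline configuration
#'
#' YAML (or an equivalent R list) with either an `inputs:` block (paths
#' `stems`, `traits`, `elevation_corners`, optional `elevation_centers`,
#' `soil_samples`) or a `simulate:` block ([synthetic_config()]
#' arguments) — exactly one of the two — plus optional `plot_width`,
#' `plot_height`, `quadrat_size`, `variogram_family`,
#' `fdis_standardize`, `carbon_fraction`, `alpha`, `seed`, `out_dir`.
#'
#' @param config path to a YAML file, or a list.
#' @return normalised config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list")
  has_in <- !is.null(config$inputs); has_sim <- !is.null(config$simulate)
  if (has_in == has_sim)
    stop("config must contain exactly one of 'inputs' or 'simulate'")
  defaults <- list(quadrat_size = 20, variogram_family = "spherical",
                   fdis_standardize = "zscore", carbon_fraction = 0.5,
                   alpha = 0.05, seed = 1)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

#' Run the end-to-end pipeline
#'
#' Loads (or simulates) the raw plot data, builds the quadrat frame, runs
#' the statistical layer and, when `out_dir` is set, writes the output
#' bundle: `quadrat_frame.csv`, `correlations_c.csv`,
#' `correlations_env.csv`, `stepwise_models.csv`, `importance.json`,
#' `variograms.json`, `path_dominance.json` / `.dot`,
#' `path_diversity.json` / `.dot`, and `run_log.txt`.  Identical config +
#' seed gives byte-identical outputs.
#'
#' @param config a YAML path or list (see [read_pipeline_config()]).
#' @return list with `quadrat_frame`, `analysis`, `variograms`,
#'   `soil_pca`, `carbon`, `config`, and `sim` (the synthetic bundle, when
#'   simulated), invisibly written to `out_dir` if set.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  log_lines <- c(sprintf("plotcarbon %s",
                         as.character(utils::packageVersion("plotcarbon"))),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("parameters: quadrat_size=%g, variogram_family=%s, fdis_standardize=%s, carbon_fraction=%g, alpha=%g",
                         cfg$quadrat_size, cfg$variogram_family,
                         cfg$fdis_standardize, cfg$carbon_fraction, cfg$alpha))
  warn <- character(0)
  wh <- function(w) { warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning") }

  sim <- NULL
  withCallingHandlers({
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- cfg$seed
      scfg <- do.call(synthetic_config, sim_args)
      sim <- simulate_plot(scfg)
      grid <- sim$grid
      stems <- sim$stems; traits <- sim$traits
      egrid <- sim$terrain; soil_samples <- sim$soil_samples
    } else {
      inp <- cfg$inputs
      for (k in c("stems", "traits", "elevation_corners", "soil_samples"))
        if (is.null(inp[[k]]) || !file.exists(inp[[k]]))
          stop("input path missing or nonexistent: ", k)
      grid <- plot_grid(cfg$plot_width, cfg$plot_height, cfg$quadrat_size)
      stems <- read_stem_table(inp$stems, grid)
      traits <- read_trait_table(inp$traits)
      egrid <- read_elevation_grid(inp$elevation_corners, grid,
                                   inp$elevation_centers)
      soil_samples <- utils::read.csv(inp$soil_samples, stringsAsFactors = FALSE)
    }
    built <- build_quadrat_frame(stems, traits, egrid, soil_samples, grid,
                                 variogram_family = cfg$variogram_family,
                                 fdis_standardize = cfg$fdis_standardize,
                                 carbon_fraction = cfg$carbon_fraction)
    analysis <- analyze_quadrat_frame(built$quadrat_frame, alpha = cfg$alpha)
  }, warning = wh)

  out <- list(quadrat_frame = built$quadrat_frame, analysis = analysis,
              variograms = built$variograms, soil_pca = built$soil_pca,
              carbon = built$carbon, config = cfg, sim = sim)
  if (length(warn) > 0)
    log_lines <- c(log_lines, paste0("warning: ", warn))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- cfg$out_dir
    utils::write.csv(built$quadrat_frame, file.path(od, "quadrat_frame.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$correlations_c,
                     file.path(od, "correlations_c.csv"), row.names = FALSE)
    utils::write.csv(analysis$correlations_env,
                     file.path(od, "correlations_env.csv"), row.names = FALSE)
    sw <- do.call(rbind, lapply(names(analysis$stepwise), function(nm) {
      f <- analysis$stepwise[[nm]]
      coefs <- f$coefficients
      eq <- paste0(
        paste(sprintf("%+.4g*%s", coefs[f$retained], f$retained), collapse = " "),
        sprintf(" %+.4g", coefs["(Intercept)"]))
      data.frame(model = nm, equation = eq,
                 adj_r_squared = f$adj_r_squared, aic = f$aic, n = f$n,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(sw, file.path(od, "stepwise_models.csv"), row.names = FALSE)
    if (!is.null(analysis$importance))
      jsonlite::write_json(
        list(shares = as.list(analysis$importance$shares),
             proportions = as.list(analysis$importance$proportions),
             r_squared = analysis$importance$r_squared,
             group_shares = as.list(analysis$importance$group_shares)),
        file.path(od, "importance.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    jsonlite::write_json(
      lapply(built$variograms, function(m)
        m[c("family", "nugget", "psill", "range", "sse")]),
      file.path(od, "variograms.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    for (nm in c("sem_dominance", "sem_diversity")) {
      f <- analysis[[nm]]$fit
      tag <- sub("sem_", "path_", nm)
      if (!is.null(f)) {
        jsonlite::write_json(
          list(paths = f$paths, r_squared = as.list(f$r_squared),
               chisq = f$chisq, df = f$df, t = f$t, p_value = f$p_value,
               aic = f$aic, n = f$n,
               pruned = analysis[[nm]]$trace),
          file.path(od, paste0(tag, ".json")), auto_unbox = TRUE,
          digits = NA, pretty = TRUE, dataframe = "rows")
        write_path_dot(f, file.path(od, paste0(tag, ".dot")))
      }
    }
    writeLines(log_lines, file.path(od, "run_log.txt"))
  }
  invisible(out)
}

#' Command-line entry point
#'
#' `plotcarbon simulate --config cfg.yaml [--seed N] --out DIR` writes the
#' four synthetic CSV schemas plus `ground_truth.json`;
#' `plotcarbon run-all --config cfg.yaml` runs [run_pipeline()].  Used by
#' the `inst/cli/plotcarbon` Rscript shim.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
plotcarbon_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: plotcarbon <simulate|run-all> --config cfg.yaml [--seed N] [--out DIR]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$config)) { message(usage); return(invisible(1L)) }
  cfg <- read_pipeline_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (cmd == "simulate") {
    if (is.null(cfg$simulate)) stop("simulate command needs a 'simulate' config block")
    sim_args <- cfg$simulate; sim_args$seed <- cfg$seed
    sim <- simulate_plot(do.call(synthetic_config, sim_args))
    write_synthetic_plot(sim, if (is.null(cfg$out_dir)) "." else cfg$out_dir)
  } else if (cmd == "run-all") {
    run_pipeline(cfg)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
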