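## Pipeline orchestration: simulate | extract | analyze | sem | all, with a
## structured config, CSV artifacts and a run manifest.

#' Pipeline run configuration
#'
#' Defaults for every stage parameter; unknown keys are rejected. A YAML
#' file with the same (possibly nested) keys can be loaded via
#' \code{config_file}.
#'
#' @param out_dir directory for all artifacts.
#' @param rng_seed integer seed driving the whole run.
#' @param generator list of overrides for \code{\link{generation_config}}.
#' @param spar_split,spar_decline smoothing parameters, see
#'   \code{\link{extract_phenology}}.
#' @param max_restarts growth-fit restart cap.
#' @param delta_window AICc window for model averaging.
#' @param responses responses for the multimodel analysis.
#' @param alpha_add,stop_p SEM refinement controls.
#' @param config_file optional YAML file whose entries override the
#'   defaults (but not explicit arguments).
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir = "phenospan_run",
                            rng_seed = 1L,
                            generator = list(),
                            spar_split = NULL,
                            spar_decline = 0.5,
                            max_restarts = 5L,
                            delta_window = 3,
                            responses = c("season_length", "peak_day",
                                          "log_b"),
                            alpha_add = 0.05,
                            stop_p = 0.2,
                            config_file = NULL) {
  cfg <- list(out_dir = out_dir, rng_seed = as.integer(rng_seed),
              generator = generator, spar_split = spar_split,
              spar_decline = spar_decline,
              max_restarts = as.integer(max_restarts),
              delta_window = delta_window, responses = responses,
              alpha_add = alpha_add, stop_p = stop_p)
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("configuration error: unknown config key(s): ",
           paste(unknown, collapse = ", "))
    supplied <- names(match.call())[-1]
    for (k in setdiff(names(file_cfg), supplied)) cfg[[k]] <- file_cfg[[k]]
  }
  structure(cfg, class = "pipeline_config")
}

.write_artifact <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

.predictor_sets <- function() {
  list(traits = c("log_height", "log_lateral_spread", "sla", "ldmc"),
       niche = c("moisture", "light", "reaction", "nutrients",
                 "temperature", "dist_frequency", "dist_severity"))
}

#' Run the pipeline
#'
#' Stages: \code{simulate} writes the synthetic measurement, covariate and
#' truth tables; \code{extract} derives shoot series, growth and senescence
#' parameters and the phenological records; \code{analyze} runs the
#' multimodel trait/niche inference, the phenology PCA with season length
#' passively projected, the season start/end SMA regression and the season
#' length multiple regression; \code{sem} refines and fits the layered
#' structural equation model. \code{all} chains the four. Every stage reads
#' its inputs from \code{out_dir} (so stages can be re-run independently)
#' and a JSON manifest with the config, its hash, versions and per-species
#' warnings is written at the end.
#'
#' @param stage one of \code{"all"}, \code{"simulate"}, \code{"extract"},
#'   \code{"analyze"}, \code{"sem"}.
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "extract", "analyze",
                                   "sem"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") c("simulate", "extract", "analyze", "sem")
            else stage
  results <- list()
  warnings <- list()

  if ("simulate" %in% stages) {
    message("[simulate] generating synthetic dataset")
    gen <- do.call(generation_config,
                   modifyList(list(rng_seed = config$rng_seed),
                              config$generator))
    ds <- simulate_dataset(gen)
    .write_artifact(ds$measurements, out, "measurements.csv")
    .write_artifact(ds$covariates, out, "covariates.csv")
    .write_artifact(ds$truth, out, "truth.csv")
    results$simulate <- ds
  }

  if ("extract" %in% stages) {
    message("[extract] deriving phenological parameters")
    set.seed(config$rng_seed + 2L)  # restart jitter draws are reproducible
    meas <- .read_required(out, "measurements.csv")
    ex <- extract_phenology(meas, spar_split = config$spar_split,
                            spar_decline = config$spar_decline,
                            max_restarts = config$max_restarts)
    .write_artifact(ex$shoot_series, out, "shoot_series.csv")
    .write_artifact(ex$growth_params, out, "growth_params.csv")
    .write_artifact(ex$senescence_params, out, "senescence_params.csv")
    .write_artifact(ex$records, out, "pheno_records.csv")
    warnings <- c(warnings, ex$warnings)
    for (sp in names(ex$warnings))
      message("  [", sp, "] ", paste(ex$warnings[[sp]], collapse = "; "))
    results$extract <- ex
  }

  if ("analyze" %in% stages) {
    message("[analyze] multimodel inference, PCA, SMA")
    records <- .read_required(out, "pheno_records.csv")
    covars <- .read_required(out, "covariates.csv")
    missing_sp <- setdiff(records$species_id, covars$species_id)
    if (length(missing_sp)) {
      warnings$analyze_missing_covariates <- missing_sp
      message("  species missing from covariates, skipped: ",
              paste(missing_sp, collapse = ", "))
    }
    merged <- merge(records, covars, by = "species_id")
    sets <- .predictor_sets()
    for (resp in config$responses) {
      for (set_name in names(sets)) {
        eff <- tryCatch({
          ms <- all_subsets(resp, sets[[set_name]], merged)
          average_effects(ms, delta_window = config$delta_window)
        }, error = function(e) e)
        if (inherits(eff, "error")) {
          warnings[[paste0("effects_", resp, "_", set_name)]] <-
            conditionMessage(eff)
          next
        }
        .write_artifact(eff, out,
                        sprintf("effects_%s_%s.csv", resp, set_name))
        results$effects[[paste(resp, set_name, sep = ".")]] <- eff
      }
    }
    pca_vars <- c("peak_day", "log_b", "season_start", "sen_date",
                  "sen_pace", "sen_shape", "season_end")
    pca <- tryCatch(pca_with_supplementary(records[, pca_vars],
                                           records$season_length),
                    error = function(e) e)
    if (!inherits(pca, "error")) {
      mat <- rbind(pca$loadings,
                   explained_fraction = pca$explained,
                   season_length_supplementary = pca$supplementary_projection)
      .write_artifact(data.frame(variable = rownames(mat), mat,
                                 row.names = NULL), out, "pca.csv")
      results$pca <- pca
    } else warnings$pca <- conditionMessage(pca)
    ok <- complete.cases(records[, c("season_start", "season_end")])
    sma <- tryCatch(
      sma_regression(records$season_start[ok], records$season_end[ok]),
      error = function(e) e)
    if (!inherits(sma, "error")) {
      .write_artifact(data.frame(slope = sma$slope,
                                 intercept = sma$intercept,
                                 r_squared = sma$r_squared,
                                 p_value = sma$p_value, n = sma$n),
                      out, "sma_start_end.csv")
      results$sma <- sma
    } else warnings$sma <- conditionMessage(sma)
    reg <- tryCatch(regress_length_on_phenology(records),
                    error = function(e) e)
    if (!inherits(reg, "error")) {
      .write_artifact(cbind(reg$coefficients,
                            r_squared = reg$r_squared, n = reg$n),
                      out, "length_regression.csv")
      results$length_regression <- reg
    } else warnings$length_regression <- conditionMessage(reg)
  }

  if ("sem" %in% stages) {
    message("[sem] piecewise structural equation model")
    records <- .read_required(out, "pheno_records.csv")
    covars <- .read_required(out, "covariates.csv")
    merged <- merge(records, covars, by = "species_id")
    spec <- default_sem_spec()
    sem_res <- tryCatch(
      sem_refine(spec, merged, alpha_add = config$alpha_add,
                 stop_p = config$stop_p),
      error = function(e) e)
    if (inherits(sem_res, "error")) {
      warnings$sem <- conditionMessage(sem_res)
    } else {
    .write_artifact(sem_res$fit$paths, out, "sem_paths.csv")
    .write_artifact(sem_res$fit$claims, out, "sem_claims.csv")
    .write_artifact(sem_res$trail, out, "sem_trail.csv")
    jsonlite::write_json(
      list(fisher_C = sem_res$fit$fisher_C, df = sem_res$fit$df,
           p_global = sem_res$fit$p_global,
           aic_sum = sem_res$fit$aic_sum, aic_c = sem_res$fit$aic_c,
           converged = sem_res$converged,
           iterations = sem_res$iterations),
      file.path(out, "sem_summary.json"), auto_unbox = TRUE, digits = NA)
    results$sem <- sem_res
    }
  }

  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  manifest <- list(
    config = unclass(config),
    config_hash = unname(md5sum(cfg_path)),
    seed = config$rng_seed,
    stages = stages,
    versions = list(phenospan = as.character(packageVersion("phenospan")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(results)
}

.read_required <- function(out_dir, name) {
  path <- file.path(out_dir, name)
  if (!file.exists(path))
    stop("configuration error: required artifact missing: ", path,
         " (run the earlier stage first)")
  read.csv(path, stringsAsFactors = FALSE)
}
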