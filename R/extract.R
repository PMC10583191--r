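## Per-species orchestration: measurement table -> shoot series -> growth
## fit -> senescence profile -> phenological record.

#' Extract phenological parameters from a measurement table
#'
#' Runs the full per-species extraction: computes scalar sizes from the
#' dimension triplets, splits each shoot's trajectory at its smoothed
#' maximum, fits the species logistic growth model on the pooled growth
#' phases, builds the averaged senescence profile from the per-shoot decline
#' splines, and assembles the phenological records. Species whose growth fit
#' fails are reported in \code{warnings} and skipped.
#'
#' @param measurements long data frame with columns \code{species_id},
#'   \code{shoot_id}, \code{day_of_year}, \code{upper_width_cm},
#'   \code{lower_width_cm}, \code{length_cm}.
#' @param spar_split smoothing parameter for the trajectory split
#'   (\code{NULL} = generalized cross-validation).
#' @param spar_decline smoothing parameter for the decline splines
#'   (default 0.5).
#' @param candidates growth-model candidate structures, see
#'   \code{\link{fit_species_growth}}.
#' @param max_restarts restart cap per growth candidate.
#' @return List: \code{records} (see \code{\link{assemble_pheno_records}}),
#'   \code{growth_params}, \code{senescence_params}, \code{shoot_series}
#'   (tidy phase table), \code{growth_fits}, \code{warnings} (named list of
#'   per-species messages).
#' @export
extract_phenology <- function(measurements, spar_split = NULL,
                              spar_decline = 0.5,
                              candidates = .growth_candidates,
                              max_restarts = 5L) {
  need <- c("species_id", "shoot_id", "day_of_year", "upper_width_cm",
            "lower_width_cm", "length_cm")
  if (!all(need %in% names(measurements)))
    stop("parse error: measurement table lacks column(s): ",
         paste(setdiff(need, names(measurements)), collapse = ", "))
  warnings <- list()
  growth_rows <- list(); sen_rows <- list()
  series_rows <- list(); fits <- list()
  for (sp in unique(measurements$species_id)) {
    msp <- measurements[measurements$species_id == sp, , drop = FALSE]
    res <- tryCatch(
      .extract_one_species(sp, msp, spar_split, spar_decline,
                           candidates, max_restarts),
      error = function(e) e)
    if (inherits(res, "error")) {
      warnings[[sp]] <- conditionMessage(res)
      next
    }
    if (length(res$notes)) warnings[[sp]] <- res$notes
    growth_rows[[sp]] <- res$growth
    sen_rows[[sp]] <- res$senescence
    series_rows[[sp]] <- res$series
    fits[[sp]] <- res$fit
  }
  if (!length(growth_rows))
    stop("fit-failure error: no species could be extracted")
  growth_params <- do.call(rbind, growth_rows)
  senescence_params <- do.call(rbind, sen_rows)
  rownames(growth_params) <- rownames(senescence_params) <- NULL
  records <- assemble_pheno_records(growth_params, senescence_params)
  list(records = records, growth_params = growth_params,
       senescence_params = senescence_params,
       shoot_series = do.call(rbind, series_rows),
       growth_fits = fits, warnings = warnings)
}

.extract_one_species <- function(sp, msp, spar_split, spar_decline,
                                 candidates, max_restarts) {
  notes <- character()
  shoots <- split(msp, msp$shoot_id)
  series <- list()
  for (sh in names(shoots)) {
    d <- shoots[[sh]]
    size <- compute_size(d$upper_width_cm, d$lower_width_cm, d$length_cm)
    s <- tryCatch(split_trajectory(d$day_of_year, size, spar = spar_split,
                                   species_id = sp, shoot_id = sh),
                  error = function(e) e)
    if (inherits(s, "error")) {
      notes <- c(notes, sprintf("shoot %s dropped: %s", sh,
                                conditionMessage(s)))
      next
    }
    series[[sh]] <- s
  }
  if (length(series) < 2)
    stop("insufficient-data error: fewer than 2 usable shoots")

  growth_data <- do.call(rbind, lapply(series, function(s)
    data.frame(shoot_id = s$shoot_id, day = s$days[s$growth_idx],
               size = s$sizes[s$growth_idx], stringsAsFactors = FALSE)))
  fit <- fit_species_growth(growth_data, candidates = candidates,
                            max_restarts = max_restarts, species_id = sp)
  growth <- extract_growth_params(fit)

  splines <- list()
  for (s in series) {
    di <- s$decline_idx
    if (length(di) < 2) next
    sp_fit <- tryCatch(
      withCallingHandlers(
        fit_decline_spline(s$days[di], s$sizes[di], spar = spar_decline),
        warning = function(w) {
          notes <<- c(notes, sprintf("shoot %s: %s", s$shoot_id,
                                     conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(sp_fit)) splines[[s$shoot_id]] <- sp_fit
  }
  if (!length(splines)) {
    ## no shoot ever declined: treat as overwintering with undefined end
    senescence <- data.frame(species_id = sp, sen_date = NA_real_,
                             sen_pace = NA_real_, sen_shape = NA_real_,
                             season_end = NA_real_, overwinters = TRUE,
                             c_days = NA_real_, d_days = NA_real_,
                             stringsAsFactors = FALSE)
    notes <- c(notes, "no declining shoots; flagged as overwintering")
  } else {
    profile <- average_profile(splines, species_id = sp)
    senescence <- extract_senescence_params(profile)
    if (is.na(senescence$sen_pace) && !is.na(senescence$sen_date))
      notes <- c(notes, "95% or 5% crossing undefined; pace/shape missing")
  }
  list(growth = growth, senescence = senescence,
       series = do.call(rbind, lapply(series, as.data.frame)),
       fit = fit, notes = notes)
}
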