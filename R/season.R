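## Season length assembly and the standardized multiple regression of season
## length on the five phenological variables.

#' Assemble per-species phenological records
#'
#' Joins the growth and senescence parameter tables on species and computes
#' season length as season end minus season start (days run continuously
#' past December 31, so a next-January end keeps plain arithmetic).
#' Overwintering species -- whose size never falls below 25\% of maximum --
#' are assigned a season length of 365 days (and season end = start + 365);
#' lengths are capped at 365. Species missing either endpoint keep a missing
#' season length and carry an exclusion reason.
#'
#' @param growth_params data frame from \code{\link{extract_growth_params}}
#'   rows (one per species).
#' @param senescence_params data frame from
#'   \code{\link{extract_senescence_params}} rows.
#' @return Data frame of phenological records, one row per species:
#'   \code{peak_day}, \code{log_b}, \code{season_start}, \code{sen_date},
#'   \code{sen_pace}, \code{sen_shape}, \code{season_end},
#'   \code{overwinters}, \code{season_length}, \code{exclusion_reason}.
#' @export
assemble_pheno_records <- function(growth_params, senescence_params) {
  if (anyDuplicated(growth_params$species_id) ||
      anyDuplicated(senescence_params$species_id))
    stop("input error: duplicate species ids")
  rec <- merge(growth_params,
               senescence_params[, setdiff(names(senescence_params),
                                           c("c_days", "d_days"))],
               by = "species_id", all = TRUE)
  rec$overwinters[is.na(rec$overwinters)] <- FALSE
  ow <- rec$overwinters & !is.na(rec$season_start)
  rec$season_end[ow] <- rec$season_start[ow] + 365
  rec$season_length <- rec$season_end - rec$season_start
  rec$season_length <- pmin(rec$season_length, 365)
  rec$season_length[rec$overwinters] <- 365
  bad <- !is.na(rec$season_length) & rec$season_length <= 0
  rec$season_length[bad] <- NA_real_
  rec$exclusion_reason <- ifelse(
    !is.na(rec$season_length), "",
    ifelse(is.na(rec$season_start), "missing_season_start",
           ifelse(is.na(rec$season_end), "missing_season_end",
                  "nonpositive_length")))
  rec[order(rec$species_id), , drop = FALSE]
}

.pheno_predictors <- c("peak_day", "log_b", "sen_date", "sen_pace",
                       "sen_shape")

#' Regress season length on the five phenological variables
#'
#' Ordinary least squares of z-scored season length on the z-scored
#' phenological variables (date of peak growth, log standardized growth
#' rate, senescence date, pace and shape), returning standardized estimates
#' with t-based 95\% confidence intervals and the model R-squared. A
#' near-singular design triggers a warning and a pseudo-inverse coefficient
#' fallback (without confidence intervals).
#'
#' @param records data frame from \code{\link{assemble_pheno_records}}.
#' @param conf_level confidence level for the intervals.
#' @return List of class \code{"pheno_regression"}: \code{coefficients}
#'   (term, estimate, ci_low, ci_high), \code{r_squared}, \code{n}.
#' @export
regress_length_on_phenology <- function(records, conf_level = 0.95) {
  vars <- c("season_length", .pheno_predictors)
  d <- records[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10)
    stop("insufficient-data error: need >= 10 complete records")
  z <- as.data.frame(scale(d))
  X <- as.matrix(cbind(1, z[.pheno_predictors]))
  if (kappa(X) > 1e8) {
    warning("collinear predictors; using pseudo-inverse coefficients")
    beta <- drop(ginv(X) %*% z$season_length)
    coefs <- data.frame(term = .pheno_predictors,
                        estimate = beta[-1],
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE)
    fitted <- drop(X %*% beta)
    r2 <- 1 - sum((z$season_length - fitted)^2) /
      sum(z$season_length^2)
    return(structure(list(coefficients = coefs, r_squared = r2,
                          n = nrow(d), method = "pseudo-inverse"),
                     class = "pheno_regression"))
  }
  fit <- lm(reformulate(.pheno_predictors, "season_length"), data = z)
  ci <- confint(fit, level = conf_level)
  coefs <- data.frame(term = .pheno_predictors,
                      estimate = unname(coef(fit)[.pheno_predictors]),
                      ci_low = ci[.pheno_predictors, 1],
                      ci_high = ci[.pheno_predictors, 2],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 r_squared = summary(fit)$r.squared,
                 n = nrow(d), method = "ols", model = fit),
            class = "pheno_regression")
}

#' @export
print.pheno_regression <- function(x, ...) {
  cat(sprintf("Season length ~ phenology (standardized, n = %d, R^2 = %.3f)\n",
              x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}
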