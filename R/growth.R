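## Species-level logistic growth: nonlinear mixed-model fits over a candidate
## set of random-effect structures, AIC selection, and spring phenological
## parameters.

#' Simplified general logistic growth curve
#'
#' \eqn{x(t) = A + (K - A)/(1 + e^{-b (t - a)})}. The inflection is at
#' \eqn{t = a} where the derivative equals \eqn{b (K - A)/4}; with \eqn{A = 0}
#' this gives the standardized-growth-rate identity \eqn{b = 4 d / K}.
#'
#' @param t day of year (vectorized).
#' @param A projected initial size (cm); often fixed to 0.
#' @param K projected final size (cm); must exceed \code{A}.
#' @param a day of peak growth (inflection).
#' @param b standardized growth rate (1/day); must be positive.
#' @return Sizes at \code{t}.
#' @export
logistic_growth <- function(t, A = 0, K, a, b) {
  if (K <= A) stop("parameter error: K must exceed A")
  if (b <= 0) stop("parameter error: b must be positive")
  A + (K - A) * plogis(b * (t - a))
}

#' Season start implied by a logistic growth curve
#'
#' Day on which the curve reaches 25\% of the span above the initial size,
#' i.e. solves \eqn{x(t) = A + 0.25 (K - A)}; in closed form
#' \eqn{t = a - \log 3 / b} for any \code{A}.
#'
#' @param a day of peak growth.
#' @param b standardized growth rate (1/day).
#' @param fraction crossing fraction of the size span (default 0.25).
#' @return Day of year.
#' @export
logistic_crossing <- function(a, b, fraction = 0.25) {
  stopifnot(all(fraction > 0 & fraction < 1), all(b > 0))
  a + log(fraction / (1 - fraction)) / b
}

## candidate codes: "A0" = initial size fixed at zero, "A" = free;
## suffix = shoot-level random effects in addition to the residual (K always
## random, one extra parameter at most)
.growth_candidates <- c("A0.K", "A0.Ka", "A0.Kb", "A.K", "A.KA", "A.Ka", "A.Kb")

## crude pooled starting values: logistic self-start, falling back to
## half-maximum heuristics when the data are degenerate (e.g. zero noise)
.growth_start <- function(data) {
  st <- tryCatch({
    fit <- nls(size ~ SSlogis(day, K, a, scal), data = data,
               control = nls.control(scaleOffset = 1))
    cf <- coef(fit)
    c(K = unname(cf["K"]), a = unname(cf["a"]), b = 1 / unname(cf["scal"]))
  }, error = function(e) NULL)
  if (!is.null(st) && st["b"] > 0 && st["K"] > 0) return(st)
  K0 <- max(data$size)
  half <- data$day[which.min(abs(data$size - K0 / 2))]
  c(K = K0, a = half, b = 0.1)
}

.meaningful_growth <- function(pars, data) {
  rng <- range(data$day)
  pars[["a"]] >= rng[1] - 60 && pars[["a"]] <= rng[2] + 60 &&
    pars[["b"]] > 1e-4 && pars[["b"]] < 5 &&
    pars[["K"]] > 0 && pars[["K"]] < 10 * max(data$size) &&
    (is.na(pars[["A"]]) || pars[["A"]] < pars[["K"]])
}

.fit_growth_candidate <- function(candidate, data, start, max_restarts) {
  free_A <- !startsWith(candidate, "A0")
  ran <- sub("^A0?\\.", "", candidate)
  model <- if (free_A)
    size ~ A + (K - A) / (1 + exp(-b * (day - a)))
  else
    size ~ K / (1 + exp(-b * (day - a)))
  fixed <- if (free_A) A + K + a + b ~ 1 else K + a + b ~ 1
  random <- switch(ran,
                   K = K ~ 1,
                   KA = pdDiag(K + A ~ 1),
                   Ka = pdDiag(K + a ~ 1),
                   Kb = pdDiag(K + b ~ 1))
  base_start <- if (free_A) c(A = 0, start) else start
  last_err <- NULL
  for (try_i in seq_len(max_restarts + 1L)) {
    st <- base_start
    if (try_i > 1L) {  # systematic jitter of the initial values
      st["K"] <- st["K"] * runif(1, 0.5, 1.5)
      st["a"] <- st["a"] + runif(1, -0.5, 0.5) * 30
      st["b"] <- st["b"] * runif(1, 0.5, 1.5)
    }
    fit <- tryCatch(
      nlme(model, data = data, fixed = fixed, random = random,
           groups = ~shoot_id, start = st, method = "ML",
           control = nlmeControl(maxIter = 200, msMaxIter = 200,
                                 returnObject = FALSE)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      fe <- fixef(fit)
      pars <- c(A = if (free_A) unname(fe["A"]) else NA_real_,
                K = unname(fe["K"]), a = unname(fe["a"]), b = unname(fe["b"]))
      if (.meaningful_growth(pars, data))
        return(list(fit = fit, restarts = try_i - 1L, error = NULL))
      last_err <- simpleError("converged outside meaningful parameter range")
    } else last_err <- fit
  }
  list(fit = NULL, restarts = max_restarts, error = conditionMessage(last_err))
}

## fixed-effects fallback for degenerate (e.g. noiseless) data where the
## mixed model's residual variance collapses: per-shoot K, common a and b
.fit_growth_fallback <- function(data, start) {
  data$shoot_id <- factor(data$shoot_id)
  nsh <- nlevels(data$shoot_id)
  st <- list(K = rep(start[["K"]], nsh), a = start[["a"]], b = start[["b"]])
  fit <- nls(size ~ K[shoot_id] / (1 + exp(-b * (day - a))),
             data = data, start = st,
             control = nls.control(scaleOffset = 1, maxiter = 200))
  fit
}

#' Fit the species-level logistic growth model
#'
#' Pools the growth-phase points of all shoots of one species and fits a
#' candidate set crossing \{initial size A free, A = 0\} with shoot-level
#' random-effect structures \{K only; K plus one of A, a, b\} by nonlinear
#' mixed-model regression (maximum likelihood). Non-converging candidates are
#' restarted from jittered initial values up to \code{max_restarts} times;
#' the converged candidate with the lowest AIC is returned. If no mixed
#' model converges (typically when the residual variance is essentially
#' zero), a fixed-effects logistic with per-shoot K is fitted instead.
#'
#' @param data data frame with columns \code{shoot_id}, \code{day},
#'   \code{size} (growth-phase points only).
#' @param candidates subset of
#'   \code{c("A0.K","A0.Ka","A0.Kb","A.K","A.KA","A.Ka","A.Kb")}.
#' @param max_restarts restart cap per candidate.
#' @param species_id optional label carried through.
#' @return An object of class \code{"logistic_fit"} with elements
#'   \code{A}, \code{K}, \code{a}, \code{b}, per-shoot \code{K_i},
#'   \code{structure}, \code{loglik}, \code{n_params}, \code{aic},
#'   \code{aic_table}, \code{converged}, \code{n_restarts}.
#' @export
fit_species_growth <- function(data,
                               candidates = .growth_candidates,
                               max_restarts = 5L,
                               species_id = NA_character_) {
  stopifnot(all(c("shoot_id", "day", "size") %in% names(data)))
  candidates <- match.arg(candidates, .growth_candidates,
                          several.ok = TRUE)
  counts <- table(data$shoot_id)
  if (sum(counts >= 4) < 2)
    stop("insufficient-data error: need >= 2 shoots with >= 4 growth points")
  data <- data[order(data$shoot_id, data$day), , drop = FALSE]
  start <- .growth_start(data)

  results <- lapply(candidates, .fit_growth_candidate, data = data,
                    start = start, max_restarts = max_restarts)
  names(results) <- candidates
  aic_table <- data.frame(
    structure = candidates,
    converged = vapply(results, function(r) !is.null(r$fit), logical(1)),
    aic = vapply(results, function(r)
      if (is.null(r$fit)) NA_real_ else AIC(r$fit), numeric(1)),
    restarts = vapply(results, function(r) r$restarts, integer(1)),
    message = vapply(results, function(r)
      if (is.null(r$error)) "" else as.character(r$error), character(1)),
    stringsAsFactors = FALSE)

  if (any(aic_table$converged)) {
    best_i <- which(aic_table$aic == min(aic_table$aic, na.rm = TRUE))[1]
    fit <- results[[best_i]]$fit
    fe <- fixef(fit)
    ll <- logLik(fit)
    ki <- coef(fit)[, "K"]
    obj <- list(species_id = species_id,
                structure = aic_table$structure[best_i],
                A = if ("A" %in% names(fe)) unname(fe["A"]) else 0,
                K = unname(fe["K"]), a = unname(fe["a"]), b = unname(fe["b"]),
                K_i = setNames(ki, rownames(coef(fit))),
                loglik = as.numeric(ll), n_params = attr(ll, "df"),
                aic = AIC(fit), aic_table = aic_table,
                converged = TRUE, n_restarts = results[[best_i]]$restarts,
                model = fit)
    class(obj) <- "logistic_fit"
    return(obj)
  }

  fb <- tryCatch(.fit_growth_fallback(data, start), error = function(e) e)
  if (inherits(fb, "error")) {
    err <- simpleError(paste0(
      "fit-failure error: no growth-model candidate converged for species ",
      species_id))
    err$diagnostics <- aic_table
    stop(err)
  }
  cf <- coef(fb)
  ki <- cf[startsWith(names(cf), "K")]
  names(ki) <- levels(factor(data$shoot_id))
  ll <- suppressWarnings(logLik(fb))
  obj <- list(species_id = species_id, structure = "nls_fixed_K",
              A = 0, K = mean(ki), a = unname(cf[["a"]]), b = unname(cf[["b"]]),
              K_i = ki,
              loglik = as.numeric(ll), n_params = attr(ll, "df"),
              aic = if (is.finite(ll)) AIC(fb) else NA_real_,
              aic_table = aic_table, converged = TRUE, n_restarts = 0L,
              model = fb)
  class(obj) <- "logistic_fit"
  obj
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic growth fit%s [%s]\n",
              if (is.na(x$species_id)) "" else paste0(" for ", x$species_id),
              x$structure))
  cat(sprintf("  A = %.3g  K = %.3g cm  a = %.1f  b = %.4g /day  AIC = %.2f\n",
              x$A, x$K, x$a, x$b, x$aic))
  invisible(x)
}

#' Extract spring phenological parameters from a growth fit
#'
#' @param fit a converged \code{"logistic_fit"}.
#' @return One-row data frame: \code{species_id}, \code{peak_day} (the
#'   inflection \code{a}), \code{log_b} (natural log of the standardized
#'   growth rate), \code{season_start} (25\% crossing,
#'   \eqn{a - \log 3 / b}), \code{growth_structure}, \code{growth_aic}.
#' @export
extract_growth_params <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"), isTRUE(fit$converged))
  data.frame(species_id = fit$species_id,
             peak_day = fit$a,
             log_b = log(fit$b),
             season_start = logistic_crossing(fit$a, fit$b, 0.25),
             growth_structure = fit$structure,
             growth_aic = fit$aic,
             stringsAsFactors = FALSE)
}
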