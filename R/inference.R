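## All-subsets AICc multimodel inference, Akaike-weight averaging, PCA with
## supplementary projection, and standardized major axis regression.

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\,\ell + 2k + 2k(k+1)/(n-k-1)}, with \eqn{k} counting every
#' estimated parameter (coefficients, intercept and residual variance).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed \eqn{k + 1}.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("size error: n must exceed k + 1 for the AICc correction")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from information-criterion values
#'
#' \eqn{w_m = e^{-\Delta_m/2} / \sum_j e^{-\Delta_j/2}} with
#' \eqn{\Delta_m = IC_m - \min IC}; invariant to adding a constant to every
#' value.
#'
#' @param ic vector of AIC/AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(ic) {
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit every predictor subset by OLS and rank by AICc
#'
#' Exhaustive all-subsets regression on z-scored variables (the dredge
#' semantics): every subset of the predictors, including the intercept-only
#' model, is fitted by ordinary least squares; models are ranked by AICc and
#' assigned Akaike weights
#' \eqn{w_m = e^{-\Delta_m/2} / \sum_j e^{-\Delta_j/2}}.
#'
#' @param response name of the response column.
#' @param predictors character vector of predictor columns (at most 12).
#' @param data data frame; incomplete rows are dropped.
#' @return An object of class \code{"model_set"}: the z-scored data, a
#'   \code{models} table (terms, k, loglik, aicc, delta, weight) and the
#'   fitted \code{lm} objects.
#' @export
all_subsets <- function(response, predictors, data) {
  stopifnot(length(predictors) >= 1, length(predictors) <= 12,
            all(c(response, predictors) %in% names(data)))
  d <- data[, c(response, predictors), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k_max <- length(predictors) + 2  # full model: slopes + intercept + sigma
  if (n <= k_max + 1)
    stop("size error: too few complete cases for the AICc correction")
  z <- as.data.frame(scale(d))
  p <- length(predictors)
  n_models <- 2^p
  fits <- vector("list", n_models)
  terms <- vector("list", n_models)
  stats <- data.frame(model_id = seq_len(n_models), k = NA_real_,
                      loglik = NA_real_, aicc = NA_real_)
  for (m in seq_len(n_models)) {
    sel <- predictors[bitwAnd(m - 1L, bitwShiftL(1L, seq_len(p) - 1L)) > 0]
    terms[[m]] <- sel
    fo <- if (length(sel)) reformulate(sel, response)
          else as.formula(paste(response, "~ 1"))
    fit <- lm(fo, data = z)
    ll <- logLik(fit)
    stats$k[m] <- attr(ll, "df")
    stats$loglik[m] <- as.numeric(ll)
    stats$aicc[m] <- aicc(as.numeric(ll), attr(ll, "df"), n)
    fits[[m]] <- fit
  }
  stats$delta <- stats$aicc - min(stats$aicc)
  stats$weight <- akaike_weights(stats$aicc)
  stats$terms <- I(terms)
  structure(list(response = response, predictors = predictors,
                 n = n, data = z, models = stats, fits = fits),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("Model set for %s: %d candidate models over %d predictors (n = %d)\n",
              x$response, nrow(x$models), length(x$predictors), x$n))
  best <- x$models[order(x$models$delta), ][1:min(5, nrow(x$models)), ]
  for (i in seq_len(nrow(best)))
    cat(sprintf("  {%s}  AICc %.2f  delta %.2f  weight %.3f\n",
                paste(best$terms[[i]], collapse = ", "),
                best$aicc[i], best$delta[i], best$weight[i]))
  invisible(x)
}

#' Akaike-weighted model averaging within the best-model window
#'
#' Restricts the set to models within \code{delta_window} AICc units of the
#' best model and renormalizes their weights. Each predictor's importance is
#' the summed weight of the window models containing it; its estimate (and
#' confidence-interval endpoints) are weight-averaged over only those models
#' (conditional averaging). Predictors absent from every window model are
#' reported with importance 0 and missing estimates.
#'
#' @param model_set a \code{"model_set"}.
#' @param delta_window AICc window half-width (strictly less than; default 3).
#' @param conf_level confidence level for per-model intervals.
#' @return Data frame: \code{predictor}, \code{estimate}, \code{ci_low},
#'   \code{ci_high}, \code{importance}. The number of window models is
#'   attached as attribute \code{"n_window"}.
#' @export
average_effects <- function(model_set, delta_window = 3, conf_level = 0.95) {
  stopifnot(inherits(model_set, "model_set"))
  win <- which(model_set$models$delta < delta_window)
  if (!length(win)) stop("empty best-model window")
  w <- model_set$models$weight[win]
  w <- w / sum(w)
  rows <- lapply(model_set$predictors, function(p) {
    has <- vapply(model_set$models$terms[win], function(tt) p %in% tt,
                  logical(1))
    if (!any(has))
      return(data.frame(predictor = p, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        importance = 0, stringsAsFactors = FALSE))
    wc <- w[has] / sum(w[has])
    est <- lo <- hi <- numeric(sum(has))
    for (j in seq_along(est)) {
      fit <- model_set$fits[[win[has][j]]]
      est[j] <- coef(fit)[[p]]
      ci <- confint(fit, p, level = conf_level)
      lo[j] <- ci[1]; hi[j] <- ci[2]
    }
    data.frame(predictor = p, estimate = sum(wc * est),
               ci_low = sum(wc * lo), ci_high = sum(wc * hi),
               importance = sum(w[has]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_window") <- length(win)
  attr(out, "ci_method") <- "weighted interval endpoints, conditional averaging"
  out
}

#' Principal component analysis with a passively projected variable
#'
#' Eigen-decomposition of the correlation matrix (PCA of centred and
#' standardized data). A supplementary variable does not influence the
#' decomposition; it is projected afterwards as its correlation with the
#' scores of each axis.
#'
#' @param x data frame or matrix of active variables; incomplete rows are
#'   dropped (jointly with \code{supplementary}).
#' @param supplementary optional numeric vector (or single-column data
#'   frame) to project passively.
#' @return An object of class \code{"pheno_pca"}: \code{scores},
#'   \code{loadings}, \code{eigenvalues}, \code{explained} (fractions
#'   summing to 1) and \code{supplementary_projection}.
#' @export
pca_with_supplementary <- function(x, supplementary = NULL) {
  x <- as.data.frame(x)
  if (!is.null(supplementary)) {
    supplementary <- as.numeric(unlist(supplementary))
    stopifnot(length(supplementary) == nrow(x))
    keep <- complete.cases(x) & !is.na(supplementary)
    supplementary <- supplementary[keep]
  } else keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3) stop("insufficient-data error: need >= 3 complete rows")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0))
    stop("degenerate-variable error: constant column(s): ",
         paste(names(x)[sds == 0], collapse = ", "))
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  eig <- fit$sdev^2
  proj <- if (is.null(supplementary)) NULL
          else setNames(drop(cor(supplementary, fit$x)), colnames(fit$x))
  structure(list(scores = fit$x, loadings = fit$rotation,
                 eigenvalues = eig, explained = eig / sum(eig),
                 supplementary_projection = proj, n = nrow(x)),
            class = "pheno_pca")
}

#' @export
print.pheno_pca <- function(x, ...) {
  cat(sprintf("PCA on %d rows, %d axes\n", x$n, length(x$eigenvalues)))
  cat("  explained:",
      paste0(sprintf("%.1f%%", 100 * x$explained[1:min(4, length(x$explained))]),
             collapse = ", "), "\n")
  if (!is.null(x$supplementary_projection))
    cat("  supplementary projection (axis correlations):",
        paste0(sprintf("%.2f", x$supplementary_projection[1:2]),
               collapse = ", "), "\n")
  invisible(x)
}

#' Standardized major axis regression
#'
#' Line of best fit treating both variables symmetrically:
#' slope \eqn{= \mathrm{sign}(r)\, s_y / s_x}, intercept through the means.
#' The p-value is that of the correlation test.
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @return An object of class \code{"sma_fit"}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_value}, \code{n}.
#' @export
sma_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("insufficient-data error: need n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate error: zero variance")
  r <- cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sd(y) / sd(x)
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 r_squared = r^2,
                 p_value = cor.test(x, y)$p.value,
                 n = length(x)),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA regression (n = %d): slope %.4g, intercept %.4g, r^2 = %.3f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}
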