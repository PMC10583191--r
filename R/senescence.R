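## Per-shoot decline splines, averaged species senescence profiles, and the
## senescence parameters (date, pace, shape) plus season end.

#' Fit a smoothing spline to the declining part of a trajectory
#'
#' Cubic smoothing spline with a fixed \code{spar} smoothing level (default
#' 0.5). With fewer than four distinct days the spline is replaced by linear
#' interpolation, with a warning.
#'
#' @param days day-of-year values of the decline-phase points.
#' @param sizes sizes (cm) at those days.
#' @param spar smoothing parameter of \code{\link[stats]{smooth.spline}}.
#' @return An object of class \code{"decline_spline"}: an evaluable
#'   \code{fun(t)}, its valid \code{range}, the point count \code{n} and the
#'   \code{method} used.
#' @export
fit_decline_spline <- function(days, sizes, spar = 0.5) {
  keep <- is.finite(days) & is.finite(sizes)
  days <- days[keep]; sizes <- sizes[keep]
  ord <- order(days)
  days <- days[ord]; sizes <- sizes[ord]
  n_distinct <- length(unique(days))
  if (n_distinct < 2)
    stop("insufficient-data error: need at least 2 decline points")
  if (n_distinct >= 4) {
    fit <- smooth.spline(days, sizes, spar = spar)
    fun <- function(t) predict(fit, t)$y
    method <- "smooth.spline"
  } else {
    warning("fewer than 4 decline points; falling back to linear interpolation")
    fun <- approxfun(days, sizes, rule = 2)
    method <- "linear"
  }
  structure(list(fun = fun, range = range(days), n = length(days),
                 method = method, spar = spar),
            class = "decline_spline")
}

#' Average individual decline splines into a species senescence profile
#'
#' Each individual's spline is evaluated on a common daily grid restricted to
#' its own observation span, normalized by that individual's own maximum
#' (by default the maximum of its decline spline), and averaged pointwise
#' over the individuals defined at each grid day. Crossing dates for the
#' 95, 50, 25 and 5\% fractions are located on the averaged curve (the 95\%
#' crossing as the \emph{last} day at or above that fraction, the others as
#' the \emph{first} day at or below).
#'
#' @param splines list of \code{"decline_spline"} objects.
#' @param maxima optional numeric vector of per-individual maximum sizes used
#'   for normalization; defaults to each spline's own maximum.
#' @param species_id optional label.
#' @return An object of class \code{"senescence_profile"}: \code{grid_days},
#'   \code{mean_fraction}, \code{n_individuals} (per grid day),
#'   \code{crossings} (named vector for fractions 0.95, 0.50, 0.25, 0.05)
#'   and the \code{overwinters} flag (25\% never reached).
#' @export
average_profile <- function(splines, maxima = NULL,
                            species_id = NA_character_) {
  stopifnot(length(splines) >= 1,
            all(vapply(splines, inherits, logical(1), "decline_spline")))
  from <- ceiling(min(vapply(splines, function(s) s$range[1], numeric(1))))
  to <- floor(max(vapply(splines, function(s) s$range[2], numeric(1))))
  if (to < from) stop("profile error: empty grid overlap")
  grid <- seq(from, to, by = 1)
  frac <- matrix(NA_real_, length(grid), length(splines))
  for (j in seq_along(splines)) {
    s <- splines[[j]]
    inside <- grid >= s$range[1] & grid <= s$range[2]
    if (!any(inside)) next
    vals <- s$fun(grid[inside])
    mx <- if (is.null(maxima)) max(vals) else maxima[j]
    if (!is.finite(mx) || mx <= 0) next
    frac[inside, j] <- vals / mx
  }
  n_ind <- rowSums(!is.na(frac))
  if (!any(n_ind > 0)) stop("profile error: no individual defined on the grid")
  mean_fraction <- rowMeans(frac, na.rm = TRUE)
  senescence_profile(grid, mean_fraction, species_id = species_id,
                     n_individuals = n_ind)
}

#' Construct a senescence profile from an averaged fraction curve
#'
#' Low-level constructor: takes a daily grid and the averaged
#' fraction-of-maximum curve, locates the standard crossings (last 95\%,
#' first 50/25/5\%) and sets the overwintering flag.
#'
#' @param grid_days daily grid (day of year).
#' @param mean_fraction averaged normalized size on the grid.
#' @param species_id optional label.
#' @param n_individuals individuals contributing per grid day.
#' @return An object of class \code{"senescence_profile"}.
#' @export
senescence_profile <- function(grid_days, mean_fraction,
                               species_id = NA_character_,
                               n_individuals = rep(1L, length(grid_days))) {
  stopifnot(length(grid_days) == length(mean_fraction))
  prof <- structure(list(species_id = species_id, grid_days = grid_days,
                         mean_fraction = mean_fraction,
                         n_individuals = n_individuals),
                    class = "senescence_profile")
  prof$crossings <- c(
    "0.95" = crossing_date(prof, 0.95, "last"),
    "0.5"  = crossing_date(prof, 0.50, "first"),
    "0.25" = crossing_date(prof, 0.25, "first"),
    "0.05" = crossing_date(prof, 0.05, "first"))
  prof$overwinters <- is.na(prof$crossings[["0.25"]])
  prof
}

#' Fraction-crossing day of a senescence profile
#'
#' \code{mode = "first"}: earliest grid day at which the averaged fraction is
#' at or below \code{fraction}; \code{mode = "last"}: latest grid day at or
#' above it. Sub-day resolution (0.1 day) by linear interpolation between the
#' adjacent grid days. Returns \code{NA} if the level is never crossed.
#'
#' @param profile a \code{"senescence_profile"}.
#' @param fraction fraction of maximum size, in (0, 1).
#' @param mode \code{"first"} or \code{"last"}.
#' @return Day of year, or \code{NA} if undefined.
#' @export
crossing_date <- function(profile, fraction, mode = c("first", "last")) {
  stopifnot(inherits(profile, "senescence_profile"),
            fraction > 0, fraction < 1)
  mode <- match.arg(mode)
  g <- profile$grid_days
  f <- profile$mean_fraction
  ok <- !is.na(f)
  g <- g[ok]; f <- f[ok]
  if (!length(g)) return(NA_real_)
  if (mode == "first") {
    hits <- which(f <= fraction)
    if (!length(hits)) return(NA_real_)
    i <- hits[1]
    if (i == 1) return(g[1])
    day <- g[i - 1] + (f[i - 1] - fraction) / (f[i - 1] - f[i]) *
      (g[i] - g[i - 1])
  } else {
    hits <- which(f >= fraction)
    if (!length(hits)) return(NA_real_)
    i <- hits[length(hits)]
    if (i == length(g)) return(g[length(g)])
    day <- g[i] + (f[i] - fraction) / (f[i] - f[i + 1]) * (g[i + 1] - g[i])
  }
  round(day, 1)
}

#' Extract senescence parameters and season end from a profile
#'
#' Senescence date is the first 50\% crossing; pace is the inverse of the
#' days between the last 95\% and first 5\% crossings; shape is
#' \eqn{\log(C/D)} with \eqn{C} the 50\%-to-5\% duration and \eqn{D} the
#' 95\%-to-50\% duration; season end is the first 25\% crossing. Species
#' whose profile never reaches 50\% yield all-\code{NA} parameters and are
#' excluded downstream; an undefined 95\% or 5\% crossing leaves pace and
#' shape \code{NA}.
#'
#' @param profile a \code{"senescence_profile"}.
#' @param flip_shape if \code{TRUE}, report \eqn{\log(D/C)} instead (the
#'   opposite sign convention).
#' @return One-row data frame: \code{species_id}, \code{sen_date},
#'   \code{sen_pace}, \code{sen_shape}, \code{season_end},
#'   \code{overwinters}, plus the raw durations \code{c_days}, \code{d_days}.
#' @export
extract_senescence_params <- function(profile, flip_shape = FALSE) {
  stopifnot(inherits(profile, "senescence_profile"))
  cr <- profile$crossings
  t95 <- cr[["0.95"]]; t50 <- cr[["0.5"]]
  t25 <- cr[["0.25"]]; t05 <- cr[["0.05"]]
  if (is.na(t50)) {
    return(data.frame(species_id = profile$species_id,
                      sen_date = NA_real_, sen_pace = NA_real_,
                      sen_shape = NA_real_, season_end = NA_real_,
                      overwinters = profile$overwinters,
                      c_days = NA_real_, d_days = NA_real_,
                      stringsAsFactors = FALSE))
  }
  pace <- if (is.na(t95) || is.na(t05)) NA_real_ else 1 / (t05 - t95)
  C <- if (is.na(t05)) NA_real_ else t05 - t50
  D <- if (is.na(t95)) NA_real_ else t50 - t95
  shape <- if (is.na(C) || is.na(D) || C <= 0 || D <= 0) NA_real_
           else if (flip_shape) log(D / C) else log(C / D)
  data.frame(species_id = profile$species_id,
             sen_date = t50, sen_pace = pace, sen_shape = shape,
             season_end = t25, overwinters = profile$overwinters,
             c_days = C, d_days = D,
             stringsAsFactors = FALSE)
}

#' @export
print.senescence_profile <- function(x, ...) {
  cat(sprintf("Senescence profile %s: days %g-%g, up to %d individuals\n",
              x$species_id, min(x$grid_days), max(x$grid_days),
              max(x$n_individuals)))
  cr <- x$crossings
  cat(sprintf("  crossings: 95%% %.1f | 50%% %.1f | 25%% %.1f | 5%% %.1f%s\n",
              cr[["0.95"]], cr[["0.5"]], cr[["0.25"]], cr[["0.05"]],
              if (isTRUE(x$overwinters)) "  (overwinters)" else ""))
  invisible(x)
}
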