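## Raw dimension triplets -> scalar plant size, and seasonal trajectory
## segmentation into growth and decline phases.

#' Conical-frustum volume of a shoot
#'
#' \eqn{V = \pi L (w_u^2 + w_u w_l + w_l^2) / 12}. Interpolates between the
#' cone (one width zero) and cylinder (equal widths) limits and uses all
#' three measured dimensions symmetrically.
#'
#' @param upper_width,lower_width,length shoot dimensions in cm, all >= 0.
#' @return Volume in cm^3.
#' @export
frustum_volume <- function(upper_width, lower_width, length) {
  if (any(c(upper_width, lower_width, length) < 0, na.rm = TRUE))
    stop("domain error: shoot dimensions must be non-negative")
  pi * length * (upper_width^2 + upper_width * lower_width +
                   lower_width^2) / 12
}

#' Scalar plant size from a shoot dimension triplet
#'
#' Size is the cube root of the shoot volume, so it carries length units and
#' grows linearly with isometric scaling of the shoot. The volume model is
#' pluggable; the default is the conical frustum.
#'
#' @inheritParams frustum_volume
#' @param volume_fun function of (upper, lower, length) returning a volume;
#'   defaults to \code{\link{frustum_volume}}.
#' @return Size in cm; zero iff length is zero or both widths are zero.
#' @export
compute_size <- function(upper_width, lower_width, length,
                         volume_fun = frustum_volume) {
  volume_fun(upper_width, lower_width, length)^(1 / 3)
}

#' Split one shoot's seasonal trajectory into growth and decline
#'
#' Fits a cubic smoothing spline to (day, size), locates its maximum on a
#' 0.1-day grid (ties broken toward the earliest day), and partitions the
#' measurement points: growth = days at or before the split day, decline =
#' days at or after it, so a measurement exactly at the maximum belongs to
#' both phases.
#'
#' @param days day-of-year values (Jan 1 = day 1; later-than-December
#'   observations continue past 365).
#' @param sizes plant sizes (cm), same length as \code{days}.
#' @param spar smoothing parameter passed to
#'   \code{\link[stats]{smooth.spline}}; \code{NULL} selects it by
#'   generalized cross-validation.
#' @param species_id,shoot_id optional labels carried through.
#' @param grid_step grid resolution (days) for locating the maximum.
#' @return An object of class \code{"shoot_series"}: the sorted data, the
#'   \code{split_day}, the spline's \code{max_size}, and index vectors
#'   \code{growth_idx} / \code{decline_idx}.
#' @export
split_trajectory <- function(days, sizes, spar = NULL,
                             species_id = NA_character_,
                             shoot_id = NA_character_,
                             grid_step = 0.1) {
  keep <- is.finite(days) & is.finite(sizes)
  days <- days[keep]; sizes <- sizes[keep]
  if (length(days) < 4)
    stop("insufficient-data error: need at least 4 observations")
  ord <- order(days)
  days <- days[ord]; sizes <- sizes[ord]
  if (all(sizes == 0))
    stop("empty-trajectory error: all sizes are zero")
  if (length(unique(sizes[sizes > 0])) < 2)
    stop("insufficient-data error: need at least 2 distinct positive sizes")
  fit <- if (is.null(spar)) smooth.spline(days, sizes)
         else smooth.spline(days, sizes, spar = spar)
  grid <- seq(min(days), max(days), by = grid_step)
  pred <- predict(fit, grid)$y
  peak <- which.max(pred)  # earliest grid day on ties
  split_day <- grid[peak]
  growth_idx <- which(days <= split_day)
  decline_idx <- which(days >= split_day)
  ## the split can fall between two measurement days; anchor the decline at
  ## the last growth observation so the decline phase starts at the peak side
  if (length(growth_idx) && length(decline_idx) &&
      max(growth_idx) + 1L == min(decline_idx))
    decline_idx <- c(max(growth_idx), decline_idx)
  structure(list(species_id = species_id, shoot_id = shoot_id,
                 days = days, sizes = sizes,
                 split_day = split_day, max_size = pred[peak],
                 growth_idx = growth_idx, decline_idx = decline_idx,
                 spline = fit),
            class = "shoot_series")
}

#' @export
print.shoot_series <- function(x, ...) {
  cat(sprintf("Shoot series %s / %s: %d points over days %g-%g\n",
              x$species_id, x$shoot_id, length(x$days),
              min(x$days), max(x$days)))
  cat(sprintf("  split day %.1f (spline max %.3g cm); %d growth / %d decline points\n",
              x$split_day, x$max_size,
              length(x$growth_idx), length(x$decline_idx)))
  invisible(x)
}

#' Tidy per-shoot phase table
#'
#' @param series a \code{"shoot_series"} object.
#' @return Data frame with one row per (point, phase) assignment.
#' @export
as.data.frame.shoot_series <- function(x, ...) {
  phase <- c(rep("growth", length(x$growth_idx)),
             rep("decline", length(x$decline_idx)))
  idx <- c(x$growth_idx, x$decline_idx)
  data.frame(species_id = x$species_id, shoot_id = x$shoot_id,
             day_of_year = x$days[idx], size_cm = x$sizes[idx],
             phase = phase, split_day = x$split_day,
             stringsAsFactors = FALSE)
}
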