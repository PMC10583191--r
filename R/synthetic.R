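## Synthetic shoot-trajectory generator with known ground truth.
##
## Each species carries a niche vector (Ellenberg-style indicator scores plus
## disturbance frequency/severity), four functional traits, logistic growth
## parameters (a, b, K) and Richards-type senescence parameters (m, s, theta).
## Traits are linear maps of niche scores; growth/senescence parameters are
## linear maps of niche and traits; both with Gaussian structural noise.
## Measurements are rendered as a long table of shoot dimension triplets with
## multiplicative lognormal noise, so every downstream extraction stage has an
## analytic parameter-recovery surface.

.niche_vars <- c("moisture", "light", "reaction", "nutrients", "temperature",
                 "dist_frequency", "dist_severity")
.trait_vars <- c("log_height", "log_lateral_spread", "sla", "ldmc")
.phen_latent <- c("a", "log_b", "m", "log_s", "log_theta", "log_K")

#' Default niche-to-trait path coefficients
#'
#' Standardized coefficients mapping niche scores to functional traits in the
#' synthetic generator. Signs follow well-established field relationships:
#' plants of moist, nutrient-rich habitats are taller and spread more
#' clonally; shade plants have high SLA; leaves on base-rich soils tend to
#' lower dry matter content.
#'
#' @return A 4 x 7 numeric matrix (traits x niche variables).
#' @export
default_niche_trait_paths <- function() {
  B <- matrix(0, length(.trait_vars), length(.niche_vars),
              dimnames = list(.trait_vars, .niche_vars))
  B["log_height", "moisture"] <- 0.40
  B["log_height", "light"] <- -0.20
  B["log_height", "nutrients"] <- 0.30
  B["log_lateral_spread", "moisture"] <- 0.35
  B["sla", "light"] <- -0.45
  B["sla", "nutrients"] <- 0.25
  B["ldmc", "reaction"] <- -0.30
  B["ldmc", "light"] <- 0.25
  B
}

#' Default (niche, trait)-to-phenology path coefficients
#'
#' Standardized coefficients mapping niche scores and traits to the latent
#' growth/senescence parameters (a, log b, m, log s, log theta, log K).
#' Tall plants peak later; open and undisturbed habitats delay senescence;
#' high-LDMC leaves senesce with a decelerating (high-theta) profile.
#'
#' @return A 6 x 11 numeric matrix (latent parameters x niche+trait columns).
#' @export
default_phenology_paths <- function() {
  cols <- c(.niche_vars, .trait_vars)
  B <- matrix(0, length(.phen_latent), length(cols),
              dimnames = list(.phen_latent, cols))
  B["a", "moisture"] <- 0.30
  B["a", "light"] <- 0.25
  B["a", "log_height"] <- 0.35
  B["log_b", "dist_frequency"] <- -0.30
  B["log_b", "log_lateral_spread"] <- 0.25
  B["log_b", "sla"] <- 0.20
  B["m", "light"] <- 0.45
  B["m", "dist_frequency"] <- -0.35
  B["m", "reaction"] <- 0.25
  B["m", "log_lateral_spread"] <- 0.30
  B["m", "log_height"] <- 0.20
  B["log_s", "sla"] <- 0.20
  B["log_s", "dist_frequency"] <- 0.20
  B["log_theta", "ldmc"] <- 0.30
  B["log_K", "nutrients"] <- 0.40
  B
}

#' Configuration for the synthetic trajectory generator
#'
#' @param n_species number of species to generate.
#' @param shoots_per_species shoots (individuals) measured per species.
#' @param cadence_days days between successive measurement dates.
#' @param first_day day-of-year of the first measurement (Jan 1 = day 1).
#' @param season_days last possible measurement day.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise applied independently to each measured dimension.
#' @param shoot_k_cv coefficient of variation of the lognormal shoot-level
#'   final size \eqn{K_i} around the species value.
#' @param structural_noise multiplier on the residual standard deviations of
#'   the trait and phenology structural equations; 0 makes species exact
#'   linear functions of their niche.
#' @param baseline named list of species-level baseline parameters:
#'   \code{a} (day of peak growth), \code{b} (1/day), \code{K} (cm),
#'   \code{m} (senescence midpoint day), \code{s} (1/day), \code{theta}
#'   (dimensionless decline asymmetry).
#' @param spread named list of across-species standard deviations on the
#'   natural scale for \code{a} and \code{m} and on the log scale for
#'   \code{log_b}, \code{log_s}, \code{log_theta}, \code{log_K}.
#' @param niche_to_traits 4 x 7 standardized path matrix, see
#'   \code{\link{default_niche_trait_paths}}.
#' @param to_phenology 6 x 11 standardized path matrix, see
#'   \code{\link{default_phenology_paths}}.
#' @param trait_scales named list of \code{c(mean, sd)} pairs for the four
#'   traits on their measurement scales.
#' @param allometry list with \code{length_ratio} (vegetative length per unit
#'   size) and \code{taper} (upper/lower width ratio); widths are solved so
#'   that the frustum size of a noiseless triplet reproduces the true size.
#' @param theta_range admissible range for the decline asymmetry theta.
#' @param rng_seed integer seed; fully determines generator output.
#' @return A list of class \code{"generation_config"}.
#' @export
generation_config <- function(n_species = 20L,
                              shoots_per_species = 7L,
                              cadence_days = 14L,
                              first_day = 7L,
                              season_days = 365L,
                              noise_cv = 0.05,
                              shoot_k_cv = 0.2,
                              structural_noise = 1,
                              baseline = list(a = 120, b = 0.12, K = 20,
                                              m = 260, s = 0.08, theta = 1),
                              spread = list(a = 12, log_b = 0.2, m = 18,
                                            log_s = 0.2, log_theta = 0.35,
                                            log_K = 0.3),
                              niche_to_traits = default_niche_trait_paths(),
                              to_phenology = default_phenology_paths(),
                              trait_scales = list(
                                log_height = c(log(40), 0.5),
                                log_lateral_spread = c(log(2), 1.0),
                                sla = c(22, 5),
                                ldmc = c(250, 60)),
                              allometry = list(length_ratio = 3, taper = 0.5),
                              theta_range = c(0.3, 3),
                              rng_seed = 1L) {
  if (n_species < 1 || shoots_per_species < 1)
    stop("configuration error: species and shoot counts must be positive")
  if (cadence_days < 1)
    stop("configuration error: cadence_days must be >= 1")
  if (noise_cv < 0 || shoot_k_cv < 0 || structural_noise < 0)
    stop("configuration error: noise levels must be non-negative")
  if (!identical(dim(niche_to_traits),
                 c(length(.trait_vars), length(.niche_vars))))
    stop("configuration error: niche_to_traits must be 4 x 7")
  if (!identical(dim(to_phenology),
                 c(length(.phen_latent),
                   length(.niche_vars) + length(.trait_vars))))
    stop("configuration error: to_phenology must be 6 x 11")
  if (baseline$b <= 0 || baseline$s <= 0 || baseline$theta <= 0 ||
      baseline$K <= 0)
    stop("configuration error: baseline rates and sizes must be positive")
  structure(list(
    n_species = as.integer(n_species),
    shoots_per_species = as.integer(shoots_per_species),
    cadence_days = as.integer(cadence_days),
    first_day = as.integer(first_day),
    season_days = as.integer(season_days),
    noise_cv = noise_cv, shoot_k_cv = shoot_k_cv,
    structural_noise = structural_noise,
    baseline = baseline, spread = spread,
    niche_to_traits = niche_to_traits, to_phenology = to_phenology,
    trait_scales = trait_scales, allometry = allometry,
    theta_range = theta_range, rng_seed = as.integer(rng_seed)),
    class = "generation_config")
}

## residual sd keeping each standardized structural equation near unit
## variance; floored so noisy regeneration never collapses
.struct_resid_sd <- function(B, floor = 0.2) {
  sqrt(pmax(1 - rowSums(B^2), floor))
}

#' Generate species-level ground truth
#'
#' Draws niche scores from independent normals (mean 5, sd 2, clipped to the
#' 1-9 indicator scale), maps them to traits and on to growth and senescence
#' parameters through the configured standardized path matrices, and returns
#' one row per species. Deterministic given \code{config$rng_seed}.
#'
#' @param config a \code{\link{generation_config}}.
#' @return A data frame with niche, trait and true parameter columns
#'   (\code{a_true}, \code{b_true}, \code{K_true}, \code{m_true},
#'   \code{s_true}, \code{theta_true}).
#' @export
generate_species <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(config$rng_seed)
  n <- config$n_species
  niche_z <- matrix(rnorm(n * length(.niche_vars)), n,
                    dimnames = list(NULL, .niche_vars))
  niche <- pmin(pmax(5 + 2 * niche_z, 1), 9)
  niche_std <- (niche - 5) / 2

  Bt <- config$niche_to_traits
  sn <- config$structural_noise
  trait_std <- niche_std %*% t(Bt) +
    matrix(rnorm(n * nrow(Bt)), n, nrow(Bt), byrow = FALSE) %*%
      diag(sn * .struct_resid_sd(Bt), nrow(Bt))
  colnames(trait_std) <- .trait_vars
  traits <- sapply(.trait_vars, function(v) {
    sc <- config$trait_scales[[v]]
    sc[1] + sc[2] * trait_std[, v]
  })
  if (n == 1L) traits <- matrix(traits, 1, dimnames = list(NULL, .trait_vars))

  Bp <- config$to_phenology
  pred <- cbind(niche_std, trait_std)
  phen_std <- pred %*% t(Bp) +
    matrix(rnorm(n * nrow(Bp)), n, nrow(Bp)) %*%
      diag(sn * .struct_resid_sd(Bp), nrow(Bp))
  colnames(phen_std) <- .phen_latent

  bl <- config$baseline
  sp <- config$spread
  a_true <- bl$a + sp$a * phen_std[, "a"]
  b_true <- exp(log(bl$b) + sp$log_b * phen_std[, "log_b"])
  m_true <- bl$m + sp$m * phen_std[, "m"]
  m_true <- pmax(m_true, a_true + 40)  # senescence midpoint after growth peak
  s_true <- exp(log(bl$s) + sp$log_s * phen_std[, "log_s"])
  theta_true <- pmin(pmax(exp(log(bl$theta) +
                              sp$log_theta * phen_std[, "log_theta"]),
                          config$theta_range[1]), config$theta_range[2])
  K_true <- exp(log(bl$K) + sp$log_K * phen_std[, "log_K"])

  out <- data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    niche, traits,
    a_true = a_true, b_true = b_true, K_true = K_true,
    m_true = m_true, s_true = s_true, theta_true = theta_true,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## decline fraction of final size: generalized (Richards-type) sigmoid
.decline_fraction <- function(t, m, s, theta) {
  (1 + exp(s * (t - m)))^(-theta)
}

#' Day the true piecewise trajectory peaks (growth/decline join)
#'
#' The growth logistic (as a fraction of final size) and the Richards decline
#' fraction intersect once between the growth inflection and deep senescence;
#' the trajectory follows the logistic before that day and the decline after,
#' so the intersection is the true peak day. Independent of shoot size.
#'
#' @param truth one row of \code{\link{generate_species}} output (or any list
#'   with \code{a_true}, \code{b_true}, \code{m_true}, \code{s_true},
#'   \code{theta_true}).
#' @return Day of year (numeric).
#' @export
true_join_day <- function(truth) {
  f <- function(t) plogis(truth$b_true * (t - truth$a_true)) -
    .decline_fraction(t, truth$m_true, truth$s_true, truth$theta_true)
  upper <- truth$m_true + 8 / truth$s_true
  uniroot(f, lower = truth$a_true, upper = upper, tol = 1e-8)$root
}

#' Evaluate the true trajectory of one shoot
#'
#' Piecewise curve: logistic growth \eqn{K_i/(1+e^{-b(t-a)})} up to the join
#' day, Richards-type decline \eqn{K_i (1+e^{s(t-m)})^{-\theta}} afterwards.
#' The two phases meet continuously at the join day, and the fraction
#' crossings of the decline phase keep their closed form.
#'
#' @param truth one species-truth row.
#' @param t day(s) of year, may be a vector.
#' @param K_i shoot-level final size; defaults to the species \code{K_true}.
#' @return Sizes (cm) at \code{t}.
#' @export
true_size <- function(truth, t, K_i = truth$K_true) {
  tj <- true_join_day(truth)
  ifelse(t <= tj,
         K_i * plogis(truth$b_true * (t - truth$a_true)),
         K_i * .decline_fraction(t, truth$m_true, truth$s_true,
                                 truth$theta_true))
}

#' Closed-form fraction-crossing day of the decline phase
#'
#' Solves \eqn{(1+e^{s(t-m)})^{-\theta} = q} for \eqn{t}:
#' \eqn{t_q = m + (1/s)\,\log(q^{-1/\theta} - 1)}.
#'
#' @param truth one species-truth row.
#' @param q fraction of final size in (0, 1).
#' @return Day of year.
#' @export
true_crossing <- function(truth, q) {
  stopifnot(all(q > 0 & q < 1))
  truth$m_true + log(q^(-1 / truth$theta_true) - 1) / truth$s_true
}

#' Analytic phenological parameters implied by the ground truth
#'
#' Applies the package's own phenological definitions to the closed-form
#' generating curves: season start as the 25\% crossing of the growth
#' logistic (\eqn{a - \log 3 / b}), senescence date/pace/shape from the 95,
#' 50 and 5\% crossings of the decline, and season end as the 25\% decline
#' crossing. Used as the reference in parameter-recovery tests.
#'
#' @param truth data frame from \code{\link{generate_species}}.
#' @return Data frame with one row per species: \code{peak_day},
#'   \code{log_b}, \code{season_start}, \code{sen_date}, \code{sen_pace},
#'   \code{sen_shape}, \code{season_end}, \code{season_length},
#'   \code{peak_day_curve} (true trajectory maximum).
#' @export
truth_phenology <- function(truth) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    t95 <- true_crossing(tr, 0.95)
    t50 <- true_crossing(tr, 0.50)
    t25 <- true_crossing(tr, 0.25)
    t05 <- true_crossing(tr, 0.05)
    start <- tr$a_true - log(3) / tr$b_true
    data.frame(
      species_id = tr$species_id,
      peak_day = tr$a_true,
      log_b = log(tr$b_true),
      season_start = start,
      sen_date = t50,
      sen_pace = 1 / (t05 - t95),
      sen_shape = log((t05 - t50) / (t50 - t95)),
      season_end = t25,
      season_length = t25 - start,
      peak_day_curve = true_join_day(tr),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## width/length multipliers such that a noiseless triplet inverts exactly to
## the true size through the conical-frustum formula
.allometry_constants <- function(allometry) {
  gamma <- allometry$length_ratio
  rho <- allometry$taper
  beta <- sqrt(12 / (pi * gamma * (rho^2 + rho + 1)))
  c(upper = rho * beta, lower = beta, length = gamma)
}

## mean-one lognormal multipliers at a given CV
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Render a long-format measurement table from species truth
#'
#' For each shoot a final size \eqn{K_i} is drawn lognormally around the
#' species \code{K_true}; the true trajectory is evaluated on the measurement
#' days and inverted to an (upper width, lower width, length) triplet
#' consistent with the conical-frustum size formula; each dimension is then
#' multiplied by mean-one lognormal noise with CV \code{noise_cv}.
#' Deterministic given the config seed (offset by one from
#' \code{\link{generate_species}} so both draws are independent).
#'
#' @param truth data frame from \code{\link{generate_species}}.
#' @param config the \code{\link{generation_config}} used to generate it.
#' @param seed seed for the rendering draws; defaults to
#'   \code{config$rng_seed + 1}.
#' @return Long data frame: \code{species_id}, \code{shoot_id},
#'   \code{day_of_year}, \code{upper_width_cm}, \code{lower_width_cm},
#'   \code{length_cm}.
#' @export
render_measurements <- function(truth, config,
                                seed = config$rng_seed + 1L) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(seed)
  days <- seq(config$first_day, config$season_days,
              by = config$cadence_days)
  const <- .allometry_constants(config$allometry)
  out <- vector("list", nrow(truth) * config$shoots_per_species)
  idx <- 1L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    for (sh in seq_len(config$shoots_per_species)) {
      K_i <- tr$K_true * .lognormal_noise(1, config$shoot_k_cv)
      sizes <- true_size(tr, days, K_i = K_i)
      nd <- length(days)
      out[[idx]] <- data.frame(
        species_id = tr$species_id,
        shoot_id = sprintf("%s_sh%02d", tr$species_id, sh),
        day_of_year = days,
        upper_width_cm = const["upper"] * sizes *
          .lognormal_noise(nd, config$noise_cv),
        lower_width_cm = const["lower"] * sizes *
          .lognormal_noise(nd, config$noise_cv),
        length_cm = const["length"] * sizes *
          .lognormal_noise(nd, config$noise_cv),
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: species truth, covariate table (niche + traits) and
#' measurement table, all determined by \code{config$rng_seed}.
#'
#' @param config a \code{\link{generation_config}}.
#' @return List with elements \code{truth}, \code{covariates},
#'   \code{measurements} and \code{config}.
#' @export
simulate_dataset <- function(config = generation_config()) {
  truth <- generate_species(config)
  measurements <- render_measurements(truth, config)
  covariates <- truth[, c("species_id", .niche_vars, .trait_vars)]
  list(truth = truth, covariates = covariates,
       measurements = measurements, config = config)
}
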