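#' Configuration for a synthetic country
#'
#' Bundles every parameter of the synthetic-country generator: the population
#' grid, the latent prevalence field, the two-stage stratified cluster survey
#' design, group-specific ART coverage, and the latent travel-time
#' distributions that are discretised into the three reported categories
#' (under one hour, one to two hours, more than two hours).
#'
#' Distances are in kilometres (1 km-square cells), travel times in hours,
#' densities in persons per square kilometre.
#'
#' @param grid_nx,grid_ny Grid dimensions in cells (>= 8 each).
#' @param n_urban_cores Number of urban population cores (Gaussian density
#'   bumps); 0 gives a uniform rural country.
#' @param urban_fraction_target Target share of the population living in
#'   urban-classified cells, in (0,1).
#' @param rural_density Background population density aged 15-59
#'   (persons/km^2).
#' @param core_peak_density Peak density of each urban core (persons/km^2,
#'   added to the background).
#' @param core_sigma_km Gaussian spread of an urban core (km).
#' @param prevalence_logit_mean Mean of the latent prevalence field on the
#'   logit scale (e.g. `qlogis(0.12)` for a 12% national epidemic).
#' @param prevalence_spatial_sd Standard deviation of the Gaussian random
#'   field on the logit scale (> 0 for a spatially varying field; 0 gives a
#'   constant field).
#' @param prevalence_spatial_range Range parameter (km) of the exponential
#'   covariance `sd^2 * exp(-h / range)`.
#' @param urban_logit_shift Additive logit shift applied to urban cells
#'   (urban epidemics are typically more intense).
#' @param sex_prevalence_logit_shift Difference in prevalence log-odds between
#'   women and men (women get `+shift/2`, men `-shift/2`), reflecting the
#'   consistently higher prevalence among women in southern/eastern Africa.
#' @param art_coverage_by_group Named list of ART-coverage proportions among
#'   people with HIV for the four sex-by-residence groups:
#'   `F_rural`, `F_urban`, `M_rural`, `M_urban`.
#' @param traveltime_params Named list of `c(mu, s)` (hours) for the latent
#'   logistic one-way travel time, per residence-by-sex group:
#'   `rural_F`, `rural_M`, `urban_F`, `urban_M`. `s` must be positive.
#' @param n_ea Total number of enumeration areas (EAs, the PSUs) to sample;
#'   allocation between strata is proportional to stratum population with a
#'   minimum of 2 per stratum (the jackknife needs at least two PSUs).
#' @param individuals_per_ea Individuals interviewed per EA.
#' @param traveltime_nonresponse Fraction of on-ART travel-time answers set
#'   missing completely at random (default 0.07, i.e. a 93% item response).
#' @param age_group_probs Sampling probabilities of the four age bands
#'   15-24, 25-34, 35-44, 45-59.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   configuration.
#'
#' @return An object of class `country_config` (a validated list).
#' @examples
#' cfg <- country_config(n_ea = 10, individuals_per_ea = 20, seed = 1)
#' cfg$strata
#' @export
country_config <- function(grid_nx = 40, grid_ny = 40,
                           n_urban_cores = 3,
                           urban_fraction_target = 0.30,
                           rural_density = 250,
                           core_peak_density = 5000,
                           core_sigma_km = 3,
                           prevalence_logit_mean = stats::qlogis(0.12),
                           prevalence_spatial_sd = 0.5,
                           prevalence_spatial_range = 10,
                           urban_logit_shift = 0.25,
                           sex_prevalence_logit_shift = 0.5,
                           art_coverage_by_group = list(
                             F_rural = 0.80, F_urban = 0.76,
                             M_rural = 0.72, M_urban = 0.66),
                           traveltime_params = list(
                             rural_F = c(1.4, 0.6), rural_M = c(1.3, 0.6),
                             urban_F = c(0.8, 0.5), urban_M = c(0.7, 0.5)),
                           n_ea = 50,
                           individuals_per_ea = 100,
                           traveltime_nonresponse = 0.07,
                           age_group_probs = c(0.39, 0.28, 0.18, 0.15),
                           seed = 1L) {
  cfg <- list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    n_urban_cores = as.integer(n_urban_cores),
    urban_fraction_target = urban_fraction_target,
    rural_density = rural_density,
    core_peak_density = core_peak_density,
    core_sigma_km = core_sigma_km,
    prevalence_logit_mean = prevalence_logit_mean,
    prevalence_spatial_sd = prevalence_spatial_sd,
    prevalence_spatial_range = prevalence_spatial_range,
    urban_logit_shift = urban_logit_shift,
    sex_prevalence_logit_shift = sex_prevalence_logit_shift,
    art_coverage_by_group = art_coverage_by_group,
    traveltime_params = traveltime_params,
    n_ea = as.integer(n_ea),
    individuals_per_ea = as.integer(individuals_per_ea),
    traveltime_nonresponse = traveltime_nonresponse,
    age_group_probs = age_group_probs,
    strata = c("urban", "rural"),
    seed = as.integer(seed))
  class(cfg) <- "country_config"
  validate_country_config(cfg)
  cfg
}

validate_country_config <- function(cfg) {
  stopifnot(inherits(cfg, "country_config"))
  if (cfg$grid_nx < 8 || cfg$grid_ny < 8)
    stop("configuration error: grid dimensions must be at least 8x8", call. = FALSE)
  if (cfg$n_urban_cores < 0)
    stop("configuration error: n_urban_cores must be >= 0", call. = FALSE)
  props <- c(cfg$urban_fraction_target, unlist(cfg$art_coverage_by_group))
  if (any(props <= 0 | props >= 1))
    stop("configuration error: proportions must lie strictly in (0, 1)", call. = FALSE)
  if (cfg$traveltime_nonresponse < 0 || cfg$traveltime_nonresponse >= 1)
    stop("configuration error: traveltime_nonresponse must be in [0, 1)", call. = FALSE)
  need <- c("F_rural", "F_urban", "M_rural", "M_urban")
  if (!all(need %in% names(cfg$art_coverage_by_group)))
    stop("configuration error: art_coverage_by_group must name ", paste(need, collapse = ", "), call. = FALSE)
  needtt <- c("rural_F", "rural_M", "urban_F", "urban_M")
  if (!all(needtt %in% names(cfg$traveltime_params)))
    stop("configuration error: traveltime_params must name ", paste(needtt, collapse = ", "), call. = FALSE)
  s_ok <- vapply(cfg$traveltime_params, function(p) length(p) == 2 && p[2] > 0, logical(1))
  if (!all(s_ok))
    stop("configuration error: every travel-time group needs c(mu, s) with s > 0", call. = FALSE)
  if (cfg$prevalence_spatial_sd < 0)
    stop("configuration error: prevalence_spatial_sd must be >= 0", call. = FALSE)
  if (cfg$prevalence_spatial_range <= 0)
    stop("configuration error: prevalence_spatial_range must be > 0", call. = FALSE)
  if (cfg$n_ea < 4)
    stop("configuration error: n_ea must be >= 4 (at least 2 EAs per stratum)", call. = FALSE)
  if (cfg$individuals_per_ea < 1)
    stop("configuration error: individuals_per_ea must be >= 1", call. = FALSE)
  if (abs(sum(cfg$age_group_probs) - 1) > 1e-8 || length(cfg$age_group_probs) != 4)
    stop("configuration error: age_group_probs must be 4 probabilities summing to 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.country_config <- function(x, ...) {
  cat("<country_config>\n")
  cat(sprintf("  grid: %d x %d km, %d urban core(s), urban fraction target %.2f\n",
              x$grid_nx, x$grid_ny, x$n_urban_cores, x$urban_fraction_target))
  cat(sprintf("  prevalence: logit mean %.3f (%.1f%%), GRF sd %.2f, range %.1f km\n",
              x$prevalence_logit_mean, 100 * stats::plogis(x$prevalence_logit_mean),
              x$prevalence_spatial_sd, x$prevalence_spatial_range))
  cat(sprintf("  survey: %d EAs x %d individuals, seed %d\n",
              x$n_ea, x$individuals_per_ea, x$seed))
  invisible(x)
}

# Age bands used throughout (survey questionnaire bands).
age_groups <- function() c("15-24", "25-34", "35-44", "45-59")

# Travel-time category tokens; NA_character_ marks item nonresponse.
traveltime_levels <- function() c("LT1H", "H1TO2", "GT2H")
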