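# Synthetic-country generator: population grid, latent prevalence field,
# two-stage stratified cluster survey with design + jackknife replicate
# weights, geomasked cluster coordinates. Ground truth is retained so every
# downstream estimator has a recoverable target.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a gridded population surface
#'
#' Builds a WorldPop-style 1 km population grid for adults aged 15-59: a
#' uniform rural background plus `n_urban_cores` Gaussian density bumps.
#' Cells are classified urban by descending density until the urban share of
#' the population first reaches `urban_fraction_target`, so the urban mask
#' covers approximately that share.
#'
#' @param config A [country_config()].
#' @param seed Seed controlling core placement (defaults to `config$seed`).
#' @return A `population_grid`: list with `counts` (an [epi_raster()] of
#'   persons/km^2), `urban_mask` (logical matrix, same layout) and `cores`
#'   (data.frame of core centres).
#' @export
generate_population_grid <- function(config, seed = config$seed) {
  validate_country_config(config)
  nx <- config$grid_nx; ny <- config$grid_ny
  ctr <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  cx <- (ctr$col - 0.5); cy <- (ny - ctr$row + 0.5)

  cores <- with_seed(seed, {
    k <- config$n_urban_cores
    if (k == 0) data.frame(x = numeric(0), y = numeric(0))
    else data.frame(x = stats::runif(k, 0.15 * nx, 0.85 * nx),
                    y = stats::runif(k, 0.15 * ny, 0.85 * ny))
  })

  dens <- rep(config$rural_density, nx * ny)
  if (nrow(cores) > 0) {
    s2 <- config$core_sigma_km^2
    for (i in seq_len(nrow(cores))) {
      d2 <- (cx - cores$x[i])^2 + (cy - cores$y[i])^2
      dens <- dens + config$core_peak_density * exp(-d2 / (2 * s2))
    }
  }
  m <- matrix(NA_real_, nrow = ny, ncol = nx)
  m[cbind(ctr$row, ctr$col)] <- dens

  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  if (nrow(cores) > 0) {
    ord <- order(dens, decreasing = TRUE)
    cum <- cumsum(dens[ord]) / sum(dens)
    n_urb <- which(cum >= config$urban_fraction_target)[1]
    sel <- ord[seq_len(n_urb)]
    mask[cbind(ctr$row[sel], ctr$col[sel])] <- TRUE
  }

  structure(list(counts = epi_raster(m), urban_mask = mask, cores = cores),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  tot <- sum(x$counts$values)
  urb <- sum(x$counts$values[x$urban_mask]) / tot
  cat(sprintf("<population_grid> %d x %d km, total population %.0f, urban share %.1f%%\n",
              ncol(x$counts$values), nrow(x$counts$values), tot, 100 * urb))
  invisible(x)
}

#' Generate a spatially autocorrelated prevalence field
#'
#' The latent truth behind the interpolated prevalence surfaces: on the logit
#' scale, `mean + urban_shift * urban + Z` with `Z` a zero-mean Gaussian
#' random field with exponential covariance `sd^2 * exp(-h / range)`, realised
#' exactly by Cholesky factorisation of the cell-centre covariance matrix.
#' Prevalence is the inverse logit of the latent field, hence strictly in
#' (0,1).
#'
#' @param config A [country_config()].
#' @param grid A `population_grid` (supplies the urban mask and geometry).
#' @param seed Seed for the random field (defaults to `config$seed + 1`).
#' @return A `prevalence_field`: list with `prevalence` and `logit`, both
#'   [epi_raster()] layers.
#' @export
generate_prevalence_field <- function(config, grid, seed = config$seed + 1L) {
  validate_country_config(config)
  sd <- config$prevalence_spatial_sd
  rng <- config$prevalence_spatial_range
  if (rng <= 0) stop("configuration error: spatial range must be > 0", call. = FALSE)
  if (sd < 0) stop("configuration error: spatial sd must be >= 0", call. = FALSE)
  nx <- config$grid_nx; ny <- config$grid_ny
  n <- nx * ny
  if (sd > 0 && n > 10000)
    stop("configuration error: exact GRF generation is limited to 10,000 cells", call. = FALSE)

  cells <- raster_cells(grid$counts)
  z <- if (sd == 0) rep(0, n) else {
    D <- as.matrix(stats::dist(cells[, c("x", "y")]))
    C <- sd^2 * exp(-D / rng)
    L <- chol(C + diag(1e-10, n))
    with_seed(seed, as.vector(crossprod(L, stats::rnorm(n))))
  }
  lg <- config$prevalence_logit_mean + z
  lg <- lg + config$urban_logit_shift * as.vector(t(grid$urban_mask))
  lgm <- matrix(lg, nrow = ny, ncol = nx, byrow = TRUE)
  structure(list(prevalence = epi_raster(stats::plogis(lgm)),
                 logit = epi_raster(lgm)),
            class = "prevalence_field")
}

# Exact population truth implied by the generator: sex-averaged prevalence
# and group-structured ART coverage, population-weighted over cells.
ground_truth <- function(config, grid, field) {
  pop <- as.vector(t(grid$counts$values))
  urb <- as.vector(t(grid$urban_mask))
  lg <- as.vector(t(field$logit$values))
  sh <- config$sex_prevalence_logit_shift
  pF <- stats::plogis(lg + sh / 2)
  pM <- stats::plogis(lg - sh / 2)
  prev_cell <- (pF + pM) / 2
  cov <- config$art_coverage_by_group
  covF <- ifelse(urb, cov$F_urban, cov$F_rural)
  covM <- ifelse(urb, cov$M_urban, cov$M_rural)
  pwh <- sum(pop * prev_cell)
  list(
    prevalence = pwh / sum(pop),
    prevalence_f = sum(pop * pF) / sum(pop),
    prevalence_m = sum(pop * pM) / sum(pop),
    art_coverage = sum(pop / 2 * (pF * covF + pM * covM)) / pwh,
    total_pwh = pwh)
}

#' Draw a two-stage stratified cluster survey
#'
#' First stage: within each stratum (urban/rural), enumeration areas (EAs)
#' are selected with probability proportional to cell population by
#' systematic sampling on a randomised cell list. Second stage: a fixed
#' number of individuals per EA. Design weights are inverse inclusion
#' probabilities. HIV status is Bernoulli at the cell prevalence with a
#' sex-specific logit shift; ART status is Bernoulli at the sex-by-residence
#' coverage; for on-ART individuals a latent one-way travel time is drawn
#' from a logistic distribution truncated at zero and discretised at 1 h and
#' 2 h into the three reported categories, with a configurable
#' missing-completely-at-random item nonresponse.
#'
#' @param config A [country_config()].
#' @param grid A `population_grid`.
#' @param field A `prevalence_field`.
#' @param seed Seed for all survey randomness (defaults to `config$seed + 2`).
#' @return List with `records` (one row per individual: `ea_id`, `stratum`,
#'   `sex`, `age_group`, `hiv_positive`, `on_art`, `traveltime_category`,
#'   `design_weight`) and `sites` (one row per EA: `ea_id`, `x_km`, `y_km`,
#'   `stratum`).
#' @export
draw_survey <- function(config, grid, field, seed = config$seed + 2L) {
  validate_country_config(config)
  cells <- raster_cells(grid$counts)
  cells$urban <- as.vector(t(grid$urban_mask))
  cells$logit <- as.vector(t(field$logit$values))
  m <- config$individuals_per_ea

  with_seed(seed, {
    # stratum allocation proportional to population, minimum 2 PSUs each
    pop_by <- tapply(cells$value, cells$urban, sum)
    P_urb <- if ("TRUE" %in% names(pop_by)) pop_by[["TRUE"]] else 0
    P_rur <- if ("FALSE" %in% names(pop_by)) pop_by[["FALSE"]] else 0
    strata <- list()
    if (P_urb > 0 && P_rur > 0) {
      n_urb <- round(config$n_ea * P_urb / (P_urb + P_rur))
      n_urb <- min(max(n_urb, 2L), config$n_ea - 2L)
      strata <- list(urban = n_urb, rural = config$n_ea - n_urb)
    } else if (P_rur > 0) {
      strata <- list(rural = config$n_ea)
    } else stop("design error: no populated rural cells", call. = FALSE)

    sites <- NULL
    for (h in names(strata)) {
      idx <- which(cells$urban == (h == "urban"))
      n_h <- strata[[h]]
      if (length(idx) < n_h)
        stop("design error: stratum ", h, " has fewer cells than EAs requested", call. = FALSE)
      idx <- sample(idx)                       # randomised list
      cum <- cumsum(cells$value[idx])
      P_h <- cum[length(cum)]
      step <- P_h / n_h
      hits <- stats::runif(1, 0, step) + (seq_len(n_h) - 1) * step
      sel <- findInterval(hits, cum) + 1L
      if (anyDuplicated(sel))
        stop("design error: a cell exceeds the PPS sampling interval in stratum ", h,
             "; increase n_ea or flatten the population surface", call. = FALSE)
      pick <- idx[sel]
      pi_ea <- pmin(1, n_h * cells$value[pick] / P_h)
      sites <- rbind(sites, data.frame(
        cell = pick, x_km = cells$x[pick], y_km = cells$y[pick],
        stratum = h, pop = cells$value[pick], pi_ea = pi_ea))
    }
    sites$ea_id <- sprintf("EA%03d", seq_len(nrow(sites)))

    n_rec <- nrow(sites) * m
    ea_row <- rep(seq_len(nrow(sites)), each = m)
    sex <- sample(c("F", "M"), n_rec, replace = TRUE)
    age <- sample(age_groups(), n_rec, replace = TRUE, prob = config$age_group_probs)
    lg <- cells$logit[sites$cell[ea_row]] +
      ifelse(sex == "F", 1, -1) * config$sex_prevalence_logit_shift / 2
    hiv <- stats::runif(n_rec) < stats::plogis(lg)
    cov <- unlist(config$art_coverage_by_group)[
      paste0(sex, "_", sites$stratum[ea_row])]
    art <- hiv & (stats::runif(n_rec) < cov)

    ttcat <- rep(NA_character_, n_rec)
    tt_grp <- paste0(sites$stratum[ea_row], "_", sex)
    for (g in unique(tt_grp[art])) {
      sel <- which(art & tt_grp == g)
      p <- config$traveltime_params[[g]]
      t <- rtrunc_logistic(length(sel), p[1], p[2])
      ttcat[sel] <- traveltime_levels()[findInterval(t, c(1, 2)) + 1L]
    }
    if (config$traveltime_nonresponse > 0) {
      nr <- art & (stats::runif(n_rec) < config$traveltime_nonresponse)
      ttcat[nr] <- NA_character_
    }

    records <- data.frame(
      ea_id = sites$ea_id[ea_row],
      stratum = sites$stratum[ea_row],
      sex = sex, age_group = age,
      hiv_positive = hiv, on_art = art,
      traveltime_category = ttcat,
      design_weight = sites$pop[ea_row] / (sites$pi_ea[ea_row] * m),
      stringsAsFactors = FALSE)
    list(records = records,
         sites = sites[, c("ea_id", "x_km", "y_km", "stratum", "pop", "pi_ea")])
  })
}

# Logistic(mu, s) truncated below at 0, drawn by inverse-CDF.
rtrunc_logistic <- function(n, mu, s) {
  f0 <- stats::plogis((0 - mu) / s)
  u <- f0 + stats::runif(n) * (1 - f0)
  mu + s * stats::qlogis(u)
}

# CDF of the truncated latent travel time; the generating category cell
# probabilities are F(1) and F(2) of this distribution.
ptrunc_logistic <- function(q, mu, s) {
  f0 <- stats::plogis((0 - mu) / s)
  pmax(0, (stats::plogis((q - mu) / s) - f0) / (1 - f0))
}

#' Geomask cluster coordinates
#'
#' Random-azimuth displacement of EA coordinates for de-identification,
#' following the displacement convention of household-survey GPS releases:
#' urban points moved up to 2 km, rural points up to 5 km, with a small
#' fraction (default 1%) of rural points displaced between 5 km and 10 km.
#' True coordinates are retained (columns `x_true`, `y_true`) for validation
#' only and are never written by the pipeline writers.
#'
#' @param sites Data frame with `x_km`, `y_km`, `stratum`.
#' @param max_urban,max_rural Maximum displacement (km) per stratum.
#' @param far_fraction Fraction of rural points displaced beyond `max_rural`.
#' @param far_max Upper bound (km) of the far rural displacement.
#' @param seed Optional seed.
#' @return `sites` with displaced `x_km`, `y_km` and the originals in
#'   `x_true`, `y_true`.
#' @export
geomask <- function(sites, max_urban = 2, max_rural = 5,
                    far_fraction = 0.01, far_max = 10, seed = NULL) {
  stopifnot(all(c("x_km", "y_km", "stratum") %in% names(sites)))
  run <- function() {
    n <- nrow(sites)
    theta <- stats::runif(n, 0, 2 * pi)
    r <- numeric(n)
    urb <- sites$stratum == "urban"
    r[urb] <- stats::runif(sum(urb), 0, max_urban)
    rur <- which(!urb)
    far <- stats::runif(length(rur)) < far_fraction
    r[rur[!far]] <- stats::runif(sum(!far), 0, max_rural)
    r[rur[far]] <- stats::runif(sum(far), max_rural, far_max)
    out <- sites
    out$x_true <- sites$x_km; out$y_true <- sites$y_km
    out$x_km <- sites$x_km + r * cos(theta)
    out$y_km <- sites$y_km + r * sin(theta)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Attach stratified delete-one-PSU jackknife replicate weights
#'
#' Builds JKn replicate weights: replicate `r` deletes PSU `i` of stratum
#' `h`; records of the deleted PSU get weight 0, records of the remaining
#' PSUs in `h` get `design_weight * n_h / (n_h - 1)`, and records outside
#' `h` keep their design weight. One replicate per PSU, columns `rw001`,
#' `rw002`, ... ordered by stratum then PSU id.
#'
#' @param records Record table with `stratum`, `ea_id`, `design_weight`.
#' @return `records` with the replicate-weight columns appended.
#' @export
make_replicate_weights <- function(records) {
  stopifnot(all(c("stratum", "ea_id", "design_weight") %in% names(records)))
  psu <- unique(records[, c("stratum", "ea_id")])
  psu <- psu[order(psu$stratum, psu$ea_id), , drop = FALSE]
  n_h <- table(psu$stratum)
  if (any(n_h < 2)) {
    bad <- names(n_h)[n_h < 2]
    stop("design error: stratum ", paste(bad, collapse = ", "),
         " has a single PSU; the jackknife needs at least two", call. = FALSE)
  }
  R <- nrow(psu)
  W <- matrix(rep(records$design_weight, R), ncol = R)
  for (r in seq_len(R)) {
    h <- psu$stratum[r]
    in_h <- records$stratum == h
    del <- in_h & records$ea_id == psu$ea_id[r]
    W[del, r] <- 0
    W[in_h & !del, r] <- records$design_weight[in_h & !del] *
      n_h[[h]] / (n_h[[h]] - 1)
  }
  colnames(W) <- sprintf("rw%03d", seq_len(R))
  cbind(records, as.data.frame(W))
}

# Names of the replicate-weight columns of a record table.
rw_columns <- function(records) grep("^rw[0-9]+$", names(records), value = TRUE)

#' Simulate a complete synthetic country
#'
#' Convenience wrapper chaining [generate_population_grid()],
#' [generate_prevalence_field()], [draw_survey()], [geomask()] and
#' [make_replicate_weights()], and computing the exact population truth
#' implied by the generator (overall prevalence, sex-specific prevalence,
#' ART coverage, total people with HIV).
#'
#' @param config A [country_config()].
#' @return List: `config`, `grid`, `field`, `records` (with replicate
#'   weights), `sites` (geomasked), `truth`.
#' @examples
#' sim <- simulate_country(country_config(n_ea = 10, individuals_per_ea = 25,
#'                                        grid_nx = 16, grid_ny = 16, seed = 7))
#' sim$truth$prevalence
#' @export
simulate_country <- function(config) {
  validate_country_config(config)
  grid <- generate_population_grid(config)
  field <- generate_prevalence_field(config, grid)
  svy <- draw_survey(config, grid, field)
  sites <- geomask(svy$sites, seed = config$seed + 3L)
  records <- make_replicate_weights(svy$records)
  list(config = config, grid = grid, field = field,
       records = records, sites = sites,
       truth = ground_truth(config, grid, field))
}
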