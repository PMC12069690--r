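# End-to-end pipeline: simulate (or load) -> design-based estimation ->
# travel-time CDFs and odds-ratio model -> kriged prevalence surface ->
# density-of-infection raster -> epidemic concentration curve. All outputs
# are plain text (CSV / ASCII grid / JSON); every stage is seeded from the
# single pipeline seed.

#' Run the full analysis pipeline on a synthetic country
#'
#' Chains all stages and writes their outputs under `out_dir`:
#' `records.csv`, `sites.csv`, `population.asc`, `prevalence_truth.asc`
#' (simulation); `group_differences.csv` (sex and residence contrasts of
#' prevalence and coverage with design-based F-tests); `traveltime_fits.csv`,
#' `traveltime_bands.csv`, `aor_table.csv` (travel-time stage);
#' `esp.asc`, `esp_se.asc`, `cv_report.json` (kriging stage); `doi.asc`,
#' `ecc.csv`, `ecc_thresholds.csv` (concentration stage); and
#' `run_report.json`. The run report records per-stage status and timing,
#' record/cell counts, the package version and a hash of the configuration,
#' and is bit-reproducible for a fixed configuration and seed.
#'
#' @param config A [country_config()]; its `seed` drives every stage.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param band_B Bootstrap replicates for the travel-time confidence bands.
#' @param k_neighbors Kriging neighborhood size.
#' @param variogram_family `"exponential"` or `"spherical"`.
#' @param coverage_targets Treatment-coverage levels for the ECC threshold
#'   solver (defaults to the current national coverage levels of the three
#'   study countries: 76.6%, 70.0%, 62.6%).
#' @param alpha Significance level of the F-tests.
#' @return A `run_report` (list), invisibly containing all in-memory stage
#'   results under `$results`.
#' @export
run_all <- function(config = country_config(), out_dir = NULL,
                    band_B = 200, k_neighbors = 15,
                    variogram_family = "exponential",
                    coverage_targets = c(0.766, 0.700, 0.626),
                    alpha = 0.05) {
  validate_country_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("accessmap")),
                 config_hash = rlang::hash(config),
                 seed = config$seed, stages = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- list(status = "ok",
                                   seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  sim <- t_stage("simulate", simulate_country(config))
  results$sim <- sim
  report$stages$simulate$n_records <- nrow(sim$records)
  report$stages$simulate$n_cells <- length(sim$grid$counts$values)
  if (!is.null(out_dir)) {
    write_records(sim$records, file.path(out_dir, "records.csv"))
    write_sites(sim$sites, file.path(out_dir, "sites.csv"))
    write_raster(sim$grid$counts, file.path(out_dir, "population.asc"))
    write_raster(sim$field$prevalence, file.path(out_dir, "prevalence_truth.asc"))
  }

  results$contrasts <- t_stage("estimate", {
    rbind(estimate_contrast(sim$records, "hiv", "sex"),
          estimate_contrast(sim$records, "hiv", "residence"),
          estimate_contrast(sim$records, "art_on_hiv", "sex"),
          estimate_contrast(sim$records, "art_on_hiv", "residence"))
  })
  if (!is.null(out_dir))
    utils::write.csv(results$contrasts,
                     file.path(out_dir, "group_differences.csv"), row.names = FALSE)

  results$traveltime <- t_stage("traveltime", {
    doms <- list(national = NULL,
                 rural = sim$records$stratum == "rural",
                 urban = sim$records$stratum == "urban")
    fits <- lapply(names(doms), function(d) {
      tab <- tabulate_categories(sim$records, doms[[d]], domain = d)
      fit <- fit_logistic_cdf(build_anchors(tab, residence = d))
      band <- bootstrap_band(sim$records, doms[[d]], residence = d,
                             B = band_B, seed = config$seed + 10L)
      list(domain = d, table = tab, fit = fit, band = band)
    })
    names(fits) <- names(doms)
    fits$aor <- fit_travel_logit(sim$records)
    fits
  })
  if (!is.null(out_dir)) {
    tt <- results$traveltime
    fits_df <- do.call(rbind, lapply(c("national", "rural", "urban"), function(d)
      data.frame(domain = d, mu = tt[[d]]$fit$mu, s = tt[[d]]$fit$s,
                 sse = tt[[d]]$fit$sse, n = tt[[d]]$table$n,
                 p_ge1h = 1 - tt[[d]]$table$p_lt1,
                 p_gt2h = tt[[d]]$table$p_gt2)))
    utils::write.csv(fits_df, file.path(out_dir, "traveltime_fits.csv"),
                     row.names = FALSE)
    bands_df <- do.call(rbind, lapply(c("national", "rural", "urban"), function(d)
      cbind(domain = d, as.data.frame(tt[[d]]$band))))
    utils::write.csv(bands_df, file.path(out_dir, "traveltime_bands.csv"),
                     row.names = FALSE)
    utils::write.csv(tt$aor$table, file.path(out_dir, "aor_table.csv"),
                     row.names = FALSE)
  }

  results$map <- t_stage("map", {
    pts <- cluster_prevalence(sim$records, sim$sites)
    emp <- empirical_variogram(pts)
    vm <- fit_variogram(emp, family = variogram_family)
    kr <- krige(pts, vm, sim$grid$counts, k_neighbors = k_neighbors)
    cv <- loo_cross_validate(pts, vm, k_neighbors = k_neighbors)
    list(points = pts, variogram = vm, esp = kr$prediction, esp_se = kr$se,
         cv = cv)
  })
  if (!is.null(out_dir)) {
    write_raster(results$map$esp, file.path(out_dir, "esp.asc"))
    write_raster(results$map$esp_se, file.path(out_dir, "esp_se.asc"))
    jsonlite::write_json(unclass(results$map$cv),
                         file.path(out_dir, "cv_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  results$ecc <- t_stage("ecc", {
    doi <- make_doi(results$map$esp, sim$grid)
    ecc <- build_ecc(doi)
    thresholds <- data.frame(
      coverage = coverage_targets,
      min_doi = vapply(coverage_targets, function(cv)
        min_doi_for_coverage(ecc, cv), numeric(1)))
    list(doi = doi, ecc = ecc, thresholds = thresholds)
  })
  if (!is.null(out_dir)) {
    write_raster(results$ecc$doi, file.path(out_dir, "doi.asc"))
    ec <- results$ecc$ecc
    utils::write.csv(data.frame(rank = seq_along(ec$doi_sorted),
                                doi = ec$doi_sorted,
                                cum_fraction = ec$cum_fraction),
                     file.path(out_dir, "ecc.csv"), row.names = FALSE)
    utils::write.csv(results$ecc$thresholds,
                     file.path(out_dir, "ecc_thresholds.csv"), row.names = FALSE)
  }

  report$results <- results
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    slim <- report[c("package_version", "config_hash", "seed", "stages")]
    jsonlite::write_json(slim, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> accessmap %s, seed %d, config %s\n",
              x$package_version, x$seed, substr(x$config_hash, 1, 8)))
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s (%.2fs)\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds))
  invisible(x)
}
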