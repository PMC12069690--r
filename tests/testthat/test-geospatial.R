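# Geostatistics: variograms, ordinary kriging vs a full-system oracle,
# cross-validation, DoI rasters and concentration curves.

test_that("the Matheron estimator matches hand-computed semivariances", {
  pts <- data.frame(x_km = c(0, 3), y_km = c(0, 0), z = c(0, 2))
  ev <- empirical_variogram(pts, n_lags = 1, max_dist = 4)
  expect_equal(ev$gamma, 2)         # (1/2) * (2)^2 / 1 pair
  expect_equal(ev$n_pairs, 1L)
  # constant field -> zero semivariance in every bin
  set.seed(2)
  const <- data.frame(x_km = runif(40, 0, 10), y_km = runif(40, 0, 10), z = 5)
  expect_true(all(empirical_variogram(const)$gamma == 0))
})

test_that("white noise yields a flat variogram at the marginal variance", {
  set.seed(4)
  pts <- data.frame(x_km = runif(2000, 0, 50), y_km = runif(2000, 0, 50),
                    z = rnorm(2000))
  ev <- empirical_variogram(pts, n_lags = 8, max_dist = 25)
  expect_true(all(abs(ev$gamma - 1) < 0.1))
})

test_that("variogram fitting recovers generating parameters and limits", {
  model <- variogram_model("exponential", nugget = 0, psill = 0.25,
                           range_km = 10)
  # pool empirical variograms over several dense realisations
  evs <- lapply(1:4, function(s)
    empirical_variogram(grf_points(350, 80, model, seed = 400 + s),
                        n_lags = 14, max_dist = 40))
  pooled <- data.frame(
    lag = evs[[1]]$lag,
    gamma = rowMeans(sapply(evs, `[[`, "gamma")),
    n_pairs = rowSums(sapply(evs, `[[`, "n_pairs")))
  fit <- fit_variogram(pooled)
  expect_lt(fit$nugget, 0.05)
  expect_lt(abs(fit$psill - 0.25) / 0.25, 0.25)
  expect_lt(abs(fit$range - 10) / 10, 0.5)
  # optimality: fitted WLS objective no worse than the generating parameters
  wls <- function(m) {
    w <- pooled$n_pairs / pooled$lag^2
    sum(w * (pooled$gamma - accessmap:::variogram_gamma(m, pooled$lag))^2)
  }
  expect_lte(wls(fit), wls(model) + 1e-9)
  # flat empirical -> pure nugget
  flat <- data.frame(lag = 1:5, gamma = rep(0.3, 5), n_pairs = 100)
  ffit <- fit_variogram(flat)
  expect_equal(ffit$nugget, 0.3, tolerance = 0.02)
  expect_lt(ffit$psill, 0.02)
  # all-zero semivariances -> pure-nugget model, zero sill
  zero <- data.frame(lag = 1:5, gamma = 0, n_pairs = 100)
  zfit <- fit_variogram(zero)
  expect_equal(zfit$nugget + zfit$psill, 0)
})

test_that("kriging interpolates exactly at data locations when nugget is zero", {
  model <- variogram_model("exponential", nugget = 0, psill = 0.2, range_km = 8)
  pts <- grf_points(25, 10, model, seed = 31)
  # move one point onto a cell centre of a 10x10 target
  pts$x_km[1] <- 4.5; pts$y_km[1] <- 6.5
  kr <- krige(pts, model, epi_raster(matrix(0, 10, 10)), k_neighbors = 10,
              clamp = NULL)
  cells <- raster_cells(kr$prediction)
  at <- which(cells$x == 4.5 & cells$y == 6.5)
  expect_equal(cells$value[at], pts$z[1], tolerance = 1e-8)
})

test_that("a constant field predicts the constant with nugget-only error", {
  model <- variogram_model("exponential", nugget = 0.01, psill = 0.1,
                           range_km = 5)
  set.seed(6)
  pts <- data.frame(x_km = runif(30, 0, 12), y_km = runif(30, 0, 12), z = 0.4)
  kr <- krige(pts, model, epi_raster(matrix(0, 12, 12)), k_neighbors = 12)
  expect_true(all(abs(kr$prediction$values - 0.4) < 1e-10))
  expect_true(all(kr$se$values >= sqrt(0.01) - 1e-6))
})

test_that("local kriging with k = n matches the full-system oracle", {
  model <- variogram_model("exponential", nugget = 0.02, psill = 0.3,
                           range_km = 12)
  pts <- grf_points(30, 20, model, seed = 77)
  target <- epi_raster(matrix(0, 8, 8), cellsize = 2.5)
  kr <- krige(pts, model, target, k_neighbors = nrow(pts), clamp = NULL)
  cells <- raster_cells(kr$prediction)
  se_cells <- raster_cells(kr$se)
  for (i in seq(1, nrow(cells), by = 7)) {
    oracle <- brute_force_ok(pts, model, cells$x[i], cells$y[i])
    expect_equal(cells$value[i], oracle$pred, tolerance = 1e-6)
    expect_equal(se_cells$value[i]^2, oracle$var, tolerance = 1e-6)
  }
})

test_that("ordinary kriging weights sum to one", {
  model <- variogram_model("exponential", nugget = 0.05, psill = 0.2,
                           range_km = 6)
  pts <- grf_points(40, 15, model, seed = 55)
  for (i in 1:5) {
    sol <- accessmap:::ok_solve(as.matrix(pts[1:15, c("x_km", "y_km")]),
                                pts$z[1:15], 3 * i, 2 * i, model)
    expect_equal(sum(sol$lambda), 1, tolerance = 1e-8)
  }
  # equivalent behavioural check: adding a constant shifts predictions by it
  shifted <- pts; shifted$z <- pts$z + 10
  t8 <- epi_raster(matrix(0, 6, 6), cellsize = 2.5)
  a <- krige(pts, model, t8, k_neighbors = 12, clamp = NULL)
  b <- krige(shifted, model, t8, k_neighbors = 12, clamp = NULL)
  expect_equal(b$prediction$values, a$prediction$values + 10, tolerance = 1e-8)
})

test_that("leave-one-out cross-validation is sane on simple fields", {
  model <- variogram_model("exponential", nugget = 0.01, psill = 0.1,
                           range_km = 5)
  set.seed(8)
  const <- data.frame(x_km = runif(20, 0, 10), y_km = runif(20, 0, 10), z = 2)
  cv <- loo_cross_validate(const, model)
  expect_equal(cv$rmse, 0, tolerance = 1e-10)
  expect_equal(cv$n, 20)
  expect_error(loo_cross_validate(const[1:5, ], model), "at least 10")
})

test_that("the ensemble mode averages to a similar surface", {
  model <- variogram_model("exponential", nugget = 0, psill = 0.04,
                           range_km = 8)
  pts <- grf_points(60, 20, model, seed = 91)
  target <- epi_raster(matrix(0, 10, 10), cellsize = 2)
  plain <- krige(pts, model, target, k_neighbors = 15, clamp = NULL)
  ens <- krige(pts, model, target, k_neighbors = 15, clamp = NULL,
               ensemble = 5, seed = 2)
  expect_equal(dim(ens$prediction$values), dim(plain$prediction$values))
  expect_lt(mean(abs(ens$prediction$values - plain$prediction$values)),
            2 * sd(pts$z))
})

test_that("DoI is the cellwise prevalence-population product", {
  esp <- epi_raster(matrix(c(0.1, 0, 0.5, NA), 2, 2))
  pop <- epi_raster(matrix(c(100, 200, 10, 50), 2, 2))
  doi <- make_doi(esp, pop)
  expect_equal(doi$values[1, 1], 10)
  expect_equal(doi$values[2, 1], 0)      # zero prevalence -> zero PWH
  expect_true(is.na(doi$values[2, 2]))   # nodata propagates
  # total PWH identity against the population-weighted mean prevalence
  set.seed(12)
  pv <- matrix(runif(64, 0, 0.4), 8, 8)
  pp <- matrix(runif(64, 10, 500), 8, 8)
  total <- sum(make_doi(epi_raster(pv), epi_raster(pp))$values)
  expect_equal(total, sum(pv * pp) / sum(pp) * sum(pp), tolerance = 1e-9)
  # geometry mismatch is refused
  expect_error(make_doi(esp, epi_raster(matrix(1, 3, 3))), "geometry")
})

test_that("concentration curves follow the ranked cumulative construction", {
  ecc <- build_ecc(c(8, 4, 2, 1, 1))
  expect_equal(ecc$cum_fraction, c(0.5, 0.75, 0.875, 0.9375, 1.0))
  expect_equal(ecc$total_pwh, 16)
  expect_true(all(diff(ecc$doi_sorted) <= 0))
  # permutation invariance
  ecc_p <- build_ecc(c(1, 2, 8, 1, 4))
  expect_equal(ecc_p$doi_sorted, ecc$doi_sorted)
  expect_equal(ecc_p$cum_fraction, ecc$cum_fraction)
  # uniform raster -> linear cumulative share
  u <- build_ecc(rep(3, 10))
  expect_equal(u$cum_fraction, (1:10) / 10)
  expect_error(build_ecc(c(0, 0)), "ECC error")
})

test_that("the coverage threshold solver matches brute force and is monotone", {
  ecc <- build_ecc(c(8, 4, 2, 1, 1))
  expect_equal(min_doi_for_coverage(ecc, 0.75), 4)
  expect_equal(min_doi_for_coverage(ecc, 0.5), 8)
  expect_equal(min_doi_for_coverage(ecc, 1.0), 1)
  expect_error(min_doi_for_coverage(ecc, 0), "domain error")
  expect_error(min_doi_for_coverage(ecc, 1.2), "domain error")
  # brute force over prefixes of an arbitrary raster
  set.seed(3)
  vals <- round(runif(40, 0, 50), 1)
  e2 <- build_ecc(vals)
  sorted <- sort(vals, decreasing = TRUE)
  for (cov in c(0.2, 0.5, 0.8, 0.95)) {
    k <- which(cumsum(sorted) / sum(sorted) >= cov)[1]
    expect_equal(min_doi_for_coverage(e2, cov), sorted[k])
  }
  covs <- seq(0.05, 1, by = 0.05)
  th <- vapply(covs, function(cv) min_doi_for_coverage(e2, cv), numeric(1))
  expect_true(all(diff(th) <= 0))
})

test_that("an interpolated surface beats the null predictor on a known field", {
  cfg <- country_config(grid_nx = 24, grid_ny = 24, n_ea = 60,
                        individuals_per_ea = 60, seed = 17)
  sim <- simulate_country(cfg)
  pts <- cluster_prevalence(sim$records, sim$sites)
  vm <- fit_variogram(empirical_variogram(pts))
  kr <- krige(pts, vm, sim$grid$counts, k_neighbors = 15)
  truth <- sim$field$prevalence$values
  rmse <- sqrt(mean((kr$prediction$values - truth)^2))
  expect_lt(rmse, sd(truth))
})
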