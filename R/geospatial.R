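# Geostatistical stage: empirical variogram, weighted-least-squares
# variogram fit, local ordinary kriging of cluster prevalence into an
# epidemic surface prevalence (ESP) raster with kriging standard errors,
# leave-one-out cross-validation, density-of-infection (DoI) rasters, and
# epidemic concentration curves (ECCs).

#' Empirical semivariogram
#'
#' Matheron estimator per distance bin:
#' `gamma(h) = (1 / (2 N(h))) * sum (z_i - z_j)^2` over point pairs whose
#' separation falls in the bin. Empty bins are dropped with a warning.
#'
#' @param points Data.frame with `x_km`, `y_km` and a value column `z`.
#' @param n_lags Number of equal-width distance bins (default 12).
#' @param max_dist Largest pair distance used (default half the maximum
#'   distance).
#' @return Data.frame `lag` (bin midpoint, km), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(points, n_lags = 12, max_dist = NULL) {
  stopifnot(all(c("x_km", "y_km", "z") %in% names(points)))
  n <- nrow(points)
  if (n < 2) stop("variogram error: need at least 2 points", call. = FALSE)
  D <- as.matrix(stats::dist(points[, c("x_km", "y_km")]))
  ut <- upper.tri(D)
  h <- D[ut]
  dz2 <- (outer(points$z, points$z, "-")^2)[ut]
  if (is.null(max_dist)) max_dist <- max(h) / 2
  keep <- h <= max_dist & h > 0
  h <- h[keep]; dz2 <- dz2[keep]
  br <- seq(0, max_dist, length.out = n_lags + 1)
  bin <- cut(h, br, include.lowest = TRUE, labels = FALSE)
  gamma <- tapply(dz2, bin, function(v) sum(v) / (2 * length(v)))
  np <- tapply(dz2, bin, length)
  mids <- (br[-1] + br[-length(br)]) / 2
  present <- as.integer(names(gamma))
  if (length(present) < n_lags)
    warning(n_lags - length(present), " empty variogram bin(s) dropped",
            call. = FALSE)
  data.frame(lag = mids[present], gamma = as.numeric(gamma),
             n_pairs = as.integer(np))
}

# Model semivariance; gamma(0) = 0 by convention, the nugget is the limit
# from above.
variogram_gamma <- function(model, h) {
  g <- switch(model$family,
    exponential = model$psill * (1 - exp(-h / model$range)),
    spherical = ifelse(h >= model$range, model$psill,
                       model$psill * (1.5 * h / model$range -
                                      0.5 * (h / model$range)^3)),
    stop("unknown variogram family: ", model$family, call. = FALSE))
  ifelse(h > 0, model$nugget + g, 0)
}

#' Variogram model constructor
#'
#' @param family `"exponential"` (default) or `"spherical"`.
#' @param nugget,psill,range_km Nonnegative nugget and partial sill;
#'   positive range (km).
#' @return A `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical"),
                            nugget = 0, psill = 1, range_km = 1) {
  family <- match.arg(family)
  if (nugget < 0 || psill < 0 || range_km <= 0)
    stop("variogram error: nugget, psill >= 0 and range > 0 required", call. = FALSE)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range_km),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, partial sill %.4g, range %.4g km\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises `sum_k w_k * (gamma_hat_k - gamma(h_k))^2` with the customary
#' weights `n_pairs / lag^2` (short, well-populated lags dominate).
#' Parameters are bounded nonnegative (L-BFGS-B on a log-ish floor). An
#' all-zero empirical variogram returns a pure-nugget model.
#'
#' @param empirical Output of [empirical_variogram()].
#' @param family Variogram family.
#' @return A `variogram_model`.
#' @export
fit_variogram <- function(empirical, family = c("exponential", "spherical")) {
  family <- match.arg(family)
  if (nrow(empirical) < 3)
    stop("variogram error: need at least 3 nonempty bins", call. = FALSE)
  g <- empirical$gamma
  if (all(g <= .Machine$double.eps))
    return(variogram_model(family, nugget = 0, psill = 0,
                           range_km = max(empirical$lag)))
  w <- empirical$n_pairs / empirical$lag^2
  obj <- function(par) {
    m <- list(family = family, nugget = par[1], psill = par[2], range = par[3])
    sum(w * (g - variogram_gamma(m, empirical$lag))^2)
  }
  sill0 <- max(g)
  start <- c(nugget = min(g) / 2, psill = sill0 - min(g) / 2,
             range = max(empirical$lag) / 3)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0, 1e-6),
                      upper = c(Inf, Inf, 100 * max(empirical$lag)))
  variogram_model(family, nugget = unname(fit$par[1]),
                  psill = unname(max(fit$par[2], 1e-12)),
                  range_km = unname(fit$par[3]))
}

# Solve the ordinary kriging system for one target given neighbor
# coordinates/values. Returns prediction, kriging variance, weights.
ok_solve <- function(xy, z, x0, y0, model, jitter_retry = TRUE) {
  k <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  G <- variogram_gamma(model, D)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  g0 <- variogram_gamma(model, sqrt((xy[, 1] - x0)^2 + (xy[, 2] - y0)^2))
  b <- c(g0, 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol) && jitter_retry) {
    A2 <- A; diag(A2)[seq_len(k)] <- diag(A2)[seq_len(k)] + 1e-10
    sol <- tryCatch(solve(A2, b), error = function(e) NULL)
  }
  if (is.null(sol)) return(NULL)
  lambda <- sol[seq_len(k)]
  mu <- sol[k + 1]
  list(pred = sum(lambda * z),
       var = max(0, sum(lambda * g0) + mu),
       lambda = lambda)
}

k_nearest <- function(px, py, x0, y0, k) {
  d2 <- (px - x0)^2 + (py - y0)^2
  order(d2)[seq_len(min(k, length(px)))]
}

#' Ordinary kriging of cluster prevalence onto a grid
#'
#' Local ordinary kriging: each cell is predicted from its `k_neighbors`
#' nearest cluster points by solving the OK system (weights constrained to
#' sum to 1 via the Lagrange multiplier). Predictions of a proportion are
#' clamped to `[0, 1]`. An optional ensemble mode refits the variogram on
#' bootstrap subsets of the points and averages the resulting predictions —
#' a light-weight analogue of empirical Bayesian kriging's semivariogram
#' ensemble. A singular neighborhood system is retried once with a
#' `1e-10` diagonal jitter, then set to nodata.
#'
#' @param points Data.frame `x_km`, `y_km`, `z` (cluster prevalence).
#' @param model A `variogram_model`.
#' @param target An [epi_raster()] supplying the prediction geometry (its
#'   values are ignored).
#' @param k_neighbors Neighborhood size (>= 4; default 15).
#' @param clamp Clamp interval for the prediction (default `c(0, 1)`;
#'   `NULL` disables).
#' @param ensemble Number of ensemble members (0 = plain OK).
#' @param seed Seed for the ensemble bootstrap.
#' @return List of two `epi_raster`s: `prediction` and `se`.
#' @export
krige <- function(points, model, target, k_neighbors = 15, clamp = c(0, 1),
                  ensemble = 0, seed = 1) {
  stopifnot(inherits(model, "variogram_model"), inherits(target, "epi_raster"))
  if (k_neighbors < 4) stop("kriging error: k_neighbors must be >= 4", call. = FALSE)
  if (ensemble > 0) {
    preds <- vars <- vector("list", ensemble)
    with_seed(seed, {
      for (e in seq_len(ensemble)) {
        idx <- sample(nrow(points), replace = TRUE)
        sub <- points[unique(idx), ]
        m_e <- tryCatch(
          fit_variogram(empirical_variogram(sub), family = model$family),
          error = function(err) model)
        r <- krige(points, m_e, target, k_neighbors, clamp, ensemble = 0)
        preds[[e]] <- r$prediction$values
        vars[[e]] <- r$se$values^2
      }
    })
    pm <- Reduce(`+`, preds) / ensemble
    vm <- Reduce(`+`, vars) / ensemble
    return(list(prediction = epi_raster(pm, target$xll, target$yll, target$cellsize),
                se = epi_raster(sqrt(vm), target$xll, target$yll, target$cellsize)))
  }

  cells <- raster_cells(target)
  n_cell <- nrow(cells)
  pred <- se <- rep(NA_real_, n_cell)
  px <- points$x_km; py <- points$y_km; pz <- points$z
  for (i in seq_len(n_cell)) {
    nb <- k_nearest(px, py, cells$x[i], cells$y[i], k_neighbors)
    sol <- ok_solve(cbind(px[nb], py[nb]), pz[nb], cells$x[i], cells$y[i], model)
    if (!is.null(sol)) {
      pred[i] <- sol$pred
      se[i] <- sqrt(sol$var)
    }
  }
  if (!is.null(clamp)) pred <- pmin(clamp[2], pmax(clamp[1], pred))
  ny <- nrow(target$values); nx <- ncol(target$values)
  list(prediction = epi_raster(matrix(pred, ny, nx, byrow = TRUE),
                               target$xll, target$yll, target$cellsize),
       se = epi_raster(matrix(se, ny, nx, byrow = TRUE),
                       target$xll, target$yll, target$cellsize))
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Each point is removed in turn and predicted from the remaining points
#' (same neighborhood rule as [krige()], no clamping). Reports the standard
#' kriging CV metrics: mean error and RMSE of `predicted - observed`, the
#' mean and root-mean-square standardized errors (error / kriging SE), and
#' the average kriging standard error. A mean error near 0 indicates
#' unbiasedness; an RMS standardized error near 1 indicates calibrated
#' prediction uncertainty.
#'
#' @param points Data.frame `x_km`, `y_km`, `z`.
#' @param model A `variogram_model`.
#' @param k_neighbors Neighborhood size.
#' @return A `cv_report`: `mean_error`, `rmse`, `mean_standardized_error`,
#'   `rms_standardized_error`, `average_standard_error`, `n`.
#' @export
loo_cross_validate <- function(points, model, k_neighbors = 15) {
  n <- nrow(points)
  if (n < 10) stop("cv error: need at least 10 points", call. = FALSE)
  err <- std <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rest <- points[-i, ]
    nb <- k_nearest(rest$x_km, rest$y_km, points$x_km[i], points$y_km[i],
                    k_neighbors)
    sol <- ok_solve(cbind(rest$x_km[nb], rest$y_km[nb]), rest$z[nb],
                    points$x_km[i], points$y_km[i], model)
    if (!is.null(sol)) {
      err[i] <- sol$pred - points$z[i]
      se[i] <- sqrt(sol$var)
      std[i] <- if (se[i] > 0) err[i] / se[i] else 0
    }
  }
  structure(list(mean_error = mean(err, na.rm = TRUE),
                 rmse = sqrt(mean(err^2, na.rm = TRUE)),
                 mean_standardized_error = mean(std, na.rm = TRUE),
                 rms_standardized_error = sqrt(mean(std^2, na.rm = TRUE)),
                 average_standard_error = mean(se, na.rm = TRUE),
                 n = n),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("LOO cross-validation (n = %d): ME %.4g, RMSE %.4g, ",
                     "std ME %.3f, std RMS %.3f, avg SE %.4g\n"),
              x$n, x$mean_error, x$rmse, x$mean_standardized_error,
              x$rms_standardized_error, x$average_standard_error))
  invisible(x)
}

#' Density-of-infection raster
#'
#' Cellwise product of a prevalence surface and a population grid on the
#' same geometry: people with HIV per square kilometre. Nodata in either
#' layer propagates.
#'
#' @param esp Prevalence `epi_raster` (values in `[0, 1]`).
#' @param population Population `epi_raster` (persons per cell) or a
#'   `population_grid`.
#' @return A DoI `epi_raster`.
#' @export
make_doi <- function(esp, population) {
  if (inherits(population, "population_grid")) population <- population$counts
  stopifnot(inherits(esp, "epi_raster"), inherits(population, "epi_raster"))
  if (!same_geometry(esp, population))
    stop("raster error: prevalence and population grids have different geometry",
         call. = FALSE)
  epi_raster(esp$values * population$values, esp$xll, esp$yll, esp$cellsize)
}

#' Epidemic concentration curve
#'
#' Ranks the DoI cells in descending order and accumulates the share of all
#' people with HIV: `cum_fraction_k = sum_{j<=k} doi_j / total`. Zero cells
#' contribute nothing to the cumulative share but are part of the total;
#' nodata cells are excluded.
#'
#' @param doi A DoI `epi_raster` or numeric vector of cell values.
#' @return An `ecc`: list with `doi_sorted` (nonincreasing), `cum_fraction`
#'   (nondecreasing, ending at 1), `total_pwh`.
#' @export
build_ecc <- function(doi) {
  v <- if (inherits(doi, "epi_raster")) as.vector(doi$values) else as.numeric(doi)
  v <- v[!is.na(v)]
  if (!any(v > 0)) stop("ECC error: raster has no positive cells", call. = FALSE)
  v <- sort(v, decreasing = TRUE)
  total <- sum(v)
  structure(list(doi_sorted = v, cum_fraction = cumsum(v) / total,
                 total_pwh = total),
            class = "ecc")
}

#' @export
print.ecc <- function(x, ...) {
  cat(sprintf("ECC over %d cells, total PWH %.1f, top cell %.3g PWH/km^2\n",
              length(x$doi_sorted), x$total_pwh, x$doi_sorted[1]))
  invisible(x)
}

#' Minimum DoI level needed for a treatment coverage
#'
#' The largest DoI value `d*` such that treating everyone in cells with
#' `DoI >= d*` reaches at least the requested share of all people with HIV:
#' the value of the first ranked cell at which the cumulative fraction
#' reaches `coverage`.
#'
#' @param ecc An `ecc`.
#' @param coverage Target treatment coverage in `(0, 1]`.
#' @return The threshold `d*` in PWH per km^2.
#' @examples
#' e <- build_ecc(c(8, 4, 2, 1, 1))
#' min_doi_for_coverage(e, 0.75)  # 4
#' @export
min_doi_for_coverage <- function(ecc, coverage) {
  stopifnot(inherits(ecc, "ecc"))
  if (coverage <= 0 || coverage > 1)
    stop("domain error: coverage must be in (0, 1]", call. = FALSE)
  k <- which(ecc$cum_fraction >= coverage - 1e-12)[1]
  ecc$doi_sorted[k]
}
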