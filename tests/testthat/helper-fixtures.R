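# Shared fixtures: all synthetic, built in code.

# A small country that simulates in well under a second.
tiny_config <- function(...) {
  defaults <- list(grid_nx = 16, grid_ny = 16, n_ea = 16,
                   individuals_per_ea = 40, seed = 42L)
  do.call(country_config, utils::modifyList(defaults, list(...)))
}

# Hand-built record table: one record per PSU, single stratum, for
# closed-form jackknife checks.
psu_records <- function(values, weights = rep(1, length(values)),
                        strata = rep("s1", length(values))) {
  rec <- data.frame(
    ea_id = sprintf("EA%02d", seq_along(values)),
    stratum = strata,
    sex = "F", age_group = "25-34",
    hiv_positive = TRUE, on_art = FALSE,
    traveltime_category = NA_character_,
    design_weight = weights,
    y = values,
    stringsAsFactors = FALSE)
  make_replicate_weights(rec)
}

# On-ART record table with given per-EA category draws, for travel-time
# tests. `counts` is a named vector over LT1H/H1TO2/GT2H per EA.
art_records <- function(n_ea, per_ea_counts, stratum = "rural",
                        sex = "F", weight = 1) {
  do.call(rbind, lapply(seq_len(n_ea), function(i) {
    cats <- rep(names(per_ea_counts), per_ea_counts)
    data.frame(ea_id = sprintf("EA%03d", i), stratum = stratum,
               sex = sex, age_group = "25-34",
               hiv_positive = TRUE, on_art = TRUE,
               traveltime_category = cats,
               design_weight = weight, stringsAsFactors = FALSE)
  }))
}

# Category table built directly from proportions (as printed summary
# tables give them), bypassing the record level.
category_table <- function(p_lt1, p_1to2, p_gt2, n = 1000, domain = "d") {
  structure(list(domain = domain, p_lt1 = p_lt1, p_1to2 = p_1to2,
                 p_gt2 = p_gt2, n = n),
            class = "category_table")
}

# Exact GRF draw at arbitrary locations under an exponential variogram
# model (nugget as iid noise), independent of the package's field
# generator. Returns the data.frame of points with z.
grf_points <- function(n, extent, model, seed) {
  set.seed(seed)
  x <- runif(n, 0, extent); y <- runif(n, 0, extent)
  D <- as.matrix(dist(cbind(x, y)))
  C <- model$psill * exp(-D / model$range)
  L <- chol(C + diag(1e-10, n))
  z <- as.vector(crossprod(L, rnorm(n)))
  if (model$nugget > 0) z <- z + rnorm(n, sd = sqrt(model$nugget))
  data.frame(x_km = x, y_km = y, z = z)
}

# Brute-force global ordinary kriging (full system, all points), the
# independent oracle for the local solver.
brute_force_ok <- function(points, model, x0, y0) {
  n <- nrow(points)
  D <- as.matrix(dist(points[, c("x_km", "y_km")]))
  G <- matrix(0, n, n)
  G[] <- accessmap:::variogram_gamma(model, D)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  g0 <- accessmap:::variogram_gamma(
    model, sqrt((points$x_km - x0)^2 + (points$y_km - y0)^2))
  sol <- solve(A, c(g0, 1))
  list(pred = sum(sol[1:n] * points$z),
       var = sum(sol[1:n] * g0) + sol[n + 1])
}

# Truncated-logistic cumulative probability, written out independently of
# the generator's internals.
trunc_logis_cdf <- function(q, mu, s) {
  f0 <- plogis((0 - mu) / s)
  (plogis((q - mu) / s) - f0) / (1 - f0)
}
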