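# Travel-time analysis: weighted category tables for the three reported
# one-way travel-time bands, cumulative anchor points, logistic CDF fits,
# bootstrap confidence bands, and the multivariable logistic model for
# adjusted odds ratios.

#' Weighted travel-time category table
#'
#' Weighted proportions of the three travel-time categories (under one hour,
#' one to two hours, more than two hours) among on-ART records of a domain.
#' Item nonresponse (NA category) is excluded from the denominator.
#'
#' @param records Record table (`on_art`, `traveltime_category`,
#'   `design_weight`).
#' @param domain_filter Optional logical domain selector.
#' @param domain Label for the table.
#' @return A `category_table`: `domain`, `p_lt1`, `p_1to2`, `p_gt2`
#'   (summing to 1), unweighted `n`.
#' @export
tabulate_categories <- function(records, domain_filter = NULL, domain = "all") {
  dom <- resolve_domain(records, domain_filter)
  ans <- dom & records$on_art & !is.na(records$traveltime_category)
  if (!any(ans))
    stop("tabulation error: no answered on-ART records in domain '",
         domain, "'", call. = FALSE)
  w <- records$design_weight[ans]
  cat <- factor(records$traveltime_category[ans], levels = traveltime_levels())
  p <- tapply(w, cat, sum, default = 0) / sum(w)
  structure(list(domain = domain, p_lt1 = unname(p["LT1H"]),
                 p_1to2 = unname(p["H1TO2"]), p_gt2 = unname(p["GT2H"]),
                 n = sum(ans)),
            class = "category_table")
}

#' @export
print.category_table <- function(x, ...) {
  cat(sprintf("%s (n = %d): <1h %.1f%%, 1-2h %.1f%%, >2h %.1f%%\n",
              x$domain, x$n, 100 * x$p_lt1, 100 * x$p_1to2, 100 * x$p_gt2))
  invisible(x)
}

#' Cumulative anchor points for a logistic CDF fit
#'
#' Converts a category table into the three cumulative points the fitted
#' curve is anchored on: `(1, p_lt1)`, `(2, p_lt1 + p_1to2)`, and
#' `(T_end, 1)`, where the endpoint is 3.5 h for urban domains and 4 h for
#' rural and national domains (rural journeys have the longer tail).
#'
#' @param table A `category_table`.
#' @param residence `"urban"`, `"rural"` or `"national"`.
#' @param weights Anchor weights (default equal).
#' @return An `anchor_set`: data.frame `t`, `p`, `w` with `t` increasing
#'   and `p` nondecreasing ending at 1.
#' @export
build_anchors <- function(table, residence = c("national", "rural", "urban"),
                          weights = c(1, 1, 1)) {
  residence <- match.arg(residence)
  t_end <- if (residence == "urban") 3.5 else 4.0
  p <- cumsum(c(table$p_lt1, table$p_1to2))
  anchors <- data.frame(t = c(1, 2, t_end),
                        p = pmin(1, c(p, 1)),
                        w = weights)
  class(anchors) <- c("anchor_set", "data.frame")
  anchors
}

#' Exact logistic CDF through two cumulative points
#'
#' Closed-form `(mu, s)` such that `F(t; mu, s) = 1 / (1 + exp(-(t-mu)/s))`
#' passes through `(t1, p1)` and `(t2, p2)`:
#' `1/s = (logit(p2) - logit(p1)) / (t2 - t1)` and `mu = t1 - s * logit(p1)`.
#' Used as the initialiser of [fit_logistic_cdf()].
#'
#' @param t1,t2 Times (hours), `t1 < t2`.
#' @param p1,p2 Cumulative proportions, `0 < p1 < p2 < 1`.
#' @return A `logistic_cdf`: list `mu`, `s`, `sse` (0 here), `converged`.
#' @examples
#' two_point_logistic_solve(1, 0.626, 2, 0.895)
#' @export
two_point_logistic_solve <- function(t1, p1, t2, p2) {
  if (!(t1 < t2) || !(p1 > 0 && p2 < 1 && p1 < p2))
    stop("domain error: need t1 < t2 and 0 < p1 < p2 < 1", call. = FALSE)
  s <- (t2 - t1) / (stats::qlogis(p2) - stats::qlogis(p1))
  mu <- t1 - s * stats::qlogis(p1)
  structure(list(mu = mu, s = s, sse = 0, converged = TRUE),
            class = "logistic_cdf")
}

#' @export
print.logistic_cdf <- function(x, ...) {
  cat(sprintf("logistic CDF: mu = %.4f h, s = %.4f h (sse %.3g)\n",
              x$mu, x$s, x$sse))
  invisible(x)
}

#' Evaluate a fitted logistic CDF
#'
#' @param object A `logistic_cdf`.
#' @param t Times (hours).
#' @param ... Unused.
#' @return `F(t) = plogis((t - mu) / s)`.
#' @export
predict.logistic_cdf <- function(object, t, ...) {
  stats::plogis((t - object$mu) / object$s)
}

#' Least-squares logistic CDF fit to cumulative anchors
#'
#' Minimises `sum_i w_i * (F(t_i; mu, s) - p_i)^2` over `(mu, log s)` (the
#' log parameterisation keeps the scale positive), starting from the exact
#' two-point solution through the first and last usable anchors. BFGS with
#' analytic gradient; convergence when the objective improvement is below
#' machine-level tolerance.
#'
#' @param anchors An `anchor_set` or data.frame with `t`, `p` and optional
#'   `w` (>= 2 distinct rows).
#' @param max_iter Iteration cap (default 10000).
#' @return A `logistic_cdf` with `mu`, `s`, `sse`, `converged`.
#' @export
fit_logistic_cdf <- function(anchors, max_iter = 10000) {
  # proportions exactly at 0 or 1 (fully censored categories) are clipped
  # into the open interval: a logistic CDF attains them only in the limit,
  # which would push the optimum onto the s -> 0 boundary
  t <- anchors$t
  p <- pmin(1 - 1e-9, pmax(1e-9, anchors$p))
  w <- if ("w" %in% names(anchors)) anchors$w else rep(1, length(t))
  if (length(unique(t)) < 2)
    stop("fit error: need at least 2 distinct anchors", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("fit error: anchor times must be strictly increasing", call. = FALSE)

  # initialiser: exact solve through the outermost anchors interior in p
  int <- which(p > 0 & p < 1)
  init <- if (length(int) >= 2) {
    i <- int[1]; j <- int[length(int)]
    if (p[i] < p[j]) two_point_logistic_solve(t[i], p[i], t[j], p[j])
    else list(mu = mean(t), s = diff(range(t)) / 4)
  } else list(mu = mean(t), s = diff(range(t)) / 4)

  obj <- function(par) {
    f <- stats::plogis((t - par[1]) / exp(par[2]))
    sum(w * (f - p)^2)
  }
  grad <- function(par) {
    s <- exp(par[2])
    z <- (t - par[1]) / s
    f <- stats::plogis(z)
    r <- w * (f - p)
    dens <- f * (1 - f)
    c(sum(2 * r * dens * (-1 / s)),
      sum(2 * r * dens * (-z)))      # d/d(log s): dens * (-z/s) * s
  }
  fit <- stats::optim(c(init$mu, log(init$s)), obj, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  # fully censored categories put the optimum on the s -> 0 boundary and the
  # iteration cap can be hit while the fit is already essentially perfect;
  # such degenerate fits are returned (converged = FALSE) rather than refused
  if (fit$convergence != 0 && fit$value > 1e-6)
    stop("fit error: logistic CDF fit did not converge (last mu = ",
         signif(fit$par[1], 6), ", s = ", signif(exp(fit$par[2]), 6), ")",
         call. = FALSE)
  structure(list(mu = fit$par[1], s = exp(fit$par[2]), sse = fit$value,
                 converged = fit$convergence == 0),
            class = "logistic_cdf")
}

#' Bootstrap confidence band for a travel-time CDF
#'
#' Cluster bootstrap respecting the survey design: EAs (PSUs) are resampled
#' with replacement within strata, the category table re-tabulated, anchors
#' rebuilt and the logistic CDF refitted; the band is the pointwise 2.5/97.5
#' percentile envelope of `F(t)` over a time grid. Replicates in which a
#' category table degenerates (no answered records, or cumulative
#' proportions unusable for fitting) are skipped and counted; more than 20%
#' skipped aborts.
#'
#' @param records Record table.
#' @param domain_filter Optional logical domain selector.
#' @param residence Endpoint convention passed to [build_anchors()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @param t_grid Evaluation grid in hours (default 0 to 5 by 0.05).
#' @param conf_level Band level (default 0.95).
#' @return A `confidence_band`: data.frame `t`, `lower`, `fit`, `upper`,
#'   with attributes `n_skipped` and the point-estimate `logistic_cdf`.
#' @export
bootstrap_band <- function(records, domain_filter = NULL,
                           residence = "national", B = 1000, seed = 1,
                           t_grid = seq(0, 5, by = 0.05), conf_level = 0.95) {
  dom <- resolve_domain(records, domain_filter)
  sub <- records[dom, , drop = FALSE]
  psu <- unique(sub[, c("stratum", "ea_id")])
  if (nrow(psu) < 2)
    stop("band error: domain has fewer than 2 PSUs", call. = FALSE)
  point <- fit_logistic_cdf(build_anchors(
    tabulate_categories(sub), residence = residence))

  by_stratum <- split(psu$ea_id, psu$stratum)
  rows_of <- split(seq_len(nrow(sub)), sub$ea_id)
  curves <- matrix(NA_real_, nrow = B, ncol = length(t_grid))
  skipped <- 0
  with_seed(seed, {
    for (b in seq_len(B)) {
      take <- unlist(lapply(by_stratum, function(ids)
        sample(ids, length(ids), replace = TRUE)), use.names = FALSE)
      idx <- unlist(rows_of[take], use.names = FALSE)
      fit_b <- tryCatch({
        tab <- tabulate_categories(sub[idx, , drop = FALSE])
        fit_logistic_cdf(build_anchors(tab, residence = residence))
      }, error = function(e) NULL)
      if (is.null(fit_b)) skipped <- skipped + 1
      else curves[b, ] <- predict(fit_b, t_grid)
    }
  })
  if (skipped > 0.2 * B)
    stop("band error: ", skipped, " of ", B,
         " bootstrap replicates degenerate", call. = FALSE)
  a <- (1 - conf_level) / 2
  qs <- apply(curves[stats::complete.cases(curves), , drop = FALSE], 2,
              stats::quantile, probs = c(a, 1 - a), names = FALSE)
  band <- data.frame(t = t_grid, lower = qs[1, ],
                     fit = predict(point, t_grid), upper = qs[2, ])
  structure(band, class = c("confidence_band", "data.frame"),
            n_skipped = skipped, point_fit = point)
}

#' Multivariable logistic model for long travel times
#'
#' Fits the odds of travelling one hour or more to reach treatment (outcome:
#' category 1-2 h or > 2 h) on rural residence, female sex, and age-group
#' dummies, among on-ART records that answered the travel-time item.
#' Default is unweighted maximum likelihood; `weighted = TRUE` uses the
#' design weights with PSU-clustered robust (sandwich) standard errors.
#' Adjusted odds ratios are `exp(beta)` with Wald 95% CIs and two-tailed
#' p-values.
#'
#' @param records Record table.
#' @param interaction Add the rural-by-female interaction term.
#' @param weighted Use design weights + cluster-robust SEs.
#' @param separation_bound Absolute coefficient magnitude treated as
#'   separation (default 15).
#' @return A `logit_model`: `fit` (the glm), `table` (term, beta, se, aOR,
#'   ci_low, ci_high, p), `n`.
#' @export
fit_travel_logit <- function(records, interaction = FALSE, weighted = FALSE,
                             separation_bound = 15) {
  use <- records$on_art & !is.na(records$traveltime_category)
  d <- records[use, , drop = FALSE]
  if (nrow(d) == 0) stop("fit error: no answered on-ART records", call. = FALSE)
  d$long <- d$traveltime_category %in% c("H1TO2", "GT2H")
  d$rural <- as.integer(d$stratum == "rural")
  d$female <- as.integer(d$sex == "F")
  d$age_group <- factor(d$age_group, levels = age_groups())
  if (length(unique(d$long)) < 2)
    stop("fit error: separation — the outcome is constant", call. = FALSE)

  keep_age <- nlevels(droplevels(d$age_group)) > 1
  rhs <- c("rural", "female", if (keep_age) "age_group",
           if (interaction) "rural:female")
  drop_const <- vapply(c(rural = "rural", female = "female"),
                       function(v) length(unique(d[[v]])) < 2, logical(1))
  rhs <- setdiff(rhs, names(drop_const)[drop_const])
  if (length(rhs) == 0) stop("fit error: no varying predictors", call. = FALSE)
  fml <- stats::as.formula(paste("long ~", paste(rhs, collapse = " + ")))

  if (weighted) {
    # weights normalised to mean 1: the fit is invariant to their scale and
    # IRLS is much better conditioned
    d$norm_w <- d$design_weight / mean(d$design_weight)
    fit <- stats::glm(fml, family = stats::quasibinomial(), data = d,
                      weights = d$norm_w,
                      control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    V <- sandwich::vcovCL(fit, cluster = d$ea_id)
  } else {
    fit <- stats::glm(fml, family = stats::binomial(), data = d,
                      control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    V <- stats::vcov(fit)
  }
  beta <- stats::coef(fit)
  if (any(abs(beta) > separation_bound)) {
    bad <- names(beta)[which.max(abs(beta))]
    stop("fit error: separation detected for covariate '", bad, "'", call. = FALSE)
  }
  se <- sqrt(diag(V))
  z <- beta / se
  tab <- data.frame(term = names(beta), beta = unname(beta), se = unname(se),
                    aOR = exp(unname(beta)),
                    ci_low = exp(unname(beta - 1.96 * se)),
                    ci_high = exp(unname(beta + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, n = nrow(d), weighted = weighted),
            class = "logit_model")
}

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf("logistic model of travelling >= 1 h (n = %d%s)\n", x$n,
              if (x$weighted) ", design-weighted" else ""))
  tab <- x$table[x$table$term != "(Intercept)", ]
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-14s aOR %.2f (%.2f, %.2f), p = %.4g\n",
                tab$term[i], tab$aOR[i], tab$ci_low[i], tab$ci_high[i],
                tab$p[i]))
  invisible(x)
}
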