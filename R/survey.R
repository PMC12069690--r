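# Design-based estimation with stratified delete-one-PSU (JKn) jackknife
# variance. Estimates are ratio means sum(w*y)/sum(w); variance follows the
# standard survey convention
#   var = sum_h (n_h - 1)/n_h * sum_{i in h} (theta_(hi) - theta_hat)^2
# with theta_(hi) the estimate under the replicate weights that delete PSU i
# of stratum h, and t-based confidence intervals on df = #PSUs - #strata.

jk_design <- function(records) {
  rw <- rw_columns(records)
  if (length(rw) == 0)
    stop("estimation error: no replicate weights (rw columns); run make_replicate_weights()",
         call. = FALSE)
  psu <- unique(records[, c("stratum", "ea_id")])
  psu <- psu[order(psu$stratum, psu$ea_id), , drop = FALSE]
  if (nrow(psu) != length(rw))
    stop("estimation error: ", length(rw), " replicate columns but ",
         nrow(psu), " PSUs", call. = FALSE)
  n_h <- table(psu$stratum)
  list(rw = rw, psu = psu, n_h = n_h,
       df = nrow(psu) - length(n_h))
}

# Jackknife variance of any statistic expressible as stat_fun(weights),
# evaluated under the full design weights and each replicate column.
jk_variance <- function(records, stat_fun) {
  dsg <- jk_design(records)
  theta <- stat_fun(records$design_weight)
  reps <- vapply(dsg$rw, function(col) stat_fun(records[[col]]), numeric(1))
  mult <- (as.numeric(dsg$n_h[dsg$psu$stratum]) - 1) /
    as.numeric(dsg$n_h[dsg$psu$stratum])
  list(theta = theta, reps = reps,
       variance = sum(mult * (reps - theta)^2), df = dsg$df)
}

resolve_indicator <- function(records, indicator) {
  y <- if (is.character(indicator) && length(indicator) == 1) {
    if (!indicator %in% names(records))
      stop("estimation error: no column '", indicator, "'", call. = FALSE)
    records[[indicator]]
  } else indicator
  as.numeric(y)
}

resolve_domain <- function(records, domain_filter) {
  if (is.null(domain_filter)) rep(TRUE, nrow(records))
  else {
    stopifnot(is.logical(domain_filter), length(domain_filter) == nrow(records))
    domain_filter & !is.na(domain_filter)
  }
}

#' Survey-weighted mean with jackknife standard error
#'
#' Computes the weighted ratio mean `sum(w * y) / sum(w)` of an indicator
#' over a domain, with the jackknife standard error and a t-based 95%
#' confidence interval (df = number of PSUs minus number of strata). Domain
#' estimation keeps the full replicate structure: records outside the domain
#' contribute nothing to the ratio but the replicate weights are still those
#' of the whole design.
#'
#' @param records Record table carrying `design_weight` and replicate-weight
#'   columns (see [make_replicate_weights()]).
#' @param indicator Column name or numeric/logical vector (length
#'   `nrow(records)`).
#' @param domain_filter Optional logical vector selecting the domain
#'   (NA treated as FALSE); `NULL` means all records.
#' @param domain Label stored on the estimate.
#' @param conf_level Confidence level (default 0.95).
#' @param min_n Unweighted domain size below which a small-domain warning is
#'   emitted (default 25).
#' @return A `weighted_estimate`: list with `estimate`, `se`, `ci_low`,
#'   `ci_high`, `n`, `df`, `domain`.
#' @examples
#' rec <- data.frame(stratum = "s", ea_id = sprintf("EA%d", 1:4),
#'                   design_weight = 1, y = c(1, 0, 1, 1))
#' rec <- make_replicate_weights(rec)
#' svy_mean(rec, "y")
#' @export
svy_mean <- function(records, indicator, domain_filter = NULL,
                     domain = "all", conf_level = 0.95, min_n = 25) {
  y <- resolve_indicator(records, indicator)
  dom <- resolve_domain(records, domain_filter)
  if (!any(dom)) stop("estimation error: empty domain '", domain, "'", call. = FALSE)
  if (any(is.na(y[dom])))
    stop("estimation error: indicator has NA inside the domain", call. = FALSE)
  n <- sum(dom)
  if (n < min_n)
    warning("domain '", domain, "' has only ", n,
            " records; estimates may be unstable", call. = FALSE)
  stat <- function(w) {
    sw <- sum(w[dom])
    if (sw <= 0) return(NA_real_)
    sum(w[dom] * y[dom]) / sw
  }
  jk <- jk_variance(records, stat)
  se <- sqrt(jk$variance)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = jk$df)
  structure(list(estimate = jk$theta, se = se,
                 ci_low = jk$theta - tq * se, ci_high = jk$theta + tq * se,
                 n = n, df = jk$df, domain = domain),
            class = "weighted_estimate")
}

#' @rdname svy_mean
#' @details `weighted_proportion()` is `svy_mean()` restricted to 0/1
#'   indicators (prevalence, coverage, category shares); it checks the
#'   indicator is binary and that the estimate lies in `[0, 1]`.
#' @export
weighted_proportion <- function(records, indicator, domain_filter = NULL,
                                domain = "all", conf_level = 0.95, min_n = 25) {
  y <- resolve_indicator(records, indicator)
  dom <- resolve_domain(records, domain_filter)
  if (!all(y[dom] %in% c(0, 1) | is.na(y[dom])))
    stop("estimation error: indicator is not 0/1; use svy_mean()", call. = FALSE)
  est <- svy_mean(records, y, domain_filter, domain, conf_level, min_n)
  est$ci_low <- max(0, est$ci_low)
  est$ci_high <- min(1, est$ci_high)
  est
}

#' Jackknife standard error of a weighted mean
#'
#' @inheritParams svy_mean
#' @return The jackknife standard error (scalar).
#' @export
jackknife_se <- function(records, indicator, domain_filter = NULL) {
  svy_mean(records, indicator, domain_filter, min_n = 0)$se
}

#' @export
print.weighted_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f (se %.4f, 95%% CI %.4f-%.4f, n = %d)\n",
              x$domain, x$estimate, x$se, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Design-based F-test for a difference between two domains
#'
#' Wald test of `H0: theta_a = theta_b` where both estimates come from the
#' same design. The variance of the contrast is obtained by jackknifing the
#' contrast itself (re-estimating both domain means under every replicate),
#' which accounts for the covariance induced by shared PSUs — not by summing
#' the two variances. The statistic `F = (theta_a - theta_b)^2 / var` is
#' referred to F(1, df) with df = #PSUs - #strata; two-tailed at `alpha`.
#'
#' @param records Record table with replicate weights.
#' @param indicator Column name or vector (the outcome proportion).
#' @param domain_a,domain_b Logical vectors selecting the two domains.
#' @param labels Length-2 character vector naming the domains.
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison`: both `weighted_estimate`s, `F`, `df1`,
#'   `df2`, `p`, `significant`.
#' @export
design_f_test <- function(records, indicator, domain_a, domain_b,
                          labels = c("a", "b"), alpha = 0.05) {
  y <- resolve_indicator(records, indicator)
  da <- resolve_domain(records, domain_a)
  db <- resolve_domain(records, domain_b)
  if (!any(da) || !any(db))
    stop("comparison error: empty domain", call. = FALSE)
  est_a <- svy_mean(records, y, da, labels[1], min_n = 0)
  est_b <- svy_mean(records, y, db, labels[2], min_n = 0)
  contrast <- function(w) {
    sum(w[da] * y[da]) / sum(w[da]) - sum(w[db] * y[db]) / sum(w[db])
  }
  jk <- jk_variance(records, contrast)
  Fstat <- if (jk$variance == 0) {
    if (jk$theta == 0) 0 else Inf
  } else jk$theta^2 / jk$variance
  p <- if (Fstat == 0) 1 else stats::pf(Fstat, 1, jk$df, lower.tail = FALSE)
  structure(list(estimate_a = est_a, estimate_b = est_b,
                 difference = jk$theta, F = Fstat, df1 = 1, df2 = jk$df,
                 p = p, significant = p < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s %.4f vs %s %.4f: F(1, %d) = %.3f, p = %.4g%s\n",
              x$estimate_a$domain, x$estimate_a$estimate,
              x$estimate_b$domain, x$estimate_b$estimate,
              x$df2, x$F, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Group-difference table of prevalence and coverage
#'
#' Reproduces the layout of the classic sex- and residence-difference
#' summary: for the chosen indicator, the weighted estimate per group with
#' sample sizes, plus the design-based F-test for the difference.
#'
#' @param records Record table with replicate weights.
#' @param indicator `"hiv"` (prevalence among all records) or
#'   `"art_on_hiv"` (ART coverage among people with HIV).
#' @param by `"sex"` or `"residence"`.
#' @return A one-row data.frame: group estimates, n, F, p, significance.
#' @export
estimate_contrast <- function(records, indicator = c("hiv", "art_on_hiv"),
                              by = c("sex", "residence")) {
  indicator <- match.arg(indicator)
  by <- match.arg(by)
  base <- if (indicator == "hiv") rep(TRUE, nrow(records)) else records$hiv_positive
  y <- if (indicator == "hiv") records$hiv_positive else records$on_art
  split_var <- if (by == "sex") records$sex else records$stratum
  lv <- if (by == "sex") c("M", "F") else c("rural", "urban")
  cmp <- design_f_test(records, y,
                       base & split_var == lv[1], base & split_var == lv[2],
                       labels = lv)
  data.frame(indicator = indicator, by = by,
             group_1 = lv[1], estimate_1 = cmp$estimate_a$estimate,
             n_1 = cmp$estimate_a$n,
             group_2 = lv[2], estimate_2 = cmp$estimate_b$estimate,
             n_2 = cmp$estimate_b$n,
             F = cmp$F, p = cmp$p, significant = cmp$significant,
             stringsAsFactors = FALSE)
}
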