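# Travel-time stage: category tables, anchors, logistic CDF fits,
# bootstrap bands, odds-ratio model.

test_that("category tables are weighted with NA excluded from the denominator", {
  rec <- art_records(1, c(LT1H = 1, H1TO2 = 1, GT2H = 1))
  tab <- tabulate_categories(rec)
  expect_equal(c(tab$p_lt1, tab$p_1to2, tab$p_gt2), rep(1 / 3, 3),
               tolerance = 1e-12)
  rec_w <- art_records(1, c(LT1H = 1, H1TO2 = 1, GT2H = 1))
  rec_w$design_weight <- c(2, 1, 1)
  tab_w <- tabulate_categories(rec_w)
  expect_equal(c(tab_w$p_lt1, tab_w$p_1to2, tab_w$p_gt2), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)
  expect_equal(tab_w$p_lt1 + tab_w$p_1to2 + tab_w$p_gt2, 1, tolerance = 1e-9)
  # all answers missing -> empty denominator
  rec_na <- rec
  rec_na$traveltime_category <- NA_character_
  expect_error(tabulate_categories(rec_na), "tabulation error")
})

test_that("anchors follow the 1 h / 2 h / endpoint construction", {
  # printed national proportions: 37.4% at one hour or more, 10.5% beyond
  # two hours -> cumulative 0.626 and 0.895, endpoint 4 h
  tab <- category_table(p_lt1 = 0.626, p_1to2 = 0.269, p_gt2 = 0.105)
  a <- build_anchors(tab, "national")
  expect_equal(a$t, c(1, 2, 4))
  expect_equal(a$p, c(0.626, 0.895, 1), tolerance = 1e-12)
  expect_equal(build_anchors(tab, "urban")$t[3], 3.5)
  expect_equal(build_anchors(tab, "rural")$t[3], 4.0)
})

test_that("the two-point solve is exact and has the symmetry properties", {
  fit <- two_point_logistic_solve(1, 0.626, 2, 0.895)
  expect_equal(predict(fit, 1), 0.626, tolerance = 1e-6)
  expect_equal(predict(fit, 2), 0.895, tolerance = 1e-6)
  # algebraic solution recomputed independently
  s_hand <- 1 / (qlogis(0.895) - qlogis(0.626))
  expect_equal(fit$s, s_hand, tolerance = 1e-12)
  expect_equal(fit$mu, 1 - s_hand * qlogis(0.626), tolerance = 1e-12)
  # median anchor pins mu
  expect_equal(two_point_logistic_solve(1.7, 0.5, 3, 0.9)$mu, 1.7,
               tolerance = 1e-12)
  # symmetric proportions centre mu between the anchors
  expect_equal(two_point_logistic_solve(1, 0.3, 3, 0.7)$mu, 2,
               tolerance = 1e-12)
  expect_error(two_point_logistic_solve(2, 0.6, 1, 0.9), "domain error")
  expect_error(two_point_logistic_solve(1, 0.9, 2, 0.6), "domain error")
})

test_that("the least-squares fit interpolates two anchors and recovers a generating curve", {
  a2 <- data.frame(t = c(1, 2), p = c(0.626, 0.895), w = 1)
  fit2 <- fit_logistic_cdf(a2)
  solve2 <- two_point_logistic_solve(1, 0.626, 2, 0.895)
  expect_equal(fit2$mu, solve2$mu, tolerance = 1e-10)
  expect_equal(fit2$s, solve2$s, tolerance = 1e-10)
  # anchors generated from (mu = 1, s = 0.7) at t = 1, 2, 4
  gen <- plogis((c(1, 2, 4) - 1) / 0.7)
  fit3 <- fit_logistic_cdf(data.frame(t = c(1, 2, 4), p = gen, w = 1))
  expect_lt(fit3$sse, 1e-12)
  expect_equal(fit3$mu, 1, tolerance = 1e-5)
  expect_equal(fit3$s, 0.7, tolerance = 1e-5)
})

test_that("a non-interpolable fit has positive sse and a stationary optimum", {
  anchors <- data.frame(t = c(1, 2, 4), p = c(0.4, 0.85, 0.95), w = 1)
  fit <- fit_logistic_cdf(anchors)
  expect_gt(fit$sse, 0)
  # numeric gradient of the objective at the optimum
  obj <- function(mu, s)
    sum((plogis((anchors$t - mu) / s) - anchors$p)^2)
  eps <- 1e-6
  g_mu <- (obj(fit$mu + eps, fit$s) - obj(fit$mu - eps, fit$s)) / (2 * eps)
  g_s <- (obj(fit$mu, fit$s + eps) - obj(fit$mu, fit$s - eps)) / (2 * eps)
  expect_lt(abs(g_mu), 1e-6)
  expect_lt(abs(g_s), 1e-6)
  # fitted curve properties: monotone, F(mu) = 0.5
  expect_equal(predict(fit, fit$mu), 0.5, tolerance = 1e-12)
  grid <- predict(fit, seq(0, 6, 0.1))
  expect_true(all(diff(grid) > 0))
})

test_that("a degenerate tail (no category beyond two hours) still fits", {
  tab <- category_table(p_lt1 = 0.7, p_1to2 = 0.3, p_gt2 = 0)
  fit <- fit_logistic_cdf(build_anchors(tab, "rural"))
  expect_true(is.finite(fit$mu) && fit$s > 0)
})

test_that("identical PSUs give a zero-width bootstrap band", {
  rec <- art_records(2, c(LT1H = 10, H1TO2 = 6, GT2H = 4))
  band <- bootstrap_band(rec, B = 20, seed = 1)
  expect_true(all(band$upper - band$lower < 1e-12))
  expect_true(all(band$lower >= 0 & band$upper <= 1))
})

test_that("the band contains the point-estimate curve", {
  set.seed(5)
  rec <- do.call(rbind, lapply(1:30, function(i) {
    k <- as.vector(rmultinom(1, 20, c(0.45, 0.35, 0.2)))
    art_records(1, c(LT1H = k[1], H1TO2 = k[2], GT2H = k[3]))
  }))
  rec$ea_id <- rep(sprintf("EA%03d", 1:30), each = 20)
  band <- bootstrap_band(rec, B = 200, seed = 9)
  expect_true(all(band$fit >= band$lower - 1e-9 & band$fit <= band$upper + 1e-9))
  expect_true(all(diff(band$fit) >= 0))
})

test_that("band width shrinks roughly as one over the square root of PSUs", {
  make_rec <- function(n_ea, seed) {
    set.seed(seed)
    rec <- do.call(rbind, lapply(seq_len(n_ea), function(i) {
      k <- as.vector(rmultinom(1, 20, c(0.45, 0.35, 0.2)))
      art_records(1, c(LT1H = k[1], H1TO2 = k[2], GT2H = k[3]))
    }))
    rec$ea_id <- rep(sprintf("EA%03d", seq_len(n_ea)), each = 20)
    rec
  }
  width <- function(rec) {
    b <- bootstrap_band(rec, B = 200, seed = 13)
    median(b$upper - b$lower)
  }
  ratio <- width(make_rec(50, 101)) / width(make_rec(200, 102))
  expect_gt(ratio, 2 / 1.3)
  expect_lt(ratio, 2 * 1.3)
})

test_that("the one-covariate logit reproduces the 2x2 odds ratio", {
  rec <- rbind(art_records(1, c(H1TO2 = 30, LT1H = 70), stratum = "rural"),
               art_records(1, c(H1TO2 = 10, LT1H = 90), stratum = "urban"))
  rec$ea_id <- rep(c("EA001", "EA002"), c(100, 100))
  fit <- fit_travel_logit(rec)
  or_hand <- (30 * 90) / (70 * 10)
  expect_equal(fit$table$aOR[fit$table$term == "rural"], or_hand,
               tolerance = 1e-6)
})

test_that("constant outcomes and separation are refused", {
  rec <- art_records(2, c(LT1H = 20))
  expect_error(fit_travel_logit(rec), "separation")
})

test_that("aOR confidence intervals cover a known rural effect", {
  # records generated under beta_rural = log(3.32); Wald 95% CIs should
  # cover the truth at about the nominal rate
  beta_r <- log(3.32)
  covered <- vapply(1:200, function(r) {
    set.seed(3000 + r)
    n <- 5000
    rural <- rbinom(n, 1, 0.5)
    female <- rbinom(n, 1, 0.5)
    age <- sample(c("15-24", "25-34", "35-44", "45-59"), n, replace = TRUE)
    p <- plogis(-1 + beta_r * rural + 0.3 * female)
    long <- rbinom(n, 1, p) == 1
    rec <- data.frame(
      ea_id = sprintf("EA%03d", rep(1:50, each = 100)),
      stratum = ifelse(rural == 1, "rural", "urban"),
      sex = ifelse(female == 1, "F", "M"), age_group = age,
      hiv_positive = TRUE, on_art = TRUE,
      traveltime_category = ifelse(long, "H1TO2", "LT1H"),
      design_weight = 1, stringsAsFactors = FALSE)
    tab <- fit_travel_logit(rec)$table
    row <- tab[tab$term == "rural", ]
    row$ci_low <= 3.32 && 3.32 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.905)
  expect_lte(mean(covered), 0.99)
})

test_that("the weighted mode runs with cluster-robust errors", {
  sim <- simulate_country(tiny_config(seed = 8, n_ea = 30,
                                      individuals_per_ea = 100))
  fw <- fit_travel_logit(sim$records, weighted = TRUE)
  fu <- fit_travel_logit(sim$records)
  expect_true(all(fw$table$se > 0))
  # same point direction, different uncertainty model
  expect_equal(sign(fw$table$beta[fw$table$term == "rural"]),
               sign(fu$table$beta[fu$table$term == "rural"]))
})
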