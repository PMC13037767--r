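# small clustered binary dataset with a person-level random intercept,
# giving genuine exchangeable within-cluster dependence
random_intercept_data <- function(n_cluster, n_time = 5, beta = c(-1, 0.3),
                                  sd_b = 1, seed = 1) {
  set.seed(seed)
  b <- rnorm(n_cluster, 0, sd_b)
  tibble::tibble(
    participant_id = rep(sprintf("c%03d", seq_len(n_cluster)), each = n_time),
    night_index = rep(seq_len(n_time), n_cluster),
    x = rnorm(n_cluster * n_time)
  ) |>
    dplyr::mutate(missing = rbinom(
      dplyr::n(), 1,
      plogis(beta[1] + beta[2] * night_index + rep(b, each = n_time))))
}

test_that("GEE with independence working structure reduces to ordinary logistic ML", {
  set.seed(2)
  n <- 350
  d <- tibble::tibble(participant_id = sprintf("i%03d", 1:n),
                      night_index = 1L, x1 = rnorm(n),
                      x2 = rbinom(n, 1, 0.4))
  d$missing <- rbinom(n, 1, plogis(-0.8 + 0.9 * d$x1 + 0.5 * d$x2))
  fit <- fit_gee(d, c("x1", "x2"), corstr = "independence")
  ml <- glm(missing ~ x1 + x2, binomial, d)
  expect_equal(unname(fit$beta), unname(coef(ml)), tolerance = 1e-6)
  # exchangeable working structure changes nothing with single-night clusters
  fit2 <- fit_gee(d, c("x1", "x2"), corstr = "exchangeable")
  expect_equal(unname(fit2$beta), unname(coef(ml)), tolerance = 1e-6)
})

test_that("robust covariance matches the HC0 sandwich on independent clusters", {
  skip_if_not_installed("sandwich")
  set.seed(3)
  n <- 300
  d <- tibble::tibble(participant_id = sprintf("i%03d", 1:n),
                      night_index = 1L, x = rnorm(n))
  d$missing <- rbinom(n, 1, plogis(-0.4 + d$x))
  fit <- fit_gee(d, "x", corstr = "independence")
  ml <- glm(missing ~ x, binomial, d, control = list(epsilon = 1e-12))
  expect_equal(unname(fit$vcov),
               unname(sandwich::vcovHC(ml, type = "HC0")),
               tolerance = 1e-6)
})

test_that("exchangeable alpha estimates genuine within-cluster dependence", {
  d <- random_intercept_data(400, sd_b = 1.2, seed = 6)
  fit <- fit_gee(d, "night_index", corstr = "exchangeable")
  expect_gt(fit$alpha, 0.05)
  expect_lt(fit$alpha, 1)
  indep <- random_intercept_data(400, sd_b = 0, seed = 6)
  fit0 <- fit_gee(indep, "night_index", corstr = "exchangeable")
  expect_lt(abs(fit0$alpha), 0.05)
})

test_that("odds ratios and CIs are exp-transformed coefficients", {
  d <- random_intercept_data(150, seed = 8)
  fit <- fit_gee(d, "night_index")
  co <- tidy(fit)
  expect_equal(co$odds.ratio, exp(co$estimate))
  expect_equal(co$or.conf.low, exp(co$estimate - 1.96 * co$std.error))
  expect_equal(co$or.conf.high, exp(co$estimate + 1.96 * co$std.error))
  expect_true(all(c("qic", "alpha", "corstr") %in% names(glance(fit))))
})

test_that("singular designs are rejected naming the collinear term", {
  d <- random_intercept_data(50, seed = 9)
  d$dup <- d$night_index * 2
  expect_error(fit_gee(d, c("night_index", "dup")), "collinear.*dup")
})

test_that("QIC-based selection returns the requested single candidate and a full table", {
  d <- random_intercept_data(80, seed = 10)
  one <- select_corstr(d, "night_index", candidates = "ar1")
  expect_equal(one$corstr, "ar1")
  expect_equal(nrow(one$qic_table), 1)
  all4 <- select_corstr(d, "night_index")
  expect_equal(nrow(all4$qic_table), 4)
  expect_true(all4$corstr %in% all4$qic_table$corstr)
  expect_equal(all4$qic_table$qic[all4$qic_table$corstr == all4$corstr],
               min(all4$qic_table$qic))
})

test_that("QIC prefers dependence-aware structures under exchangeable truth", {
  wins <- vapply(1:10, function(s) {
    d <- random_intercept_data(150, sd_b = 1.5, seed = 40 + s)
    sel <- select_corstr(d, "night_index",
                         candidates = c("independence", "exchangeable",
                                        "unstructured"))
    sel$corstr %in% c("exchangeable", "unstructured")
  }, logical(1))
  expect_gte(mean(wins), 0.6)

  spreads <- vapply(1:10, function(s) {
    d <- random_intercept_data(150, sd_b = 0, seed = 60 + s)
    diff(range(select_corstr(d, "night_index")$qic_table$qic))
  }, numeric(1))
  expect_gte(mean(spreads < 2), 0.6)
})

test_that("forward selection keeps significant terms and drops noise", {
  # single strongly significant candidate
  d <- random_intercept_data(200, beta = c(-1, 0.5), seed = 12)
  fit <- forward_select(d, "night_index")
  expect_equal(fit$terms, "night_index")
  steps <- attr(fit, "steps")
  expect_equal(nrow(steps), 1)

  # pure noise predictors: intercept-only in most replicates
  keeps <- vapply(1:8, function(s) {
    set.seed(500 + s)
    d <- random_intercept_data(120, beta = c(-0.8, 0), seed = 500 + s)
    d$z1 <- rnorm(nrow(d)); d$z2 <- rnorm(nrow(d))
    fit <- forward_select(d, c("night_index", "z1", "z2"))
    length(fit$terms)
  }, numeric(1))
  expect_gte(mean(keeps == 0), 0.6)
})

test_that("forward selection recovers night and employment on MAR data with hr uncoupled", {
  hits <- vapply(1:10, function(s) {
    cfg <- generator_config(seed = 700 + s, hr_prob_missing = 0.95)
    ds <- generate_sleep_data(cfg)
    fit <- forward_select(ds, c("night_index", "hr_present", "employed",
                                "married", "education_level",
                                "household_size"))
    setequal(fit$terms, c("night_index", "employed"))
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("predictions and confusion matrix align with fitted probabilities", {
  d <- random_intercept_data(100, seed = 15)
  fit <- fit_gee(d, "night_index")
  expect_equal(nrow(fit$predictions), nrow(d))
  expect_equal(fit$predictions$pred, as.integer(fit$predictions$prob >= 0.5))
  cm <- fit$confusion
  expect_equal(cm$tn + cm$fp + cm$fn + cm$tp, nrow(d))
  expect_equal(predict(fit, d), fit$predictions$prob, tolerance = 1e-12)
})
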