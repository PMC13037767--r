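test_that("EM on complete data returns sample mean and ML covariance", {
  set.seed(1)
  y <- matrix(rnorm(60), 20, 3)
  f <- em_mvn(y)
  expect_equal(f$mu, colMeans(y), ignore_attr = TRUE)
  expect_equal(f$sigma, cov(y) * (20 - 1) / 20, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("EM matches direct observed-data likelihood maximization (monotone bivariate)", {
  skip_if_not_installed("mvtnorm")
  set.seed(4)
  y <- cbind(rnorm(50, 1, 1.4), NA)
  y[, 2] <- 0.7 * y[, 1] + rnorm(50, 0.5, 0.8)
  y[1:20, 2] <- NA
  f <- em_mvn(y, tol = 1e-12)
  nll <- function(par) {
    mu <- par[1:2]
    ch <- matrix(c(exp(par[3]), par[4], 0, exp(par[5])), 2, 2)
    s <- ch %*% t(ch)
    -sum(vapply(seq_len(nrow(y)), function(i) {
      o <- !is.na(y[i, ])
      mvtnorm::dmvnorm(y[i, o], mu[o], s[o, o, drop = FALSE], log = TRUE)
    }, numeric(1)))
  }
  opt <- optim(c(0, 0, 0, 0, 0), nll, method = "BFGS",
               control = list(maxit = 3000, reltol = 1e-14))
  ch <- matrix(c(exp(opt$par[3]), opt$par[4], 0, exp(opt$par[5])), 2, 2)
  expect_equal(unname(f$mu), opt$par[1:2], tolerance = 1e-4)
  expect_equal(unname(f$sigma), ch %*% t(ch), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("observed-data log-likelihood is non-decreasing across EM iterations", {
  for (s in 1:20) {
    y <- mvn_missing(n = 30, p = 4, miss_prob = 0.25, seed = s)
    f <- em_mvn(y, tol = 1e-8)
    expect_true(all(diff(f$loglik) > -1e-7),
                info = paste("seed", s))
  }
})

test_that("a never-observed variable is an error; complete data degenerate", {
  y <- matrix(rnorm(20), 10, 2)
  y[, 2] <- NA
  expect_error(em_mvn(y), "never observed")

  complete <- matrix(rnorm(30), 10, 3)
  expect_warning(res <- little_test(complete), "df = 0")
  expect_equal(res$d2, 0, tolerance = 1e-20)
  expect_equal(res$df, 0L)
  expect_true(is.na(res$p_value))
})

test_that("d2 matches the independent quadratic-form oracle on a small constructed table", {
  set.seed(9)
  y <- matrix(rnorm(60, mean = rep(c(0, 1, 2), each = 20)), 20, 3)
  y[1:8, 3] <- NA  # exactly two patterns
  res <- little_test(y)
  expect_equal(res$n_patterns, 2)
  expect_equal(res$df, (3 + 2) - 3)
  expect_equal(res$d2, little_d2_oracle(y, res$mu, res$sigma),
               tolerance = 1e-10)
  expect_gte(res$d2, 0)
  expect_equal(res$p_value, pchisq(res$d2, res$df, lower.tail = FALSE))
})

test_that("d2 is invariant to row order and to affine rescaling of variables", {
  y <- mvn_missing(n = 60, p = 4, miss_prob = 0.3, seed = 12)
  base <- little_test(y)
  perm <- little_test(y[sample(nrow(y)), ])
  expect_equal(perm$d2, base$d2, tolerance = 1e-8)
  scaled <- sweep(y, 2, c(10, 0.02, 5, 100), `*`)
  scaled <- sweep(scaled, 2, c(-3, 7, 0, 12), `+`)
  expect_equal(little_test(scaled)$d2, base$d2, tolerance = 1e-6)
})

test_that("all-missing rows are skipped with their count reported", {
  y <- mvn_missing(n = 50, p = 3, miss_prob = 0.2, seed = 3)
  y2 <- rbind(y, matrix(NA_real_, 4, 3))
  a <- little_test(y)
  b <- little_test(y2)
  expect_equal(b$n_all_missing, 4)
  expect_equal(b$n_patterns, a$n_patterns + 1)
  expect_equal(b$d2, a$d2, tolerance = 1e-8)
  expect_equal(b$df, a$df)
})

test_that("MCAR deletion keeps the test near its nominal level; strong MAR is rejected", {
  # moderate Monte-Carlo check (the full calibration study lives in the
  # acceptance suite)
  ps <- vapply(1:40, function(s) {
    y <- mvn_missing(n = 150, p = 5, miss_prob = 0.3, seed = 100 + s)
    suppressWarnings(little_test(y))$p_value
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)

  rej <- vapply(1:12, function(s) {
    cfg <- generator_config(
      n_participants = 299L, seed = 300 + s,
      mar_coefficients = c(intercept = -1.8546, night = 0.2554,
                           employed = 1.6))
    ds <- generate_sleep_data(cfg)
    w <- to_wide(ds)
    sc <- grep("_s_n", names(w), value = TRUE)
    w[sc] <- lapply(w[sc], log1p)
    suppressWarnings(little_test(w[-1]))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.75)
})

test_that("tidy and glance summarise the result", {
  y <- mvn_missing(n = 60, p = 3, miss_prob = 0.25, seed = 5)
  res <- little_test(y)
  g <- glance(res)
  expect_equal(g$statistic, res$d2)
  expect_equal(g$df, res$df)
  expect_equal(tidy(res), g)
})
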