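#' EM estimation of a multivariate-normal mean and covariance with missing data
#'
#' Maximum-likelihood estimates of the mean vector and covariance matrix of a
#' multivariate normal from an incomplete data matrix, assuming ignorable
#' missingness. Rows are grouped by missingness pattern; the E-step fills in
#' conditional means of the missing block given the observed block (adding the
#' conditional covariance to the cross-product accumulator) and the M-step
#' recomputes the ML mean and covariance (divisor `n`). The observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param wide A data frame or matrix of numeric variables; `NA` marks missing
#'   cells. Non-numeric columns (e.g. a participant identifier) are dropped
#'   with a message.
#' @param tol Convergence tolerance on the maximum absolute change in any
#'   parameter (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500); non-convergence is
#'   flagged on the result, not raised.
#' @param ridge Relative ridge added to a pattern's observed-block covariance
#'   when it is numerically singular (default 1e-8, scaled by `trace/p`).
#' @return A list with `mu`, `sigma`, `iterations`, `converged`, and the
#'   `loglik` trace.
#' @export
em_mvn <- function(wide, tol = 1e-6, max_iter = 500L, ridge = 1e-8) {
  y <- as_numeric_matrix(wide)
  n <- nrow(y); p <- ncol(y)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)
  never <- colSums(!is.na(y)) == 0
  if (any(never)) {
    stop("variable(s) never observed: ",
         paste(colnames(y)[never], collapse = ", "), call. = FALSE)
  }

  pat <- pattern_groups(y)

  # start from available-case moments
  mu <- colMeans(y, na.rm = TRUE)
  sigma <- diag(apply(y, 2, function(col) {
    v <- stats::var(col, na.rm = TRUE)
    if (!is.finite(v) || v <= 0) 1 else v
  }), p)
  dimnames(sigma) <- list(colnames(y), colnames(y))

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    ll <- 0
    for (g in pat) {
      o <- g$obs; m <- !g$obs; nj <- nrow(g$y)
      if (!any(o)) { next }  # all-missing rows carry no information
      yo <- g$y[, o, drop = FALSE]
      soo <- safe_spd(sigma[o, o, drop = FALSE], ridge)
      ch <- soo$chol
      ctr <- sweep(yo, 2, mu[o])
      z <- backsolve(ch, t(ctr), transpose = TRUE)
      ll <- ll - nj * sum(log(diag(ch))) - 0.5 * sum(z^2) -
        0.5 * nj * sum(o) * log(2 * pi)
      if (any(m)) {
        # regression of missing block on observed block
        b <- backsolve(ch, backsolve(ch, sigma[o, m, drop = FALSE],
                                     transpose = TRUE))
        em <- matrix(mu[m], nj, sum(m), byrow = TRUE) + ctr %*% b
        cmm <- sigma[m, m, drop = FALSE] -
          crossprod(sigma[o, m, drop = FALSE], b)
        yfull <- matrix(0, nj, p)
        yfull[, o] <- yo
        yfull[, m] <- em
        t1 <- t1 + colSums(yfull)
        t2 <- t2 + crossprod(yfull)
        t2[m, m] <- t2[m, m] + nj * cmm
      } else {
        t1 <- t1 + colSums(yo)
        t2 <- t2 + crossprod(yo)
      }
    }
    n_eff <- sum(vapply(pat, function(g) if (any(g$obs)) nrow(g$y) else 0L,
                        numeric(1)))
    mu_new <- t1 / n_eff
    sigma_new <- t2 / n_eff - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    loglik <- c(loglik, ll)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(mu = mu, sigma = sigma, iterations = iter, converged = converged,
       loglik = loglik)
}

#' Little's test that data are missing completely at random
#'
#' Tests the MCAR null hypothesis for an incomplete multivariate table. The
#' mean and covariance are first estimated by EM ([em_mvn()]); rows are then
#' grouped by missingness pattern and, for each pattern `j` with `n_j` rows
#' and observed-variable mean `ybar_j`, the statistic accumulates
#' `n_j * (ybar_j - mu_obs)' Sigma_obs^{-1} (ybar_j - mu_obs)` over the
#' observed coordinates of that pattern. Under MCAR the statistic is
#' asymptotically chi-square with `sum_j p_j - p` degrees of freedom, where
#' `p_j` is the number of observed variables in pattern `j` and `p` the total
#' number of variables. Rows with every variable missing form a
#' zero-dimensional pattern: they contribute nothing to the statistic or the
#' degrees of freedom and are reported via `n_all_missing`.
#'
#' @inheritParams em_mvn
#' @return A `little_result` list: `d2`, `df`, `p_value`, `n_patterns`,
#'   `n_all_missing`, `em_iterations`, `converged`, `n`, `p`.
#' @export
little_test <- function(wide, tol = 1e-6, max_iter = 500L, ridge = 1e-8) {
  y <- as_numeric_matrix(wide)
  fit <- em_mvn(y, tol = tol, max_iter = max_iter, ridge = ridge)
  pat <- pattern_groups(y)
  p <- ncol(y)
  d2 <- 0
  df <- 0L
  n_empty <- 0L
  for (g in pat) {
    o <- g$obs
    if (!any(o)) { n_empty <- n_empty + nrow(g$y); next }
    nj <- nrow(g$y)
    ybar <- colMeans(g$y[, o, drop = FALSE])
    dev <- ybar - fit$mu[o]
    soo <- safe_spd(fit$sigma[o, o, drop = FALSE], 1e-8)
    z <- backsolve(soo$chol, dev, transpose = TRUE)
    d2 <- d2 + nj * sum(z^2)
    df <- df + sum(o)
  }
  df <- df - p
  n_patterns <- length(pat)
  p_value <- if (df > 0) stats::pchisq(d2, df, lower.tail = FALSE) else {
    warning("only one (complete) missingness pattern after dropping ",
            "all-missing rows: df = 0, p-value undefined", call. = FALSE)
    NA_real_
  }
  structure(list(d2 = d2, df = as.integer(df), p_value = p_value,
                 n_patterns = n_patterns, n_all_missing = n_empty,
                 em_iterations = fit$iterations, converged = fit$converged,
                 n = nrow(y), p = p, mu = fit$mu, sigma = fit$sigma),
            class = "little_result")
}

#' @export
print.little_result <- function(x, ...) {
  cat(sprintf(
    "Little's MCAR test: d2 = %.2f, df = %d, p = %s (%d patterns",
    x$d2, x$df,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    x$n_patterns))
  if (x$n_all_missing > 0) {
    cat(sprintf(", %d all-missing rows", x$n_all_missing))
  }
  cat(")\n")
  if (!x$converged) cat("  warning: EM did not converge\n")
  invisible(x)
}

#' @method glance little_result
#' @export
glance.little_result <- function(x, ...) {
  tibble::tibble(statistic = x$d2, df = x$df, p.value = x$p_value,
                 n.patterns = x$n_patterns, n.all.missing = x$n_all_missing,
                 em.iterations = x$em_iterations, converged = x$converged,
                 nobs = x$n)
}

#' @method tidy little_result
#' @export
tidy.little_result <- function(x, ...) glance.little_result(x, ...)

# ---- internals --------------------------------------------------------------

as_numeric_matrix <- function(wide) {
  if (is.matrix(wide)) {
    storage.mode(wide) <- "double"
    if (is.null(colnames(wide))) {
      colnames(wide) <- paste0("V", seq_len(ncol(wide)))
    }
    return(wide)
  }
  d <- tibble::as_tibble(wide)
  num <- vapply(d, is.numeric, logical(1))
  if (any(!num)) {
    message("dropping non-numeric column(s): ",
            paste(names(d)[!num], collapse = ", "))
    d <- d[num]
  }
  as.matrix(d)
}

# split rows of y into missingness-pattern groups
pattern_groups <- function(y) {
  obs <- !is.na(y)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  idx <- split(seq_len(nrow(y)), key)
  lapply(idx, function(i) {
    list(obs = obs[i[1], ], y = y[i, , drop = FALSE])
  })
}

# Cholesky with an escalating relative ridge fallback for near-singular blocks
safe_spd <- function(s, ridge) {
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch)) {
    scale <- max(sum(diag(s)) / ncol(s), 1e-12)
    mult <- ridge
    while (is.null(ch) && mult <= 1) {
      ch <- tryCatch(chol(s + diag(mult * scale, ncol(s))),
                     error = function(e) NULL)
      mult <- mult * 100
    }
    if (is.null(ch)) {
      stop("covariance block is not positive definite", call. = FALSE)
    }
    warning("near-singular covariance block; ridge fallback used",
            call. = FALSE)
  }
  list(chol = ch)
}
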