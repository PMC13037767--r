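GEE_STRUCTURES <- c("independence", "exchangeable", "ar1", "unstructured")

#' GEE logistic regression for night-level missingness
#'
#' Fits a marginal logistic model for the binary missingness indicator by
#' generalized estimating equations with participants as clusters and nights
#' ordered within cluster. Coefficients are obtained by iterated weighted
#' scoring with working covariance `phi * A^{1/2} R(alpha) A^{1/2}`; the
#' working-correlation parameter(s) `alpha` and the dispersion `phi` are
#' updated at each step by the usual moment estimators from Pearson
#' residuals. Standard errors are robust (sandwich), so inference is valid
#' even when the working structure is wrong. The quasi-likelihood under the
#' independence model information criterion (QIC) is reported for comparing
#' working structures, and a 0.5-threshold confusion matrix (positive class =
#' night missing) summarises in-sample classification.
#'
#' @param data A `sleep_data` tibble (or any data frame with the outcome,
#'   cluster id and predictor columns).
#' @param terms Character vector of predictor column names, in order.
#' @param corstr Working correlation structure: `"independence"`,
#'   `"exchangeable"`, `"ar1"` or `"unstructured"`.
#' @param outcome Binary outcome column (default `"missing"`, coded 1 for a
#'   missing night).
#' @param id Cluster identifier column (default `"participant_id"`).
#' @param time Within-cluster ordering column (default `"night_index"`).
#' @param tol,max_iter Scoring convergence tolerance and iteration cap;
#'   non-convergence is flagged on the result, not raised.
#' @return A `gee_fit` object; see [tidy.gee_fit()] and [glance.gee_fit()].
#' @export
fit_gee <- function(data, terms, corstr = "exchangeable",
                    outcome = "missing", id = "participant_id",
                    time = "night_index", tol = 1e-8, max_iter = 50L) {
  corstr <- match.arg(corstr, GEE_STRUCTURES)
  d <- tibble::as_tibble(data)
  needed <- c(outcome, id, time, terms)
  absent <- setdiff(needed, names(d))
  if (length(absent) > 0) {
    stop("column(s) not in data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  d <- d[order(d[[id]], d[[time]]), ]
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  x <- cbind(`(Intercept)` = 1,
             as.matrix(dplyr::mutate(d[terms],
                                     dplyr::across(dplyr::everything(),
                                                   as.numeric))))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    drop_cols <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("singular design matrix; collinear term(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  cl <- split(seq_len(nrow(d)), d[[id]])
  tvals <- match(d[[time]], sort(unique(d[[time]])))
  t_max <- max(tvals)
  p <- ncol(x)
  n_obs <- length(y)

  # independence logistic start
  beta <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial())$coefficients)

  alpha <- 0
  r_un <- diag(t_max)
  phi <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    e <- (y - mu) / sqrt(w)
    phi <- sum(e^2) / (n_obs - p)
    est <- estimate_alpha(e, cl, tvals, corstr, phi, p, t_max)
    alpha <- est$alpha; r_un <- est$r_un

    bmat <- matrix(0, p, p)
    u <- numeric(p)
    for (ix in cl) {
      ni <- length(ix)
      rinv <- corr_inverse(corstr, ni, alpha, r_un, tvals[ix])
      xa <- x[ix, , drop = FALSE] * sqrt(w[ix])   # A^{1/2} X
      bmat <- bmat + crossprod(xa, rinv %*% xa)
      u <- u + drop(crossprod(xa, rinv %*% e[ix]))
    }
    delta <- drop(solve(bmat, u))
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("GEE scoring did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }

  # final quantities at beta-hat
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  e <- (y - mu) / sqrt(w)
  phi <- sum(e^2) / (n_obs - p)
  est <- estimate_alpha(e, cl, tvals, corstr, phi, p, t_max)
  alpha <- est$alpha; r_un <- est$r_un

  bmat <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (ix in cl) {
    rinv <- corr_inverse(corstr, length(ix), alpha, r_un, tvals[ix])
    xa <- x[ix, , drop = FALSE] * sqrt(w[ix])
    bmat <- bmat + crossprod(xa, rinv %*% xa)
    gi <- crossprod(xa, rinv %*% e[ix])
    meat <- meat + tcrossprod(gi)
  }
  binv <- solve(bmat)
  vcov_robust <- binv %*% meat %*% binv
  dimnames(vcov_robust) <- list(colnames(x), colnames(x))

  # QIC under the independence quasi-likelihood (binomial, phi = 1)
  quasi <- sum(y * log(pmax(mu, 1e-12)) +
                 (1 - y) * log(pmax(1 - mu, 1e-12)))
  omega_i <- crossprod(x * sqrt(w))          # independence model information
  cic <- sum(diag(omega_i %*% vcov_robust))
  qic <- -2 * quasi + 2 * cic

  se <- sqrt(diag(vcov_robust))
  zstat <- beta / se
  pval <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  coefs <- tibble::tibble(
    term = colnames(x),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(zstat),
    p.value = unname(pval),
    odds.ratio = exp(unname(beta)),
    or.conf.low = exp(unname(beta - 1.96 * se)),
    or.conf.high = exp(unname(beta + 1.96 * se)))

  pred_class <- as.integer(mu >= 0.5)
  predictions <- tibble::tibble(
    !!id := d[[id]], !!time := d[[time]],
    truth = as.integer(y), prob = mu, pred = pred_class)

  structure(list(
    coefficients = coefs, beta = beta, vcov = vcov_robust,
    alpha = alpha, phi = phi, corstr = corstr, qic = qic, cic = cic,
    quasi_lik = quasi, converged = converged, iterations = it,
    n_clusters = length(cl), n_obs = n_obs, terms = terms,
    outcome = outcome, id = id, time = time,
    predictions = predictions,
    confusion = confusion_matrix(predictions$truth, predictions$pred)
  ), class = "gee_fit")
}

# moment estimators of the working-correlation parameter(s)
estimate_alpha <- function(e, cl, tvals, corstr, phi, p, t_max) {
  alpha <- 0
  r_un <- diag(t_max)
  if (corstr == "exchangeable") {
    num <- 0; n_pairs <- 0
    for (ix in cl) {
      ei <- e[ix]
      num <- num + (sum(ei)^2 - sum(ei^2)) / 2
      n_pairs <- n_pairs + length(ix) * (length(ix) - 1) / 2
    }
    alpha <- num / (phi * (n_pairs - p))
  } else if (corstr == "ar1") {
    num <- 0; n_pairs <- 0
    for (ix in cl) {
      ei <- e[ix]
      if (length(ei) > 1) {
        num <- num + sum(ei[-length(ei)] * ei[-1])
        n_pairs <- n_pairs + length(ei) - 1
      }
    }
    alpha <- num / (phi * (n_pairs - p))
    alpha <- max(min(alpha, 0.99), -0.99)
  } else if (corstr == "unstructured") {
    num <- matrix(0, t_max, t_max)
    cnt <- matrix(0, t_max, t_max)
    for (ix in cl) {
      tt <- tvals[ix]
      num[tt, tt] <- num[tt, tt] + tcrossprod(e[ix])
      cnt[tt, tt] <- cnt[tt, tt] + 1
    }
    r_un <- num / (phi * pmax(cnt - p, 1))
    diag(r_un) <- 1
    r_un <- (r_un + t(r_un)) / 2
    # shrink toward identity until positive definite
    shrink <- 1
    while (inherits(tryCatch(chol(r_un), error = function(e) e), "error") &&
           shrink > 0.01) {
      shrink <- shrink * 0.9
      r_un <- shrink * r_un + (1 - shrink) * diag(t_max)
      diag(r_un) <- 1
    }
  }
  list(alpha = alpha, r_un = r_un)
}

# inverse working correlation for one cluster
corr_inverse <- function(corstr, ni, alpha, r_un, tt) {
  if (corstr == "independence" || ni == 1) return(diag(ni))
  r <- switch(corstr,
    exchangeable = {
      a <- max(min(alpha, 0.99), -1 / (ni - 1) + 1e-6)
      (1 - a) * diag(ni) + a
    },
    ar1 = alpha^abs(outer(tt, tt, "-")),
    unstructured = r_un[tt, tt, drop = FALSE])
  solve(r)
}

#' Predicted missingness probabilities from a GEE fit
#'
#' @param object A `gee_fit`.
#' @param newdata Data frame with the model's predictor columns; defaults to
#'   the training predictions.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.gee_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions$prob)
  x <- cbind(1, as.matrix(dplyr::mutate(
    tibble::as_tibble(newdata)[object$terms],
    dplyr::across(dplyr::everything(), as.numeric))))
  plogis(drop(x %*% object$beta))
}

#' Tidy a GEE fit
#'
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @return One row per model term: estimate, robust `std.error`, Wald
#'   `statistic` and `p.value`, odds ratio with 95% CI.
#' @method tidy gee_fit
#' @export
tidy.gee_fit <- function(x, ...) x$coefficients

#' One-row summary of a GEE fit
#'
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @return A one-row tibble: QIC, working correlation, `alpha`, dispersion,
#'   cluster/observation counts, convergence flag.
#' @method glance gee_fit
#' @export
glance.gee_fit <- function(x, ...) {
  tibble::tibble(qic = x$qic, cic = x$cic, corstr = x$corstr,
                 alpha = x$alpha, phi = x$phi,
                 n.clusters = x$n_clusters, nobs = x$n_obs,
                 converged = x$converged)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE logistic fit (%s working correlation, %d clusters, %d obs)\n",
              x$corstr, x$n_clusters, x$n_obs))
  cat(sprintf("  QIC %.1f | alpha %.3f | phi %.3f%s\n", x$qic, x$alpha, x$phi,
              if (x$converged) "" else " | NOT CONVERGED"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Choose a working correlation structure by QIC
#'
#' Fits the model under each candidate working structure and returns the
#' structure attaining minimal QIC together with the full QIC table.
#' Candidate fits that fail are excluded from the comparison with a message.
#'
#' @inheritParams fit_gee
#' @param candidates Structures to compare.
#' @return A list with `corstr` (the winner), `qic_table` and `fits`.
#' @export
select_corstr <- function(data, terms, candidates = GEE_STRUCTURES,
                          outcome = "missing", id = "participant_id",
                          time = "night_index") {
  candidates <- match.arg(candidates, GEE_STRUCTURES, several.ok = TRUE)
  fits <- purrr::map(setNames(candidates, candidates), function(cs) {
    tryCatch(fit_gee(data, terms, corstr = cs, outcome = outcome,
                     id = id, time = time),
             error = function(e) {
               message("working structure '", cs, "' failed: ",
                       conditionMessage(e))
               NULL
             })
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no working structure could be fitted", call. = FALSE)
  qic_table <- purrr::map_dfr(fits[ok], glance)
  best <- qic_table$corstr[which.min(qic_table$qic)]
  list(corstr = best, qic_table = qic_table, fits = fits[ok])
}

#' Forward selection of missingness predictors under GEE
#'
#' Enters candidate terms sequentially in the given order, fitting one model
#' per step; after the final step, terms whose robust Wald p-value is at or
#' above `alpha` are dropped and the reduced model refit. The full step trace
#' (terms, estimates, p-values, QIC per step) is attached to the returned fit
#' as the `"steps"` attribute.
#'
#' @inheritParams fit_gee
#' @param candidate_terms Ordered character vector of candidate predictors.
#' @param alpha Retention significance level (default 0.05).
#' @return The final `gee_fit`, with attributes `"steps"` (trace tibble) and
#'   `"selected_terms"`.
#' @export
forward_select <- function(data, candidate_terms, alpha = 0.05,
                           corstr = "exchangeable", outcome = "missing",
                           id = "participant_id", time = "night_index") {
  stopifnot(length(candidate_terms) > 0)
  steps <- purrr::map_dfr(seq_along(candidate_terms), function(s) {
    fit <- fit_gee(data, candidate_terms[seq_len(s)], corstr = corstr,
                   outcome = outcome, id = id, time = time)
    added <- candidate_terms[s]
    row <- fit$coefficients[fit$coefficients$term == added, ]
    tibble::tibble(step = s, terms = paste(candidate_terms[seq_len(s)],
                                           collapse = " + "),
                   added = added, estimate = row$estimate,
                   p.value = row$p.value, qic = fit$qic)
  })
  full <- fit_gee(data, candidate_terms, corstr = corstr, outcome = outcome,
                  id = id, time = time)
  keep <- full$coefficients |>
    dplyr::filter(.data$term != "(Intercept)", .data$p.value < alpha) |>
    dplyr::pull("term")
  final <- if (length(keep) == 0) {
    fit_intercept_only(data, corstr, outcome, id, time)
  } else if (setequal(keep, candidate_terms)) full else {
    fit_gee(data, keep[order(match(keep, candidate_terms))], corstr = corstr,
            outcome = outcome, id = id, time = time)
  }
  attr(final, "steps") <- steps
  attr(final, "selected_terms") <- setdiff(final$terms, character(0))
  final
}

# intercept-only GEE: a dummy constant term would be collinear, so fit the
# marginal rate directly with cluster-robust variance
fit_intercept_only <- function(data, corstr, outcome, id, time) {
  d <- tibble::as_tibble(data)
  y <- as.numeric(d[[outcome]])
  mu <- mean(y)
  beta <- qlogis(mu)
  cl <- split(y - mu, d[[id]])
  w <- mu * (1 - mu)
  # sandwich: B = N w, meat = sum_i (sum_j residual_ij)^2
  se <- sqrt(sum(vapply(cl, function(r) sum(r)^2, numeric(1)))) / (length(y) * w)
  coefs <- tibble::tibble(
    term = "(Intercept)", estimate = beta, std.error = se,
    statistic = beta / se,
    p.value = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
    odds.ratio = exp(beta), or.conf.low = exp(beta - 1.96 * se),
    or.conf.high = exp(beta + 1.96 * se))
  predictions <- tibble::tibble(
    !!id := d[[id]], !!time := d[[time]],
    truth = as.integer(y), prob = mu, pred = as.integer(mu >= 0.5))
  quasi <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  structure(list(
    coefficients = coefs, beta = setNames(beta, "(Intercept)"),
    vcov = matrix(se^2, 1, 1), alpha = 0, phi = 1, corstr = corstr,
    qic = -2 * quasi + 2, cic = 1, quasi_lik = quasi, converged = TRUE,
    iterations = 1L, n_clusters = length(cl), n_obs = length(y),
    terms = character(0), outcome = outcome, id = id, time = time,
    predictions = predictions,
    confusion = confusion_matrix(predictions$truth, predictions$pred)
  ), class = "gee_fit")
}
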