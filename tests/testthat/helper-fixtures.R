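# builders for small in-code fixtures; no files on disk

# one participant-night row with plausible observed stage seconds
night_row <- function(id, night, missing = FALSE, light = 14000,
                      covs = list(household_size = 3, education_level = 2,
                                  employed = 0, married = 1, n_children = 1,
                                  site = "A")) {
  tibble::tibble(
    participant_id = id, night_index = night,
    deep_s = if (missing) NA_real_ else 4500,
    light_s = if (missing) NA_real_ else light,
    rem_s = if (missing) NA_real_ else 5800,
    awake_s = if (missing) NA_real_ else 1200,
    unmeasurable_s = if (missing) NA_real_ else 0,
    hr_present = 1L,
    household_size = covs$household_size,
    education_level = covs$education_level,
    employed = covs$employed, married = covs$married,
    n_children = covs$n_children, site = covs$site)
}

# toy dataset: `missing` is a named list participant -> missing night indices
toy_sleep <- function(ids = c("a", "b", "c"), missing = list()) {
  rows <- purrr::map_dfr(ids, function(id) {
    purrr::map_dfr(1:5, function(n) {
      night_row(id, n, missing = n %in% (missing[[id]] %||% integer(0)))
    })
  })
  as_sleep_data(rows)
}

# cohort fixture encoding the published per-site, per-night missing counts:
# 99 + 100 + 100 participants; night totals 67/79/81/88/140 of 299 (455/1495)
table1_fixture <- function() {
  site_n <- c(Banda = 99L, Bwaise = 100L, Makindye = 100L)
  miss <- rbind(Banda = c(22, 32, 32, 35, 49),
                Bwaise = c(25, 26, 25, 21, 44),
                Makindye = c(20, 21, 24, 32, 47))
  rows <- purrr::map_dfr(names(site_n), function(s) {
    purrr::map_dfr(seq_len(site_n[[s]]), function(i) {
      id <- sprintf("%s%03d", substr(s, 1, 2), i)
      purrr::map_dfr(1:5, function(n) {
        night_row(id, n, missing = i <= miss[s, n],
                  covs = list(household_size = 3, education_level = 2,
                              employed = as.integer(i %% 3 == 0),
                              married = 1L, n_children = 1L, site = s))
      })
    })
  })
  as_sleep_data(rows)
}

# incomplete MVN sample for Little-test checks
mvn_missing <- function(n, p, miss_prob, seed, rho = 0.3) {
  set.seed(seed)
  s <- matrix(rho, p, p); diag(s) <- 1
  y <- matrix(rnorm(n * p), n, p) %*% chol(s)
  y[matrix(runif(n * p) < miss_prob, n, p)] <- NA
  # keep every variable observed somewhere
  for (j in seq_len(p)) if (all(is.na(y[, j]))) y[1, j] <- rnorm(1)
  y
}

# independent recomputation of the pattern quadratic forms from EM output
little_d2_oracle <- function(y, mu, sigma) {
  obs <- !is.na(y)
  key <- apply(obs, 1, paste, collapse = "")
  d2 <- 0
  for (k in unique(key)) {
    rows <- y[key == k, , drop = FALSE]
    o <- obs[which(key == k)[1], ]
    if (!any(o)) next
    ybar <- colMeans(rows[, o, drop = FALSE])
    dev <- ybar - mu[o]
    d2 <- d2 + nrow(rows) *
      drop(t(dev) %*% solve(sigma[o, o, drop = FALSE]) %*% dev)
  }
  d2
}
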