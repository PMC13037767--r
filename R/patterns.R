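#' Enumerate night-level missingness patterns
#'
#' Maps every participant to their binary missingness pattern over the study
#' nights (1 = night missing) and counts participants per distinct pattern,
#' ordered from most to least common; equal counts are ordered
#' lexicographically by the pattern string so the ordering is stable.
#'
#' @param ds A `sleep_data` tibble.
#' @return A `pattern_table` tibble with columns `pattern` (character, e.g.
#'   `"00001"`), `n_missing_nights`, `count` and `proportion`; attributes
#'   `n_participants` and `n_patterns`.
#' @export
enumerate_patterns <- function(ds) {
  k <- attr(ds, "n_nights") %||% max(ds$night_index)
  pat <- tibble::as_tibble(ds) |>
    dplyr::arrange(.data$participant_id, .data$night_index) |>
    dplyr::summarise(pattern = paste(.data$missing, collapse = ""),
                     .by = "participant_id")
  tab <- pat |>
    dplyr::count(.data$pattern, name = "count") |>
    dplyr::mutate(
      n_missing_nights = vapply(
        strsplit(.data$pattern, ""),
        function(x) sum(x == "1"), integer(1)),
      proportion = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pattern) |>
    dplyr::select("pattern", "n_missing_nights", "count", "proportion")
  structure(tab,
            class = c("pattern_table", class(tibble::tibble())),
            n_participants = nrow(pat),
            n_patterns = nrow(tab),
            n_nights = as.integer(k))
}

RATE_GROUPINGS <- c("night_index", "site", "n_children", "household_size",
                    "employed", "married", "education_level", "none")

#' Missingness rate table by a grouping variable
#'
#' Per-level counts of missing nights over total nights, with the percent
#' rounded to an integer as such tables are conventionally printed, plus an
#' overall row. `by = "none"` returns the overall row alone.
#'
#' @param ds A `sleep_data` tibble.
#' @param by One of `"night_index"`, `"site"`, `"n_children"`,
#'   `"household_size"`, `"employed"`, `"married"`, `"education_level"`,
#'   `"none"`.
#' @return A `rate_table` tibble with columns `level`, `n_missing`, `n_total`,
#'   `fraction` and `percent` (integer-rounded).
#' @export
missingness_rates <- function(ds, by = "night_index") {
  if (!by %in% RATE_GROUPINGS) {
    stop("unknown grouping '", by, "'; use one of: ",
         paste(RATE_GROUPINGS, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(ds)
  overall <- tibble::tibble(level = "overall",
                            n_missing = sum(d$missing),
                            n_total = nrow(d))
  tab <- if (by == "none") overall else {
    d |>
      dplyr::summarise(n_missing = sum(.data$missing),
                       n_total = dplyr::n(),
                       .by = dplyr::all_of(by)) |>
      dplyr::arrange(.data[[by]]) |>
      dplyr::mutate(level = as.character(.data[[by]]), .keep = "unused") |>
      dplyr::select("level", "n_missing", "n_total") |>
      dplyr::bind_rows(overall)
  }
  tab <- tab |>
    dplyr::mutate(fraction = .data$n_missing / .data$n_total,
                  percent = round(100 * .data$fraction))
  structure(tab, class = c("rate_table", class(tibble::tibble())),
            grouping = by)
}

#' Plot a missingness-pattern table as an observed/missing grid
#'
#' One row per pattern ordered from most common (top) to least common, one
#' column per night; cell fill encodes observed vs missing, with pattern
#' counts on the right axis.
#'
#' @param object A [enumerate_patterns()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pattern_table
#' @export
autoplot.pattern_table <- function(object, ...) {
  k <- attr(object, "n_nights")
  grid <- tibble::as_tibble(object) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::mutate(cells = strsplit(.data$pattern, "")) |>
    tidyr::unnest_longer("cells", indices_to = "night") |>
    dplyr::mutate(state = ifelse(.data$cells == "1", "missing", "observed"))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$night,
                                     y = stats::reorder(.data$pattern,
                                                        -.data$rank))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$state), colour = "white") +
    ggplot2::scale_fill_manual(values = c(observed = "grey25",
                                          missing = "goldenrod2")) +
    ggplot2::scale_y_discrete(
      labels = setNames(paste0(object$pattern, "  (", object$count, ")"),
                        object$pattern)) +
    ggplot2::labs(x = "night", y = NULL, fill = NULL,
                  title = "Missingness patterns (most common at top)") +
    ggplot2::theme_minimal()
}

#' Plot per-night missingness rates
#'
#' @param ds A `sleep_data` tibble.
#' @param by Grouping variable, as in [missingness_rates()].
#' @return A ggplot object.
#' @export
plot_missingness_rates <- function(ds, by = "night_index") {
  tab <- missingness_rates(ds, by = by) |>
    dplyr::filter(.data$level != "overall")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$level, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = by, y = "% nights missing") +
    ggplot2::theme_minimal()
}
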