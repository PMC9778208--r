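#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Group comparison of window signal between strains
#'
#' Bundles the per-group distribution summaries and the pairwise Welch
#' tests for a set of strains into one fitted-object-style result with
#' [tidy()], [glance()] and [autoplot()] methods.
#'
#' @param windows A multi-strain window-signal tibble (see
#'   [window_signal()]).
#' @param origins An origin set tibble.
#' @param groups Origin groups to compare.
#' @param strains Strains to include; default all present.
#' @return An object of class `group_comparison` with elements `stats`
#'   (five-number summaries per strain and group), `tests` (Welch tests
#'   per group for every strain pair) and `windows`.
#' @export
group_comparison <- function(windows, origins,
                             groups = c("confirmed", "fkh_activated",
                                        "cen_proximal"),
                             strains = NULL) {
  strains <- strains %||% unique(windows$strain)
  windows <- dplyr::filter(windows, .data$strain %in% strains)
  stats <- group_boxplot_stats(windows, origins, groups)
  tests <- tibble::tibble()
  if (length(strains) >= 2) {
    pairs <- utils::combn(strains, 2, simplify = FALSE)
    tests <- dplyr::bind_rows(purrr::map(pairs, function(p) {
      tt <- group_ttests(windows, origins, p[1], p[2], groups)
      tt$strain_a <- p[1]; tt$strain_b <- p[2]
      dplyr::relocate(tt, "strain_a", "strain_b")
    }))
  }
  structure(list(stats = stats, tests = tests, windows = windows,
                 origins = origins, groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of window signal\n")
  cat("Strains:", paste(unique(x$stats$strain), collapse = ", "), "\n")
  cat("Groups:", paste(x$groups, collapse = ", "), "\n\n")
  print(x$stats)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The five-number summary tibble (strain, group, n, min, q1,
#'   median, q3, max).
#' @export
#' @method tidy group_comparison
tidy.group_comparison <- function(x, ...) x$stats

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A tibble with the number of strains, groups, tests and the
#'   smallest raw p-value.
#' @export
#' @method glance group_comparison
glance.group_comparison <- function(x, ...) {
  tibble::tibble(n_strains = length(unique(x$stats$strain)),
                 n_groups = length(x$groups),
                 n_tests = nrow(x$tests),
                 min_p = if (nrow(x$tests)) min(x$tests$p, na.rm = TRUE) else NA_real_)
}

#' Tidy per-group fit coefficients
#'
#' @param x A `scatter_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `group`, `term` (slope/intercept),
#'   `estimate`.
#' @export
#' @method tidy scatter_fit
tidy.scatter_fit <- function(x, ...) {
  df <- tibble::as_tibble(unclass(x))
  tidyr::pivot_longer(df[, c("group", "slope", "intercept")],
                      cols = c("slope", "intercept"),
                      names_to = "term", values_to = "estimate")
}

#' One-row pooled fit summary
#'
#' @param x A `scatter_fit`.
#' @param ... Unused.
#' @return A tibble with the pooled-across-groups OLS fit and Pearson r.
#' @export
#' @method glance scatter_fit
glance.scatter_fit <- function(x, ...) {
  d <- attr(x, "data")
  fit <- stats::lm(y ~ x, data = d)
  tibble::tibble(n = nrow(d), slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = cor(d$x, d$y))
}
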