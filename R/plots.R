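# ggplot2 displays for the main result types.

#' Plot a Kaplan-Meier cumulative incidence curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object (step curve of cumulative incidence over days).
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(tibble(time = 0, cuminc = 0),
                         as_tibble(object)[c("time", "cuminc")])
  ggplot(df, aes(x = time, y = cuminc)) +
    geom_step(linewidth = 0.7) +
    labs(x = "Days from therapy start", y = "Cumulative incidence") +
    coord_cartesian(ylim = c(0, 1)) +
    theme_minimal()
}

#' Plot signal strength for the top events of a result table
#'
#' Point-and-interval display of the empirical-Bayes geometric mean (with
#' its lower bound) for the strongest signals.
#'
#' @param object A `signal_result` tibble.
#' @param n Number of top events (by EBGM) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_result
#' @export
autoplot.signal_result <- function(object, n = 20, ...) {
  df <- as_tibble(object) |>
    dplyr::filter(!is.na(ebgm)) |>
    dplyr::arrange(dplyr::desc(ebgm)) |>
    head(n) |>
    dplyr::mutate(event = factor(event, levels = rev(event)))
  ggplot(df, aes(x = ebgm, y = event)) +
    geom_point() +
    geom_segment(aes(x = ebgm05, xend = ebgm, yend = event)) +
    scale_x_log10() +
    labs(x = "EBGM (point) with EBGM05 (segment)", y = NULL) +
    theme_minimal()
}

#' Histogram of onset durations with bin percentages
#'
#' @param object An `onset_sample`.
#' @param bins Upper bin edges in days (as in [onset_summary()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot onset_sample
#' @export
autoplot.onset_sample <- function(object, bins = c(30, 60, 90, 180, 360), ...) {
  tab <- onset_summary(object, bins = bins)$bins
  tab$bin <- factor(tab$bin, levels = tab$bin)
  ggplot(tab, aes(x = bin, y = n)) +
    geom_col(fill = "grey35") +
    geom_text(aes(label = paste0(pct, "%")), vjust = -0.4, size = 3) +
    labs(x = "Time to onset (days)", y = "Reports") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
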