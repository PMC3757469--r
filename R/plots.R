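#' Plot energy profiles along the reaction coordinate
#'
#' One panel per mutant, energy against interpolation frame, with the ES
#' reference at frame 0. When an analysis table is supplied, panel strips
#' are annotated with the disposition so the automated regularity verdict
#' can be checked visually — the plot recovers the visual-inspection step
#' the filters formalize.
#'
#' @param profiles A profile table (`mutant`, `frame`, `energy`).
#' @param analyses Optional output of [analyze_profiles()].
#' @param ncol Facet columns (default 4).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, analyses = NULL, ncol = 4) {
  data <- tibble::as_tibble(profiles)
  if (!is.null(analyses)) {
    data <- dplyr::left_join(
      data, dplyr::select(analyses, "mutant", "disposition"),
      by = "mutant"
    ) |>
      dplyr::mutate(
        panel = paste0(.data$mutant, "\n[", .data$disposition, "]")
      )
  } else {
    data$panel <- data$mutant
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data$frame, y = .data$energy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, ncol = ncol, scales = "free_y") +
    ggplot2::labs(
      x = "Interpolation frame (0 = ES, last = TI)",
      y = "Energy (kcal/mol)"
    ) +
    ggplot2::theme_bw()
}

#' @describeIn benchmark Scatter plot of barrier against experimental
#'   fold-activity with the cutoff and activity thresholds marked;
#'   misclassified mutants are highlighted.
#' @param object An `activity_benchmark`.
#' @export
autoplot.activity_benchmark <- function(object, ...) {
  data <- tidy(object) |>
    dplyr::mutate(
      outcome = dplyr::case_when(
        .data$experimental_factor == 0L ~ "neutral",
        .data$agree ~ "correct",
        TRUE ~ "incorrect"
      )
    )
  th <- object$thresholds
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$activity, y = .data$barrier, colour = .data$outcome)
  ) +
    ggplot2::geom_hline(yintercept = th$barrier_cutoff, linetype = "dashed") +
    ggplot2::geom_vline(
      xintercept = c(th$degrade_max, th$improve_min),
      linetype = "dotted"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(correct = "#2166ac", incorrect = "#b2182b", neutral = "grey50")
    ) +
    ggplot2::labs(
      x = "Experimental activity (fold wild type, log scale)",
      y = "Computed barrier (kcal/mol)",
      colour = NULL,
      subtitle = sprintf(
        "%d/%d correct at cutoff %.1f kcal/mol",
        object$n_agree, object$n_scored, th$barrier_cutoff
      )
    ) +
    ggplot2::theme_bw()
}

#' @describeIn optimize_cutoff Step plot of agreement count against
#'   candidate cutoff, with the optimal cutoffs marked.
#' @param object A `cutoff_scan`.
#' @export
autoplot.cutoff_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$cutoff, y = .data$n_agree)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = object$scan[object$scan$n_agree == object$max_agreement, ],
      colour = "#b2182b", size = 2
    ) +
    ggplot2::labs(
      x = "Barrier cutoff (kcal/mol)",
      y = "Agreements with experiment"
    ) +
    ggplot2::theme_bw()
}
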