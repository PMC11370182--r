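# ggplot2 figure builders for the two result types.

#' Retention curves for a perturbation grid
#'
#' One line per phenotype (mean retention over replicate seeds, with a
#' min--max ribbon where replicates exist), facetted by data-type target.
#'
#' @param object A `dq_grid` from [run_grid()].
#' @param y `"retention"` (default) or `"fraction_of_cohort"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dq_grid
#' @export
autoplot.dq_grid <- function(object, y = c("retention", "fraction_of_cohort"),
                             ...) {
  y <- match.arg(y)
  summ <- dplyr::summarise(
    dplyr::group_by(object, .data$axis, .data$phenotype,
                    .data$data_type_target, .data$level),
    mid = mean(.data[[y]]), lo = min(.data[[y]]), hi = max(.data[[y]]),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(.data$level, .data$mid,
                                     colour = .data$phenotype,
                                     fill = .data$phenotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~data_type_target) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = switch(unique(object$axis)[1],
                 timeliness = , compound_timeliness = "date shift (days)",
                 inaccuracy = , compound_inaccuracy = "inaccuracy level",
                 "fraction of events dropped"),
      y = if (y == "retention") "identified population retained"
      else "fraction of cohort identified",
      colour = "phenotype", fill = "phenotype",
      title = paste("Phenotype robustness:", unique(object$axis)[1])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dq_grid
#' @export
plot_retention <- function(object, ...) autoplot.dq_grid(object, ...)

#' Bar chart of overlap partition regions
#'
#' @param object A `dq_overlap` from [overlap_partition()].
#' @param min_n Hide regions smaller than this count (default 0: show all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dq_overlap
#' @export
autoplot.dq_overlap <- function(object, min_n = 0, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$n >= min_n)
  d$region <- stats::reorder(d$region, d$n)
  ggplot2::ggplot(d, ggplot2::aes(.data$n, .data$region,
                                  fill = factor(.data$k))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "patients identified by exactly this set",
                  y = NULL, fill = "set size",
                  title = sprintf(
                    "Overlap partition (union %d of %d patients)",
                    attr(object, "union_n"), attr(object, "denominator_n"))) +
    ggplot2::theme_minimal()
}
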