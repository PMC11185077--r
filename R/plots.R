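#' Per-day LR statistic trajectories across replicates
#'
#' Reproduces the layout of the study's day-by-day diagnostic panels: one
#' grey line per replicate, the across-replicate mean in red, and the
#' adequate-model reference (0 for bias, 1 for dispersion/accuracy) in
#' black, faceted by scenario and model.
#'
#' @param day_stats The `day_stats` tibble of an [run_experiment()] result.
#' @param stat Which column to draw (e.g. `"delta_hat"`, `"slope_true"`).
#' @return A ggplot object.
#' @export
plot_lr_days <- function(day_stats,
                         stat = c("delta_hat", "delta_true", "slope_hat",
                                  "slope_true", "acc_hat", "acc_true",
                                  "cov_hat", "cov_true")) {
  stat <- match.arg(stat)
  ref <- if (grepl("slope|acc", stat)) 1 else 0
  ggplot2::ggplot(day_stats,
                  ggplot2::aes(x = .data$age, y = .data[[stat]],
                               group = .data$replicate)) +
    ggplot2::geom_hline(yintercept = ref, colour = "black") +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "red", linewidth = 0.7) +
    ggplot2::facet_grid(model ~ scenario) +
    ggplot2::labs(x = "age (days)", y = stat) +
    ggplot2::theme_bw()
}

#' @rdname plot_lr_days
#' @param object An `lr_experiment`.
#' @param ... Passed to [plot_lr_days()] (e.g. `stat`).
#' @export
autoplot.lr_experiment <- function(object, ...) {
  plot_lr_days(object$day_stats, ...)
}

#' Growth-curve panel for one simulated animal
#'
#' Phenotype records, true breeding-value curve, and (optionally) EBV
#' curves from partial and whole fits for one animal.
#'
#' @param dataset A `growth_dataset`.
#' @param animal Animal id.
#' @param ebv Optional named list of EBV surfaces (each from
#'   [posterior_ebv()]) to overlay, e.g.
#'   `list(partial = ebv_p, whole = ebv_w)`.
#' @return A ggplot object.
#' @export
plot_animal_curve <- function(dataset, animal, ebv = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  animal <- as.character(animal)
  rec <- dplyr::filter(dataset$records, as.character(.data$animal) == !!animal)
  ages <- dataset$config$ages
  curves <- tibble::tibble(age = ages, value = dataset$bv[animal, ],
                           what = "true BV")
  for (nm in names(ebv)) {
    curves <- dplyr::bind_rows(
      curves,
      tibble::tibble(age = as.numeric(colnames(ebv[[nm]])),
                     value = ebv[[nm]][animal, ],
                     what = paste("EBV", nm)))
  }
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$age, y = .data$weight)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$value, colour = .data$what)) +
    ggplot2::labs(x = "age (days)", y = "body weight (kg)", colour = NULL) +
    ggplot2::theme_bw()
}
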