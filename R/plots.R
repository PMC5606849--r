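# ggplot2 displays for the result types.

#' Plot a feature as a function of vertebra number
#'
#' Group mean with standard-error ribbon per vertebra, the standard
#' display for vertebral phenotypic trends.
#'
#' @param cohort List of `phenome` objects with group attributes.
#' @param feature Measure short name.
#' @param vertebrae Vertebra window.
#' @return A ggplot.
#' @export
plot_feature_curve <- function(cohort, feature, vertebrae = 1:16) {
  fc <- feature_curve(cohort, feature, vertebrae)
  long <- tidyr::pivot_longer(fc, dplyr::starts_with("v"),
                              names_to = "vertebra", values_to = "value")
  long$vertebra <- as.integer(sub("^v", "", long$vertebra))
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$vertebra),
    mean = mean(.data$value, na.rm = TRUE),
    se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$vertebra, .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "vertebra", y = feature) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.barcode <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), !"vertebra",
                              names_to = "measure",
                              values_to = "score")
  long$measure <- factor(long$measure,
                         levels = rev(intersect(names(measure_names()),
                                                unique(long$measure))))
  ggplot2::ggplot(long, ggplot2::aes(.data$vertebra, .data$measure,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-4, 4),
                                  oob = scales_squish) +
    ggplot2::labs(x = "vertebra", y = NULL, fill = "z") +
    ggplot2::theme_minimal()
}

# local squish to avoid a scales dependency
scales_squish <- function(x, range = c(-4, 4)) pmin(pmax(x, range[1]),
                                                    range[2])

#' @export
autoplot.correlation_profile <- function(object, ...) {
  m <- object$matrix
  df <- tibble::tibble(i = rep(seq_len(nrow(m)), ncol(m)),
                       j = rep(seq_len(ncol(m)), each = nrow(m)),
                       r = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), option = "magma") +
    ggplot2::labs(x = NULL, y = NULL, fill = "|r|",
                  title = sprintf("median |r| = %.2f",
                                  object$median_abs_r)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.power_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("sensitivity", "specificity"),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$procedure, .data$value,
                                     fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.global_test_result <- function(object, ...) {
  tb <- object$per_vertebra
  tb$vertebra <- factor(tb$vertebra, levels = tb$vertebra)
  ggplot2::ggplot(tb, ggplot2::aes(.data$vertebra, -log10(.data$p))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "vertebra", y = "-log10 component p") +
    ggplot2::theme_minimal()
}
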