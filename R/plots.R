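#' Plot an IES size histogram
#'
#' @param object An [size_histogram()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ies_size_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = "IES length (bp)", y = "count",
                  title = "IES size distribution") +
    ggplot2::theme_minimal()
}

#' Plot an IES end-consensus logo (information-scaled letter heights)
#'
#' @param object An [end_logo()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ies_logo <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(object$freq))) %>%
    rename(base = "Var1", position = "Var2", freq = "Freq") %>%
    mutate(position = as.integer(.data$position),
           height = .data$freq * object$ic[.data$position])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::labs(x = "position", y = "information (bits)",
                  title = "IES end consensus") +
    ggplot2::theme_minimal()
}

#' Plot IES density against gene-expression bins
#'
#' @param object A [density_by_expression()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ies_density_fit <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$rank, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = "expression bin (rank)", y = "IES per kb of CDS",
                  title = "IES density vs gene expression") +
    ggplot2::theme_minimal()
}

#' @rdname size_periodicity
#' @param x An `ies_periodicity` object.
#' @param ... Unused.
#' @export
tidy.ies_periodicity <- function(x, ...) {
  tibble(peak_index = x$peak_index, peak_position = x$peaks)
}

#' @rdname size_periodicity
#' @export
glance.ies_periodicity <- function(x, ...) {
  tibble(period = x$period, n_peaks = x$n_peaks, residual = x$residual,
         first_peak_fraction = x$first_peak_fraction,
         second_peak_ratio = x$second_peak_ratio)
}

#' @rdname density_by_expression
#' @param x An `ies_density_fit` object.
#' @param ... Unused.
#' @export
tidy.ies_density_fit <- function(x, ...) x$bins

#' @rdname density_by_expression
#' @export
glance.ies_density_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_bins = nrow(x$bins))
}
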