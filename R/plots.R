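#' Four-panel electromechanics trace plot
#'
#' Membrane potential, cytosolic Ca2+, sarcomere length and normalised
#' active force against time for one or more pacing results.
#'
#' @param ... Named `pacing_result` objects (names become the legend).
#' @return A ggplot object.
#' @export
plot_trace <- function(...) {
  runs <- list(...)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- vapply(runs, function(r)
      paste(r$region, r$remodeling, sep = "/"), character(1))
  df <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    tr <- runs[[nm]]$trace
    tibble::tibble(run = nm, t = tr$t - min(tr$t), V = tr$V,
                   Ca_i = tr$Ca_i * 1000, SL = tr$SL,
                   F_active = tr$F_active)
  }))
  long <- tidyr::pivot_longer(df, c("V", "Ca_i", "SL", "F_active"),
                              names_to = "quantity")
  long$quantity <- factor(long$quantity,
                          levels = c("V", "Ca_i", "SL", "F_active"),
                          labels = c("V (mV)", "[Ca2+]_i (uM)", "SL (um)",
                                     "Active force (norm.)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pacing_result <- function(object, ...) plot_trace(object, ...)

#' @export
autoplot.force_ca_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$ca, .data$force_norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[Ca2+] (uM)", y = "steady-state force (norm.)",
                  subtitle = sprintf("Ca50 = %.2f uM, Hill n = %.1f",
                                     attr(object, "ca50"),
                                     attr(object, "hill"))) +
    ggplot2::theme_minimal()
}

#' Activation-count map of a re-entry run
#'
#' @param object A `reentry_report`.
#' @param ... Unused.
#' @return A ggplot tile map of per-node activation counts.
#' @export
autoplot.reentry_report <- function(object, ...) {
  m <- attr(object, "act_count")
  df <- tibble::tibble(
    x = rep(seq_len(nrow(m)), ncol(m)),
    y = rep(seq_len(ncol(m)), each = nrow(m)),
    activations = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$activations)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activations") +
    ggplot2::theme_minimal()
}

#' Regional biomarker overview
#'
#' APD90 per region and condition from a [region_sweep()].
#'
#' @param object A `region_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_sweep <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), is.na(.data$error))
  ggplot2::ggplot(df, ggplot2::aes(
    stats::reorder(.data$region, .data$apd90), .data$apd90,
    fill = .data$remodeling)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "APD90 (ms)", fill = NULL) +
    ggplot2::theme_minimal()
}
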