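#' Plot the channels of an epoch
#'
#' One panel per channel, free y scales; long high-rate channels are thinned
#' for display.
#'
#' @param object A `pfr_epoch`.
#' @param max_points Display cap per channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfr_epoch <- function(object, max_points = 3000, ...) {
  df <- object |>
    dplyr::group_by(.data$channel) |>
    dplyr::slice(seq(1L, dplyr::n(),
                     by = max(1L, floor(dplyr::n() / max_points)))) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 60, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an autoregulation index series
#'
#' @param object A `pfr_indices` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfr_indices <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t / 60, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "time (min)", y = attr(object, "index") %||% "index") +
    ggplot2::theme_minimal()
}

#' Plot joint (PRx, Mx) density surfaces
#'
#' Filled contours per group; the conventional single-index impairment
#' thresholds and the joint-index boundary can be overlaid.
#'
#' @param object A `pfr_density` from [joint_density()].
#' @param boundary_c Optional discriminant coefficient to overlay as the
#'   curve `Mx = c * (1 - PRx)`.
#' @param index_cut Optional single-index threshold to overlay as reference
#'   lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfr_density <- function(object, boundary_c = NULL, index_cut = NULL,
                                 ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$prx, y = .data$mx,
                                    z = .data$density)) +
    ggplot2::geom_contour_filled(bins = 10) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "PRx", y = "Mx") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(index_cut)) {
    p <- p + ggplot2::geom_hline(yintercept = index_cut, colour = "darkgreen",
                                 linetype = 2) +
      ggplot2::geom_vline(xintercept = index_cut, colour = "darkgreen",
                          linetype = 2)
  }
  if (!is.null(boundary_c)) {
    bnd <- tibble::tibble(prx = seq(-1, 1, length.out = 100))
    bnd$mx <- boundary_c * (1 - bnd$prx)
    bnd <- bnd[abs(bnd$mx) <= 1, ]
    p <- p + ggplot2::geom_line(data = bnd,
                                ggplot2::aes(x = .data$prx, y = .data$mx),
                                inherit.aes = FALSE, colour = "blue")
  }
  p
}

#' Plot the discriminant objective over the coefficient grid
#'
#' @param object A `pfr_discriminant`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfr_discriminant <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$c, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$c, colour = "blue",
                        linetype = 2) +
    ggplot2::labs(x = "boundary coefficient c", y = object$method) +
    ggplot2::theme_minimal()
}

#' Plot a predictor-importance ranking
#'
#' @param object A `pfr_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfr_ranking <- function(object, ...) {
  df <- dplyr::mutate(object,
                      predictor = stats::reorder(.data$predictor, .data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$predictor)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("importance (%s)", object$method[1L]),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot regime proportions from a pipeline report
#'
#' @param object A `pfr_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfr_report <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$label, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of QC-passing intervals") +
    ggplot2::theme_minimal()
}
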