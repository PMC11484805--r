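#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_segment geom_text geom_curve labs theme_minimal coord_fixed
#'   arrow unit scale_linewidth_continuous geom_hline facet_wrap
#' @export
ggplot2::autoplot

#' Plot posterior intervals of a fitted model
#'
#' Point (posterior mean) and HPD95% interval for each heritability,
#' correlation and, for SEM fits, each structural path.
#'
#' @param object A `lact_mtm_fit` or `lact_sem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lact_mtm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$parameter, y = .data$mean)) +
    geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    geom_errorbar(aes(ymin = .data$hpd_lower, ymax = .data$hpd_upper),
                  width = 0.2) +
    geom_point(aes(colour = .data$relevant)) +
    facet_wrap(~type, scales = "free") +
    labs(x = NULL, y = "posterior mean and HPD95%") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname autoplot.lact_mtm_fit
#' @export
autoplot.lact_sem_fit <- function(object, ...) autoplot.lact_mtm_fit(object, ...)

#' Plot a bootstrap-averaged trait network
#'
#' Nodes on a circle; retained edges drawn as arrows with line width
#' proportional to bootstrap strength and labelled with the strength
#' (direction proportion in parentheses).
#'
#' @param object A `lact_avg_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lact_avg_network <- function(object, ...) {
  nodes <- object$nodes
  k <- length(nodes)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  layout <- tibble::tibble(node = nodes, x = cos(ang), y = sin(ang))
  e <- tidy(object)
  e <- e[e$retained, , drop = FALSE]
  if (nrow(e) > 0) {
    e <- dplyr::left_join(e, layout, by = c(from = "node")) %>%
      dplyr::rename(x0 = "x", y0 = "y") %>%
      dplyr::left_join(layout, by = c(to = "node")) %>%
      dplyr::mutate(
        # shrink segments so arrows stop short of the node labels
        xs = .data$x0 + 0.12 * (.data$x - .data$x0),
        ys = .data$y0 + 0.12 * (.data$y - .data$y0),
        xe = .data$x - 0.12 * (.data$x - .data$x0),
        ye = .data$y - 0.12 * (.data$y - .data$y0),
        label = sprintf("%.0f%% (%.0f%%)", 100 * .data$strength,
                        100 * .data$direction)
      )
  }
  p <- ggplot(layout, aes(x = .data$x, y = .data$y)) +
    geom_text(aes(label = .data$node), fontface = "bold") +
    coord_fixed(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    theme_minimal() +
    labs(x = NULL, y = NULL,
         title = sprintf("Averaged network (%d bootstrap replicates)",
                         object$n_boot)) +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (nrow(e) > 0) {
    p <- p +
      geom_segment(data = e,
                   aes(x = .data$xs, y = .data$ys, xend = .data$xe,
                       yend = .data$ye, linewidth = .data$strength),
                   arrow = arrow(length = unit(0.15, "inches")),
                   colour = "steelblue") +
      geom_text(data = e,
                aes(x = (.data$xs + .data$xe) / 2,
                    y = (.data$ys + .data$ye) / 2, label = .data$label),
                size = 3, vjust = -0.6) +
      scale_linewidth_continuous(range = c(0.3, 1.6), guide = "none")
  }
  p
}
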