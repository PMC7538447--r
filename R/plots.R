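#' Plot force-law profiles
#'
#' Overlays the scalar force profiles of one or more parameterised laws;
#' the horizontal zero line separates repulsion (below) from adhesion
#' (above), with vertical guides at the rest length and cutoff of the first
#' law.
#'
#' @param ... [force_params()] objects (optionally named for the legend).
#' @param r Optional shared separation grid.
#' @return A ggplot object.
#' @export
plot_force_profiles <- function(..., r = NULL) {
  laws <- list(...)
  stopifnot(length(laws) > 0)
  nms <- names(laws)
  if (is.null(nms)) nms <- rep("", length(laws))
  profs <- purrr::map2(laws, seq_along(laws), function(p, i) {
    prof <- force_profile(p, r = r)
    prof$law <- if (nzchar(nms[i])) nms[i] else paste0(i, ": ", p$law)
    prof
  })
  df <- bind_rows(profs)
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$force, colour = .data$law)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey40") +
    ggplot2::geom_vline(
      xintercept = c(laws[[1]]$s, laws[[1]]$r_A),
      linetype = 2, colour = "grey70"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "separation r (cell diameters)",
      y = "force F(r) (cell diameters / h)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cell_trajectory <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
    group = interaction(.data$segment, .data$cell_id),
    colour = factor(.data$cell_id)
  )) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_point(
      data = df[df$time == max(df$time), ],
      show.legend = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cell diameters)", y = "y (cell diameters)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.monolayer_result <- function(object, ...) {
  df <- summarise_radius(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mean_radius)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_radius - .data$sd_radius,
        ymax = .data$mean_radius + .data$sd_radius
      ),
      fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = attr(object, "initial_radius"),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::labs(
      x = "time (h)", y = "population radius (cell diameters)",
      title = paste0(
        attr(object, "law"), " force, ", attr(object, "n_init"),
        " initial cells"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.convergence_result <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[is.finite(df$rel_error), ]
  slope <- attr(object, "fitted_order")
  ggplot2::ggplot(df, ggplot2::aes(.data$dt, .data$rel_error)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(Delta * t ~ "(h)"), y = "relative error",
      title = paste0(
        attr(object, "scheme"), " on ", attr(object, "problem"),
        " (fitted order ", round(slope, 2), ")"
      )
    ) +
    ggplot2::theme_minimal()
}
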