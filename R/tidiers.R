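## broom-style tidiers and ggplot2 autoplot methods for the package's
## result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ellipsoid model
#'
#' @param x An `ellipsoid_model`.
#' @param ... Unused.
#' @return One row per principal axis: `axis`, `semi_axis`, direction
#'   cosines.
#' @export
tidy.ellipsoid_model <- function(x, ...) {
  tibble::tibble(axis = 1:3,
                 semi_axis = x$semi_axes,
                 dir_x = x$orientation[1, ],
                 dir_y = x$orientation[2, ],
                 dir_z = x$orientation[3, ])
}

#' @rdname tidy.ellipsoid_model
#' @export
glance.ellipsoid_model <- function(x, ...) {
  tibble::tibble(center_x = x$center[1], center_y = x$center[2],
                 center_z = x$center[3],
                 inlier_fraction = x$inlier_fraction)
}

#' Tidy a symmetry system
#'
#' @param x A `symmetry_system`.
#' @param ... Unused.
#' @return One row per plane with its normal components and anchor.
#' @export
tidy.symmetry_system <- function(x, ...) {
  N <- system_normals(x)
  tibble::tibble(plane = 1:3,
                 nx = N[1, ], ny = N[2, ], nz = N[3, ],
                 anchor_x = x$anchor[1], anchor_y = x$anchor[2],
                 anchor_z = x$anchor[3])
}

#' Tidy / summarise a completion result
#'
#' @param x An `assm_completion`.
#' @param ... Unused.
#' @return `tidy()`: the per-plane system table. `glance()`: one row with
#'   point counts and the estimated input occlusion.
#' @export
tidy.assm_completion <- function(x, ...) tidy(x$system)

#' @rdname tidy.assm_completion
#' @export
glance.assm_completion <- function(x, ...) {
  out <- tibble::tibble(n_input = x$n_input, n_added = x$n_added,
                        n_fused = nrow(x$cloud),
                        plane_iterations = attr(x$plane, "iterations"),
                        mirror_objective = attr(x$plane, "objective"))
  if (!is.null(x$report)) out <- dplyr::bind_cols(out, x$report)
  out
}

#' Tidy an experiment report
#'
#' @param x An `assm_experiment`.
#' @param ... Unused.
#' @return `tidy()`: the metrics table (per level, method and dimension).
#'   `glance()`: one row with cohort-wide counts.
#' @export
tidy.assm_experiment <- function(x, ...) x$metrics

#' @rdname tidy.assm_experiment
#' @export
glance.assm_experiment <- function(x, ...) {
  tibble::tibble(n_fruit = dplyr::n_distinct(x$per_fruit$id),
                 n_rows = nrow(x$per_fruit),
                 n_skipped = x$n_skipped)
}

#' Plot a point cloud as paired orthographic projections
#'
#' @param object A `point_cloud`.
#' @param colour Column name used for the point colour (defaults to
#'   `provenance` when present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.point_cloud <- function(object, colour = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(colour) && "provenance" %in% names(df)) colour <- "provenance"
  long <- dplyr::bind_rows(
    dplyr::transmute(df, view = "x-y", u = .data$x, v = .data$y,
                     col = if (!is.null(colour)) factor(df[[colour]])),
    dplyr::transmute(df, view = "x-z", u = .data$x, v = .data$z,
                     col = if (!is.null(colour)) factor(df[[colour]])))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$u, .data$v)) +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm") +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$col), size = 0.3) +
      ggplot2::labs(colour = colour)
  } else {
    p + ggplot2::geom_point(size = 0.3, alpha = 0.6)
  }
}

#' Plot a completion result (observed vs filled points)
#'
#' @param object An `assm_completion`.
#' @param ... Passed on to [autoplot.point_cloud()].
#' @return A ggplot object.
#' @export
autoplot.assm_completion <- function(object, ...) {
  autoplot(object$cloud, colour = "provenance", ...) +
    ggplot2::ggtitle("Completed fruit (0 = observed, 1-3 = mirror fills)")
}

#' Plot predicted against true dimensions for an experiment
#'
#' @param object An `assm_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assm_experiment <- function(object, ...) {
  ggplot2::ggplot(object$per_fruit,
                  ggplot2::aes(.data$truth, .data$predicted,
                               colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~dimension, scales = "free") +
    ggplot2::labs(x = "true (mm)", y = "predicted (mm)") +
    ggplot2::theme_minimal()
}
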