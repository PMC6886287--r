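#' Plot a cumulative DVH curve set
#'
#' @param object a `dvh_curve` tibble (possibly stacking several
#'   structures, as produced by binding [dvh()] outputs).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot dvh_curve
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_Gy, y = .data$volume_pct,
                                       colour = .data$structure)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

#' Plot dose and structures, DVHs, or weight trajectories of a run
#'
#' `autoplot.autofmo_run()` draws the cumulative DVHs of the final plan.
#' `plot_weight_history()` draws the importance-factor trajectories across
#' outer iterations. `plot_dose()` draws the planar dose with structure
#' outlines.
#'
#' @param object,run an `autofmo_run`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot autofmo_run
#' @export
autoplot.autofmo_run <- function(object, ...) {
  phantom <- object$phantom
  curves <- purrr::map_dfr(names(phantom$masks), function(nm)
    dvh(object$plan$dose, phantom$masks[[nm]], structure = nm))
  class(curves) <- c("dvh_curve", class(tibble::tibble()))
  autoplot(curves)
}

#' @rdname autoplot.autofmo_run
#' @export
plot_weight_history <- function(run) {
  td <- tidy(run)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$outer_iter, y = .data$weight,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Outer iteration", y = "Importance factor", colour = NULL)
}

#' @rdname autoplot.autofmo_run
#' @export
plot_dose <- function(run) {
  im_vox <- tibble::tibble(
    voxel = seq_along(run$plan$dose),
    dose_Gy = run$plan$dose
  )
  phantom <- run$phantom
  xy <- voxel_coords(phantom$grid_shape, phantom$voxel_size)
  im_vox$x_mm <- as.vector(xy$x)
  im_vox$y_mm <- as.vector(xy$y)
  outlines <- mask_voxels(phantom)
  outlines <- outlines[outlines$structure != "body", ]
  ggplot2::ggplot(im_vox, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$dose_Gy)) +
    ggplot2::geom_point(data = outlines,
                        ggplot2::aes(colour = .data$structure),
                        size = 0.1, alpha = 0.3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "Dose (Gy)", colour = NULL)
}
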