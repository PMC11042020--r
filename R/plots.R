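# ggplot2 visualisation helpers.

#' Plot a feature map
#'
#' Raster view of the 45 x 48 reconfigured boundary-voltage matrix
#' (rows: measurement position within the cycle; columns: excitation).
#'
#' @param object an `eit_featuremap`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot eit_featuremap
#' @export
autoplot.eit_featuremap <- function(object, ...) {
  df <- expand.grid(measurement = seq_len(45L), excitation = seq_len(48L))
  df$voltage <- as.vector(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$excitation, .data$measurement,
                                   fill = .data$voltage)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "excitation", y = "measurement",
                  fill = "V", title = "Feature map (45 x 48)") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object an `eit_model`.
#' @param ... unused.
#' @return a ggplot object with per-epoch train/validation loss.
#' @method autoplot eit_model
#' @export
autoplot.eit_model <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_loss, split = "train"),
    data.frame(epoch = h$epoch, loss = h$val_loss, split = "validation")
  )
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "amplified MSE", title = "Training history") +
    ggplot2::theme_minimal()
}

#' Horizontal slice of a conductivity field
#'
#' Scatter-raster of element centroids within a thin slab around the
#' requested height, coloured by conductivity; a quick look at interior
#' structure without a 3-D viewer.
#'
#' @param field an `eit_field` bound to `mesh`.
#' @param mesh an `eit_mesh`.
#' @param z_cm slice height in cm.
#' @param thickness_cm slab thickness in cm (default 1).
#' @return a ggplot object.
#' @export
plot_slice <- function(field, mesh, z_cm, thickness_cm = 1) {
  check_binding(field, mesh)
  cen <- mesh$element_centroids * 100
  sel <- abs(cen[, 3L] - z_cm) <= thickness_cm / 2
  df <- data.frame(x = cen[sel, 1L], y = cen[sel, 2L],
                   sigma = field$values[sel])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$sigma)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = "S/m",
                  title = sprintf("sigma at z = %g cm", z_cm)) +
    ggplot2::theme_minimal()
}
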