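# ggplot2 views of the main result types. (autoplot.exp_fit lives with the
# fitter in exp-fit.R.)

#' @rdname iv_curve
#' @param object An `iv_curve`.
#' @param ... Unused.
#' @export
autoplot.iv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v_mV, y = .data$i_pA_pF)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "step potential (mV)",
                  y = "late current density (pA/pF)") +
    ggplot2::theme_minimal()
}

#' @rdname idealize_trace
#' @param object A `sparklet_idealization`.
#' @param ... Unused.
#' @export
autoplot.sparklet_idealization <- function(object, ...) {
  q <- attr(object, "quantal_df")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$df), colour = "grey55") +
    ggplot2::geom_step(ggplot2::aes(y = .data$k * q), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "dF (quantal units)",
                  title = sprintf("Idealized sparklet record (nPs = %.3f)",
                                  mean(object$k))) +
    ggplot2::theme_minimal()
}

#' @rdname simulate_assembly
#' @param object An `assembly_result`.
#' @param ... Unused.
#' @export
autoplot.assembly_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$step,
                                             y = .data$occupancy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "occupied sites",
                  title = sprintf("Self-assembly occupancy (p_n=%g, p_g=%g, p_r=%g)",
                                  object$params$p_n, object$params$p_g,
                                  object$params$p_r)) +
    ggplot2::theme_minimal()
}

#' Display a synthetic localization field with its ground truth
#'
#' @param field A `localization_field`.
#' @param show_truth Overlay ground-truth centroids?
#' @return A ggplot.
#' @export
plot_localization_field <- function(field, show_truth = TRUE) {
  stopifnot(inherits(field, "localization_field"))
  px <- field$spec$pixel_nm
  df <- tidyr::expand_grid(iy = seq_len(ncol(field$image)),
                           ix = seq_len(nrow(field$image)))
  df$intensity <- as.vector(field$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ix * px, y = .data$iy * px,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  if (show_truth && nrow(field$truth) > 0) {
    p <- p + ggplot2::geom_point(
      data = field$truth,
      ggplot2::aes(x = .data$x_nm, y = .data$y_nm),
      inherit.aes = FALSE, colour = "red", shape = 1)
  }
  p
}
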