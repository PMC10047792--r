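#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained implicit model
#'
#' One row per training epoch: learning rate, training loss and (where
#' computed) validation accuracy.
#'
#' @param x An `eit_implicit_model`.
#' @param ... Unused.
#' @return A tibble `epoch`, `lr`, `train_loss`, `val_acc`.
#' @method tidy eit_implicit_model
#' @export
tidy.eit_implicit_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), lr = numeric(),
                          train_loss = numeric(), val_acc = numeric()))
  }
  x$history
}

#' @rdname tidy.eit_implicit_model
#' @method glance eit_implicit_model
#' @export
glance.eit_implicit_model <- function(x, ...) {
  tibble::tibble(
    scale = x$config$scale,
    n_parameters = count_parameters(x$config),
    embedding_dim = x$config$embedding_dim,
    epochs_trained = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    best_val_acc = if (is.null(attr(x, "best_val_acc"))) NA_real_ else attr(x, "best_val_acc")
  )
}

#' Tidy an IRGN reconstruction
#'
#' One row per triangle with the reconstructed conductivity and centroid.
#'
#' @param x An `eit_recon_result`.
#' @param ... Unused.
#' @return A tibble `triangle`, `x`, `y`, `sigma`, `masked`.
#' @method tidy eit_recon_result
#' @export
tidy.eit_recon_result <- function(x, ...) {
  cents <- triangle_centroids(x$mesh)
  sigma <- x$sigma
  masked <- if (is.null(x$mask)) rep(TRUE, length(sigma)) else x$mask
  tibble::tibble(triangle = cents$triangle, x = cents$x, y = cents$y,
                 sigma = sigma, masked = masked)
}

#' @rdname tidy.eit_recon_result
#' @method glance eit_recon_result
#' @export
glance.eit_recon_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    iterations = length(x$residuals),
    final_residual = if (length(x$residuals)) x$residuals[length(x$residuals)] else NA_real_,
    converged_at = x$converged_at,
    n_components = if (is.null(x$components)) NA_integer_ else length(x$components),
    l2_error = x$l2_error
  )
}

#' Tidy a monotonicity result
#' @param x An `eit_monotonicity_result`.
#' @param ... Unused.
#' @return The per-ball tibble (`cx`, `cy`, `radius`, `flag`, `margin`).
#' @method tidy eit_monotonicity_result
#' @export
tidy.eit_monotonicity_result <- function(x, ...) x$balls

#' @rdname tidy.eit_monotonicity_result
#' @method glance eit_monotonicity_result
#' @export
glance.eit_monotonicity_result <- function(x, ...) {
  tibble::tibble(n_balls = nrow(x$balls), n_flagged = sum(x$balls$flag),
                 n_masked = sum(x$mask), direction = as.character(x$direction),
                 tol = x$tol)
}

#' Plot a shape prediction over the mesh outline
#'
#' @param object Prediction tibble from [predict_points()] or
#'   [super_resolution_eval()].
#' @param ... Unused.
#' @return A ggplot: points coloured by anomaly probability.
#' @method autoplot eit_shape_prediction
#' @export
autoplot.eit_shape_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$prob_anomaly)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient(low = "grey85", high = "firebrick",
                                   limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "P(anomaly)") +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed conductivity field
#' @param object An `eit_recon_result`.
#' @param ... Unused.
#' @return A ggplot of per-triangle conductivities at the centroids.
#' @method autoplot eit_recon_result
#' @export
autoplot.eit_recon_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$sigma)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = expression(sigma)) +
    ggplot2::theme_minimal()
}

#' Plot an accuracy report
#' @param object An `eit_accuracy_report` from [noise_sweep()].
#' @param ... Unused.
#' @return A ggplot of mean accuracy vs noise level with +-1 sd ribbon.
#' @method autoplot eit_accuracy_report
#' @export
autoplot.eit_accuracy_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "validation noise level (%)", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
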