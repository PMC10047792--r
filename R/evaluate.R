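#' Classification accuracy
#'
#' Exact fraction of agreeing labels.
#'
#' @param predicted,truth Equal-length binary label vectors.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    stop("label vectors must have equal nonzero length", call. = FALSE)
  }
  mean(predicted == truth)
}

#' Evaluate a model on mesh triangle centroids
#'
#' Adds noise at level `delta` to the record's clean measurements (with a
#' logged seed), predicts anomaly membership at every triangle centroid of
#' `mesh`, and scores against the continuous-domain circle-membership truth
#' of the phantom (not the rasterized conductivity, which would couple the
#' evaluation to the discretization).
#'
#' @param model An `eit_implicit_model` (or any object with a
#'   `predict_points`-compatible method).
#' @param phantom The ground-truth `eit_phantom`.
#' @param m Clean measurement vector of that phantom.
#' @param mesh Evaluation mesh.
#' @param delta Noise level in percent.
#' @param noise_seed Seed set before drawing the measurement noise.
#' @return Single accuracy value.
#' @export
evaluate_on_mesh <- function(model, phantom, m, mesh, delta = 0, noise_seed = 1L) {
  cents <- triangle_centroids(mesh)
  if (delta > 0) {
    set.seed(noise_seed)
    m <- add_noise(m, delta)
  }
  pred <- predict_points(model, m, cents)
  accuracy(pred$label, label_point(phantom, cents$x, cents$y))
}

#' Noise sweep over a validation set
#'
#' Per-phantom centroid accuracies for each noise level, with one fixed
#' noise seed per (sweep, delta) so reports are reproducible.
#'
#' @param model An `eit_implicit_model`.
#' @param val_set An `eit_dataset`.
#' @param mesh Evaluation mesh.
#' @param deltas Noise levels in percent (default 0..5).
#' @param noise_seed Base seed; each delta uses `noise_seed + 1000*delta`.
#' @return An `eit_accuracy_report` tibble: one row per delta with columns
#'   `delta`, `mean`, `sd`, `n`, `cell` (a `"0.9778±0.0123"`-style string)
#'   and `per_phantom` (list column of the individual accuracies).
#' @export
noise_sweep <- function(model, val_set, mesh, deltas = 0:5, noise_seed = 202L) {
  cents <- triangle_centroids(mesh)
  truth <- purrr::map(val_set$phantom, function(ph) label_point(ph, cents$x, cents$y))
  rows <- purrr::map(deltas, function(d) {
    acc <- validate_on_centroids(model$params, model$config, model$stats,
                                 val_set, cents, truth, delta = d,
                                 noise_seed = noise_seed + as.integer(1000 * d))
    tibble::tibble(delta = d, mean = mean(acc), sd = stats::sd(acc),
                   n = length(acc),
                   cell = sprintf("%.4f±%.4f", mean(acc), stats::sd(acc)),
                   per_phantom = list(acc))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eit_accuracy_report", class(out))
  out
}

#' Super-resolution evaluation on a finer mesh
#'
#' Simulates the measurements of `phantom` on `fine_mesh` (a mesh finer than
#' the one the model was trained on), then queries the trained implicit
#' model at the fine-mesh centroids — no retraining; the model input stays a
#' 208-vector regardless of mesh.
#'
#' @param model An `eit_implicit_model`.
#' @param fine_mesh Evaluation/simulation mesh.
#' @param phantom An `eit_phantom`.
#' @param delta Noise level in percent.
#' @param noise_seed Seed for the noise draw.
#' @return Tibble `x`, `y`, `prob_anomaly`, `label`, one row per fine-mesh
#'   triangle, with attribute `accuracy` (vs continuous truth).
#' @export
super_resolution_eval <- function(model, fine_mesh, phantom, delta = 0,
                                  noise_seed = 1L) {
  m <- measure(rasterize(phantom, fine_mesh))
  if (delta > 0) {
    set.seed(noise_seed)
    m <- add_noise(m, delta)
  }
  cents <- triangle_centroids(fine_mesh)
  pred <- predict_points(model, m, cents)
  attr(pred, "accuracy") <- accuracy(pred$label,
                                     label_point(phantom, cents$x, cents$y))
  pred
}

#' Centroid of the predicted anomaly region
#'
#' Mean position of the points a prediction labels anomalous; used to check
#' that noisy reconstructions still localize an inclusion.
#'
#' @param pred A prediction tibble (`x`, `y`, `label`).
#' @return Length-2 numeric `(x, y)`, or `c(NA, NA)` if nothing is flagged.
#' @export
predicted_anomaly_centroid <- function(pred) {
  flagged <- pred$label == 1L
  if (!any(flagged)) return(c(NA_real_, NA_real_))
  c(mean(pred$x[flagged]), mean(pred$y[flagged]))
}
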