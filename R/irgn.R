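#' IRGN configuration
#'
#' Iteratively regularized Gauss-Newton settings. The Tikhonov weight decays
#' geometrically from `alpha0` (when `alpha0` is `NULL` it is set adaptively
#' to `1e-3 * max|grad|` of the initial residual); updates are projected onto
#' the conductivity box after every step.
#'
#' @param mode `"standard"`, `"constrained"` or `"piecewise"`.
#' @param alpha0 Initial regularization weight (NULL = adaptive).
#' @param alpha_decay Per-iteration multiplier in (0, 1].
#' @param max_iterations Iteration cap.
#' @param sigma_init Initial guess / Tikhonov anchor (background 1).
#' @param sigma_lo,sigma_hi Projection box.
#' @param rel_tol Stop when the relative residual improvement drops below
#'   this.
#' @return An `eit_irgn_config`.
#' @export
irgn_config <- function(mode = "standard", alpha0 = NULL, alpha_decay = 0.8,
                        max_iterations = 20L, sigma_init = 1,
                        sigma_lo = 0.05, sigma_hi = 20, rel_tol = 1e-4) {
  mode <- match.arg(mode, c("standard", "constrained", "piecewise"))
  stopifnot(is.null(alpha0) || alpha0 > 0, alpha_decay > 0, alpha_decay <= 1,
            sigma_lo < sigma_init, sigma_init < sigma_hi)
  structure(list(mode = mode, alpha0 = alpha0, alpha_decay = alpha_decay,
                 max_iterations = as.integer(max_iterations),
                 sigma_init = sigma_init, sigma_lo = sigma_lo,
                 sigma_hi = sigma_hi, rel_tol = rel_tol),
            class = "eit_irgn_config")
}

#' Area-weighted L2 reconstruction error
#'
#' `sqrt(sum_T area_T (sigma_hat_T - sigma_T)^2)` over a common mesh.
#'
#' @param estimate,truth `eit_field`s on the same mesh (or numeric
#'   per-triangle vectors with `mesh` supplied).
#' @param mesh Mesh, required when bare vectors are given.
#' @return Nonnegative scalar; zero iff the fields agree.
#' @export
l2_error <- function(estimate, truth, mesh = NULL) {
  if (inherits(estimate, "eit_field")) { mesh <- estimate$mesh; estimate <- estimate$sigma }
  if (inherits(truth, "eit_field")) {
    if (!is.null(mesh) && !identical(dim(truth$mesh$triangles), dim(mesh$triangles))) {
      stop("fields live on different meshes", call. = FALSE)
    }
    mesh <- if (is.null(mesh)) truth$mesh else mesh
    truth <- truth$sigma
  }
  if (length(estimate) != length(truth)) stop("fields live on different meshes", call. = FALSE)
  sqrt(sum(triangle_areas(mesh) * (estimate - truth)^2))
}

# core Gauss-Newton driver in a reduced parameterization:
# sigma(theta) = base + P %*% theta where P has one column per unknown
# (identity for standard/constrained over the masked triangles; component
# indicator columns for piecewise).
irgn_run <- function(m_obs, mesh, P, base, config) {
  m_obs <- as.numeric(m_obs)
  n_par <- ncol(P)
  theta <- rep(0, n_par)
  sigma_of <- function(th) {
    pmin(pmax(base + as.numeric(P %*% th), config$sigma_lo), config$sigma_hi)
  }
  residuals <- numeric(0)
  alphas <- numeric(0)
  sigma <- sigma_of(theta)
  f <- conductivity_field(mesh, sigma, config$sigma_lo, config$sigma_hi)
  r0 <- m_obs - as.numeric(measure(f))
  alpha <- config$alpha0
  converged_at <- NA_integer_
  for (k in seq_len(config$max_iterations)) {
    f <- conductivity_field(mesh, sigma, config$sigma_lo, config$sigma_hi)
    r <- m_obs - as.numeric(measure(f))
    residuals <- c(residuals, sqrt(sum(r^2)))
    J <- as.matrix(jacobian(f) %*% P)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    if (is.null(alpha)) {
      # adaptive scale off the initial gradient, with a floor tied to the
      # normal-matrix scale so exact data (zero residual) stays well posed
      alpha <- max(1e-3 * max(abs(g)), 1e-9 * max(diag(JtJ)), 1e-300)
    }
    alpha_k <- alpha * config$alpha_decay^(k - 1)
    alphas <- c(alphas, alpha_k)
    H <- JtJ + alpha_k * diag(n_par)
    # Tikhonov anchored at the initial guess: theta_init = 0
    step <- solve(H, g + alpha_k * (0 - theta))
    if (any(!is.finite(step))) stop("non-finite Gauss-Newton update", call. = FALSE)
    theta <- theta + as.numeric(step)
    sigma_new <- sigma_of(theta)
    # recover theta consistent with the projected sigma for piecewise modes
    sigma <- sigma_new
    if (length(residuals) >= 2) {
      imp <- (residuals[length(residuals) - 1] - residuals[length(residuals)]) /
        max(residuals[length(residuals) - 1], 1e-300)
      if (abs(imp) < config$rel_tol) { converged_at <- k; break }
    }
  }
  list(sigma = sigma, theta = theta, residuals = residuals, alphas = alphas,
       converged_at = converged_at)
}

new_recon_result <- function(run, mesh, config, mask, components, truth) {
  err <- if (is.null(truth)) NA_real_ else l2_error(run$sigma, truth, mesh = mesh)
  structure(list(sigma = run$sigma, mesh = mesh, mode = config$mode,
                 residuals = run$residuals, alphas = run$alphas,
                 converged_at = run$converged_at, mask = mask,
                 components = components, l2_error = err, config = config),
            class = "eit_recon_result")
}

#' Standard Tikhonov-regularized IRGN reconstruction
#'
#' Gauss-Newton least squares fit of the per-triangle conductivity to the
#' observed measurement vector with a geometrically decaying identity
#' Tikhonov penalty anchored at the initial (background) guess, box-projected
#' after each step.
#'
#' @param m_obs Observed measurement vector (208 entries for L = 16).
#' @param mesh Reconstruction mesh.
#' @param config An `eit_irgn_config`.
#' @param truth Optional ground-truth `eit_field` (or sigma vector) for
#'   error reporting.
#' @return An `eit_recon_result`: per-triangle `sigma`, residual history,
#'   per-iteration `alphas`, `l2_error` (when truth given).
#' @export
irgn_standard <- function(m_obs, mesh, config = irgn_config("standard"),
                          truth = NULL) {
  nt <- nrow(mesh$triangles)
  P <- Matrix::Diagonal(nt)
  run <- irgn_run(m_obs, mesh, P, rep(config$sigma_init, nt), config)
  new_recon_result(run, mesh, config, mask = NULL, components = NULL, truth = truth)
}

#' Shape-constrained IRGN reconstruction
#'
#' Identical iteration restricted to the flagged triangles of a predicted
#' anomaly mask; every unflagged triangle stays fixed at the unit background.
#'
#' @inheritParams irgn_standard
#' @param mask Logical per-triangle anomaly mask (from the implicit model or
#'   the monotonicity baseline).
#' @return An `eit_recon_result`.
#' @export
irgn_constrained <- function(m_obs, mesh, mask,
                             config = irgn_config("constrained"), truth = NULL) {
  nt <- nrow(mesh$triangles)
  mask <- as.logical(mask)
  stopifnot(length(mask) == nt)
  if (!any(mask)) {
    warning("empty mask: returning the background field")
    run <- list(sigma = rep(config$sigma_init, nt), theta = numeric(0),
                residuals = numeric(0), alphas = numeric(0), converged_at = NA_integer_)
    return(new_recon_result(run, mesh, config, mask, NULL, truth))
  }
  P <- Matrix::sparseMatrix(i = which(mask), j = seq_len(sum(mask)),
                            x = 1, dims = c(nt, sum(mask)))
  run <- irgn_run(m_obs, mesh, P, rep(config$sigma_init, nt), config)
  new_recon_result(run, mesh, config, mask, NULL, truth)
}

#' Piecewise-constant IRGN reconstruction
#'
#' One scalar conductivity per edge-connected component of the mask
#' (background fixed at 1): Gauss-Newton in this low-dimensional
#' parameterization, giving a reconstruction that is piecewise constant by
#' construction.
#'
#' @inheritParams irgn_constrained
#' @return An `eit_recon_result`; `components` holds the triangle-index sets.
#' @export
irgn_piecewise <- function(m_obs, mesh, mask,
                           config = irgn_config("piecewise"), truth = NULL) {
  nt <- nrow(mesh$triangles)
  mask <- as.logical(mask)
  stopifnot(length(mask) == nt)
  comps <- connected_components(mesh, mask)
  if (length(comps) == 0L) {
    warning("empty mask: returning the background field")
    run <- list(sigma = rep(config$sigma_init, nt), theta = numeric(0),
                residuals = numeric(0), alphas = numeric(0), converged_at = NA_integer_)
    return(new_recon_result(run, mesh, config, mask, comps, truth))
  }
  P <- Matrix::sparseMatrix(
    i = unlist(comps),
    j = rep(seq_along(comps), lengths(comps)),
    x = 1, dims = c(nt, length(comps)))
  run <- irgn_run(m_obs, mesh, P, rep(config$sigma_init, nt), config)
  new_recon_result(run, mesh, config, mask, comps, truth)
}

#' @export
print.eit_recon_result <- function(x, ...) {
  cat(sprintf("<eit_recon_result> mode %s, %d iterations, final residual %.4g%s\n",
              x$mode, length(x$residuals),
              if (length(x$residuals)) x$residuals[length(x$residuals)] else NA,
              if (is.na(x$l2_error)) "" else sprintf(", L2 error %.4f", x$l2_error)))
  invisible(x)
}
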