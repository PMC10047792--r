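#' Hexagonal grid of test balls
#'
#' Centres on a hexagonal packing with the given spacing, keeping only balls
#' entirely inside radius 0.95; the monotonicity test probes each ball for
#' membership in the anomalous region.
#'
#' @param spacing Centre spacing (default 0.1).
#' @param radius Ball radius (default 0.1).
#' @param rmax Containment bound: `|centre| + radius <= rmax`.
#' @return Tibble `cx`, `cy`, `radius`.
#' @export
ball_grid <- function(spacing = 0.1, radius = 0.1, rmax = 0.95) {
  rows <- ceiling(2 / (spacing * sqrt(3) / 2))
  out <- list()
  for (j in -rows:rows) {
    y <- j * spacing * sqrt(3) / 2
    off <- if (j %% 2 == 0) 0 else spacing / 2
    xs <- seq(-1, 1, by = spacing) + off
    keep <- sqrt(xs^2 + y^2) + radius <= rmax
    if (any(keep)) out[[length(out) + 1L]] <- tibble::tibble(cx = xs[keep], cy = y)
  }
  g <- dplyr::bind_rows(out)
  g$radius <- radius
  g
}

#' Precompute NtD matrices of ball test fields
#'
#' For each ball, the Neumann-to-Dirichlet matrix of the field
#' `background + contrast` inside the ball (centroid-membership
#' rasterization) on the given mesh. These are the reference operators the
#' monotonicity test compares against; computing them once is what makes the
#' test fast.
#'
#' @param mesh An `eit_mesh`.
#' @param balls Tibble from [ball_grid()].
#' @param contrast Conductivity offset inside the ball (nonzero; sign gives
#'   the test direction).
#' @param background Background conductivity (1).
#' @param cache_dir Optional directory: operators are stored there as one
#'   JSON file keyed by a hash of (mesh, balls, contrast, background); a
#'   cache hit returns the stored matrices (full-precision decimal
#'   round-trip, agreement to ~1e-15 relative).
#' @return List of `(L-1) x (L-1)` matrices, one per ball row.
#' @export
precompute_ball_ntds <- function(mesh, balls, contrast = 1, background = 1,
                                 cache_dir = NULL) {
  stopifnot(inherits(mesh, "eit_mesh"))
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    key <- rlang::hash(list(mesh$nodes, mesh$triangles, as.data.frame(balls),
                            contrast, background))
    cache_file <- file.path(cache_dir, paste0("ball_ntds_", key, ".json"))
    if (file.exists(cache_file)) {
      raw <- jsonlite::read_json(cache_file, simplifyVector = FALSE)
      return(lapply(raw, function(m) {
        do.call(rbind, lapply(m, function(row) unlist(row, use.names = FALSE)))
      }))
    }
  }
  cents <- triangle_centroids(mesh)
  ops <- purrr::pmap(balls, function(cx, cy, radius) {
    sigma <- rep.int(background, nrow(mesh$triangles))
    inside <- (cents$x - cx)^2 + (cents$y - cy)^2 < radius^2
    sigma[inside] <- background + contrast
    ntd_matrix(conductivity_field(mesh, sigma))
  })
  if (!is.null(cache_file)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(lapply(ops, function(m) apply(unclass(m), 1, as.numeric,
                                                       simplify = FALSE)),
                         cache_file, digits = NA)
  }
  ops
}

#' Positive semi-definiteness test
#'
#' @param M Symmetric matrix (validated to relative tolerance 1e-8).
#' @param tol Relative eigenvalue tolerance: PSD iff the smallest eigenvalue
#'   is `>= -tol * max(1, largest |eigenvalue|)`.
#' @return List with `psd` (logical) and `margin` (smallest eigenvalue).
#' @export
is_psd <- function(M, tol = 1e-10) {
  nm <- max(abs(M))
  if (nm > 0 && max(abs(M - t(M))) / nm > 1e-8) {
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  }
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  margin <- min(ev)
  list(psd = margin >= -tol * max(1, max(abs(ev))), margin = margin)
}

#' Monotonicity-test shape reconstruction
#'
#' Flags each test ball as inside the anomalous region when the sign-definite
#' NtD comparison holds: for direction `+1` (anomalies more conductive than
#' background) a ball is flagged iff `Lambda(ball field) - Lambda_measured`
#' is positive semi-definite; for direction `-1` the mirrored difference is
#' tested; `"both"` flags a ball if either directional test passes. The
#' per-triangle mask flags a triangle iff its centroid lies inside any
#' flagged ball.
#'
#' @param lambda_measured Measured NtD matrix (same mesh/electrode basis as
#'   the precomputed operators).
#' @param mesh An `eit_mesh`.
#' @param balls Tibble from [ball_grid()].
#' @param direction `+1`, `-1`, or `"both"`.
#' @param tol PSD tolerance (see [is_psd()]); the test is noise-sensitive
#'   through this value.
#' @param ball_ntds_pos,ball_ntds_neg Optional precomputed operator lists
#'   (from [precompute_ball_ntds()] with positive / negative contrast);
#'   computed on the fly when missing.
#' @param contrast_pos,contrast_neg Test contrasts used when operators are
#'   computed here (defaults +1.0 and -0.5).
#' @return An `eit_monotonicity_result`: list with `balls` (tibble plus
#'   `flag` and `margin` columns), `mask` (per-triangle logical), and the
#'   call parameters.
#' @export
monotonicity_reconstruct <- function(lambda_measured, mesh, balls = ball_grid(),
                                     direction = "both", tol = 1e-10,
                                     ball_ntds_pos = NULL, ball_ntds_neg = NULL,
                                     contrast_pos = 1, contrast_neg = -0.5) {
  stopifnot(inherits(mesh, "eit_mesh"))
  dirs <- if (identical(direction, "both")) c(1, -1) else as.numeric(direction)
  flags <- rep(FALSE, nrow(balls))
  margins <- rep(-Inf, nrow(balls))
  for (d in dirs) {
    ops <- if (d > 0) ball_ntds_pos else ball_ntds_neg
    if (is.null(ops)) {
      ops <- precompute_ball_ntds(mesh, balls,
                                  contrast = if (d > 0) contrast_pos else contrast_neg)
    }
    for (i in seq_len(nrow(balls))) {
      Dm <- if (d > 0) ops[[i]] - lambda_measured else lambda_measured - ops[[i]]
      r <- is_psd(Dm, tol)
      if (r$psd) flags[i] <- TRUE
      margins[i] <- max(margins[i], r$margin)
    }
  }
  cents <- triangle_centroids(mesh)
  mask <- rep(FALSE, nrow(mesh$triangles))
  for (i in which(flags)) {
    mask <- mask | ((cents$x - balls$cx[i])^2 + (cents$y - balls$cy[i])^2 < balls$radius[i]^2)
  }
  structure(list(balls = dplyr::mutate(balls, flag = flags, margin = margins),
                 mask = mask, direction = direction, tol = tol),
            class = "eit_monotonicity_result")
}

#' @export
print.eit_monotonicity_result <- function(x, ...) {
  cat(sprintf("<eit_monotonicity_result> %d/%d balls flagged, %d triangles masked\n",
              sum(x$balls$flag), nrow(x$balls), sum(x$mask)))
  invisible(x)
}
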