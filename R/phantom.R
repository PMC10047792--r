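#' Circular-anomaly phantom
#'
#' A phantom is a set of circular inclusions over a constant unit background:
#' a tibble with columns `cx`, `cy`, `radius`, `conductivity` (one row per
#' circle) carrying class `eit_phantom`. Zero rows is the homogeneous field.
#'
#' @param cx,cy,radius,conductivity Equal-length numeric vectors describing
#'   the circles; later rows override earlier ones where circles overlap.
#' @param margin Containment margin: every circle must satisfy
#'   `sqrt(cx^2+cy^2) + radius <= 1 - margin`.
#' @return An `eit_phantom` tibble.
#' @export
phantom <- function(cx = numeric(), cy = numeric(), radius = numeric(),
                    conductivity = numeric(), margin = 0.05) {
  ph <- tibble::tibble(cx = as.numeric(cx), cy = as.numeric(cy),
                       radius = as.numeric(radius),
                       conductivity = as.numeric(conductivity))
  if (nrow(ph) > 4L) stop("at most 4 circular anomalies", call. = FALSE)
  if (nrow(ph) > 0L) {
    if (any(ph$radius <= 0)) stop("radius must be positive", call. = FALSE)
    if (any(ph$conductivity <= 0)) stop("conductivity must be positive", call. = FALSE)
    if (any(sqrt(ph$cx^2 + ph$cy^2) + ph$radius > 1 - margin + 1e-12)) {
      stop("every circle must lie inside the disk with margin", call. = FALSE)
    }
  }
  class(ph) <- c("eit_phantom", class(ph))
  attr(ph, "background") <- 1
  ph
}

#' Draw a random phantom
#'
#' Radii are Uniform(0.1, 0.35); centres uniform over the sub-disk where the
#' circle fits with margin 0.05; conductivities log-uniform on [0.2, 5] with
#' the dead zone (0.8, 1.25) around the unit background excluded, so every
#' inclusion has a workable contrast.
#'
#' @param n_anomalies Number of circles, 0 to 4 (0 gives the homogeneous
#'   phantom, used by fixtures).
#' @return An `eit_phantom`. Deterministic given the RNG state.
#' @export
sample_phantom <- function(n_anomalies) {
  stopifnot(n_anomalies >= 0, n_anomalies <= 4)
  n <- as.integer(n_anomalies)
  if (n == 0L) return(phantom())
  r <- stats::runif(n, 0.1, 0.35)
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    rmax <- 1 - 0.05 - r[i]
    repeat {
      p <- stats::runif(2, -rmax, rmax)
      if (sum(p^2) <= rmax^2) break
    }
    cx[i] <- p[1]; cy[i] <- p[2]
  }
  # log-uniform with dead zone: sample until outside (0.8, 1.25)
  cond <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      s <- exp(stats::runif(1, log(0.2), log(5)))
      if (s <= 0.8 || s >= 1.25) break
    }
    cond[i] <- s
  }
  phantom(cx, cy, r, cond)
}

#' Rasterize a phantom onto a mesh
#'
#' A triangle takes a circle's conductivity iff its centroid lies inside the
#' circle; on overlap, later circles in the list override earlier ones.
#' Everything else is the unit background.
#'
#' @param ph An `eit_phantom`.
#' @param mesh An `eit_mesh`.
#' @return An `eit_field`.
#' @export
rasterize <- function(ph, mesh) {
  stopifnot(inherits(ph, "eit_phantom"), inherits(mesh, "eit_mesh"))
  cc <- triangle_centroids(mesh)
  sigma <- rep.int(attr(ph, "background"), nrow(mesh$triangles))
  for (i in seq_len(nrow(ph))) {
    inside <- (cc$x - ph$cx[i])^2 + (cc$y - ph$cy[i])^2 < ph$radius[i]^2
    sigma[inside] <- ph$conductivity[i]
  }
  conductivity_field(mesh, sigma)
}

#' Continuous-domain anomaly labels
#'
#' Labels points of the closed unit disk: 1 iff strictly inside at least one
#' circle, else 0. Mesh-independent — this is the ground truth every
#' classifier and mask is scored against.
#'
#' @param ph An `eit_phantom`.
#' @param x,y Point coordinates (vectors of equal length).
#' @return Integer vector of 0/1 labels.
#' @export
label_point <- function(ph, x, y) {
  stopifnot(inherits(ph, "eit_phantom"))
  if (any(x^2 + y^2 > 1 + 1e-9)) stop("points must lie in the closed unit disk", call. = FALSE)
  lab <- rep.int(0L, length(x))
  for (i in seq_len(nrow(ph))) {
    lab[(x - ph$cx[i])^2 + (y - ph$cy[i])^2 < ph$radius[i]^2] <- 1L
  }
  lab
}

# total anomaly area (union of circles) by a deterministic quasi-MC grid;
# exact enough for the sanity checks that need it
phantom_anomaly_area <- function(ph, n_grid = 400L) {
  g <- seq(-1, 1, length.out = n_grid)
  gx <- rep(g, each = n_grid); gy <- rep(g, n_grid)
  inside_disk <- gx^2 + gy^2 <= 1
  lab <- label_point(ph, gx[inside_disk], gy[inside_disk])
  mean(lab) * pi  # fraction of disk area
}

#' Stratified labelled point cloud
#'
#' Draws exactly `n_per_stratum` points uniformly from the background region
#' and `n_per_stratum` from the anomalous region (rejection sampling against
#' the circle membership rule), then shuffles. This balanced sampling is what
#' makes small inclusions learnable.
#'
#' @param ph An `eit_phantom` with nonempty anomaly region when
#'   `n_per_stratum > 0`.
#' @param n_per_stratum Points per class (512 for the reference protocol,
#'   giving clouds of 1024).
#' @return A tibble with columns `x`, `y`, `label`.
#' @export
sample_point_cloud <- function(ph, n_per_stratum = 512L) {
  stopifnot(inherits(ph, "eit_phantom"))
  n <- as.integer(n_per_stratum)
  if (n == 0L) return(tibble::tibble(x = numeric(), y = numeric(), label = integer()))
  if (nrow(ph) == 0L) stop("phantom has no anomaly region to sample", call. = FALSE)
  draw_uniform_disk <- function(k) {
    th <- stats::runif(k, 0, 2 * pi)
    r <- sqrt(stats::runif(k))
    cbind(r * cos(th), r * sin(th))
  }
  sample_stratum <- function(target_label) {
    got_x <- got_y <- numeric(0)
    # anomaly stratum: draw inside the circles directly (rejecting overlap
    # double-counting via uniform-over-union rejection) -- much faster than
    # rejecting from the whole disk for small inclusions
    while (length(got_x) < n) {
      k <- max(64L, 2L * (n - length(got_x)))
      if (target_label == 1L) {
        wt <- ph$radius^2
        ci <- sample.int(nrow(ph), k, replace = TRUE, prob = wt)
        th <- stats::runif(k, 0, 2 * pi); r <- ph$radius[ci] * sqrt(stats::runif(k))
        px <- ph$cx[ci] + r * cos(th); py <- ph$cy[ci] + r * sin(th)
        # uniform over the union: accept a point with prob 1/(number of
        # circles covering it)
        cover <- rep.int(0L, k)
        for (i in seq_len(nrow(ph))) {
          cover <- cover + as.integer((px - ph$cx[i])^2 + (py - ph$cy[i])^2 < ph$radius[i]^2)
        }
        keep <- cover >= 1L & stats::runif(k) < 1 / pmax(cover, 1L)
      } else {
        p <- draw_uniform_disk(k)
        px <- p[, 1]; py <- p[, 2]
        keep <- label_point(ph, px, py) == 0L
      }
      got_x <- c(got_x, px[keep]); got_y <- c(got_y, py[keep])
    }
    tibble::tibble(x = got_x[seq_len(n)], y = got_y[seq_len(n)],
                   label = rep.int(target_label, n))
  }
  out <- dplyr::bind_rows(sample_stratum(0L), sample_stratum(1L))
  out[sample.int(nrow(out)), ]
}

#' Noise specification
#' @param delta Noise level in percent (>= 0).
#' @return An `eit_noise_spec`.
#' @export
noise_spec <- function(delta) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  structure(list(delta = delta), class = "eit_noise_spec")
}

#' Add Gaussian measurement noise
#'
#' Perturbs a clean measurement vector with i.i.d. Gaussian noise of standard
#' deviation `max(|m|) * delta / 100` (max magnitude over the entries of the
#' clean vector; under this package's pair-orientation convention all
#' adjacent-pair differences are negative, so the magnitude is the only
#' well-defined scale). `delta = 0` returns the input unchanged.
#'
#' @param m An `eit_measurement` (or plain numeric vector).
#' @param spec An `eit_noise_spec`, or a bare percentage.
#' @return Noisy measurement of the same class/attributes.
#' @export
add_noise <- function(m, spec) {
  if (!inherits(spec, "eit_noise_spec")) spec <- noise_spec(spec)
  if (spec$delta == 0) return(m)
  sd <- max(abs(as.numeric(m))) * spec$delta / 100
  noisy <- as.numeric(m) + stats::rnorm(length(m), 0, sd)
  attributes(noisy) <- attributes(m)
  noisy
}

#' Fit 0-1 normalization statistics from training data
#'
#' Measurements are scaled by a single global min/max over every entry of the
#' training measurement matrix; points are mapped per coordinate from
#' `[-1, 1]` to `[0, 1]`. Statistics are fitted on the training split only
#' and then frozen.
#'
#' @param measurements Numeric matrix (records x 208) or list of measurement
#'   vectors from the training split.
#' @param per_channel Use one min/max per measurement channel instead of the
#'   default single global pair ("the maximum-minimum", singular, is the
#'   reference reading; per-channel is offered behind this flag).
#' @return An `eit_norm_stats`.
#' @export
fit_normalization <- function(measurements, per_channel = FALSE) {
  if (is.list(measurements)) measurements <- do.call(rbind, lapply(measurements, as.numeric))
  if (length(measurements) == 0L) stop("empty training set", call. = FALSE)
  if (per_channel) {
    lo <- apply(measurements, 2, min); hi <- apply(measurements, 2, max)
  } else {
    lo <- min(measurements); hi <- max(measurements)
  }
  if (any(hi <= lo)) stop("degenerate training data: max equals min", call. = FALSE)
  structure(list(m_min = lo, m_max = hi, p_min = c(-1, -1), p_max = c(1, 1)),
            class = "eit_norm_stats")
}

#' Apply measurement normalization
#' @param m Measurement vector/matrix.
#' @param stats An `eit_norm_stats`.
#' @return `(m - min) / (max - min)`; values outside the training range map
#'   outside `[0, 1]` (affine, never clipped).
#' @export
normalize_measurement <- function(m, stats) {
  (as.numeric(m) - stats$m_min) / (stats$m_max - stats$m_min)
}

#' Apply point normalization
#' @param xy Two-column matrix of points in the unit disk.
#' @param stats An `eit_norm_stats`.
#' @return Matrix mapped per coordinate from `[-1, 1]` to `[0, 1]`.
#' @export
normalize_points <- function(xy, stats) {
  xy <- rbind(xy)
  sweep(sweep(xy, 2, stats$p_min, "-"), 2, stats$p_max - stats$p_min, "/")
}

#' Build a simulated dataset
#'
#' Draws phantoms (equal numbers per anomaly count 1..4), rasterizes them on
#' `mesh`, and solves the forward problem for each to get clean measurement
#' vectors. Records are seeded individually so any record can be regenerated
#' bit-exactly from the master seed.
#'
#' @param n_total Total number of records (divided equally over anomaly
#'   counts 1..4; the reference composition is 16384 train / 1024 val).
#' @param mesh An `eit_mesh`.
#' @param master_seed Integer master seed.
#' @param split Split tag stored on each record.
#' @return An `eit_dataset` tibble with columns `id`, `split`, `seed`,
#'   `n_anomalies`, `phantom` (list), `m` (list of clean measurements).
#' @export
build_dataset <- function(n_total, mesh, master_seed = 1L, split = "train") {
  stopifnot(inherits(mesh, "eit_mesh"), n_total >= 4)
  per <- n_total %/% 4L
  counts <- rep(per, 4L)
  counts[seq_len(n_total - 4L * per)] <- counts[seq_len(n_total - 4L * per)] + 1L
  n_anom <- rep(1:4, counts)
  seeds <- as.integer((as.numeric(master_seed) * 100003 + seq_along(n_anom)) %% 2147483647)
  recs <- purrr::map2(n_anom, seeds, function(na, sd) {
    set.seed(sd)
    ph <- sample_phantom(na)
    m <- measure(rasterize(ph, mesh))
    list(phantom = ph, m = m)
  })
  out <- tibble::tibble(
    id = seq_along(recs), split = split, seed = seeds, n_anomalies = n_anom,
    phantom = purrr::map(recs, "phantom"), m = purrr::map(recs, "m"))
  class(out) <- c("eit_dataset", class(out))
  attr(out, "mesh_h") <- mesh$h
  out
}

#' Scripted fixture phantoms
#'
#' A deterministic pack of five handcrafted phantoms used across the
#' cross-module tests: one centred inclusion; two disjoint inclusions (one
#' conductive, one resistive); three inclusions; a cluster of four; and the
#' homogeneous control.
#'
#' @return Named list of `eit_phantom`s.
#' @export
make_fixtures <- function() {
  list(
    single = phantom(0.25, 0.1, 0.3, 2),
    pair = phantom(c(-0.45, 0.45), c(0.35, -0.35), c(0.22, 0.22), c(2, 0.5)),
    triple = phantom(c(-0.5, 0.45, 0.05), c(0, 0.35, -0.5), c(0.18, 0.2, 0.15),
                     c(3, 0.4, 2)),
    cluster = phantom(c(-0.35, 0.35, 0.35, -0.35), c(0.35, 0.35, -0.35, -0.35),
                      c(0.16, 0.16, 0.16, 0.16), c(2, 2.5, 0.45, 3)),
    homogeneous = phantom()
  )
}

#' Phantom JSON exchange
#' @param ph An `eit_phantom`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom_json <- function(ph, path) {
  circles <- purrr::pmap(ph, function(cx, cy, radius, conductivity) {
    list(center = c(cx, cy), radius = radius, conductivity = conductivity)
  })
  jsonlite::write_json(circles, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  circles <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(circles) == 0L) return(phantom())
  phantom(
    cx = vapply(circles, function(c) c$center[[1]], numeric(1)),
    cy = vapply(circles, function(c) c$center[[2]], numeric(1)),
    radius = vapply(circles, function(c) c$radius, numeric(1)),
    conductivity = vapply(circles, function(c) c$conductivity, numeric(1))
  )
}
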