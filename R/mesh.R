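#' Domain specification for the EIT disk problem
#'
#' Describes the imaging domain: the unit disk with `L` point electrodes
#' equispaced on its boundary. The dimension field accepts 2 or 3 so that
#' point-cloud types generalise, but mesh construction is 2-D only.
#'
#' @param d Spatial dimension, 2 or 3 (meshing requires 2).
#' @param radius Disk radius; fixed at 1 for all experiments.
#' @param n_electrodes Number of boundary electrodes `L` (>= 4).
#' @return An object of class `eit_domain_spec`.
#' @export
disk_spec <- function(d = 2L, radius = 1, n_electrodes = 16L) {
  if (!d %in% c(2L, 3L)) stop("dimension must be 2 or 3", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (n_electrodes < 4) stop("need at least 4 electrodes", call. = FALSE)
  structure(
    list(d = as.integer(d), radius = radius, n_electrodes = as.integer(n_electrodes)),
    class = "eit_domain_spec"
  )
}

#' Triangulate the unit disk
#'
#' Places nodes on concentric rings (ring `i` of `M` at radius `i/M`, with
#' node count proportional to circumference so edges are close to `h`
#' everywhere) and Delaunay-triangulates them. The outer-ring node count is
#' rounded to a multiple of `L` so each electrode angle `2*pi*k/L` lands
#' exactly on a boundary node. Electrode `k`'s right-hand neighbour is
#' electrode `(k+1) %% L`, counterclockwise.
#'
#' @param spec An `eit_domain_spec` (only `d = 2` supported).
#' @param h Target edge length, `0 < h < 1`.
#' @return An `eit_mesh`: list with `nodes` (N x 2), `triangles` (T x 3,
#'   1-based rows, counterclockwise), `boundary_nodes` (counterclockwise
#'   order), `electrode_nodes` (length `L`), `h`, and `spec`.
#' @export
build_disk_mesh <- function(spec = disk_spec(), h = 0.08) {
  if (!inherits(spec, "eit_domain_spec")) stop("spec must be an eit_domain_spec", call. = FALSE)
  if (spec$d != 2L) stop("mesh construction requires d = 2", call. = FALSE)
  if (h <= 0 || h >= 1) stop("h must lie in (0, 1)", call. = FALSE)
  L <- spec$n_electrodes
  M <- max(2L, as.integer(round(1 / h)))
  # the boundary must naturally host L distinct electrode nodes at spacing h
  if (round(2 * pi * spec$radius / h) < L) {
    stop("h too large to resolve the electrode spacing (fewer boundary nodes than electrodes)",
         call. = FALSE)
  }
  xs <- 0; ys <- 0
  ring_id <- 0L
  for (i in seq_len(M)) {
    r <- i / M
    if (i < M) {
      n_i <- max(6L, as.integer(round(6 * i)))
    } else {
      n_i <- max(L, as.integer(round(6 * M / L)) * L)
    }
    # stagger alternate rings by half a spacing for better-shaped triangles
    off <- if (i %% 2L == 0L) 0 else pi / n_i
    if (i == M) off <- 0  # electrodes must sit exactly at 2*pi*k/L
    th <- 2 * pi * (seq_len(n_i) - 1L) / n_i + off
    rr <- rep.int(r, n_i)
    if (i < M) {
      # break exact co-circularity (degenerate for Delaunay) with a tiny
      # deterministic radial ripple; boundary ring stays exact
      rr <- r * (1 + 1e-4 * cos(3 * th + i))
      th <- th + 1e-3 * (2 * pi / n_i) * sin(5 * th + 2 * i)
    }
    xs <- c(xs, rr * cos(th)); ys <- c(ys, rr * sin(th))
    ring_id <- c(ring_id, rep.int(i, n_i))
  }
  n_outer <- sum(ring_id == M)
  dd <- deldir::deldir(xs, ys)
  tri <- deldir::triMat(dd)
  # enforce counterclockwise orientation
  a <- signed_areas(cbind(xs, ys), tri)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  boundary <- which(ring_id == M)
  ang <- atan2(ys[boundary], xs[boundary])
  boundary <- boundary[order(ang %% (2 * pi))]
  # nearest boundary node to each electrode angle (exact by construction)
  el_ang <- 2 * pi * (seq_len(L) - 1L) / L
  bnd_ang <- atan2(ys[boundary], xs[boundary]) %% (2 * pi)
  electrode_nodes <- vapply(el_ang, function(a) {
    d <- pmin(abs(bnd_ang - a), 2 * pi - abs(bnd_ang - a))
    boundary[which.min(d)]
  }, integer(1))
  if (anyDuplicated(electrode_nodes)) {
    stop("h too large to resolve the electrode spacing (duplicate electrode nodes)",
         call. = FALSE)
  }
  structure(
    list(nodes = cbind(x = xs, y = ys), triangles = tri,
         boundary_nodes = boundary, electrode_nodes = electrode_nodes,
         h = h, spec = spec),
    class = "eit_mesh"
  )
}

signed_areas <- function(nodes, tri) {
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Triangle centroids of a mesh
#'
#' @param mesh An `eit_mesh`.
#' @return A tibble with columns `triangle`, `x`, `y` — the vertex-mean
#'   centre of every triangle. All centroids lie strictly inside the disk.
#' @export
triangle_centroids <- function(mesh) {
  stopifnot(inherits(mesh, "eit_mesh"))
  tri <- mesh$triangles
  cx <- (mesh$nodes[tri[, 1], 1] + mesh$nodes[tri[, 2], 1] + mesh$nodes[tri[, 3], 1]) / 3
  cy <- (mesh$nodes[tri[, 1], 2] + mesh$nodes[tri[, 2], 2] + mesh$nodes[tri[, 3], 2]) / 3
  tibble::tibble(triangle = seq_len(nrow(tri)), x = unname(cx), y = unname(cy))
}

#' Triangle areas of a mesh
#' @param mesh An `eit_mesh`.
#' @return Numeric vector of (positive) triangle areas.
#' @export
triangle_areas <- function(mesh) {
  stopifnot(inherits(mesh, "eit_mesh"))
  abs(signed_areas(mesh$nodes, mesh$triangles))
}

# T x 3 matrix of edge keys ("lo-hi" node pairs) per triangle
triangle_edge_keys <- function(tri) {
  e1 <- pmin(tri[, 1], tri[, 2]) * 1e7 + pmax(tri[, 1], tri[, 2])
  e2 <- pmin(tri[, 2], tri[, 3]) * 1e7 + pmax(tri[, 2], tri[, 3])
  e3 <- pmin(tri[, 1], tri[, 3]) * 1e7 + pmax(tri[, 1], tri[, 3])
  cbind(e1, e2, e3)
}

#' Edge-connected components of a flagged triangle set
#'
#' Two triangles are adjacent iff they share a full edge (shared vertices do
#' not connect). Components are ordered by their smallest triangle index.
#'
#' @param mesh An `eit_mesh`.
#' @param element_flags Logical vector, one entry per triangle.
#' @return List of integer vectors, each a sorted set of triangle indices;
#'   together they partition `which(element_flags)`.
#' @export
connected_components <- function(mesh, element_flags) {
  stopifnot(inherits(mesh, "eit_mesh"))
  if (length(element_flags) != nrow(mesh$triangles)) {
    stop("element_flags must have one entry per triangle", call. = FALSE)
  }
  idx <- which(as.logical(element_flags))
  if (length(idx) == 0L) return(list())
  keys <- triangle_edge_keys(mesh$triangles[idx, , drop = FALSE])
  ek <- data.frame(key = as.vector(keys), tri = rep(seq_along(idx), 3L))
  sp <- split(ek$tri, ek$key)
  pairs <- sp[lengths(sp) == 2L]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(pairs)) {
    g <- igraph::add_edges(g, unlist(pairs, use.names = FALSE))
  }
  memb <- igraph::components(g)$membership
  comps <- split(idx, memb)
  comps <- lapply(unname(comps), sort)
  comps[order(vapply(comps, min, numeric(1)))]
}

#' Export a mesh as plain text
#'
#' Writes a human-readable node list and triangle list (two whitespace
#' separated blocks) for inspection or exchange.
#'
#' @param mesh An `eit_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_text <- function(mesh, path) {
  stopifnot(inherits(mesh, "eit_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# eit_mesh h=%g nodes=%d triangles=%d electrodes=%d",
                     mesh$h, nrow(mesh$nodes), nrow(mesh$triangles),
                     length(mesh$electrode_nodes)), con)
  writeLines("nodes", con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines("triangles", con)
  utils::write.table(mesh$triangles, con, row.names = FALSE, col.names = FALSE)
  writeLines("boundary_nodes", con)
  writeLines(paste(mesh$boundary_nodes, collapse = " "), con)
  writeLines("electrode_nodes", con)
  writeLines(paste(mesh$electrode_nodes, collapse = " "), con)
  invisible(path)
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("<eit_mesh> %d nodes, %d triangles, h = %g, %d electrodes\n",
              nrow(x$nodes), nrow(x$triangles), x$h, length(x$electrode_nodes)))
  invisible(x)
}
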