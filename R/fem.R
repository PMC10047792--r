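#' Per-triangle conductivity field
#'
#' Piecewise-constant (P0) conductivity on a triangular mesh. Values must lie
#' inside the admissible band `[sigma_lo, sigma_hi]`; the defaults bracket the
#' unit background generously.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Numeric vector, one positive value per triangle (a scalar is
#'   recycled).
#' @param sigma_lo,sigma_hi Admissible conductivity bounds.
#' @return An `eit_field`.
#' @export
conductivity_field <- function(mesh, sigma = 1, sigma_lo = 0.05, sigma_hi = 20) {
  stopifnot(inherits(mesh, "eit_mesh"))
  nt <- nrow(mesh$triangles)
  if (length(sigma) == 1L) sigma <- rep.int(sigma, nt)
  if (length(sigma) != nt) stop("sigma must have one value per triangle", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("conductivity must be positive and finite", call. = FALSE)
  }
  if (any(sigma < sigma_lo - 1e-12) || any(sigma > sigma_hi + 1e-12)) {
    stop(sprintf("conductivity outside admissible band [%g, %g]", sigma_lo, sigma_hi),
         call. = FALSE)
  }
  structure(list(mesh = mesh, sigma = as.numeric(sigma),
                 sigma_lo = sigma_lo, sigma_hi = sigma_hi),
            class = "eit_field")
}

#' Adjacent source-sink injection pattern
#'
#' @param source,sink 0-based electrode indices, distinct.
#' @param amplitude Injected current (default 1).
#' @param L Number of electrodes (for validation).
#' @return An `eit_pattern`.
#' @export
injection_pattern <- function(source, sink, amplitude = 1, L = 16L) {
  source <- as.integer(source); sink <- as.integer(sink)
  if (source == sink) stop("source and sink must differ", call. = FALSE)
  if (source < 0 || source >= L || sink < 0 || sink >= L) {
    stop("electrode index out of range", call. = FALSE)
  }
  structure(list(source = source, sink = sink, amplitude = amplitude, L = as.integer(L)),
            class = "eit_pattern")
}

# Element geometry used by both assembly and gradient evaluation:
# for each triangle, barycentric gradient matrix (2 x 3) and area.
element_geometry <- function(mesh) {
  tri <- mesh$triangles
  x <- matrix(mesh$nodes[t(tri), 1], nrow = 3)  # 3 x T
  y <- matrix(mesh$nodes[t(tri), 2], nrow = 3)
  # gradients of P1 basis: grad phi_i = perp of opposite edge / (2A)
  bx <- rbind(y[2, ] - y[3, ], y[3, ] - y[1, ], y[1, ] - y[2, ])
  by <- rbind(x[3, ] - x[2, ], x[1, ] - x[3, ], x[2, ] - x[1, ])
  area2 <- (x[2, ] - x[1, ]) * (y[3, ] - y[1, ]) - (x[3, ] - x[1, ]) * (y[2, ] - y[1, ])
  list(bx = bx, by = by, area = area2 / 2)
}

#' Assemble the P1 stiffness matrix
#'
#' Standard linear finite-element stiffness matrix for `div(sigma grad u)`
#' with piecewise-constant conductivity: symmetric, positive semi-definite,
#' with the constants as null space (pure Neumann problem).
#'
#' @param field An `eit_field`.
#' @return A sparse symmetric `dgCMatrix` of size nodes x nodes.
#' @export
assemble_stiffness <- function(field) {
  stopifnot(inherits(field, "eit_field"))
  mesh <- field$mesh
  geo <- element_geometry(mesh)
  tri <- mesh$triangles
  nt <- nrow(tri)
  coef <- field$sigma / (4 * geo$area)  # sigma/(4A); local K = coef * (b bT)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- tri[, a]
    jj[[k]] <- tri[, b]
    vv[[k]] <- coef * (geo$bx[a, ] * geo$bx[b, ] + geo$by[a, ] * geo$by[b, ])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = rep(nrow(mesh$nodes), 2L))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# Grounded system: pure-Neumann stiffness augmented with a Lagrange
# multiplier row/column enforcing zero mean over the boundary nodes.
# Returns a reusable factorization closure: solve(B) for multi-RHS.
grounded_factorization <- function(field) {
  mesh <- field$mesh
  K <- assemble_stiffness(field)
  n <- nrow(mesh$nodes)
  bn <- mesh$boundary_nodes
  c_vec <- Matrix::sparseMatrix(i = bn, j = rep(1L, length(bn)),
                                x = rep(1 / length(bn), length(bn)),
                                dims = c(n, 1L))
  A <- rbind(cbind(K, c_vec), cbind(Matrix::t(c_vec), Matrix::Matrix(0, 1, 1, sparse = TRUE)))
  A <- methods::as(A, "CsparseMatrix")
  lu <- Matrix::lu(A)
  function(B) {
    B <- as.matrix(B)
    Baug <- rbind(B, matrix(0, 1L, ncol(B)))
    U <- as.matrix(Matrix::solve(lu, Baug))
    U[seq_len(n), , drop = FALSE]
  }
}

pattern_load <- function(mesh, pattern) {
  n <- nrow(mesh$nodes)
  b <- numeric(n)
  src <- mesh$electrode_nodes[pattern$source + 1L]
  snk <- mesh$electrode_nodes[pattern$sink + 1L]
  b[src] <- b[src] + pattern$amplitude
  b[snk] <- b[snk] - pattern$amplitude
  b
}

#' Solve one injection pattern
#'
#' Solves the grounded Neumann problem with unit current entering at the
#' source electrode node and leaving at the sink node (point-electrode
#' model). The returned potential has zero mean over the boundary nodes.
#'
#' @param field An `eit_field`.
#' @param pattern An `eit_pattern`.
#' @return An `eit_solution`: list with `u` (nodal potentials) and `pattern`.
#' @export
solve_pattern <- function(field, pattern) {
  stopifnot(inherits(field, "eit_field"), inherits(pattern, "eit_pattern"))
  solver <- grounded_factorization(field)
  b <- pattern_load(field$mesh, pattern)
  u <- drop(solver(matrix(b, ncol = 1L)))
  structure(list(u = u, pattern = pattern), class = "eit_solution")
}

# all L adjacent source-sink patterns, solved with one factorization;
# returns nodal potential matrix (nodes x L), column s+1 = source electrode s
solve_all_patterns <- function(field, amplitude = 1) {
  mesh <- field$mesh
  L <- mesh$spec$n_electrodes
  solver <- grounded_factorization(field)
  B <- vapply(seq_len(L) - 1L, function(s) {
    pattern_load(mesh, injection_pattern(s, (s + 1L) %% L, amplitude, L))
  }, numeric(nrow(mesh$nodes)))
  solver(B)
}

# measurement bookkeeping: for drive pattern s (0-based), the recorded
# adjacent pairs (k, k+1 mod L) are those with {k, k+1} disjoint from
# {s, s+1}; L-3 pairs per pattern, pattern-major ordering.
measurement_pairs <- function(L) {
  out <- vector("list", L)
  for (s in seq_len(L) - 1L) {
    drive <- c(s, (s + 1L) %% L)
    ks <- Filter(function(k) !(k %in% drive) && !(((k + 1L) %% L) %in% drive),
                 seq_len(L) - 1L)
    out[[s + 1L]] <- tibble::tibble(pattern = s, pair = unlist(ks))
  }
  dplyr::bind_rows(out)
}

#' Simulate the adjacent-pair measurement vector
#'
#' Runs all `L` adjacent source-sink injections and records the voltage
#' difference `u(electrode k) - u(electrode k+1)` for every adjacent pair
#' containing neither drive electrode: `L - 3` values per pattern,
#' `L * (L - 3)` in total (208 for `L = 16`), concatenated pattern-major.
#'
#' @param field An `eit_field`.
#' @param amplitude Drive current amplitude.
#' @return An `eit_measurement`: numeric vector with attributes `L` and
#'   `pairs` (tibble of pattern/pair indices, 0-based).
#' @export
measure <- function(field, amplitude = 1) {
  stopifnot(inherits(field, "eit_field"))
  mesh <- field$mesh
  L <- mesh$spec$n_electrodes
  U <- solve_all_patterns(field, amplitude)
  Ue <- U[mesh$electrode_nodes, , drop = FALSE]           # L x L
  pairs <- measurement_pairs(L)
  vals <- Ue[cbind(pairs$pair + 1L, pairs$pattern + 1L)] -
    Ue[cbind((pairs$pair + 1L) %% L + 1L, pairs$pattern + 1L)]
  structure(as.numeric(vals), L = L, pairs = pairs, class = "eit_measurement")
}

#' Measurement vector as a one-row tibble
#'
#' Column names follow `p{pattern}_d{pair}` (0-based indices), the CSV
#' exchange layout: one row per experiment.
#'
#' @param m An `eit_measurement`.
#' @return A 1 x 208 tibble (for L = 16).
#' @export
measurement_tibble <- function(m) {
  pairs <- attr(m, "pairs")
  out <- tibble::as_tibble(as.list(stats::setNames(
    as.numeric(m), sprintf("p%d_d%d", pairs$pattern, pairs$pair))))
  out
}

#' Discrete Neumann-to-Dirichlet matrix
#'
#' The NtD operator restricted to the span of the `L - 1` mean-free
#' adjacent-pair current basis patterns `e_j - e_{j+1}` (j = 0..L-2): entry
#' (i, j) is the voltage response to basis current j evaluated against basis
#' current i. Symmetric by discrete reciprocity.
#'
#' @param field An `eit_field`.
#' @return An `(L-1) x (L-1)` numeric matrix with attribute
#'   `basis = "adjacent-pair"`.
#' @export
ntd_matrix <- function(field) {
  stopifnot(inherits(field, "eit_field"))
  mesh <- field$mesh
  L <- mesh$spec$n_electrodes
  solver <- grounded_factorization(field)
  n <- nrow(mesh$nodes)
  en <- mesh$electrode_nodes
  B <- matrix(0, n, L - 1L)
  for (j in seq_len(L - 1L)) {
    B[en[j], j] <- 1
    B[en[j + 1L], j] <- -1
  }
  U <- solver(B)
  Ue <- U[en, , drop = FALSE]
  Lam <- matrix(0, L - 1L, L - 1L)
  for (i in seq_len(L - 1L)) Lam[i, ] <- Ue[i, ] - Ue[i + 1L, ]
  Lam <- (Lam + t(Lam)) / 2
  attr(Lam, "basis") <- "adjacent-pair"
  Lam
}

#' Jacobian of the measurement map
#'
#' Exact derivative of [measure()] with respect to each triangle's
#' conductivity, by the adjoint method: for measurement functional `l` and
#' drive solution `u`, `d m / d sigma_T = -area_T * grad(w)|_T . grad(u)|_T`
#' where `K w = l`. All 16 drive solves and 16 adjoint solves share one
#' factorization.
#'
#' @param field An `eit_field`.
#' @param amplitude Drive current amplitude.
#' @return Dense matrix, `L*(L-3)` rows (measurements) by `T` columns
#'   (triangles).
#' @export
jacobian <- function(field, amplitude = 1) {
  stopifnot(inherits(field, "eit_field"))
  mesh <- field$mesh
  L <- mesh$spec$n_electrodes
  n <- nrow(mesh$nodes)
  en <- mesh$electrode_nodes
  solver <- grounded_factorization(field)
  # drive solves
  Bd <- vapply(seq_len(L) - 1L, function(s) {
    pattern_load(mesh, injection_pattern(s, (s + 1L) %% L, amplitude, L))
  }, numeric(n))
  U <- solver(Bd)
  # adjoint solves: one per adjacent electrode pair (k, k+1)
  Ba <- matrix(0, n, L)
  for (k in seq_len(L)) {
    Ba[en[k], k] <- 1
    Ba[en[k %% L + 1L], k] <- -1
  }
  W <- solver(Ba)
  geo <- element_geometry(mesh)
  tri <- mesh$triangles
  grad_of <- function(V) {
    # returns list(gx, gy): T x ncol(V) per-triangle gradients
    v1 <- V[tri[, 1], , drop = FALSE]; v2 <- V[tri[, 2], , drop = FALSE]
    v3 <- V[tri[, 3], , drop = FALSE]
    inv2A <- 1 / (2 * geo$area)
    gx <- (geo$bx[1, ] * v1 + geo$bx[2, ] * v2 + geo$bx[3, ] * v3) * inv2A
    gy <- (geo$by[1, ] * v1 + geo$by[2, ] * v2 + geo$by[3, ] * v3) * inv2A
    list(gx = gx, gy = gy)
  }
  gu <- grad_of(U); gw <- grad_of(W)
  pairs <- measurement_pairs(L)
  J <- matrix(0, nrow(pairs), nrow(tri))
  for (r in seq_len(nrow(pairs))) {
    s <- pairs$pattern[r] + 1L
    k <- pairs$pair[r] + 1L
    J[r, ] <- -geo$area * (gw$gx[, k] * gu$gx[, s] + gw$gy[, k] * gu$gy[, s])
  }
  J
}

#' @export
print.eit_measurement <- function(x, ...) {
  cat(sprintf("<eit_measurement> %d values (L = %d), range [%.4g, %.4g]\n",
              length(x), attr(x, "L"), min(x), max(x)))
  invisible(x)
}
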