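# Shared fixtures: meshes are expensive enough to build once per test run.
coarse_mesh <- function() {
  if (is.null(.fixture_env$coarse)) .fixture_env$coarse <- build_disk_mesh(disk_spec(), 0.12)
  .fixture_env$coarse
}

training_mesh <- function() {
  if (is.null(.fixture_env$training)) .fixture_env$training <- build_disk_mesh(disk_spec(), 0.08)
  .fixture_env$training
}

.fixture_env <- new.env(parent = emptyenv())

# independent flood-fill oracle for connected components (edge adjacency),
# deliberately naive: repeated sweeps until no growth
flood_fill_components <- function(mesh, flags) {
  idx <- which(flags)
  if (length(idx) == 0L) return(list())
  tri <- mesh$triangles[idx, , drop = FALSE]
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- cbind(edge_key(tri[, 1], tri[, 2]),
                edge_key(tri[, 2], tri[, 3]),
                edge_key(tri[, 1], tri[, 3]))
  comp <- seq_along(idx)
  repeat {
    changed <- FALSE
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (comp[i] != comp[j] && length(intersect(keys[i, ], keys[j, ])) > 0) {
        old <- max(comp[i], comp[j]); new <- min(comp[i], comp[j])
        comp[comp == old] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unname(split(idx, comp)), sort)
  out[order(vapply(out, min, numeric(1)))]
}
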