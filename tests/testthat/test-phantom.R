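test_that("random phantoms satisfy the containment and contrast constraints", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    ph <- sample_phantom(n)
    expect_equal(nrow(ph), n)
    expect_true(all(sqrt(ph$cx^2 + ph$cy^2) + ph$radius <= 0.95 + 1e-12))
    expect_true(all(ph$radius >= 0.1 & ph$radius <= 0.35))
    expect_true(all(ph$conductivity >= 0.2 & ph$conductivity <= 5))
    expect_false(any(ph$conductivity > 0.8 & ph$conductivity < 1.25))
  }
  expect_equal(nrow(sample_phantom(0)), 0L)
})

test_that("rasterization follows the centroid membership rule", {
  mesh <- training_mesh()
  # empty phantom -> homogeneous field
  expect_true(all(rasterize(phantom(), mesh)$sigma == 1))
  # circle covering the whole disk
  big <- phantom(0, 0, 1, 2, margin = 0)
  expect_true(all(rasterize(big, mesh)$sigma == 2))
  # area fraction of a radius-0.3 circle: ~0.09 of the disk
  f <- rasterize(phantom(0, 0, 0.3, 2), mesh)
  frac <- sum(triangle_areas(mesh)[f$sigma == 2]) / sum(triangle_areas(mesh))
  expect_equal(frac, 0.09, tolerance = 0.15)
  # later circles override earlier ones on overlap
  ph <- phantom(c(0, 0.05), c(0, 0), c(0.3, 0.3), c(2, 3))
  f2 <- rasterize(ph, mesh)
  cents <- triangle_centroids(mesh)
  both <- (cents$x^2 + cents$y^2 < 0.3^2) & ((cents$x - 0.05)^2 + cents$y^2 < 0.3^2)
  expect_true(all(f2$sigma[both] == 3))
})

test_that("point labels implement strict circle membership on the continuous domain", {
  ph <- phantom(c(0.3, -0.4), c(0.2, -0.1), c(0.15, 0.2), c(2, 0.5))
  expect_equal(label_point(ph, 0.3, 0.2), 1L)       # centre
  expect_equal(label_point(ph, -0.95, 0), 0L)       # far boundary
  expect_equal(label_point(ph, 0.45, 0.2), 0L)      # just outside circle 1
  expect_error(label_point(ph, 1.2, 0), "disk")
  # Monte-Carlo positive fraction approximates the union area / pi
  set.seed(12)
  th <- stats::runif(30000, 0, 2 * pi); r <- sqrt(stats::runif(30000))
  frac <- mean(label_point(ph, r * cos(th), r * sin(th)))
  area <- (pi * 0.15^2 + pi * 0.2^2) / pi  # disjoint circles
  expect_equal(frac, area, tolerance = 0.08)
})

test_that("stratified clouds are balanced, label-consistent and angularly uniform", {
  ph <- phantom(0.2, -0.1, 0.3, 2)
  set.seed(13)
  pc <- sample_point_cloud(ph, 512)
  expect_equal(nrow(pc), 1024L)
  expect_equal(sum(pc$label == 1), 512L)
  expect_equal(label_point(ph, pc$x, pc$y), pc$label)
  expect_true(all(pc$x^2 + pc$y^2 <= 1))
  # background points should be angularly uniform (chi-square over 8 sectors)
  big <- dplyr::bind_rows(lapply(1:10, function(i) sample_point_cloud(ph, 512)))
  bg <- big[big$label == 0, ]
  sector <- cut(atan2(bg$y, bg$x), breaks = seq(-pi, pi, length.out = 9))
  # expected counts weighted by background area per sector are nonuniform
  # because of the inclusion; use the phantom-free control instead
  ph0 <- phantom(0, 0, 1e-3, 2, margin = 0)  # negligible inclusion
  ctrl <- dplyr::bind_rows(lapply(1:10, function(i) sample_point_cloud(ph0, 500)))
  cg <- ctrl[ctrl$label == 0, ]
  sec <- table(cut(atan2(cg$y, cg$x), breaks = seq(-pi, pi, length.out = 9)))
  expect_gt(stats::chisq.test(sec)$p.value, 0.01)
  # sampling from a phantom with no anomaly region errors
  expect_error(sample_point_cloud(phantom(), 10), "anomaly")
})

test_that("measurement noise follows the max-magnitude scaling", {
  mesh <- coarse_mesh()
  m <- measure(conductivity_field(mesh, 1))
  expect_identical(add_noise(m, 0), m)
  set.seed(14)
  draws <- replicate(8000, (add_noise(m, 1) - as.numeric(m))[c(1, 57)])
  target <- max(abs(as.numeric(m))) / 100
  expect_equal(stats::sd(draws[1, ]), target, tolerance = 0.03)
  expect_equal(stats::sd(draws[2, ]), target, tolerance = 0.03)
  expect_lt(abs(stats::cor(draws[1, ], draws[2, ])), 0.05)
  expect_equal(mean(draws[1, ]), 0, tolerance = 3 * target / sqrt(8000))
})

test_that("normalization maps training endpoints to 0/1 and never clips", {
  M <- rbind(c(-2, 0.5), c(1, 3))
  st <- fit_normalization(M)
  expect_equal(normalize_measurement(3, st), 1)
  expect_equal(normalize_measurement(-2, st), 0)
  expect_gt(normalize_measurement(4, st), 1)   # affine, not clipped
  expect_lt(normalize_measurement(-3, st), 0)
  expect_equal(as.numeric(normalize_points(cbind(0, 0), st)), c(0.5, 0.5))
  expect_equal(as.numeric(normalize_points(cbind(-1, 1), st)), c(0, 1))
  expect_error(fit_normalization(matrix(1, 2, 2)), "degenerate")
})

test_that("datasets are seed-reproducible with the reference composition rule", {
  mesh <- coarse_mesh()
  d1 <- build_dataset(8, mesh, 3L)
  d2 <- build_dataset(8, mesh, 3L)
  expect_identical(lapply(d1$m, as.numeric), lapply(d2$m, as.numeric))
  expect_equal(sort(table(d1$n_anomalies)), sort(table(c(1, 1, 2, 2, 3, 3, 4, 4))),
               ignore_attr = TRUE)
  d3 <- build_dataset(8, mesh, 4L)
  expect_false(identical(lapply(d1$m, as.numeric), lapply(d3$m, as.numeric)))
})

test_that("fixture pack is deterministic and valid", {
  fx <- make_fixtures()
  expect_length(fx, 5L)
  expect_equal(nrow(fx$homogeneous), 0L)
  for (ph in fx) {
    expect_s3_class(ph, "eit_phantom")
    if (nrow(ph) > 0) {
      expect_true(all(sqrt(ph$cx^2 + ph$cy^2) + ph$radius <= 0.95 + 1e-12))
    }
  }
  # conductive and resistive inclusion present in the pair fixture
  expect_true(any(fx$pair$conductivity > 1) && any(fx$pair$conductivity < 1))
})

test_that("phantom JSON round-trips", {
  ph <- make_fixtures()$triple
  path <- tempfile(fileext = ".json")
  write_phantom_json(ph, path)
  ph2 <- read_phantom_json(path)
  expect_equal(as.data.frame(ph), as.data.frame(ph2))
})

test_that("per-channel normalization is available behind its flag", {
  M <- rbind(c(-2, 10), c(0, 20))
  st <- fit_normalization(M, per_channel = TRUE)
  expect_length(st$m_min, 2L)
  expect_equal(normalize_measurement(c(-2, 10), st), c(0, 0))
  expect_equal(normalize_measurement(c(0, 20), st), c(1, 1))
})
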