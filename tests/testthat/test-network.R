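test_that("activation and softmax primitives match their closed forms", {
  expect_equal(leaky_relu(-2), -0.02)
  expect_equal(leaky_relu(0), 0)
  expect_equal(leaky_relu(3.5), 3.5)
  expect_equal(leaky_relu(c(-1, 2)), c(-0.01, 2))
  expect_equal(unname(softmax2(c(0, 0))), c(0.5, 0.5))
  expect_equal(unname(softmax2(c(1, 0))), c(0.7311, 0.2689), tolerance = 1e-4)
  big <- softmax2(c(1000, 0))
  expect_false(any(!is.finite(big)))
  expect_equal(unname(big), c(1, 0))
})

test_that("the classification rule is strict for background, ties to anomaly", {
  expect_equal(classify(c(0.7, 0.3)), 0L)
  expect_equal(classify(c(0.2, 0.8)), 1L)
  expect_equal(classify(c(0.5, 0.5)), 1L)
  expect_equal(classify(rbind(c(0.9, 0.1), c(0.4, 0.6))), c(0L, 1L))
})

test_that("ResNet blocks honour the shortcut contract", {
  slope <- 0.01
  # in == out, zero weights: identity shortcut survives
  p_same <- list(W1 = matrix(0, 4, 4), b1 = rep(0, 4),
                 W2 = matrix(0, 4, 4), b2 = rep(0, 4))
  x <- matrix(c(1, -2, 0.5, 3), 1)
  out <- eitshape:::block_forward(x, p_same, slope)
  expect_equal(as.numeric(out), leaky_relu(as.numeric(x)))
  # in != out, zero weights: linear shortcut collapses to zero
  p_diff <- list(W1 = matrix(0, 4, 6), b1 = rep(0, 6),
                 W2 = matrix(0, 6, 6), b2 = rep(0, 6),
                 Ws = matrix(0, 4, 6), bs = rep(0, 6))
  expect_equal(as.numeric(eitshape:::block_forward(x, p_diff, slope)), rep(0, 6))
  # random params, in == out: output recomposes from branch + input
  set.seed(21)
  p_rnd <- eitshape:::new_block_params(4, 4)
  branch <- leaky_relu(x %*% p_rnd$W1 + matrix(p_rnd$b1, 1)) %*% p_rnd$W2 +
    matrix(p_rnd$b2, 1)
  expect_equal(eitshape:::block_forward(x, p_rnd, slope),
               leaky_relu(branch + x, slope))
})

test_that("encoder/decoder dimensions follow the architecture tables", {
  for (s in c(1L, 2L)) {
    cfg <- network_config(s)
    p <- init_params(cfg, seed = 30 + s)
    me <- measure_encoder(matrix(stats::runif(208), 1), p)
    expect_equal(ncol(me), 64L * s)
    pe <- point_encoder(matrix(stats::runif(6), 3, 2), p)
    expect_equal(dim(pe), c(3L, 64L * s))
    q <- decode(pe, pe, p)
    expect_equal(dim(q), c(3L, 2L))
    expect_equal(rowSums(q), rep(1, 3), tolerance = 1e-12)
  }
  cfg <- network_config(2)
  p <- init_params(cfg, 1)
  expect_error(measure_encoder(matrix(1, 1, 100), p), "208")
  expect_error(point_encoder(matrix(1, 1, 3), p), "dimension")
})

test_that("decoding is symmetric in the two embeddings", {
  cfg <- network_config(1)
  p <- init_params(cfg, 41)
  a <- matrix(stats::runif(64), 1); b <- matrix(stats::runif(64), 1)
  expect_equal(decode(a, b, p), decode(b, a, p))
})

test_that("parameter counts are a deterministic function of scale", {
  counts <- vapply(c(1L, 2L, 4L), function(s) count_parameters(network_config(s)), numeric(1))
  # closed form: sum over blocks of in*out + out + out^2 + out (+ shortcut)
  closed_form <- function(s) {
    dims <- list(c(208, 128 * s), c(128 * s, 128 * s), c(128 * s, 128 * s),
                 c(128 * s, 64 * s), c(64 * s, 64 * s), c(64 * s, 64 * s),
                 c(2, 32 * s), c(32 * s, 64 * s),
                 c(64 * s, 32 * s), c(32 * s, 2))
    sum(vapply(dims, function(d) {
      n <- d[1] * d[2] + d[2] + d[2]^2 + d[2]
      if (d[1] != d[2]) n <- n + d[1] * d[2] + d[2]
      n
    }, numeric(1)))
  }
  expect_equal(counts, vapply(c(1L, 2L, 4L), closed_form, numeric(1)))
  # actual parameter arrays agree with the count
  for (s in c(1L, 2L)) {
    p <- init_params(network_config(s), 50)
    total <- sum(unlist(lapply(p, function(comp) lapply(comp, function(blk) {
      lapply(blk, length)
    }))))
    expect_equal(total, count_parameters(network_config(s)))
  }
})

test_that("amortized prediction equals per-point evaluation and is order-invariant", {
  cfg <- network_config(1)
  p <- init_params(cfg, 60)
  stats <- structure(list(m_min = -1, m_max = 1, p_min = c(-1, -1), p_max = c(1, 1)),
                     class = "eit_norm_stats")
  model <- implicit_model(p, stats, cfg)
  m <- stats::rnorm(208) * 0.1
  set.seed(61)
  pts <- cbind(stats::runif(50, -0.7, 0.7), stats::runif(50, -0.7, 0.7))
  all_pred <- predict_points(model, m, pts)
  one <- predict_points(model, m, pts[7, , drop = FALSE])
  expect_equal(one$prob_anomaly, all_pred$prob_anomaly[7], tolerance = 1e-12)
  # permutation invariance
  perm <- sample(50)
  perm_pred <- predict_points(model, m, pts[perm, ])
  expect_equal(perm_pred$prob_anomaly, all_pred$prob_anomaly[perm], tolerance = 1e-12)
  # labels are the classification of the probabilities
  expect_equal(all_pred$label,
               classify(cbind(1 - all_pred$prob_anomaly, all_pred$prob_anomaly)))
  # determinism
  expect_identical(predict_points(model, m, pts), all_pred)
})

test_that("model JSON serialization round-trips predictions exactly", {
  cfg <- network_config(1)
  p <- init_params(cfg, 70)
  stats <- structure(list(m_min = -2, m_max = 0.5, p_min = c(-1, -1), p_max = c(1, 1)),
                     class = "eit_norm_stats")
  model <- implicit_model(p, stats, cfg)
  path <- tempfile(fileext = ".json")
  write_model_json(model, path)
  model2 <- read_model_json(path)
  m <- stats::rnorm(208) * 0.05
  pts <- cbind(c(0.1, -0.4), c(0.2, 0.3))
  expect_equal(predict_points(model2, m, pts)$prob_anomaly,
               predict_points(model, m, pts)$prob_anomaly, tolerance = 1e-12)
})
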