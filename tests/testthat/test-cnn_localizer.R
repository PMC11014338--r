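test_that("the seven catalog structures chain and share the 1024-wide head", {
  expected_7 <- list(c(1, 2), c(2, 4), c(4, 8), c(8, 16), c(16, 32),
                     c(32, 32))
  s7 <- structure_spec(7)
  expect_equal(s7$channels, expected_7)
  for (id in 1:7) {
    s <- structure_spec(id)
    ins <- vapply(s$channels, `[`, 1, 1)
    outs <- vapply(s$channels, `[`, 1, 2)
    expect_identical(ins[1], 1)               # single-channel input
    expect_equal(ins[-1], outs[-6])           # chaining
    expect_identical(flatten_dim(s, 2048), 1024L)
    expect_identical(s$kernel, 3L)
    expect_identical(s$pool, 2L)
    expect_identical(s$pool_stride, 2L)
    expect_identical(s$fc_hidden, 512L)
  }
  expect_error(structure_spec(9), "1..7")
  expect_error(structure_spec(channels = list(c(1, 4), c(8, 16))), "chain")
})

test_that("depth variants recompute the flatten size as 32 * 2048 / 2^d", {
  flat <- vapply(3:10, function(d)
    flatten_dim(structure_spec(7, n_conv = d), 2048), 1L)
  expect_identical(flat, as.integer(32 * 2048 / 2^(3:10)))
  expect_identical(flat, c(8192L, 4096L, 2048L, 1024L, 512L, 256L, 128L, 64L))
})

test_that("smooth L1: knee continuity, zero point, linear tail, properties", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(1), 0.5)        # both branches agree at the knee
  expect_equal(smooth_l1(1 - 1e-9), 0.5, tolerance = 1e-6)
  expect_equal(smooth_l1(-3), 2.5)
  expect_equal(smooth_l1(c(0, 1, -3)), mean(c(0, 0.5, 2.5)))
  g <- seq(-4, 4, by = 0.01)
  v <- smooth_l1(g, reduce = "none")
  expect_true(all(v >= 0))
  expect_true(all(diff(v[g >= 0]) >= 0))          # monotone in |x|
  expect_true(all(abs(diff(v)) <= 0.011 * 4))     # Lipschitz (cont.)
  big <- c(5, 10, 100)
  expect_equal(smooth_l1(big, reduce = "none"), big - 0.5)
})

test_that("build_localizer enforces divisibility and the scalar head", {
  s <- structure_spec(7)
  expect_error(build_localizer(s, input_length = 2000), "divisible")
  m <- build_localizer(s, input_length = 2048, seed = 1)
  X <- matrix(rnorm(2048 * 3), 2048, 3)
  fw <- cardiovib:::nn_forward(m$params, s, X)
  expect_length(fw$yhat, 3)
  # fixed weights, fixed input: identical output across calls
  expect_identical(fw$yhat, cardiovib:::nn_forward(m$params, s, X)$yhat)
})

test_that("analytic gradients match central differences on a tiny net", {
  set.seed(42)
  spec <- structure_spec(7, n_conv = 3)
  L <- 32; B <- 4
  params <- cardiovib:::init_params(spec, L)
  X <- matrix(rnorm(L * B), L, B)
  y <- rnorm(B)
  loss_of <- function(p)
    smooth_l1(cardiovib:::nn_forward(p, spec, X)$yhat - y)
  fw <- cardiovib:::nn_forward(params, spec, X, keep_cache = TRUE)
  grads <- cardiovib:::nn_backward(
    params, spec, fw$cache,
    cardiovib:::smooth_l1_grad(fw$yhat - y) / B)
  eps <- 1e-6
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is seed-deterministic and the early stop contract holds", {
  ds <- tiny_dataset()
  cfg <- train_config(lr = 1e-3, max_epochs = 3, patience = 2, seed = 5)
  m1 <- train_localizer(ds, "MC", structure_spec(7), cfg)
  m2 <- train_localizer(ds, "MC", structure_spec(7), cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  # constant inputs & labels: no improvement possible after the first epoch
  dsc <- ds
  for (i in seq_along(dsc$segments))
    dsc$segments[[i]]$traces$SCG <- rep(0.5, 2048)
  dsc$labels[, "MC"] <- 100
  cfgc <- train_config(lr = 0, max_epochs = 100, patience = 30, seed = 1)
  mc <- train_localizer(dsc, "MC", structure_spec(7), cfgc)
  expect_lte(length(mc$history), 31)
  # best-so-far sequence is non-increasing by construction
  expect_true(all(diff(cummin(m1$history)) <= 0))
})

test_that("overfit sanity: a converged model memorizes 10 segments", {
  ds <- tiny_dataset()
  small <- ds
  keep <- seq_len(10)
  small$segments <- small$segments[keep]
  small$labels <- small$labels[keep, , drop = FALSE]
  small$split <- rep("train", 10)
  # small batches give enough updates to interpolate 10 points
  cfg <- train_config(lr = 5e-3, batch_size = 5, max_epochs = 250,
                      patience = 249, seed = 3)
  m <- train_localizer(small, "MC", structure_spec(1), cfg)
  pr <- predict(m, small)
  expect_lt(mae(small$labels[, "MC"], pr$coord), 2)
})

test_that("predict validates lengths and clips out-of-range coordinates", {
  m <- build_localizer(structure_spec(7), seed = 2)
  expect_error(predict(m, matrix(0, 100, 2)), "does not match")
  # force a coordinate beyond the segment: huge bias on the head
  m$params$b2 <- 1e5
  pr <- predict(m, matrix(0.1, 2048, 1))
  expect_identical(pr$index, 2047L)
  expect_true(pr$out_of_range)
  m$params$b2 <- -1e5
  pr2 <- predict(m, matrix(0.1, 2048, 1))
  expect_identical(pr2$index, 0L)
})

test_that("depth sweep recomputes heads per depth and defaults to depth 6", {
  ds <- tiny_dataset()
  ds$split <- rep(c("train", "test"), length.out = length(ds$segments))
  cfg <- train_config(lr = 1e-3, max_epochs = 2, patience = 1, seed = 0)
  sw <- depth_sweep(ds, "MC", depths = c(5, 6), config = cfg)
  expect_identical(sw$flatten, c(2048L, 1024L))
  expect_true(all(is.na(sw$error)))
  expect_identical(sw$selected, c(FALSE, TRUE))
  # depth-6 variant of the sweep is the canonical structure
  expect_identical(structure_spec(7, n_conv = 6)$channels,
                   structure_spec(7)$channels)
})
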