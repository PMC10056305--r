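test_that("convolution output arithmetic matches the published shapes", {
  expect_equal(conv_output_size(256, 12, 0, 4), 62)
  expect_equal(conv_output_size(32, 5, 0, 1), 28)
  for (n in c(5, 17, 64)) expect_equal(conv_output_size(n, 1, 0, 1), n)
  expect_error(conv_output_size(4, 9, 0, 1), "kernel")
})

test_that("shape propagation reproduces the original architecture table", {
  spec <- build_original_spec(115)
  shapes <- propagate_shapes(spec)
  expected <- list(
    c(62, 62, 96),    # conv 12x12 s4
    c(31, 31, 96),    # pool 2x2 s2
    c(31, 31, 256),   # conv 5x5 p2
    c(15, 15, 256),   # pool 3x3 s2
    c(15, 15, 384),   # conv 3x3 p1
    c(15, 15, 384),   # conv 3x3 p1
    c(15, 15, 256),   # conv 3x3 p1
    c(7, 7, 256),     # pool 3x3 s2
    12544,            # flatten
    4096, 4096, 4096, 4096, 115
  )
  expect_equal(lapply(shapes, as.numeric), expected)
})

test_that("shape propagation reproduces the scaled-down architecture table", {
  spec <- build_scaled_spec(115)
  shapes <- propagate_shapes(spec)
  expected <- list(
    c(28, 28, 32),    # conv 5x5
    c(14, 14, 32),    # pool 2x2 s2
    c(13, 13, 32),    # conv 2x2
    5408,             # flatten
    1024, 1024, 1024, 1024, 115
  )
  expect_equal(lapply(shapes, as.numeric), expected)
})

test_that("propagation validates wiring and flags impossible layers", {
  spec <- build_scaled_spec(10)
  expect_silent(propagate_shapes(spec))
  bad <- network_spec(
    layers = list(conv2d(1, 4, kernel = 3), flatten(),
                  fully_connected(4 * 6 * 6, 2, activation = "softmax")),
    input_shape = c(8, 8, 1), num_classes = 2
  )
  expect_equal(propagate_shapes(bad)[[1]], c(6L, 6L, 4L))
  expect_error(
    network_spec(list(conv2d(1, 4, kernel = 9), flatten(),
                      fully_connected(4, 2, activation = "softmax")),
                 c(4, 4, 1), 2),
    "kernel")
})

test_that("parameter counts match the published totals exactly", {
  expect_identical(count_parameters(build_original_spec(115)), 72362963)
  expect_identical(count_parameters(build_scaled_spec(115)), 6711251)
  one_fc <- network_spec(
    list(flatten(), fully_connected(2, 3, activation = "softmax")),
    c(1, 2, 1), 3)
  expect_equal(count_parameters(one_fc), 9)
})

test_that("shrinking the class count only shrinks the final layer", {
  full <- count_parameters(build_original_spec(115))
  small <- count_parameters(build_original_spec(5))
  expect_equal(full - small, 4096 * 110 + 110)
  fs <- count_parameters(build_scaled_spec(115)) -
    count_parameters(build_scaled_spec(5))
  expect_equal(fs, 1024 * 110 + 110)
  expect_error(build_original_spec(1), "num_classes")
  expect_error(build_scaled_spec(1), "num_classes")
})

test_that("counting formula agrees with enumerating instantiated tensors", {
  for (spec in list(build_scaled_spec(7), tiny_spec(4))) {
    model <- instantiate_network(spec, seed = 1)
    expect_equal(sum(model_tensors(model)$n_params),
                 count_parameters(spec))
  }
})

test_that("instantiated networks output probability rows summing to one", {
  withr::with_seed(5, {
    sc <- instantiate_network(build_scaled_spec(9), seed = 2)
    x <- matrix(rbinom(32 * 32 * 3, 1, 0.2), 1024, 3)
    p <- predict_proba(sc, x)
    expect_equal(dim(p), c(9L, 3L))
    expect_equal(colSums(p), rep(1, 3), tolerance = 1e-5)
    expect_true(all(p >= 0))

    orig <- instantiate_network(build_original_spec(5), seed = 2)
    xo <- matrix(rbinom(256 * 256, 1, 0.1), 256 * 256, 1)
    po <- predict_proba(orig, xo)
    expect_equal(sum(po), 1, tolerance = 1e-5)
  })
})

test_that("network specifications round-trip through JSON", {
  spec <- build_scaled_spec(12)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(propagate_shapes(back), propagate_shapes(spec))
  expect_equal(count_parameters(back), count_parameters(spec))
})
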