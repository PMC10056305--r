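test_that("normalization maps to [0, 1] and rejects constant beats", {
  expect_equal(normalize_unit(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_unit(c(0, 0.25, 1)), c(0, 0.25, 1))
  expect_error(normalize_unit(c(1, 1, 1)), "degenerate")
  x <- rnorm(100)
  y <- normalize_unit(x)
  expect_equal(range(y), c(0, 1))
  expect_identical(order(x), order(y))
})

test_that("Gaussian upsampling interpolates with the expected length", {
  const <- upsample_gaussian(rep(0.5, 20), 10)
  expect_length(const, 10 * 19 + 1)
  expect_true(all(abs(const - 0.5) < 1e-9))

  ramp <- seq(0, 1, length.out = 11)
  up <- upsample_gaussian(ramp, 10)
  ideal <- seq(0, 1, length.out = length(up))
  expect_lt(max(abs(up - ideal)), 0.01)

  x <- runif(30)
  expect_equal(upsample_gaussian(x, 1), x)
  # the interpolant passes through every original sample
  up2 <- upsample_gaussian(x, 10)
  expect_equal(up2[seq(1, length(up2), by = 10)], x)
  expect_error(upsample_gaussian(x, 0), "factor")
})

test_that("delay embedding follows its printed definition", {
  pts <- delay_embed(c(0, 0.5, 1, 0.5), 1)
  expect_equal(unname(pts),
               cbind(c(0, 0.5, 1), c(0.5, 1, 0.5)))
  x <- runif(50)
  d0 <- delay_embed(x, 0)
  expect_equal(d0[, 1], d0[, 2])
  for (k in c(0, 1, 7, 49)) {
    expect_equal(nrow(delay_embed(x, k)), 50 - k)
  }
  expect_error(delay_embed(x, 50), "tau_samples")
})

test_that("rasterization places boundary points in the correct corner cells", {
  g <- rasterize_trajectory(cbind(0, 0), 16)
  expect_equal(sum(g), 1)
  expect_equal(g[16, 1], 1L)  # bottom-left
  g <- rasterize_trajectory(cbind(1, 1), 16)
  expect_equal(sum(g), 1)
  expect_equal(g[1, 16], 1L)  # top-right
  expect_error(rasterize_trajectory(cbind(1.2, 0), 16), "\\[0, 1\\]")
  expect_error(rasterize_trajectory(cbind(0.5, 0.5), 1), "partitions")
})

test_that("rasterization agrees with the brute-force occupancy oracle", {
  diag_pts <- cbind(seq(0, 1, length.out = 10000),
                    seq(0, 1, length.out = 10000))
  g <- rasterize_trajectory(diag_pts, 32)
  expect_equal(sum(g), 32)
  expect_true(all(g[cbind(32:1, 1:32)] == 1L))

  withr::with_seed(99, {
    for (r in c(4, 16, 32)) {
      pts <- cbind(runif(200), runif(200))
      expect_identical(rasterize_trajectory(pts, r),
                       rasterize_bruteforce(pts, r))
    }
  })
})

test_that("portrait resizing replicates blocks and preserves occupancy", {
  g <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_identical(resize_portrait(g, 2), g)
  big <- resize_portrait(g, 4)
  expect_identical(big, g[rep(1:2, each = 2), rep(1:2, each = 2)])
  expect_equal(mean(big), mean(g))
  withr::with_seed(1, {
    g2 <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(mean(resize_portrait(g2, 32)), mean(g2))
  })
  expect_error(resize_portrait(g2, 4), "divisible|>=")
  expect_error(resize_portrait(matrix(1L, 8, 8), 4), ">=")
})

test_that("delay conversion and the transform chain compose as documented", {
  beat <- small_beats()$samples[[1]]
  pt <- beat_to_portrait(beat, tau_ms = 20, partitions = 32,
                         out_pixels = 32, fs = 1000)
  # manual chain with tau_samples = 20 ms * 1 kSa/s * 10 / 1000 = 200
  up <- upsample_gaussian(beat, 10)
  xn <- normalize_unit(up)
  manual <- rasterize_trajectory(delay_embed(xn, 200), 32)
  expect_identical(pt$grid, manual)
})

test_that("small delays contract the portrait toward the diagonal", {
  beat <- small_beats()$samples[[1]]
  p2 <- beat_to_portrait(beat, tau_ms = 2, partitions = 32, out_pixels = 32)
  p20 <- beat_to_portrait(beat, tau_ms = 20, partitions = 32,
                          out_pixels = 32)
  expect_lt(sum(p2$grid), sum(p20$grid))
})

test_that("a clean beat's portrait shows the nested loop structure", {
  subj <- make_subject(31, rr_jitter_sd = 0, amplitude_modulation_depth = 0)
  rec <- synthesize_record(subj, n_beats = 3, noise_sd = 0,
                           baseline_amp = 0, seed = 0)
  segs <- segment_beats(rec, rec$true_r_locations)
  pt <- beat_to_portrait(segs[1, ], tau_ms = 20, partitions = 256,
                         out_pixels = 256)
  # the trajectory's loops enclose >= 2 background holes besides the
  # outer background region
  holes <- count_components(pt$grid == 0L) - 1L
  expect_gte(holes, 2)
})

test_that("portraits are invariant to affine amplitude changes", {
  beat <- small_beats()$samples[[2]]
  p <- beat_to_portrait(beat, 20, 32, 32)
  p_scaled <- beat_to_portrait(3.7 * beat + 11, 20, 32, 32)
  expect_identical(p$grid, p_scaled$grid)
  expect_identical(p$image, p_scaled$image)
})

test_that("time reversal transposes the portrait across the anti-diagonal", {
  beat <- small_beats()$samples[[3]]
  r <- 32
  fwd <- beat_to_portrait(beat, 20, r, r)$grid
  rev_grid <- beat_to_portrait(rev(beat), 20, r, r)$grid
  expect_identical(rev_grid, t(fwd[r:1, r:1]))
})

test_that("occupied cells stay covered under grid refinement", {
  beat <- small_beats()$samples[[1]]
  for (r in c(16, 32, 64)) {
    coarse <- beat_to_portrait(beat, 20, r, 256)$grid
    fine <- beat_to_portrait(beat, 20, 2 * r, 256)$grid
    for (i in seq_len(r)) for (j in seq_len(r)) {
      if (coarse[i, j] == 1L) {
        block <- fine[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
        expect_true(any(block == 1L))
      }
    }
  }
})
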