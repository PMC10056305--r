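# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small preprocessed cohort: 3 subjects x 45 beats, enough for a 25/10 split
small_beats <- function() {
  fixture("small_beats", function() {
    cohort <- make_cohort(3, n_beats = 45, seed = 11)
    preprocess_cohort(cohort, min_duration_s = 0, min_beats = 35)
  })
}

small_portraits <- function(tau_ms = 20, partitions = 16, out_pixels = 16) {
  key <- sprintf("small_portraits_%g_%d_%d", tau_ms, partitions, out_pixels)
  fixture(key, function() {
    portraits_from_beats(small_beats(), tau_ms = tau_ms,
                         partitions = partitions, out_pixels = out_pixels)
  })
}

# compact CNN for engine tests: 16 x 16 input
tiny_spec <- function(num_classes = 3, px = 16) {
  network_spec(
    layers = list(
      conv2d(1, 4, kernel = 3),
      maxpool2d(2, stride = 2),
      flatten(),
      fully_connected(4 * ((px - 2) %/% 2)^2, 32),
      fully_connected(32, num_classes, activation = "softmax")
    ),
    input_shape = c(px, px, 1),
    num_classes = num_classes
  )
}

# brute-force occupancy oracle: double loop over points x cells
rasterize_bruteforce <- function(points, r) {
  grid <- matrix(0L, r, r)
  for (row in seq_len(r)) {
    for (col in seq_len(r)) {
      x_lo <- (col - 1) / r
      x_hi <- col / r
      y_hi <- (r - row + 1) / r
      y_lo <- (r - row) / r
      for (k in seq_len(nrow(points))) {
        x <- points[k, 1]; y <- points[k, 2]
        in_x <- (x >= x_lo & x < x_hi) || (col == r && x == 1)
        in_y <- (y >= y_lo & y < y_hi) || (row == 1 && y == 1)
        if (in_x && in_y) { grid[row, col] <- 1L; break }
      }
    }
  }
  grid
}

# count connected components of a binary mask (4-connectivity, BFS)
count_components <- function(mask) {
  r <- nrow(mask); cc <- ncol(mask)
  seen <- matrix(FALSE, r, cc)
  n <- 0L
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= r && q[2] >= 1 && q[2] <= cc &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  n
}

# magnitude response of a digital filter (b, a) at frequency f for rate fs
filter_gain <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  b <- filt$b; a <- filt$a
  num <- sum(b * z^(seq_along(b) - 1))
  den <- sum(a * z^(seq_along(a) - 1))
  Mod(num / den)
}
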