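test_that("band-limiting matches the designed filter's frequency response", {
  fs <- 1000
  t <- seq(0, 40, by = 1 / fs)
  hp <- signal::butter(2, 1 / (fs / 2), type = "high")
  lp <- signal::butter(2, 40 / (fs / 2), type = "low")
  # oracle: squared magnitude (forward-backward) of the designed cascade
  gain2 <- function(f) (filter_gain(hp, f, fs) * filter_gain(lp, f, fs))^2

  for (f in c(0.1, 10)) {
    x <- sin(2 * pi * f * t)
    rec <- new_ecg_record(x, fs)
    y <- bandlimit(rec)$samples
    core <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
    ratio <- sqrt(mean(y[core]^2) / mean(x[core]^2))
    expect_equal(ratio, gain2(f), tolerance = 0.02)
  }
  # stated contracts on the same tones
  x <- sin(2 * pi * 0.1 * t)
  y <- bandlimit(new_ecg_record(x, fs))$samples
  expect_lt(sqrt(mean(y^2)) / sqrt(mean(x^2)), 0.05)
  x <- sin(2 * pi * 10 * t)
  y <- bandlimit(new_ecg_record(x, fs))$samples
  core <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
  r <- sqrt(mean(y[core]^2) / mean(x[core]^2))
  expect_gte(r, 0.90)
  expect_lte(r, 1.0 + 1e-6)
})

test_that("band-limiting is zero-phase and near-idempotent in the passband", {
  fs <- 1000
  c0 <- 3000
  x <- exp(-((seq_len(6000) - c0)^2) / (2 * 15^2))
  rec <- new_ecg_record(x, fs)
  y <- bandlimit(rec)$samples
  expect_lte(abs(which.max(y) - c0), 1)

  tone <- new_ecg_record(sin(2 * pi * 10 * seq(0, 30, by = 1 / fs)), fs)
  once <- bandlimit(tone)
  twice <- bandlimit(once)
  core <- seq(7500, 22500)
  rms1 <- sqrt(mean(once$samples[core]^2))
  rms2 <- sqrt(mean(twice$samples[core]^2))
  expect_lt(abs(rms2 - rms1) / rms1, 0.02)

  expect_error(bandlimit(new_ecg_record(rnorm(100), fs = 80)), "fs")
})

test_that("QRS detection recovers the configured beats on clean input", {
  subj <- make_subject(21, mean_rr = 1.0, rr_jitter_sd = 0,
                       amplitude_modulation_depth = 0)
  rec <- synthesize_record(subj, n_beats = 130, fs = 1000, noise_sd = 0,
                           baseline_amp = 0, seed = 0)
  fid <- detect_qrs(rec)
  expect_length(fid, 130)
  err <- abs(fid - rec$true_r_locations)
  expect_true(all(err <= 20))
})

test_that("QRS detection handles degenerate input and refractory spacing", {
  expect_identical(detect_qrs(new_ecg_record(numeric(5000), 1000)),
                   integer(0))
  expect_error(detect_qrs(new_ecg_record(numeric(1000), 1000)), "2 s")
  subj <- make_subject(22)
  rec <- synthesize_record(subj, n_beats = 40, seed = 2)
  fid <- detect_qrs(rec)
  expect_true(!is.unsorted(fid, strictly = TRUE))
  expect_true(all(diff(fid) >= 200))
})

test_that("beat verification keeps clean interior beats and rejects insertions", {
  subj <- make_subject(23, rr_jitter_sd = 0.01)
  rec <- synthesize_record(subj, n_beats = 30, noise_sd = 0.01, seed = 4)
  filt <- bandlimit(rec)
  fid <- detect_qrs(filt)
  kept <- verify_beats(filt, fid)
  expect_identical(kept, fid[2:(length(fid) - 1)])

  # a spurious detection between two true beats violates both RR rules
  insert <- as.integer(round(mean(fid[10:11])))
  fid_bad <- sort(c(fid, insert))
  kept_bad <- verify_beats(filt, fid_bad)
  expect_false(insert %in% kept_bad)
  expect_error(verify_beats(filt, fid[1:2]), "3 fiducials")
})

test_that("verification keeps all interior fiducials of a periodic signal", {
  fs <- 1000
  n <- 30000
  fid <- seq(500, n - 500, by = 1000)
  x <- numeric(n)
  for (f in fid) x <- x + exp(-((seq_len(n) - f)^2) / (2 * 10^2))
  rec <- new_ecg_record(x, fs)
  expect_identical(verify_beats(rec, fid), fid[2:(length(fid) - 1)])
})

test_that("segmentation applies the 35%/65% cardiac-cycle split", {
  fs <- 1000
  x <- rnorm(10000)
  rec <- new_ecg_record(x, fs)
  fid <- c(4000, 5000, 6000)
  segs <- segment_beats(rec, fid)
  expect_equal(unique(segs$cycle_len), 1000)
  expect_equal(unique(segs$fiducial_offset), 350)
  # fiducial at 5000 covers [4650, 5649] so that 35% of the cycle precedes it
  i <- which(segs$fiducial == 5000)
  expect_identical(segs$samples[[i]], x[4650:5649])

  # a beat whose window underflows the record start is dropped
  segs2 <- segment_beats(rec, c(100, 1100, 2100))
  expect_false(100 %in% segs2$fiducial)
  expect_true(all(c(1100, 2100) %in% segs2$fiducial))
})

test_that("a full-length synthetic record yields the training beat budget", {
  subj <- make_subject(24)
  rec <- synthesize_record(subj, n_beats = 130, seed = 6)
  filt <- bandlimit(rec)
  fid <- detect_qrs(filt)
  kept <- verify_beats(filt, fid)
  segs <- segment_beats(filt, kept)
  expect_gte(nrow(segs), 125)
  expect_length(unique(segs$fiducial_offset), 1)
  expect_true(!is.unsorted(segs$fiducial))
})

test_that("recording screening enforces duration and beat-count rules", {
  rec110 <- new_ecg_record(numeric(110000), 1000)
  rec90 <- new_ecg_record(numeric(90000), 1000)
  expect_true(screen_recording(rec110, seq_len(130)))
  expect_false(screen_recording(rec90, seq_len(130)))
  expect_false(screen_recording(rec110, seq_len(120)))
})
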