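#' Draw a synthetic subject's ECG morphology
#'
#' Samples a per-subject parameter set for a five-wave (P, Q, R, S, T)
#' Gaussian beat model on lead-I-like ECG. Each wave has a signed amplitude
#' (mV), a center expressed as a fraction of the cardiac cycle, and a width
#' (s). The R wave is always the largest deflection in absolute value and
#' wave centers are ordered P < Q < R < S < T. Beat-to-beat variability is
#' controlled by `rr_jitter_sd` (RR-interval jitter) and
#' `amplitude_modulation_depth` (slow respiration-like scaling of the whole
#' beat), both of which can be overridden.
#'
#' Parameter ranges target normal lead-I morphology: R amplitude 0.8--1.5 mV,
#' P 0.05--0.2 mV, T 0.1--0.4 mV, Q and S -0.3 to -0.05 mV; QRS wave widths
#' 8--20 ms, P and T widths 40--90 ms.
#'
#' @param seed Non-negative integer; fully determines the subject.
#' @param mean_rr Mean RR interval in seconds (default drawn in 0.7--1.0 s).
#' @param rr_jitter_sd Standard deviation of per-beat RR jitter, seconds.
#' @param amplitude_modulation_depth Dimensionless depth of the 0.25 Hz
#'   per-beat amplitude modulation.
#' @return An object of class `ecg_subject`: a list with elements
#'   `amplitude`, `center`, `width` (named numeric vectors over P, Q, R, S,
#'   T), `mean_rr`, `rr_jitter_sd`, `amplitude_modulation_depth`,
#'   `subject_id`.
#' @examples
#' subj <- make_subject(1)
#' subj$amplitude
#' @export
make_subject <- function(seed, mean_rr = NULL, rr_jitter_sd = 0.030,
                         amplitude_modulation_depth = 0.05) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  withr::with_seed(subseed(seed, 1L), {
    amp <- c(
      P = stats::runif(1, 0.05, 0.20),
      Q = -stats::runif(1, 0.05, 0.30),
      R = stats::runif(1, 0.80, 1.50),
      S = -stats::runif(1, 0.05, 0.30),
      T = stats::runif(1, 0.10, 0.40)
    )
    width <- c(
      P = stats::runif(1, 0.040, 0.090),
      Q = stats::runif(1, 0.008, 0.020),
      R = stats::runif(1, 0.008, 0.020),
      S = stats::runif(1, 0.008, 0.020),
      T = stats::runif(1, 0.040, 0.090)
    )
    center <- c(
      P = stats::runif(1, 0.14, 0.20),
      Q = stats::runif(1, 0.305, 0.325),
      R = stats::runif(1, 0.345, 0.355),
      S = stats::runif(1, 0.375, 0.395),
      T = stats::runif(1, 0.55, 0.68)
    )
    if (is.null(mean_rr)) mean_rr <- stats::runif(1, 0.70, 1.00)
    subj <- list(
      amplitude = amp, center = center, width = width,
      mean_rr = mean_rr, rr_jitter_sd = rr_jitter_sd,
      amplitude_modulation_depth = amplitude_modulation_depth,
      subject_id = sprintf("S%03d", seed)
    )
    class(subj) <- "ecg_subject"
    validate_subject(subj)
    subj
  })
}

validate_subject <- function(subj) {
  a <- subj$amplitude
  if (!all(abs(a["R"]) > abs(a[c("P", "Q", "S", "T")]))) {
    stop("R amplitude must be the largest deflection in absolute value")
  }
  if (is.unsorted(subj$center[c("P", "Q", "R", "S", "T")], strictly = TRUE)) {
    stop("wave centers must be strictly ordered P < Q < R < S < T")
  }
  if (subj$mean_rr < 0.4 || subj$mean_rr > 1.5) {
    stop("mean_rr must lie in [0.4, 1.5] s")
  }
  if (any(subj$width <= 0)) stop("wave widths must be positive")
  invisible(subj)
}

# Counter-based sub-seeding: one global seed fans out into independent
# per-purpose streams without coupling consecutive subjects.
subseed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729 + 12345) %%
               2147483647)
}

#' @export
print.ecg_subject <- function(x, ...) {
  cat("<ecg_subject>", x$subject_id,
      sprintf("mean RR %.3f s, RR jitter sd %.0f ms, amp. modulation %.2f\n",
              x$mean_rr, 1000 * x$rr_jitter_sd, x$amplitude_modulation_depth))
  m <- rbind(`amplitude (mV)` = x$amplitude,
             `center (cycle)` = x$center,
             `width (s)`      = x$width)
  print(round(m, 3), ...)
  invisible(x)
}

#' Synthesize a single-lead ECG record for one subject
#'
#' Renders `n_beats` cardiac cycles of the subject's five-Gaussian beat
#' model at sampling rate `fs`. Each beat's RR interval is drawn from
#' Normal(`mean_rr`, `rr_jitter_sd`), the whole beat is scaled by
#' `1 + depth * sin(2 * pi * 0.25 * t)` (respiration-like amplitude
#' modulation), and the record carries a sinusoidal baseline wander at
#' 0.2 Hz of amplitude `baseline_amp` plus white Gaussian noise of standard
#' deviation `noise_sd`.
#'
#' @param subject An `ecg_subject` from [make_subject()].
#' @param n_beats Number of cardiac cycles (>= 1).
#' @param fs Sampling rate, Sa/s (>= 250).
#' @param noise_sd Additive white noise standard deviation, mV.
#' @param baseline_amp Amplitude of the 0.2 Hz baseline wander, mV.
#' @param seed Integer seed controlling RR draws and noise.
#' @return An `ecg_record`: list with `samples` (mV), `fs`, `subject_id`,
#'   and `true_r_locations` (1-based sample indices of the R-wave Gaussian
#'   centers, one per beat).
#' @examples
#' rec <- synthesize_record(make_subject(1), n_beats = 5, seed = 1)
#' length(rec$true_r_locations)
#' @export
synthesize_record <- function(subject, n_beats, fs = 1000, noise_sd = 0.02,
                              baseline_amp = 0.05, seed = 0) {
  stopifnot(inherits(subject, "ecg_subject"))
  if (!is.numeric(n_beats) || n_beats < 1) {
    stop("n_beats must be a positive integer")
  }
  if (!is.numeric(fs) || fs < 250) {
    stop("fs must be at least 250 Sa/s")
  }
  withr::with_seed(subseed(seed, 2L), {
    rr <- stats::rnorm(n_beats, subject$mean_rr, subject$rr_jitter_sd)
    rr <- pmax(rr, 0.4 * subject$mean_rr)  # guard against degenerate draws
    onsets <- c(0, cumsum(rr))[seq_len(n_beats)]
    total <- sum(rr)
    n <- max(2L, as.integer(round(total * fs)))
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    r_locs <- integer(n_beats)
    depth <- subject$amplitude_modulation_depth
    for (b in seq_len(n_beats)) {
      # Bazett-like interval scaling: intra-beat intervals (P-R, R-T)
      # track sqrt(RR) rather than RR, as QT intervals do physiologically
      cyc <- sqrt(rr[b] * subject$mean_rr)
      centers <- onsets[b] + subject$center * cyc
      scale_b <- 1 + depth * sin(2 * pi * 0.25 * onsets[b])
      # beats only contribute near their own cycle; restrict the window
      lo <- max(1L, floor((onsets[b] - 0.2) * fs))
      hi <- min(n, ceiling((onsets[b] + rr[b] + 0.2) * fs))
      idx <- lo:hi
      tb <- t[idx]
      for (w in names(subject$amplitude)) {
        # width is the wave's effective duration: +/- 2 sd of the Gaussian
        # for the sharp QRS deflections, +/- 1 sd for the smooth, rounded
        # P and T waves
        sd_w <- subject$width[[w]] / (if (w %in% c("P", "T")) 2 else 4)
        x[idx] <- x[idx] + scale_b * subject$amplitude[[w]] *
          exp(-(tb - centers[[w]])^2 / (2 * sd_w^2))
      }
      r_locs[b] <- as.integer(round(centers[["R"]] * fs)) + 1L
    }
    x <- x + baseline_amp * sin(2 * pi * 0.2 * t)
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    r_locs <- as.integer(pmin(pmax(r_locs, 1L), n))
    new_ecg_record(x, fs, subject$subject_id, true_r_locations = r_locs)
  })
}

#' Construct an ECG record object
#'
#' @param samples Numeric vector of amplitudes, mV.
#' @param fs Sampling rate, Sa/s.
#' @param subject_id Subject label.
#' @param true_r_locations Optional strictly increasing 1-based indices of
#'   ground-truth R peaks (synthetic mode only).
#' @return An `ecg_record` object.
#' @export
new_ecg_record <- function(samples, fs, subject_id = NA_character_,
                           true_r_locations = NULL) {
  if (length(samples) == 0) stop("samples must be non-empty")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (!is.null(true_r_locations)) {
    if (is.unsorted(true_r_locations, strictly = TRUE) ||
        any(true_r_locations < 1) ||
        any(true_r_locations > length(samples))) {
      stop("true_r_locations must be strictly increasing and within bounds")
    }
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         subject_id = subject_id, true_r_locations = true_r_locations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Sa/s (%.1f s)%s\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$true_r_locations)) "" else
                sprintf(", %d annotated R peaks",
                        length(x$true_r_locations))))
  invisible(x)
}

#' Generate a multi-subject synthetic cohort
#'
#' One record per subject, each with a distinct morphology drawn from the
#' subject model and `n_beats` cardiac cycles. Deterministic in `seed`;
#' per-subject sub-seeds are derived by a counter scheme so a cohort can be
#' extended without changing existing subjects.
#'
#' @param n_subjects Number of subjects (>= 2: identification needs at
#'   least two classes).
#' @param n_beats Beats per record.
#' @param seed Global integer seed.
#' @param fs Sampling rate, Sa/s.
#' @param noise_sd,baseline_amp Noise and baseline-wander levels passed to
#'   [synthesize_record()].
#' @return A tibble with one row per subject: `subject_id` and a `record`
#'   list-column of `ecg_record` objects.
#' @examples
#' cohort <- make_cohort(3, n_beats = 10, seed = 1)
#' cohort$subject_id
#' @export
make_cohort <- function(n_subjects, n_beats = 130, seed = 0, fs = 1000,
                        noise_sd = 0.02, baseline_amp = 0.05) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("n_subjects must be at least 2: identification needs >= 2 classes")
  }
  records <- purrr::map(seq_len(n_subjects), function(i) {
    subj <- make_subject(subseed(seed, 100L + i) %% 100000L)
    subj$subject_id <- sprintf("S%03d", i)
    synthesize_record(subj, n_beats = n_beats, fs = fs, noise_sd = noise_sd,
                      baseline_amp = baseline_amp,
                      seed = subseed(seed, 200L + i))
  })
  tibble::tibble(
    subject_id = purrr::map_chr(records, "subject_id"),
    record = records
  )
}
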