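#' Band-limit an ECG record (1--40 Hz, zero phase)
#'
#' Applies two anti-causal (forward--backward, zero-phase) Butterworth
#' filters: a high-pass at 1 Hz that removes low-frequency baseline wander,
#' then a low-pass at 40 Hz that suppresses high-frequency noise. Each pass
#' uses an order-2 design, so the effective magnitude response is order 4.
#' Zero-phase filtering leaves fiducial timing untouched: a symmetric pulse
#' keeps its peak position.
#'
#' @param record An `ecg_record`.
#' @param highpass_hz,lowpass_hz Cutoff frequencies, Hz.
#' @return A filtered `ecg_record` of identical length.
#' @export
bandlimit <- function(record, highpass_hz = 1, lowpass_hz = 40) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs <= 2 * lowpass_hz) {
    stop("fs must exceed twice the low-pass cutoff (", 2 * lowpass_hz, " Hz)")
  }
  x <- record$samples
  hp <- signal::butter(2, highpass_hz / (record$fs / 2), type = "high")
  lp <- signal::butter(2, lowpass_hz / (record$fs / 2), type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  out <- record
  out$samples <- as.numeric(y)
  out
}

#' Detect QRS complexes (Pan--Tompkins style)
#'
#' Classic detection chain: band-pass emphasis of the QRS band (5--15 Hz),
#' differentiation, squaring, moving-window integration over 150 ms, then
#' adaptive dual-threshold peak classification with running signal/noise
#' level estimates, a search-back pass for missed beats (gaps longer than
#' 1.66 times the running RR average re-examined at half threshold), and a
#' refractory period between detections. Detections are finally snapped to
#' the local absolute maximum of the 1--40 Hz band-limited signal within
#' +/- 50 ms so the fiducial is the R peak itself.
#'
#' @param record An `ecg_record` of at least 2 s duration (raw or
#'   band-limited; band-limiting is applied internally).
#' @param refractory_ms Minimum spacing between detections, ms.
#' @return Integer vector of strictly increasing 1-based R-peak indices.
#' @export
detect_qrs <- function(record, refractory_ms = 200) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  n <- length(record$samples)
  if (n / fs < 2) stop("record must be at least 2 s long")

  xf <- bandlimit(record)$samples
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- as.numeric(signal::filtfilt(bp, record$samples))
  der <- c(0, diff(xb)) * fs
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refr <- as.integer(round(refractory_ms / 1000 * fs))
  peaks <- local_maxima(mwi, min_sep = refr)
  if (length(peaks) == 0) return(integer(0))

  init <- seq_len(min(n, 2L * round(fs)))
  spki <- 0.25 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  thr <- function() npki + 0.25 * (spki - npki)

  # T-wave discrimination: maximal absolute slope around a peak, compared
  # against the preceding QRS's slope for peaks closer than 360 ms
  absder <- abs(der)
  twave_win <- as.integer(round(0.075 * fs))
  max_slope <- function(p) {
    max(absder[max(1L, p - twave_win):min(n, p + twave_win)])
  }

  accepted <- integer(0)
  rejected <- integer(0)
  rr_hist <- numeric(0)
  for (p in peaks) {
    v <- mwi[p]
    if (length(accepted) && p - accepted[length(accepted)] < refr) next
    if (length(accepted) &&
        p - accepted[length(accepted)] < round(0.360 * fs) &&
        max_slope(p) < 0.5 * max_slope(accepted[length(accepted)])) {
      rejected <- c(rejected, p)
      npki <- 0.125 * v + 0.875 * npki
      next
    }
    if (v > thr()) {
      # search-back: long gap since the last beat, re-examine skipped peaks
      if (length(accepted) >= 2 && length(rr_hist) >= 2) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        gap_start <- accepted[length(accepted)]
        if (p - gap_start > 1.66 * rr_avg) {
          cand <- rejected[rejected > gap_start + refr & rejected < p - refr]
          if (length(cand)) {
            slopes <- vapply(cand, max_slope, numeric(1))
            cand <- cand[slopes >= 0.5 * max_slope(gap_start)]
          }
          if (length(cand)) {
            best <- cand[which.max(mwi[cand])]
            if (mwi[best] > 0.5 * thr()) {
              spki <- 0.25 * mwi[best] + 0.75 * spki
              rr_hist <- c(rr_hist, best - gap_start)
              accepted <- c(accepted, best)
            }
          }
        }
      }
      if (length(accepted)) {
        rr_hist <- c(rr_hist, p - accepted[length(accepted)])
      }
      accepted <- c(accepted, p)
      spki <- 0.125 * v + 0.875 * spki
    } else {
      rejected <- c(rejected, p)
      npki <- 0.125 * v + 0.875 * npki
    }
  }
  if (length(accepted) == 0) return(integer(0))

  # snap each detection to the R peak: local |max| of the band-limited
  # signal within +/- 50 ms
  half <- as.integer(round(0.050 * fs))
  snapped <- vapply(accepted, function(p) {
    lo <- max(1L, as.integer(p) - half)
    hi <- min(n, as.integer(p) + half)
    lo + which.max(abs(xf[lo:hi])) - 1L
  }, integer(1))
  snapped <- sort(unique(snapped))
  # refractory after snapping: keep the stronger of any close pair
  keep <- rep(TRUE, length(snapped))
  i <- 1L
  while (i < length(snapped)) {
    j <- i + 1L
    if (keep[i] && snapped[j] - snapped[i] < refr) {
      if (abs(xf[snapped[j]]) > abs(xf[snapped[i]])) keep[i] <- FALSE
      else keep[j] <- FALSE
      i <- j
    } else i <- i + 1L
  }
  snapped[keep]
}

# strict local maxima with positive value, greedily thinned to min_sep
local_maxima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
               x[2:(n - 1)] > 0) + 1L
  if (length(i) < 2 || min_sep <= 1) return(i)
  ord <- i[order(-x[i])]
  taken <- integer(0)
  for (p in ord) {
    if (!length(taken) || all(abs(taken - p) >= min_sep)) taken <- c(taken, p)
  }
  sort(taken)
}

#' Verify detected beats against rhythm and morphology
#'
#' A fiducial is kept iff (a) both adjacent RR intervals are within
#' +/- `rr_tol` of the record's median RR and (b) the Pearson correlation
#' of its QRS window (+/- `window_ms`) with the record's median QRS
#' template is at least `min_cor`. This removes false detections and
#' ectopic (e.g. ventricular premature) beats, whose prematurity and
#' aberrant morphology violate (a) and (b) respectively. The first and
#' last fiducials lack two adjacent intervals and are never kept.
#'
#' @param record An `ecg_record`.
#' @param fiducials Integer vector of detected R-peak indices (>= 3).
#' @param rr_tol Relative RR tolerance around the median (default 0.2).
#' @param min_cor Minimum template correlation (default 0.8).
#' @param window_ms Half-width of the QRS correlation window, ms.
#' @return The kept subset of `fiducials`, order preserved.
#' @export
verify_beats <- function(record, fiducials, rr_tol = 0.2, min_cor = 0.8,
                         window_ms = 100) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(fiducials) < 3) {
    stop("at least 3 fiducials are required to form a QRS template")
  }
  fs <- record$fs
  x <- record$samples
  half <- round(window_ms / 1000 * fs)
  rr <- diff(fiducials)
  med_rr <- stats::median(rr)

  in_bounds <- fiducials - half >= 1 & fiducials + half <= length(x)
  windows <- vapply(fiducials[in_bounds],
                    function(f) x[(f - half):(f + half)],
                    numeric(2 * half + 1))
  template <- apply(windows, 1, stats::median)

  n <- length(fiducials)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1 || i == n || !in_bounds[i]) next
    rr_ok <- abs(rr[i - 1] - med_rr) <= rr_tol * med_rr &&
      abs(rr[i] - med_rr) <= rr_tol * med_rr
    if (!rr_ok) next
    f <- fiducials[i]
    wv <- x[(f - half):(f + half)]
    if (stats::sd(wv) == 0 || stats::sd(template) == 0) next
    keep[i] <- stats::cor(wv, template) >= min_cor
  }
  fiducials[keep]
}

#' Cut single-cycle beat segments around verified fiducials
#'
#' The cardiac-cycle window places the fiducial 35% of the way into the
#' cycle: each segment contains the preceding 35% and the succeeding 65%
#' of one cycle's samples. The cycle length is fixed at the record's
#' median RR so every segment of a record has equal length; beats whose
#' window would overrun the record bounds are dropped.
#'
#' @param record An `ecg_record`.
#' @param fiducials Verified fiducial indices (>= 2 to define an RR).
#' @return A tibble with one row per kept beat: `subject_id`, `beat`
#'   (index among kept beats), `fiducial` (R index in the record),
#'   `fiducial_offset` (samples preceding the fiducial within the
#'   segment, `round(0.35 * cycle_len)`), `cycle_len`, and a `samples`
#'   list-column.
#' @export
segment_beats <- function(record, fiducials) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(fiducials) < 2) {
    return(tibble::tibble(subject_id = character(), beat = integer(),
                          fiducial = integer(), fiducial_offset = integer(),
                          cycle_len = integer(), samples = list()))
  }
  n <- length(record$samples)
  cycle_len <- as.integer(round(stats::median(diff(fiducials))))
  offset <- as.integer(round(0.35 * cycle_len))
  starts <- fiducials - offset
  ends <- starts + cycle_len - 1L
  ok <- starts >= 1 & ends <= n
  starts <- starts[ok]
  segs <- purrr::map(starts, function(s) record$samples[s:(s + cycle_len - 1L)])
  tibble::tibble(
    subject_id = record$subject_id,
    beat = seq_along(segs),
    fiducial = as.integer(fiducials[ok]),
    fiducial_offset = offset,
    cycle_len = cycle_len,
    samples = segs
  )
}

#' Decide whether a recording qualifies for the biometric cohort
#'
#' A recording passes iff it lasts at least `min_duration_s` seconds and
#' at least `min_beats` beats survive verification, mirroring the cohort
#' inclusion rule (short or beat-poor recordings cannot supply the
#' training/validation beat budget).
#'
#' @param record An `ecg_record`.
#' @param kept_fiducials Verified fiducials (or segmented beats).
#' @param min_duration_s Minimum duration, seconds.
#' @param min_beats Minimum verified beat count.
#' @return Logical scalar.
#' @export
screen_recording <- function(record, kept_fiducials, min_duration_s = 100,
                             min_beats = 125) {
  stopifnot(inherits(record, "ecg_record"))
  duration <- length(record$samples) / record$fs
  duration >= min_duration_s && length(kept_fiducials) >= min_beats
}

#' Run the full preprocessing chain on one record
#'
#' Band-limit, detect QRS, verify, segment. Returns the beat tibble from
#' [segment_beats()]; attach `screened` as an attribute-free column check
#' via [screen_recording()] yourself when cohort screening is wanted.
#'
#' @param record An `ecg_record`.
#' @return Beat tibble (see [segment_beats()]).
#' @export
preprocess_record <- function(record) {
  filtered <- bandlimit(record)
  fid <- detect_qrs(filtered)
  if (length(fid) < 3) {
    return(segment_beats(filtered, integer(0)))
  }
  kept <- verify_beats(filtered, fid)
  segment_beats(filtered, kept)
}

#' Preprocess a cohort and report screening
#'
#' Applies [preprocess_record()] to every record of a cohort tibble and
#' binds the beats. The screening report (one row per subject:
#' `subject_id`, `duration_s`, `n_beats`, `passed`) is attached as
#' attribute `"screening"` and also returned by [screening_report()].
#'
#' @param cohort Tibble with `subject_id` and `record` list-column, as
#'   from [make_cohort()].
#' @param min_duration_s,min_beats Screening thresholds; see
#'   [screen_recording()].
#' @param keep_failed Keep beats of subjects that fail screening
#'   (default FALSE).
#' @return Beat tibble over all (passing) subjects.
#' @export
preprocess_cohort <- function(cohort, min_duration_s = 100, min_beats = 125,
                              keep_failed = FALSE) {
  stopifnot(is.data.frame(cohort), all(c("subject_id", "record") %in%
                                         names(cohort)))
  beats <- purrr::map(cohort$record, preprocess_record)
  report <- tibble::tibble(
    subject_id = cohort$subject_id,
    duration_s = purrr::map_dbl(cohort$record,
                                ~ length(.x$samples) / .x$fs),
    n_beats = purrr::map_int(beats, nrow),
    passed = purrr::map2_lgl(cohort$record, beats, function(r, b) {
      screen_recording(r, seq_len(nrow(b)), min_duration_s, min_beats)
    })
  )
  keep <- if (keep_failed) rep(TRUE, nrow(report)) else report$passed
  out <- dplyr::bind_rows(beats[keep])
  attr(out, "screening") <- report
  out
}

#' @rdname preprocess_cohort
#' @param beats A beat tibble produced by [preprocess_cohort()].
#' @export
screening_report <- function(beats) {
  rep <- attr(beats, "screening")
  if (is.null(rep)) stop("no screening report attached to these beats")
  rep
}
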