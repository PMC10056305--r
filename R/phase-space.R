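#' Normalize a beat to the unit interval
#'
#' Order-preserving affine map `(x - min) / (max - min)` so the minimum
#' maps to 0 and the maximum to 1. A constant beat is degenerate (no
#' amplitude range) and is rejected.
#'
#' @param samples Numeric vector (length >= 2).
#' @return Numeric vector in \[0, 1\].
#' @examples
#' normalize_unit(c(2, 4, 6))
#' @export
normalize_unit <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 samples")
  rng <- range(samples)
  if (rng[1] == rng[2]) stop("degenerate beat: constant amplitude")
  (samples - rng[1]) / (rng[2] - rng[1])
}

#' Upsample a sequence by Gaussian interpolation
#'
#' Evaluates the signal on a grid `factor` times finer. Each query point
#' takes a Gaussian-kernel weighted average of the original samples within
#' +/- 4 standard deviations (sigma = 0.5 original sample periods),
#' weights renormalized to sum to one; query points coinciding with an
#' original sample return that sample exactly, so the interpolant passes
#' through the input.
#'
#' @param samples Numeric vector (length >= 2).
#' @param factor Integer upsampling factor (>= 1).
#' @param sigma Kernel standard deviation in original sample periods.
#' @return Numeric vector of length `factor * (length(samples) - 1) + 1`.
#' @examples
#' upsample_gaussian(c(0, 1), 4)
#' @export
upsample_gaussian <- function(samples, factor, sigma = 0.5) {
  if (!is.numeric(factor) || factor < 1 || factor != floor(factor)) {
    stop("factor must be a positive integer")
  }
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples")
  factor <- as.integer(factor)
  if (factor == 1L) return(as.numeric(samples))
  # query positions in units of the original sample index (0-based)
  q <- seq(0, n - 1, by = 1 / factor)
  m <- length(q)
  support <- ceiling(4 * sigma)
  base <- floor(q)
  acc_w <- numeric(m)
  acc_x <- numeric(m)
  for (d in (-support):(support + 1L)) {
    k <- base + d
    ok <- k >= 0 & k <= (n - 1) & abs(k - q) <= 4 * sigma
    w <- ifelse(ok, exp(-(k - q)^2 / (2 * sigma^2)), 0)
    xi <- ifelse(ok, samples[pmin(pmax(k, 0), n - 1) + 1], 0)
    acc_w <- acc_w + w
    acc_x <- acc_x + w * xi
  }
  out <- acc_x / acc_w
  on_knot <- abs(q - round(q)) < 1e-9
  out[on_knot] <- samples[round(q[on_knot]) + 1]
  out
}

#' Embed a sequence into 2D phase space by time delay
#'
#' Maps a scalar series x to points (x(t), x(t + tau)): point i is
#' `(samples[i], samples[i + tau_samples])` for i = 1 .. N - tau_samples.
#' The embedding dimension is fixed at 2.
#'
#' @param samples Numeric vector (typically normalized to \[0, 1\]).
#' @param tau_samples Delay in samples, `0 <= tau_samples < length(samples)`.
#' @return Two-column matrix (`x`, `y`) with `N - tau_samples` rows.
#' @examples
#' delay_embed(c(0, 0.5, 1, 0.5), 1)
#' @export
delay_embed <- function(samples, tau_samples) {
  n <- length(samples)
  if (tau_samples < 0 || tau_samples >= n) {
    stop("tau_samples must satisfy 0 <= tau_samples < length(samples)")
  }
  tau_samples <- as.integer(tau_samples)
  m <- n - tau_samples
  cbind(x = samples[seq_len(m)], y = samples[seq_len(m) + tau_samples])
}

#' Rasterize a trajectory onto a binary occupancy grid
#'
#' Partitions the unit square into `r x r` equal cells and records the
#' absence (0) or presence (1) of the trajectory in each cell. The column
#' index of a point is `min(floor(x * r), r - 1)`; y increases upward, so
#' matrix row 1 is the top of the image: row index
#' `r - min(floor(y * r), r - 1)`. Points on the upper boundaries (x or y
#' equal to 1) are clamped into the last cell.
#'
#' @param points Two-column matrix of coordinates in \[0, 1\]^2.
#' @param partitions Grid partitions per axis, `r >= 2`.
#' @return Binary `r x r` matrix (integer 0/1).
#' @export
rasterize_trajectory <- function(points, partitions) {
  if (!is.matrix(points) || ncol(points) != 2) {
    stop("points must be a two-column matrix")
  }
  if (partitions < 2) stop("partitions must be at least 2")
  if (any(points < 0) || any(points > 1)) {
    stop("all coordinates must lie in [0, 1]")
  }
  r <- as.integer(partitions)
  col <- pmin(floor(points[, 1] * r), r - 1L) + 1L
  row <- r - pmin(floor(points[, 2] * r), r - 1L)
  grid <- matrix(0L, r, r)
  grid[cbind(row, col)] <- 1L
  grid
}

#' Resize a binary portrait by block replication
#'
#' Nearest-neighbour upscaling: each grid cell becomes a
#' `(p / r) x (p / r)` block of identical pixels, so the image stays
#' binary and the occupied-pixel fraction equals the occupied-cell
#' fraction exactly. `p` must be a multiple of `r`.
#'
#' @param grid Binary `r x r` matrix.
#' @param out_pixels Output size `p` (>= r, divisible by r).
#' @return Binary `p x p` matrix.
#' @export
resize_portrait <- function(grid, out_pixels) {
  r <- nrow(grid)
  if (out_pixels < r) stop("out_pixels must be >= the grid size")
  if (out_pixels %% r != 0) stop("out_pixels must be divisible by the grid size")
  b <- out_pixels %/% r
  if (b == 1L) return(grid)
  grid[rep(seq_len(r), each = b), rep(seq_len(r), each = b)]
}

#' Transform a single beat into a binary phase portrait
#'
#' Full transform chain: Gaussian upsampling by `upsample_factor`,
#' amplitude normalization to \[0, 1\], 2D delay embedding with
#' `tau_ms`, rasterization over a `partitions x partitions` grid, and
#' block resize to `out_pixels x out_pixels`. The delay is converted to
#' samples at the upsampled rate:
#' `tau_samples = round(tau_ms * fs * upsample_factor / 1000)`, so delays
#' of a few ms are exactly representable at 1 kSa/s input. Because the
#' normalization absorbs affine amplitude changes, portraits are
#' invariant to beat-wise gain and offset.
#'
#' @param beat Numeric vector of one beat's samples, or a one-row slice
#'   of the beat tibble from [segment_beats()].
#' @param tau_ms Time delay, ms.
#' @param partitions Grid partitions per axis.
#' @param out_pixels Output image size (default 256).
#' @param fs Sampling rate of the beat, Sa/s (default 1000).
#' @param subject_id Label carried into the portrait.
#' @param upsample_factor Upsampling factor (default 10).
#' @return A `phase_portrait`: list with `grid`, `image`, `tau_ms`,
#'   `partitions`, `out_pixels`, `subject_id`.
#' @export
beat_to_portrait <- function(beat, tau_ms, partitions, out_pixels = 256,
                             fs = 1000, subject_id = NA_character_,
                             upsample_factor = 10) {
  if (is.data.frame(beat)) {
    stopifnot(nrow(beat) == 1)
    subject_id <- beat$subject_id
    beat <- beat$samples[[1]]
  }
  up <- upsample_gaussian(beat, upsample_factor)
  xn <- normalize_unit(up)
  tau_samples <- round(tau_ms * fs * upsample_factor / 1000)
  pts <- delay_embed(xn, tau_samples)
  grid <- rasterize_trajectory(pts, partitions)
  image <- resize_portrait(grid, out_pixels)
  new_phase_portrait(grid, image, tau_ms, partitions, out_pixels, subject_id)
}

#' Construct a phase-portrait object
#'
#' @param grid Binary `r x r` occupancy matrix with at least one
#'   occupied cell.
#' @param image Binary `p x p` resized image.
#' @param tau_ms Time delay, ms.
#' @param partitions Grid partitions `r`.
#' @param out_pixels Image size `p`.
#' @param subject_id Label.
#' @return A `phase_portrait` object.
#' @export
new_phase_portrait <- function(grid, image, tau_ms, partitions, out_pixels,
                               subject_id = NA_character_) {
  stopifnot(all(grid %in% c(0L, 1L)), any(grid == 1L),
            all(image %in% c(0L, 1L)),
            nrow(grid) == partitions, ncol(grid) == partitions,
            nrow(image) == out_pixels, ncol(image) == out_pixels,
            out_pixels >= partitions)
  structure(
    list(grid = grid, image = image, tau_ms = tau_ms,
         partitions = as.integer(partitions),
         out_pixels = as.integer(out_pixels), subject_id = subject_id),
    class = "phase_portrait"
  )
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf(
    "<phase_portrait> %s: tau = %g ms, %d x %d grid -> %d x %d image, %d/%d cells occupied\n",
    x$subject_id, x$tau_ms, x$partitions, x$partitions, x$out_pixels,
    x$out_pixels, sum(x$grid), x$partitions^2))
  invisible(x)
}

#' Build portraits for every beat of a beat tibble
#'
#' @param beats Beat tibble from [segment_beats()] / [preprocess_cohort()].
#' @param tau_ms Time delay, ms.
#' @param partitions Grid partitions per axis.
#' @param out_pixels Image size (default 256).
#' @param fs Sampling rate, Sa/s.
#' @return The beat tibble with a `portrait` list-column appended (the
#'   `samples` column is dropped).
#' @export
portraits_from_beats <- function(beats, tau_ms, partitions, out_pixels = 256,
                                 fs = 1000) {
  stopifnot(is.data.frame(beats), "samples" %in% names(beats))
  out <- dplyr::mutate(
    beats,
    portrait = purrr::map2(.data$samples, .data$subject_id,
                           ~ beat_to_portrait(.x, tau_ms, partitions,
                                              out_pixels, fs,
                                              subject_id = .y))
  )
  dplyr::select(out, -"samples")
}
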