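# WFDB interchange (format 16): plain-text .hea header plus interleaved
# little-endian int16 .dat. This covers the layout used by the public
# diagnostic ECG archives this pipeline targets; other storage formats
# are out of scope.

#' Read one lead of a WFDB record
#'
#' Parses the header for sampling rate, gain, baseline and lead names,
#' reads the interleaved 16-bit signal file, and converts the requested
#' lead to physical units via `(adc - baseline) / gain`. Lead names are
#' matched case-insensitively.
#'
#' @param path Record path without extension (reads `path.hea` and the
#'   signal file named in the header).
#' @param lead Lead name, e.g. `"I"` (default).
#' @return An `ecg_record` in mV. If a sibling file `<record>.rpeaks`
#'   exists (one 1-based index per line), it is attached as
#'   `true_r_locations`.
#' @export
read_wfdb_record <- function(path, lead = "I") {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- sub("/.*", "", head_fields[1])
  nsig <- as.integer(head_fields[2])
  fs <- if (length(head_fields) >= 3) as.numeric(sub("/.*", "", head_fields[3])) else 250
  nsamp <- if (length(head_fields) >= 4) as.integer(head_fields[4]) else NA_integer_

  sig <- lapply(lines[1 + seq_len(nsig)], parse_signal_line)
  leads <- vapply(sig, `[[`, character(1), "description")
  hit <- which(tolower(leads) == tolower(lead))
  if (length(hit) != 1) {
    stop("lead '", lead, "' not found; available leads: ",
         paste(leads, collapse = ", "))
  }
  fmt <- unique(vapply(sig, `[[`, character(1), "format"))
  if (!identical(fmt, "16")) {
    stop("only WFDB format 16 is supported, got: ",
         paste(fmt, collapse = ", "))
  }
  dat <- unique(vapply(sig, `[[`, character(1), "file"))
  if (length(dat) != 1) stop("multi-file records are not supported")
  datpath <- file.path(dirname(path), dat)
  if (!file.exists(datpath)) stop("signal file not found: ", datpath)
  raw_n <- file.info(datpath)$size / 2
  adc <- readBin(datpath, "integer", n = raw_n, size = 2, signed = TRUE,
                 endian = "little")
  total <- length(adc) %/% nsig
  if (!is.na(nsamp)) total <- min(total, nsamp)
  channel <- adc[seq.int(hit, by = nsig, length.out = total)]
  s <- sig[[hit]]
  samples <- (channel - s$baseline) / s$gain
  rp <- paste0(path, ".rpeaks")
  r_locs <- if (file.exists(rp)) as.integer(readLines(rp, warn = FALSE)) else NULL
  new_ecg_record(samples, fs, subject_id = record_name,
                 true_r_locations = r_locs)
}

parse_signal_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  gain_field <- if (length(f) >= 3) f[3] else "200"
  gain_core <- sub("/.*", "", gain_field)
  baseline <- 0
  if (grepl("\\(", gain_core)) {
    baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_core))
    gain_core <- sub("\\(.*", "", gain_core)
  }
  gain <- as.numeric(gain_core)
  if (is.na(gain) || gain == 0) gain <- 200
  # description: everything after the fixed numeric fields (field 9+), or a
  # fallback name
  desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else
    paste0("ch", f[1])
  list(file = f[1], format = sub("[+:x].*", "", f[2]), gain = gain,
       baseline = baseline, description = desc)
}

#' Write an ECG record in WFDB format 16
#'
#' Quantizes physical mV samples with the given gain and writes
#' `<name>.hea` and `<name>.dat`; ground-truth R locations, when present,
#' go to `<name>.rpeaks` (one 1-based index per line).
#'
#' @param record An `ecg_record`.
#' @param dir Output directory (created if needed).
#' @param name Record name (default the subject id).
#' @param lead Lead name written to the header.
#' @param gain ADC units per mV.
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(record, dir, name = record$subject_id,
                              lead = "I", gain = 2000) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(record$samples)
  adc <- as.integer(round(record$samples * gain))
  adc <- pmin(pmax(adc, -32768L), 32767L)
  datfile <- paste0(name, ".dat")
  writeLines(c(
    sprintf("%s 1 %g %d", name, record$fs, n),
    sprintf("%s 16 %d(0)/mV 16 0 %d %d 0 %s", datfile, as.integer(gain),
            adc[1], 0L, lead)
  ), file.path(dir, paste0(name, ".hea")))
  writeBin(adc, file.path(dir, datfile), size = 2, endian = "little")
  if (!is.null(record$true_r_locations)) {
    writeLines(as.character(record$true_r_locations),
               file.path(dir, paste0(name, ".rpeaks")))
  }
  invisible(file.path(dir, name))
}

#' Persist a phase portrait as PNG plus JSON sidecar
#'
#' The binary image round-trips bit-exactly through an 8-bit grayscale
#' PNG (values 0 and 1 map to black and white); the sidecar
#' (`<path>.json`) stores `tau_ms`, `partitions`, `out_pixels` and
#' `subject_id`. Loading verifies that the image dimensions match the
#' sidecar.
#'
#' @param portrait A `phase_portrait`.
#' @param path Output PNG path.
#' @return `save_portrait()` returns `path` invisibly; `load_portrait()`
#'   returns the reconstructed `phase_portrait` (its `grid` is recovered
#'   by block-downsampling the image, exact because resizing replicates
#'   blocks).
#' @export
save_portrait <- function(portrait, path) {
  stopifnot(inherits(portrait, "phase_portrait"))
  img <- portrait$image
  storage.mode(img) <- "double"   # writePNG expects values in [0, 1]
  png::writePNG(img, path)
  meta <- list(tau_ms = portrait$tau_ms, partitions = portrait$partitions,
               out_pixels = portrait$out_pixels,
               subject_id = portrait$subject_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_portrait
#' @export
load_portrait <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!all(img %in% c(0, 1))) stop("portrait PNG is not binary")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (nrow(img) != meta$out_pixels || ncol(img) != meta$out_pixels) {
    stop("sidecar out_pixels (", meta$out_pixels,
         ") does not match image size (", nrow(img), ")")
  }
  if (meta$out_pixels %% meta$partitions != 0 ||
      meta$out_pixels < meta$partitions) {
    stop("sidecar partitions (", meta$partitions,
         ") incompatible with image size (", meta$out_pixels, ")")
  }
  b <- meta$out_pixels %/% meta$partitions
  sel <- seq(1, meta$out_pixels, by = b)
  grid <- matrix(as.integer(img[sel, sel]), meta$partitions)
  storage.mode(img) <- "integer"
  new_phase_portrait(grid, img, meta$tau_ms, meta$partitions,
                     meta$out_pixels, meta$subject_id)
}

#' Write sweep results to CSV files
#'
#' Writes `results.csv` (columns `tau_ms`, `grid`, `epoch`,
#' `val_accuracy`), `stages.csv` (stage averages), and, when any cell
#' failed, `failed.csv`. Accuracies are formatted at two decimals and row
#' order is fixed (tau, grid, epoch), so output is byte-stable for equal
#' inputs.
#'
#' @param sweep A `psr_sweep`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep_results <- function(sweep, dir) {
  stopifnot(inherits(sweep, "psr_sweep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- dplyr::arrange(sweep$results, .data$tau_ms, .data$grid, .data$epoch)
  res$val_accuracy <- sprintf("%.2f", res$val_accuracy)
  readr::write_csv(res, file.path(dir, "results.csv"))
  st <- dplyr::arrange(sweep$stages, .data$tau_ms, .data$grid, .data$stage)
  st$mean_accuracy <- sprintf("%.2f", st$mean_accuracy)
  readr::write_csv(st, file.path(dir, "stages.csv"))
  if (nrow(sweep$failed)) {
    readr::write_csv(sweep$failed, file.path(dir, "failed.csv"))
  }
  invisible(dir)
}

#' @rdname write_sweep_results
#' @param config The `experiment_config` to attach (defaults to a fresh
#'   default configuration).
#' @export
read_sweep_results <- function(dir, config = experiment_config()) {
  res <- readr::read_csv(file.path(dir, "results.csv"),
                         show_col_types = FALSE)
  st <- readr::read_csv(file.path(dir, "stages.csv"), show_col_types = FALSE,
                        col_types = readr::cols(
                          epochs = readr::col_character()))
  fpath <- file.path(dir, "failed.csv")
  failed <- if (file.exists(fpath)) {
    readr::read_csv(fpath, show_col_types = FALSE)
  } else {
    tibble::tibble(tau_ms = numeric(), grid = numeric(),
                   reason = character())
  }
  structure(list(results = res, stages = st, failed = failed,
                 config = config),
            class = "psr_sweep")
}
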