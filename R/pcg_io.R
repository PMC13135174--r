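#' Construct a phonocardiogram record
#'
#' The central container of the package: a single-channel heart-sound signal
#' with its sampling rate, the participant it came from, optional ECG R-peak
#' times, and an optional angiographic stenosis label.
#'
#' @param samples numeric vector of amplitudes (dimensionless).
#' @param fs sampling rate in Hz (> 0).
#' @param participant_id opaque identifier string.
#' @param r_times optional strictly increasing ECG R-peak times in seconds.
#' @param stenosis_pct optional stenosis percent in `[0, 100]`.
#' @param label optional class label; if omitted and `stenosis_pct` is given,
#'   it is derived via [stenosis_to_class()].
#' @return an object of class `pcg_record`.
#' @export
pcg_record <- function(samples, fs, participant_id = "anon", r_times = NULL,
                       stenosis_pct = NULL, label = NULL) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (!is.null(r_times)) {
    if (is.unsorted(r_times, strictly = TRUE)) stop("r_times must be strictly increasing")
  }
  if (!is.null(stenosis_pct)) {
    if (stenosis_pct < 0 || stenosis_pct > 100) stop("stenosis_pct must lie in [0, 100]")
    derived <- stenosis_to_class(stenosis_pct)
    if (is.null(label)) label <- derived
    else if (!identical(label, derived)) {
      stop(sprintf("label '%s' inconsistent with stenosis_pct %.1f (expected '%s')",
                   label, stenosis_pct, derived))
    }
  }
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 participant_id = as.character(participant_id),
                 r_times = r_times, stenosis_pct = stenosis_pct, label = label),
            class = "pcg_record")
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("<pcg_record> participant %s: %d samples @ %g Hz (%.2f s)%s\n",
              x$participant_id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (!is.null(x$stenosis_pct)) sprintf(", stenosis %.0f%% [%s]",
                                                    x$stenosis_pct, x$label) else ""))
  invisible(x)
}

#' Read a RIFF WAV file into a `pcg_record`
#'
#' Supports 16-bit integer PCM and 32-bit IEEE float encodings. Multi-channel
#' files are reduced to the first channel with a logged warning. Integer PCM
#' samples are scaled by `1 / 2^(bits - 1)` so the amplitude range is
#' `[-1, 1]`.
#'
#' @param path path to a WAV file.
#' @param participant_id identifier stored on the returned record.
#' @return a [pcg_record()].
#' @export
read_wav <- function(path, participant_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      fmt <- list(format = audio_format, channels = n_channels, fs = sample_rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$format == 1L && fmt$bits == 16L) {
        raw <- readBin(con, "integer", n = size / 2, size = 2, endian = "little", signed = TRUE)
        samples <- raw / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", n = size / 4, size = 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d-bit)", fmt$format, fmt$bits))
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(samples) || length(samples) == 0L) stop("WAV file contains no audio data: ", path)
  if (fmt$channels > 1L) {
    pcg_log("read_wav: %d channels in %s, keeping channel 1", fmt$channels, basename(path))
    samples <- samples[seq(1, length(samples), by = fmt$channels)]
  }
  pcg_record(samples, fmt$fs, participant_id = participant_id)
}

#' Write a `pcg_record` (or numeric vector) to a WAV file
#'
#' @param x a [pcg_record()] or numeric vector.
#' @param path output path.
#' @param fs sampling rate in Hz; taken from the record when `x` is one.
#' @param bit_depth `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL, bit_depth = c("pcm16", "float32")) {
  bit_depth <- match.arg(bit_depth)
  if (inherits(x, "pcg_record")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stop("fs required when x is a bare numeric vector")
  if (length(x) == 0L) stop("refusing to write zero-length audio")
  con <- file(path, "wb")
  on.exit(close(con))
  if (bit_depth == "pcm16") {
    q <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    data_size <- 2L * length(q); fmt_code <- 1L; bits <- 16L
  } else {
    data_size <- 4L * length(x); fmt_code <- 3L; bits <- 32L
  }
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs) * bits / 8), con, size = 4, endian = "little")
  writeBin(as.integer(bits / 8), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "pcm16") writeBin(q, con, size = 2, endian = "little")
  else writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Load a cohort manifest CSV
#'
#' Required columns: `participant_id`, `stenosis_pct`, `path`; optional `age`
#' and `sex`. Participant ids must be unique and stenosis percentages must lie
#' in `[0, 100]`.
#'
#' @param path CSV path.
#' @return a `data.frame` of class `cohort_manifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

validate_manifest <- function(df) {
  required <- c("participant_id", "stenosis_pct", "path")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (anyDuplicated(df$participant_id))
      stop("duplicate participant_id in manifest: ",
           paste(unique(df$participant_id[duplicated(df$participant_id)]), collapse = ", "))
    if (any(df$stenosis_pct < 0 | df$stenosis_pct > 100))
      stop("stenosis_pct outside [0, 100] in manifest")
  }
  class(df) <- c("cohort_manifest", "data.frame")
  pcg_log("load_manifest: %d participants", nrow(df))
  df
}

# info-level stage logging, silenced unless options(pcgewt.verbose = TRUE)
pcg_log <- function(fmt, ...) {
  if (isTRUE(getOption("pcgewt.verbose", FALSE))) message(sprintf(fmt, ...))
  invisible(NULL)
}
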