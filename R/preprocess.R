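#' Resample a record to a target rate
#'
#' Rational-factor polyphase resampling with a windowed-sinc anti-alias
#' filter. A record already at the target rate is returned unchanged.
#'
#' @param record a [pcg_record()].
#' @param target_fs target sampling rate in Hz (default 2000).
#' @return the resampled [pcg_record()].
#' @export
resample_pcg <- function(record, target_fs = 2000) {
  stopifnot(inherits(record, "pcg_record"))
  if (target_fs <= 0) stop("target sampling rate must be positive")
  if (record$fs == target_fs) return(record)
  record$samples <- resample_signal(record$samples, record$fs, target_fs)
  record$fs <- target_fs
  pcg_log("resample_pcg: %s -> %g Hz (%d samples)", record$participant_id,
          target_fs, length(record$samples))
  record
}

#' Normalize amplitude to `[-1, 1]`
#'
#' Divides by the maximum absolute sample so the peak amplitude is exactly 1.
#' Applied per record, not per segment.
#'
#' @param record a [pcg_record()].
#' @return normalized [pcg_record()].
#' @export
normalize_pcg <- function(record) {
  stopifnot(inherits(record, "pcg_record"))
  m <- max(abs(record$samples))
  if (m == 0) stop("cannot normalize an all-zero signal")
  record$samples <- record$samples / m
  record
}

#' Full preprocessing chain: resample, normalize, denoise
#'
#' @param record a [pcg_record()].
#' @param config a [default_config()] list (the `preprocess` block is used).
#' @return preprocessed [pcg_record()] at the target rate.
#' @export
preprocess_pcg <- function(record, config = default_config()) {
  p <- config$preprocess
  record <- resample_pcg(record, p$target_fs)
  record <- normalize_pcg(record)
  wavelet_denoise(record, wavelet = p$wavelet, levels = p$levels,
                  mode = p$threshold_mode)
}
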