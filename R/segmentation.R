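# S2 detection and fixed-window diastole extraction.
#
# S2 candidates come from peak detection on the envelope of the high-passed
# signal (the nominal 200-2000 Hz band collapses to a 200 Hz high-pass at
# fs = 2000). S2 is told apart from S1 either by ECG R-peak gating or, when
# no ECG is available, by the rule that the gap after S2 (diastole) is
# longer than the gap after S1 (systole). The S2 end is the first time after
# the peak where the envelope drops below 10% of the peak envelope.

#' Smoothed analytic envelope
#'
#' Magnitude of the analytic (Hilbert) signal followed by a centered moving
#' average (default 20 ms).
#'
#' @param x numeric signal (non-empty).
#' @param fs sampling rate in Hz.
#' @param smooth_ms moving-average width in milliseconds.
#' @return non-negative envelope, same length as `x`.
#' @export
pcg_envelope <- function(x, fs, smooth_ms = 20) {
  if (length(x) == 0L) stop("empty signal")
  env <- analytic_envelope(x)
  moving_average(env, round(smooth_ms / 1000 * fs))
}

# local maxima above `thr`, greedily thinned to a minimum separation
find_peaks <- function(env, thr, min_sep) {
  n <- length(env)
  if (n < 3L) return(integer(0))
  cand <- which(env[2:(n - 1)] > env[1:(n - 2)] & env[2:(n - 1)] >= env[3:n]) + 1L
  cand <- cand[env[cand] >= thr]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(env[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Detect second heart sounds
#'
#' @param record a preprocessed [pcg_record()] at 2000 Hz.
#' @param r_times optional ECG R-peak times (seconds); when supplied, the
#'   envelope peak falling 0.25-0.55 of the RR interval after each R peak is
#'   taken as that cycle's S2. Otherwise S2 is the member of the alternating
#'   peak train followed by the longer inter-peak gap.
#' @param config pipeline configuration (the `segmentation` block is used).
#' @return `data.frame` with columns `peak_time`, `end_time`,
#'   `peak_envelope` (one row per detected S2; possibly zero rows).
#' @export
detect_s2 <- function(record, r_times = NULL, config = default_config()) {
  stopifnot(inherits(record, "pcg_record"))
  sc <- config$segmentation
  fs <- record$fs
  x <- record$samples
  h <- fir_highpass(201L, sc$highpass_hz / fs)
  env <- pcg_envelope(filter_zerophase(x, h), fs, sc$envelope_smooth_ms)

  thr <- sc$peak_threshold_frac * stats::quantile(env, sc$peak_threshold_quantile, names = FALSE)
  peaks <- find_peaks(env, thr, round(sc$min_peak_separation_s * fs))
  if (!length(peaks)) {
    pcg_log("detect_s2 %s: no envelope peaks", record$participant_id)
    return(data.frame(peak_time = numeric(0), end_time = numeric(0),
                      peak_envelope = numeric(0)))
  }
  pt <- (peaks - 1) / fs

  if (!is.null(r_times) && length(r_times) >= 1L) {
    rr <- diff(r_times)
    med_rr <- if (length(rr)) stats::median(rr) else 0.8
    s2_idx <- integer(0)
    for (k in seq_along(r_times)) {
      rrk <- if (k < length(r_times)) r_times[k + 1] - r_times[k] else med_rr
      in_win <- which(pt > r_times[k] + 0.25 * rrk & pt < r_times[k] + 0.55 * rrk)
      if (length(in_win)) s2_idx <- c(s2_idx, in_win[which.max(env[peaks[in_win]])])
    }
    s2_idx <- unique(s2_idx)
  } else if (length(peaks) >= 4L) {
    # alternating S1/S2: the parity class followed by the longer mean gap is S2
    gap_after <- c(diff(pt), NA)
    parity <- seq_along(peaks) %% 2L
    m1 <- mean(gap_after[parity == 1L], na.rm = TRUE)
    m0 <- mean(gap_after[parity == 0L], na.rm = TRUE)
    s2_idx <- which(parity == (if (m1 > m0) 1L else 0L))
  } else {
    s2_idx <- seq_along(peaks)  # too few peaks to disambiguate; take all
  }
  if (!length(s2_idx)) {
    return(data.frame(peak_time = numeric(0), end_time = numeric(0),
                      peak_envelope = numeric(0)))
  }
  s2_idx <- sort(s2_idx)

  out <- lapply(s2_idx, function(i) {
    p <- peaks[i]
    below <- which(env[p:length(env)] < 0.10 * env[p])
    if (!length(below)) return(NULL)
    end_i <- p + below[1] - 1L
    data.frame(peak_time = (p - 1) / fs, end_time = (end_i - 1) / fs,
               peak_envelope = env[p])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(peak_time = numeric(0), end_time = numeric(0),
                                      peak_envelope = numeric(0))
  pcg_log("detect_s2 %s: %d S2 events", record$participant_id, nrow(out))
  out
}

#' Extract fixed diastolic analysis windows
#'
#' One window per S2 event, starting `offset` (default 100 ms) after the S2
#' end and lasting `duration` (default 128 ms, i.e. 256 samples at 2000 Hz).
#' Windows running past the record end, and windows overlapping the next S1
#' onset when S1 onsets are supplied, are dropped. The first `n_keep` valid
#' windows are retained.
#'
#' @param record a [pcg_record()] at 2000 Hz.
#' @param s2_events `data.frame` from [detect_s2()] (needs `end_time`).
#' @param n_keep number of segments to retain (default 10).
#' @param offset start of the window after S2 end, seconds.
#' @param duration window length, seconds.
#' @param s1_onsets optional S1 onset times used for overlap rejection.
#' @return object of class `diastole_segments`: list with `segments` (a
#'   `round(duration * fs)` x k matrix, one column per diastole) and `meta`
#'   (`data.frame` of participant_id, cycle_index, start_time).
#' @export
extract_diastoles <- function(record, s2_events, n_keep = 10L, offset = 0.100,
                              duration = 0.128, s1_onsets = NULL) {
  stopifnot(inherits(record, "pcg_record"))
  fs <- record$fs
  len <- round(duration * fs)
  n <- length(record$samples)
  segs <- list(); meta <- list()
  for (i in seq_len(nrow(s2_events))) {
    if (length(segs) >= n_keep) break
    start_time <- s2_events$end_time[i] + offset
    start <- round(start_time * fs)        # 0-based index
    if (start + len > n) next              # past record end
    if (!is.null(s1_onsets)) {
      nxt <- s1_onsets[s1_onsets > s2_events$end_time[i]]
      if (length(nxt) && start_time + duration > nxt[1]) next  # hits next S1
    }
    segs[[length(segs) + 1L]] <- record$samples[(start + 1L):(start + len)]
    meta[[length(meta) + 1L]] <- data.frame(
      participant_id = record$participant_id, cycle_index = i,
      start_time = start / fs, stringsAsFactors = FALSE)
  }
  out <- list(
    segments = if (length(segs)) do.call(cbind, segs) else matrix(numeric(0), nrow = len, ncol = 0),
    meta = if (length(meta)) do.call(rbind, meta) else
      data.frame(participant_id = character(0), cycle_index = integer(0), start_time = numeric(0)),
    fs = fs
  )
  class(out) <- "diastole_segments"
  pcg_log("extract_diastoles %s: %d segments", record$participant_id, ncol(out$segments))
  out
}
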