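# Band spectral-energy features.
#
# Energies use the Parseval convention: the squared magnitude spectrum is
# scaled so that summing it over the whole one-sided grid equals the
# time-domain energy sum(x^2) / fs (units V^2 s). Each mode's energy e(n) is
# integrated over the full grid; because the filters partition unity, the
# mode spectra are already confined to their nominal bands (up to the smooth
# transitions) and e(1) + e(2) + e(3) equals the segment energy exactly.

#' Band-restricted spectral energy
#'
#' Sums `|F(k)|^2` over the FFT bins whose (folded, two-sided) frequency lies
#' in `band_hz`, scaled so that the full-range sum equals `sum(x^2) / fs` for
#' the spectrum `F = fft(x)` (Parseval; units V^2 s). Bands are half-open
#' `[lo, hi)` except that a band reaching Nyquist includes it.
#'
#' @param spectrum complex FFT of a (possibly zero-padded) segment.
#' @param fs sampling rate in Hz.
#' @param band_hz numeric `c(lo, hi)` with `0 <= lo < hi <= fs / 2`.
#' @return energy in V^2 s.
#' @export
spectral_energy <- function(spectrum, fs, band_hz) {
  if (band_hz[1] >= band_hz[2]) stop("inverted frequency band")
  if (band_hz[1] < 0 || band_hz[2] > fs / 2 + 1e-9) stop("band outside [0, fs/2]")
  nfft <- length(spectrum)
  f <- (0:(nfft - 1)) * fs / nfft
  fmod <- pmin(f, fs - f)
  sel <- fmod >= band_hz[1] & fmod < band_hz[2]
  if (band_hz[2] >= fs / 2 - 1e-9) sel <- sel | abs(fmod - fs / 2) < 1e-9
  sum(Mod(spectrum[sel])^2) / (nfft * fs)
}

#' Compute the diastolic feature vector
#'
#' Band energies `e1`, `e2`, `e3` (V^2 s) of the three modes and the ratios
#' `P1 = e2 / e1`, `P2 = e3 / e1`. Ratios are `NA` (with a logged warning)
#' when `e1` is zero.
#'
#' @param modes an `ewt_modes` object from [ewt_decompose()].
#' @param participant_id,cycle_index provenance stored on the row.
#' @return one-row `data.frame` with columns `participant_id`, `cycle_index`,
#'   `e1`, `e2`, `e3`, `P1`, `P2`.
#' @export
compute_features <- function(modes, participant_id = NA_character_,
                             cycle_index = NA_integer_) {
  stopifnot(inherits(modes, "ewt_modes"))
  nfft <- modes$bank$nfft
  e <- colSums(Mod(modes$spectra)^2) / (nfft * modes$fs)
  if (e[1] > 0) {
    p1 <- e[2] / e[1]; p2 <- e[3] / e[1]
  } else {
    warning("e1 = 0: ratios P1/P2 undefined for participant ", participant_id)
    p1 <- NA_real_; p2 <- NA_real_
  }
  data.frame(participant_id = participant_id, cycle_index = cycle_index,
             e1 = e[[1]], e2 = e[[2]], e3 = e[[3]], P1 = p1, P2 = p2,
             stringsAsFactors = FALSE)
}

#' Per-group feature summary
#'
#' Means (and SDs) of the feature columns within each level of `group`,
#' optionally rounded to a number of significant figures for display.
#'
#' @param rows `data.frame` of feature rows.
#' @param group name of the grouping column in `rows`.
#' @param features feature column names (default the five standard ones).
#' @param signif_digits if non-`NULL`, round the summary for display (2 is
#'   the conventional table precision).
#' @return `data.frame` with one row per group and `<feature>_mean` /
#'   `<feature>_sd` columns.
#' @export
aggregate_cohort <- function(rows, group, features = c("e1", "e2", "e3", "P1", "P2"),
                             signif_digits = NULL) {
  if (!nrow(rows)) stop("no feature rows to aggregate")
  if (!group %in% names(rows)) stop("grouping column not found: ", group)
  g <- rows[[group]]
  out <- lapply(split(rows, g), function(d) {
    stats_row <- lapply(features, function(f) {
      v <- d[[f]]
      c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
    })
    row <- as.data.frame(as.list(unlist(stats_row)))
    names(row) <- as.vector(t(outer(features, c("mean", "sd"), paste, sep = "_")))
    row$n <- nrow(d)
    row
  })
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE),
               do.call(rbind, out))
  rownames(res) <- NULL
  if (!is.null(signif_digits)) {
    num <- setdiff(names(res), c("group", "n"))
    res[num] <- lapply(res[num], signif, digits = signif_digits)
  }
  res
}

#' Train-set standardization
#'
#' Learns per-feature mean and standard deviation from training rows;
#' `apply_standardizer()` transforms any rows with the training statistics
#' only (no test-set leakage).
#'
#' @param train `data.frame` of training rows.
#' @param features columns to standardize.
#' @return object of class `pcg_standardizer`.
#' @export
fit_standardizer <- function(train, features = c("e1", "e2", "e3", "P1", "P2")) {
  if (nrow(train) < 2L) stop("need at least 2 training rows")
  center <- vapply(features, function(f) mean(train[[f]]), numeric(1))
  scale <- vapply(features, function(f) stats::sd(train[[f]]), numeric(1))
  zero <- features[scale == 0 | !is.finite(scale)]
  if (length(zero)) stop("zero-variance feature(s): ", paste(zero, collapse = ", "))
  structure(list(features = features, center = center, scale = scale),
            class = "pcg_standardizer")
}

#' @rdname fit_standardizer
#' @param std a `pcg_standardizer`.
#' @param rows rows to transform.
#' @export
apply_standardizer <- function(std, rows) {
  stopifnot(inherits(std, "pcg_standardizer"))
  for (f in std$features) {
    rows[[f]] <- (rows[[f]] - std$center[[f]]) / std$scale[[f]]
  }
  rows
}
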