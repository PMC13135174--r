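# Meyer-type empirical wavelet filter bank with fixed boundaries.
#
# The spectrum on [0, pi] (radians/sample) is split at w_1 and w_2 (150 and
# 500 Hz by default at fs = 2000). Band 1 is a scaling filter: flat to
# w_1 - tau, raised-cosine rolloff across [w_1 - tau, w_1 + tau]. Band 2 is
# a wavelet filter: sine rise across the first transition, flat passband,
# cosine fall across the second. Band 3 rises at w_2 and stays flat to pi.
# The transitions are shaped by beta(x) = x^2 (3 - 2x), which satisfies
# beta(x) + beta(1 - x) = 1, so the squared responses sum to 1 at every
# frequency: the bank is a tight frame, and analysis/synthesis with the same
# filters preserves both energy and the signal itself.

#' Meyer transition polynomial
#'
#' `beta(x) = x^2 (3 - 2x)` clamped to 0 below 0 and 1 above 1; satisfies
#' `beta(x) + beta(1 - x) = 1` on `[0, 1]`.
#'
#' @param x numeric (vectorized).
#' @return values in `[0, 1]`.
#' @export
ewt_beta <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^2 * (3 - 2 * x)
}

#' Build the three-band Meyer filter bank
#'
#' @param fs sampling rate in Hz.
#' @param boundaries_hz the two band boundaries in Hz (default `c(150, 500)`),
#'   strictly increasing and below `fs / 2`.
#' @param tau transition half-width in radians/sample (default `0.1 * pi`,
#'   shared by both boundaries).
#' @param nfft frequency-grid size (default 1024, i.e. 4x zero-padding for a
#'   256-sample diastole window).
#' @return object of class `ewt_filter_bank`: list with the `nfft` x 3 matrix
#'   `filters` of real frequency responses (symmetric about DC on the full
#'   FFT grid), the boundaries, `tau`, `fs`, `nfft` and the nominal Hz bands.
#' @export
ewt_filter_bank <- function(fs, boundaries_hz = c(150, 500), tau = 0.1 * pi,
                            nfft = 1024L) {
  if (length(boundaries_hz) != 2L || diff(boundaries_hz) <= 0)
    stop("boundaries_hz must be two strictly increasing frequencies")
  if (any(boundaries_hz >= fs / 2)) stop("band boundary at or above Nyquist")
  w_b <- pi * boundaries_hz / (fs / 2)       # radians/sample
  if (w_b[1] - tau <= 0) stop("first transition reaches DC (tau too wide)")
  if (w_b[1] + tau >= w_b[2] - tau) stop("transition bands overlap")

  # frequency of each FFT bin folded to [0, pi]
  w <- 2 * pi * (0:(nfft - 1)) / nfft
  w <- pmin(w, 2 * pi - w)

  ramp <- function(wv, wn) ewt_beta((wv - (wn - tau)) / (2 * tau))

  phi1 <- ifelse(w <= w_b[1] - tau, 1,
          ifelse(w >= w_b[1] + tau, 0, cos(pi / 2 * ramp(w, w_b[1]))))
  psi1 <- ifelse(w <= w_b[1] - tau | w >= w_b[2] + tau, 0,
          ifelse(w < w_b[1] + tau, sin(pi / 2 * ramp(w, w_b[1])),
          ifelse(w <= w_b[2] - tau, 1, cos(pi / 2 * ramp(w, w_b[2])))))
  psi2 <- ifelse(w <= w_b[2] - tau, 0,
          ifelse(w >= w_b[2] + tau, 1, sin(pi / 2 * ramp(w, w_b[2]))))

  bank <- list(
    filters = cbind(mode1 = phi1, mode2 = psi1, mode3 = psi2),
    boundaries_hz = boundaries_hz, tau = tau, fs = fs, nfft = as.integer(nfft),
    bands_hz = list(mode1 = c(0, boundaries_hz[1]),
                    mode2 = boundaries_hz,
                    mode3 = c(boundaries_hz[2], fs / 2))
  )
  class(bank) <- "ewt_filter_bank"
  bank
}

#' @export
print.ewt_filter_bank <- function(x, ...) {
  cat(sprintf("<ewt_filter_bank> fs %g Hz, boundaries %g/%g Hz, tau %.3f rad, nfft %d\n",
              x$fs, x$boundaries_hz[1], x$boundaries_hz[2], x$tau, x$nfft))
  invisible(x)
}

#' Decompose a segment into three spectral modes
#'
#' The segment is zero-padded to `nfft`, transformed, multiplied by each
#' filter response, and inverse-transformed. The returned time-domain modes
#' are truncated to the input length; the padded mode spectra are kept on the
#' object because both exact energy accounting ([compute_features()]) and
#' exact reconstruction ([ewt_reconstruct()]) live on the padded grid.
#'
#' @param segment numeric vector, length at most `bank$nfft`.
#' @param bank an [ewt_filter_bank()].
#' @return object of class `ewt_modes`: list with `modes` (length(segment) x 3
#'   real matrix), `spectra` (`nfft` x 3 complex matrix), `n`, `fs`, `bank`.
#' @export
ewt_decompose <- function(segment, bank) {
  stopifnot(inherits(bank, "ewt_filter_bank"))
  n <- length(segment)
  if (n > bank$nfft) stop("segment longer than the filter-bank grid (", bank$nfft, ")")
  if (n == 0L) stop("empty segment")
  X <- stats::fft(c(segment, rep(0, bank$nfft - n)))
  spectra <- bank$filters * matrix(X, nrow = bank$nfft, ncol = 3L)
  modes <- apply(spectra, 2L, function(s) Re(stats::fft(s, inverse = TRUE) / bank$nfft)[seq_len(n)])
  out <- list(modes = modes, spectra = spectra, n = n, fs = bank$fs, bank = bank)
  class(out) <- "ewt_modes"
  out
}

#' Reconstruct a segment from its modes
#'
#' For an `ewt_modes` object this is frame synthesis: each mode spectrum is
#' weighted by its filter once more and the results are summed, which by the
#' partition of unity returns the original segment to machine precision.
#' For a bare matrix of hand-built modes it falls back to the element-wise
#' sum of the columns.
#'
#' @param modes an `ewt_modes` object from [ewt_decompose()], or an n x 3
#'   numeric matrix of equal-length modes.
#' @return the reconstructed segment.
#' @export
ewt_reconstruct <- function(modes) {
  if (inherits(modes, "ewt_modes")) {
    bank <- modes$bank
    S <- rowSums(bank$filters * modes$spectra)
    return(Re(stats::fft(S, inverse = TRUE) / bank$nfft)[seq_len(modes$n)])
  }
  m <- as.matrix(modes)
  if (is.list(modes) && !is.data.frame(modes)) {
    lens <- lengths(modes)
    if (length(unique(lens)) != 1L) stop("modes must have equal lengths")
    m <- do.call(cbind, modes)
  }
  rowSums(m)
}
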