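# Internal DSP primitives: FFT convolution, windowed-sinc FIR design,
# analytic-signal envelope, rational resampling. No external DSP dependency.

next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

# Linear convolution via FFT, full length (length(x) + length(h) - 1).
fft_convolve <- function(x, h) {
  nx <- length(x)
  nh <- length(h)
  nfft <- next_pow2(nx + nh - 1)
  X <- stats::fft(c(x, rep(0, nfft - nx)))
  H <- stats::fft(c(h, rep(0, nfft - nh)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[seq_len(nx + nh - 1)]
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Hamming-windowed sinc low-pass. `fc` is the cutoff in cycles/sample
# (0 < fc < 0.5). Odd `numtaps` gives a symmetric (linear-phase) filter
# with integer group delay (numtaps - 1) / 2.
fir_lowpass <- function(numtaps, fc) {
  stopifnot(fc > 0, fc < 0.5)
  if (numtaps %% 2 == 0) numtaps <- numtaps + 1
  m <- seq_len(numtaps) - 1 - (numtaps - 1) / 2
  h <- 2 * fc * sinc(2 * fc * m)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(numtaps - 1)) / (numtaps - 1))
  h <- h * w
  h / sum(h)  # unit DC gain
}

# High-pass by spectral inversion of the complementary low-pass.
fir_highpass <- function(numtaps, fc) {
  h <- -fir_lowpass(numtaps, fc)
  mid <- (length(h) + 1) / 2
  h[mid] <- h[mid] + 1
  h
}

# Zero-phase FIR filtering: convolve with a symmetric odd-length kernel and
# remove the integer group delay so features stay time-aligned.
filter_zerophase <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  d <- (length(h) - 1) / 2
  y <- fft_convolve(x, h)
  y[(d + 1):(d + length(x))]
}

# Magnitude of the analytic signal (FFT-based Hilbert transform).
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  if (n == 1L) return(abs(x))
  X <- stats::fft(x)
  w <- rep(0, n)
  w[1] <- 1
  if (n %% 2 == 0) {
    w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * w, inverse = TRUE) / n)
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rational-factor resampling: upsample by L, anti-alias FIR, downsample by M.
# Sampling rates are taken as integers (Hz).
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_out <= 0) stop("target sampling rate must be positive")
  if (fs_in <= 0) stop("input sampling rate must be positive")
  fs_in_i <- round(fs_in)
  fs_out_i <- round(fs_out)
  if (fs_in_i == fs_out_i) return(x)
  if (length(x) < 2L) stop("signal too short to resample (need >= 2 samples)")
  g <- gcd_int(fs_in_i, fs_out_i)
  up <- fs_out_i %/% g
  down <- fs_in_i %/% g
  n <- length(x)
  # zero-stuff
  y <- numeric(n * up)
  y[seq(1, length(y), by = up)] <- x
  # anti-alias / anti-image low-pass at the upsampled rate
  fc <- 0.5 / max(up, down)
  numtaps <- 2L * 10L * max(up, down) + 1L
  h <- fir_lowpass(numtaps, fc * 0.98) * up
  y <- filter_zerophase(y, h)
  out_len <- floor(n * up / down)
  idx <- 1L + (seq_len(out_len) - 1L) * down
  y[idx]
}

gcd_int <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Band-limited unit-RMS Gaussian noise via an FFT-domain mask with
# raised-cosine edges (used by the murmur synthesizer).
bandlimited_noise <- function(n, fs, band, edge_hz = 20) {
  w <- stats::rnorm(n)
  nfft <- next_pow2(n)
  X <- stats::fft(c(w, rep(0, nfft - n)))
  f <- (0:(nfft - 1)) * fs / nfft
  fmod <- pmin(f, fs - f)
  mask <- rep(0, nfft)
  lo <- band[1]; hi <- band[2]
  mask[fmod >= lo & fmod <= hi] <- 1
  rise <- fmod > lo - edge_hz & fmod < lo
  mask[rise] <- 0.5 * (1 + cos(pi * (lo - fmod[rise]) / edge_hz))
  fall <- fmod > hi & fmod < hi + edge_hz
  mask[fall] <- 0.5 * (1 + cos(pi * (fmod[fall] - hi) / edge_hz))
  y <- Re(stats::fft(X * mask, inverse = TRUE) / nfft)[seq_len(n)]
  r <- sqrt(mean(y^2))
  if (r == 0) y else y / r
}
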