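# Orthogonal discrete wavelet transform (periodized) and universal-threshold
# denoising. The sym3 filter (identical to db3) is the default basis; the
# synthesis step is the adjoint of the analysis step, which for an
# orthonormal periodized filter pair gives exact reconstruction.

# db3 / sym3 orthonormal scaling filter (reconstruction low-pass)
.wavelet_filters <- list(
  sym3 = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849160,
           -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db3 = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849160,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953)
)

get_wavelet_filters <- function(name) {
  h <- .wavelet_filters[[tolower(name)]]
  if (is.null(h)) stop("unknown wavelet: ", name,
                       " (available: ", paste(names(.wavelet_filters), collapse = ", "), ")")
  L <- length(h)
  n <- seq_len(L) - 1
  list(dec_lo = rev(h), dec_hi = (-1)^n * h)
}

# One periodized analysis step; x must have even length.
dwt_step <- function(x, f) {
  N <- length(x)
  half <- N %/% 2L
  base <- 2L * (seq_len(half) - 1L)
  a <- numeric(half); d <- numeric(half)
  for (n in seq_along(f$dec_lo)) {
    xv <- x[((base + n - 1L) %% N) + 1L]
    a <- a + f$dec_lo[n] * xv
    d <- d + f$dec_hi[n] * xv
  }
  list(a = a, d = d)
}

# Adjoint (= inverse, by orthonormality) of dwt_step.
idwt_step <- function(a, d, f) {
  half <- length(a)
  N <- 2L * half
  base <- 2L * (seq_len(half) - 1L)
  y <- numeric(N)
  for (n in seq_along(f$dec_lo)) {
    idx <- ((base + n - 1L) %% N) + 1L
    contrib <- f$dec_lo[n] * a + f$dec_hi[n] * d
    y[idx] <- y[idx] + contrib
  }
  y
}

# Multi-level periodized DWT. Input is zero-padded to a multiple of 2^levels;
# the original length is kept so the inverse can truncate back.
dwt_forward <- function(x, wavelet = "sym3", levels = 3L) {
  f <- get_wavelet_filters(wavelet)
  n0 <- length(x)
  if (n0 < 2^levels) stop("signal too short for ", levels, "-level decomposition")
  block <- 2^levels
  pad <- (block - n0 %% block) %% block
  a <- c(x, rep(0, pad))
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- dwt_step(a, f)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details, wavelet = wavelet, levels = levels, n = n0)
}

dwt_inverse <- function(dec) {
  f <- get_wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$details[[j]], f)
  }
  a[seq_len(dec$n)]
}

#' Robust noise scale from detail coefficients
#'
#' `sigma = median(|CD_j|) / 0.6745`, the median-absolute-deviation estimate
#' of the noise standard deviation at decomposition level j.
#'
#' @param cd numeric vector of detail coefficients (non-empty).
#' @return estimated noise standard deviation.
#' @export
noise_sigma <- function(cd) {
  if (length(cd) == 0L) stop("empty detail coefficient vector")
  stats::median(abs(cd)) / 0.6745
}

#' Universal shrinkage threshold
#'
#' `beta = sigma * sqrt(2 * ln(N))` with the natural logarithm, where `N` is
#' the number of coefficients at the level being thresholded.
#'
#' @param sigma noise scale (>= 0), typically from [noise_sigma()].
#' @param n coefficient count (>= 1).
#' @return the threshold.
#' @export
universal_threshold <- function(sigma, n) {
  if (n < 1) stop("coefficient count must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  sigma * sqrt(2 * log(n))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
hard_threshold <- function(x, t) x * (abs(x) > t)

#' Wavelet threshold denoising
#'
#' Decomposes the signal with a `levels`-deep sym3 wavelet transform,
#' thresholds each detail band with its own universal threshold (noise scale
#' estimated per level from the median absolute detail coefficient), leaves
#' the approximation band untouched, and reconstructs at the original length.
#'
#' @param x a [pcg_record()] or numeric vector.
#' @param wavelet wavelet name (default `"sym3"`).
#' @param levels decomposition depth (default 3).
#' @param mode `"soft"` (default) or `"hard"` thresholding.
#' @return same type as `x`, denoised.
#' @export
wavelet_denoise <- function(x, wavelet = "sym3", levels = 3L, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  rec <- NULL
  if (inherits(x, "pcg_record")) { rec <- x; x <- rec$samples }
  dec <- dwt_forward(x, wavelet, levels)
  shrink <- if (mode == "soft") soft_threshold else hard_threshold
  for (j in seq_len(levels)) {
    cd <- dec$details[[j]]
    beta <- universal_threshold(noise_sigma(cd), length(cd))
    dec$details[[j]] <- shrink(cd, beta)
  }
  y <- dwt_inverse(dec)
  pcg_log("wavelet_denoise: %d samples, %d levels (%s)", length(y), levels, mode)
  if (is.null(rec)) y else { rec$samples <- y; rec }
}
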