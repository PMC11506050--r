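#' Remove mean and linear trend
#'
#' Least-squares removal of an affine trend, the standard guard against very
#' slow electrode drift before infra-slow phase analysis.
#'
#' @param x numeric vector (>= 3 samples).
#' @return residual of the ordinary least-squares line fit (zero mean, zero
#'   linear trend).
#' @export
detrend_zero_mean <- function(x) {
  if (length(x) < 3)
    isa_stop("isa_insufficient_data", "detrending needs at least 3 samples")
  tt <- seq_along(x)
  stats::.lm.fit(cbind(1, tt), x)$residuals
}

# FFT-based convolution of x with FIR taps b, "same" alignment assuming the
# group delay of a linear-phase filter of length(b) taps.
fir_conv_same <- function(x, b) {
  n <- length(x); m <- length(b)
  nfft <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(b, numeric(nfft - m))), inverse = TRUE)) / nfft
  d <- (m - 1) %/% 2
  y[(d + 1):(d + n)]
}

# Zero-phase FIR filtering: forward pass, then a pass over the time-reversed
# output. Magnitude response is |B|^2; phase response is exactly zero.
fir_filtfilt <- function(x, b) {
  y <- fir_conv_same(x, b)
  rev(fir_conv_same(rev(y), b))
}

#' Downsample with anti-alias filtering
#'
#' Low-pass filters (Hamming-window FIR, cutoff 0.4 * `fs_out`, applied
#' forward-backward for zero phase) and then decimates by the integer factor
#' `fs_in / fs_out`.
#'
#' @param x numeric vector.
#' @param fs_in input sampling rate (Hz); must be an integer multiple of
#'   `fs_out`.
#' @param fs_out output sampling rate (Hz), default 8.
#' @return decimated vector of length `ceiling(length(x) * fs_out / fs_in)`.
#' @export
downsample <- function(x, fs_in, fs_out = 8) {
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    isa_stop("isa_invalid_rate", "fs_in (%g) must be an integer multiple of fs_out (%g)",
             fs_in, fs_out)
  ratio <- round(ratio)
  if (ratio == 1) return(x)
  cutoff <- 0.4 * fs_out
  transition <- 0.1 * fs_out
  ntaps <- ceiling(3.3 * fs_in / transition)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  b <- signal::fir1(ntaps - 1, cutoff / (fs_in / 2), type = "low")
  b <- b / sum(b)   # exact unit gain at DC
  y <- fir_filtfilt(x, b)
  y[seq(1, length(x), by = ratio)]
}

#' Zero-phase narrow-band FIR filter
#'
#' Hamming-window FIR band-pass applied forward-backward (zero phase
#' distortion, as required for instantaneous-phase analysis). The filter
#' length is `ceiling(3.3 * fs / transition)` taps, i.e. the classic
#' Hamming-window design rule for the requested transition width.
#'
#' @param x numeric vector, longer than the filter.
#' @param band numeric length-2: (low, high) edges in Hz, 0 < low < high < fs/2.
#' @param fs sampling rate in Hz.
#' @param transition transition width in Hz (default 0.005).
#' @return filtered vector of the same length, with attributes `valid_mask`
#'   (logical; FALSE within one filter length of either end) and
#'   `filter_length` (taps).
#' @export
bandpass_fir <- function(x, band, fs, transition = 0.005) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    isa_stop("isa_invalid_spec", "band edges must satisfy 0 < low < high < fs/2")
  ntaps <- ceiling(3.3 * fs / transition)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  if (length(x) <= ntaps)
    isa_stop("isa_insufficient_data",
             "signal (%d samples) is not longer than the filter (%d taps)",
             length(x), ntaps)
  b <- signal::fir1(ntaps - 1, band / (fs / 2), type = "pass")
  y <- fir_filtfilt(x, b)
  valid <- rep(TRUE, length(x))
  valid[seq_len(min(ntaps, length(x)))] <- FALSE
  valid[seq(length(x), by = -1, length.out = min(ntaps, length(x)))] <- FALSE
  attr(y, "valid_mask") <- valid
  attr(y, "filter_length") <- ntaps
  y
}

#' Instantaneous phase via the Hilbert transform
#'
#' Phase (argument) of the analytic signal, computed in the frequency domain.
#' Meaningful for zero-mean narrow-band input.
#'
#' @param x numeric vector, not identically zero.
#' @return phase vector in (-pi, pi].
#' @export
hilbert_phase <- function(x) {
  if (all(x == 0))
    isa_stop("isa_undefined_phase", "phase of an all-zero signal is undefined")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(h * stats::fft(x), inverse = TRUE) / n
  wrap_pi(Arg(analytic))
}

#' Preprocess a recording into per-band phase tensors
#'
#' Applies, in order: zero-mean linear detrending, downsampling to `fs_out`,
#' the spherical-spline surface Laplacian (EEG only), zero-phase narrow-band
#' FIR filtering for each analysis band, and the Hilbert transform. The GSR
#' channel receives the identical treatment minus the Laplacian.
#'
#' @param rec an `isa_recording`.
#' @param bands numeric vector of band lower edges (Hz).
#' @param band_width band width in Hz (band b spans `[f_b, f_b + band_width]`).
#' @param fs_out analysis sampling rate (Hz).
#' @param transition FIR transition width in Hz.
#' @param apply_csd apply the surface Laplacian to the EEG (default TRUE).
#' @param csd_m,csd_lambda,csd_nmax spline flexibility, smoothing constant and
#'   Legendre truncation order of the surface Laplacian.
#' @param keep_filtered also return the band-passed EEG (needed for
#'   functional connectivity).
#' @return list of class `isa_phase_tensors`: `eeg` (channels x samples x
#'   bands phase array), `gsr` (samples x bands phase matrix), `valid`
#'   (samples x bands logical), `fs`, `band_edges` (bands x 2), and optionally
#'   `filtered_eeg` (channels x samples x bands).
#' @export
preprocess_recording <- function(rec, bands, band_width = 0.01, fs_out = 8,
                                 transition = 0.005, apply_csd = TRUE,
                                 csd_m = 4, csd_lambda = 1e-5, csd_nmax = 50,
                                 keep_filtered = FALSE) {
  stopifnot(inherits(rec, "isa_recording"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cls <- class(e)[1]
      isa_stop(cls, "[stage %s] %s", name, conditionMessage(e))
    })
  }
  nch <- nrow(rec$eeg)
  eeg <- stage("detrend", t(apply(rec$eeg, 1, detrend_zero_mean)))
  gsr <- stage("detrend", detrend_zero_mean(rec$gsr))
  if (rec$fs != fs_out) {
    eeg <- stage("downsample",
                 t(apply(eeg, 1, downsample, fs_in = rec$fs, fs_out = fs_out)))
    gsr <- stage("downsample", downsample(gsr, rec$fs, fs_out))
  }
  if (apply_csd) {
    eeg <- stage("surface_laplacian",
                 surface_laplacian(eeg, rec$montage, m = csd_m,
                                   lambda = csd_lambda, n_legendre = csd_nmax))
  }
  n <- length(gsr)
  nb <- length(bands)
  phases <- array(NA_real_, c(nch, n, nb))
  gsr_ph <- matrix(NA_real_, n, nb)
  valid <- matrix(TRUE, n, nb)
  filt <- if (keep_filtered) array(NA_real_, c(nch, n, nb)) else NULL
  for (b in seq_len(nb)) {
    edge <- c(bands[b], bands[b] + band_width)
    g <- stage("bandpass", bandpass_fir(gsr, edge, fs_out, transition))
    valid[, b] <- attr(g, "valid_mask")
    gsr_ph[, b] <- stage("hilbert", hilbert_phase(as.numeric(g)))
    for (ch in seq_len(nch)) {
      y <- stage("bandpass", bandpass_fir(eeg[ch, ], edge, fs_out, transition))
      if (keep_filtered) filt[ch, , b] <- as.numeric(y)
      phases[ch, , b] <- stage("hilbert", hilbert_phase(as.numeric(y)))
    }
  }
  structure(list(
    eeg = phases, gsr = gsr_ph, valid = valid, fs = fs_out,
    band_edges = cbind(low = bands, high = bands + band_width),
    filtered_eeg = filt
  ), class = "isa_phase_tensors")
}
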