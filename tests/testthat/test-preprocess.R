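test_that("detrending removes exactly the least-squares line", {
  tt <- 1:500
  expect_lt(max(abs(detrend_zero_mean(3 + 0.25 * tt))), 1e-9)
  # zero-mean, zero-trend input passes through (cosine over whole periods,
  # symmetric about the midpoint, has no least-squares line component)
  n <- 1000
  x <- cos(2 * pi * 0.005 * ((0:(n - 1)) - (n - 1) / 2))
  expect_lt(max(abs(detrend_zero_mean(x) - x)), 1e-6)
  # brute-force normal-equations oracle
  set.seed(42)
  y <- rnorm(200) + 0.1 * (1:200)
  X <- cbind(1, 1:200)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(detrend_zero_mean(y), as.numeric(y - X %*% beta), tolerance = 1e-10)
  out <- detrend_zero_mean(y)
  expect_lt(abs(mean(out)), 1e-10 * sd(y))
  expect_error(detrend_zero_mean(c(1, 2)), class = "isa_insufficient_data")
})

test_that("downsampling preserves the passband and suppresses near-Nyquist tones", {
  fs_in <- 256
  tt <- (0:(fs_in * 200 - 1)) / fs_in
  d <- downsample(sin(2 * pi * 0.05 * tt), fs_in, 8)
  expect_equal(length(d), ceiling(length(tt) * 8 / fs_in))
  interior <- 200:(length(d) - 200)
  expect_lt(abs(max(abs(d[interior])) - 1), 0.01)
  # DC is preserved (away from the anti-alias filter's edge transients)
  dc <- downsample(rep(2.5, 256 * 120), 256, 8)
  expect_equal(length(dc), 960)
  expect_equal(dc[300:660], rep(2.5, 361), tolerance = 1e-6)
  # FFT-amplitude oracle: 3.9 Hz tone attenuated > 20 dB, 0.05 Hz intact
  d2 <- downsample(sin(2 * pi * 0.05 * tt) + sin(2 * pi * 3.9 * tt), fs_in, 8)
  sp <- 2 * abs(fft(d2)) / length(d2)
  fr <- (seq_along(sp) - 1) * 8 / length(sp)
  amp_hi <- max(sp[abs(fr - 3.9) < 0.02])
  amp_lo <- max(sp[abs(fr - 0.05) < 0.02])
  expect_lt(20 * log10(amp_hi), -20)
  expect_gt(amp_lo, 0.95)
  expect_error(downsample(rnorm(100), 12, 8), class = "isa_invalid_rate")
})

test_that("zero-phase band-pass keeps the passband tone and kills distant tones", {
  fs <- 8
  tt <- (0:49999) / fs
  x <- cos(2 * pi * 0.045 * tt)
  y <- bandpass_fir(x, c(0.04, 0.05), fs, transition = 0.01)
  v <- attr(y, "valid_mask")
  L <- attr(y, "filter_length")
  expect_false(any(v[1:(L %/% 2)]))
  expect_false(any(v[(length(v) - L %/% 2):length(v)]))
  # amplitude within 5%
  expect_lt(abs(max(abs(y[v])) - 1), 0.05)
  # zero phase: project both onto the tone's analytic exponential
  zref <- sum(x[v] * exp(-1i * 2 * pi * 0.045 * tt[v]))
  zout <- sum(y[v] * exp(-1i * 2 * pi * 0.045 * tt[v]))
  expect_lt(abs(Arg(zout / zref)), 0.01)
  # tone at 3x the upper edge: >= 40 dB down (FFT-amplitude oracle)
  x2 <- cos(2 * pi * 0.15 * tt)
  y2 <- bandpass_fir(x2, c(0.04, 0.05), fs, transition = 0.01)
  expect_lt(20 * log10(max(abs(y2[v])) / 1), -40)
  # linearity: zeros map to zeros
  expect_equal(as.numeric(bandpass_fir(numeric(30000), c(0.04, 0.05), fs,
                                       transition = 0.01)),
               numeric(30000))
  expect_error(bandpass_fir(rnorm(100), c(0.04, 0.05), fs, transition = 0.01),
               class = "isa_insufficient_data")
  expect_error(bandpass_fir(rnorm(100), c(0.05, 0.04), fs),
               class = "isa_invalid_spec")
})

test_that("Hilbert phase tracks analytic-signal identities", {
  fs <- 8
  tt <- (0:19999) / fs
  ph <- hilbert_phase(cos(2 * pi * 0.04 * tt))
  mid <- 2000:18000
  slope <- mean(diff(cumsum(c(0, wrap_pi(diff(ph))))[mid])) * fs
  expect_lt(abs(slope - 2 * pi * 0.04) / (2 * pi * 0.04), 0.01)
  # quadrature: phase of sin lags phase of cos by pi/2
  ph_sin <- hilbert_phase(sin(2 * pi * 0.04 * tt))
  lag <- Arg(mean(exp(1i * (ph[mid] - ph_sin[mid]))))
  expect_lt(abs(lag - pi / 2), 0.02)
  # amplitude modulation leaves the phase slope nearly unchanged
  am <- (1 + 0.5 * cos(2 * pi * 0.004 * tt)) * cos(2 * pi * 0.04 * tt)
  ph_am <- hilbert_phase(am)
  slope_am <- mean(diff(cumsum(c(0, wrap_pi(diff(ph_am))))[mid])) * fs
  expect_lt(abs(slope_am - slope) / slope, 0.02)
  expect_error(hilbert_phase(numeric(100)), class = "isa_undefined_phase")
  expect_true(all(ph > -pi & ph <= pi))
})

test_that("surface Laplacian annihilates spatially constant fields and is reference-free", {
  m <- make_montage(16, seed = 1)
  common <- matrix(rep(rnorm(200), each = 16), 16, 200)
  out <- surface_laplacian(common, m)
  expect_lt(max(abs(out)), 1e-6 * sd(common))
  X <- matrix(rnorm(16 * 200), 16, 200)
  base <- surface_laplacian(X, m)
  shifted <- surface_laplacian(X + common, m)
  expect_lt(max(abs(base - shifted)), 1e-8 * sd(X))
  # duplicate electrodes are rejected
  m2 <- m
  m2[2, c("x", "y", "z")] <- m2[1, c("x", "y", "z")]
  expect_error(surface_laplacian(X, m2), class = "isa_singular_montage")
})

test_that("surface Laplacian matches an independent dense spline solve", {
  skip_if_not_installed("pracma")
  m <- make_montage(8, seed = 2)
  pos <- as.matrix(m[, c("x", "y", "z")])
  set.seed(11)
  X <- matrix(rnorm(8 * 5), 8, 5)
  # independent oracle: explicit Legendre series + constrained block solve
  mm <- 4; lambda <- 1e-5; nmax <- 50
  cosang <- pmin(pmax(tcrossprod(pos), -1), 1)
  G <- matrix(0, 8, 8); H <- matrix(0, 8, 8)
  for (n in 1:nmax) {
    Pn <- matrix(pracma::legendre(n, as.vector(cosang))[1, ], 8, 8)
    G <- G + (2 * n + 1) / (n * (n + 1))^mm * Pn
    H <- H + (2 * n + 1) / (n * (n + 1))^(mm - 1) * Pn
  }
  G <- G / (4 * pi); H <- H / (4 * pi)
  A <- rbind(cbind(G + lambda * diag(8), rep(1, 8)), c(rep(1, 8), 0))
  oracle <- sapply(seq_len(ncol(X)), function(j) {
    sol <- solve(A, c(X[, j], 0))
    as.numeric(H %*% sol[1:8])
  })
  # tolerance reflects pracma's Legendre precision at order 50 (~1e-9)
  # amplified by the ~1e4-magnitude spline coefficients
  expect_equal(unname(surface_laplacian(X, m)), unname(oracle), tolerance = 1e-4)
})

test_that("preprocessing is invariant to linear drift and handles edge cases", {
  spec0 <- fast_spec(duration = 900, drift_slope = 0)
  spec1 <- fast_spec(duration = 900, drift_slope = 0.5)
  p <- make_participants(spec0)
  r0 <- generate_recording(spec0, p[1, ], 1)$recording
  r1 <- generate_recording(spec1, p[1, ], 1)$recording
  pt0 <- preprocess_recording(r0, spec0$bands, fs_out = 8, transition = 0.02,
                              apply_csd = FALSE)
  pt1 <- preprocess_recording(r1, spec1$bands, fs_out = 8, transition = 0.02,
                              apply_csd = FALSE)
  expect_lt(max(abs(wrap_pi(pt1$eeg - pt0$eeg))), 1e-3)
  # empty band list gives empty tensors
  pt_empty <- preprocess_recording(r0, numeric(0), fs_out = 8, transition = 0.02,
                                   apply_csd = FALSE)
  expect_equal(dim(pt_empty$eeg)[3], 0)
  # all phases wrapped
  expect_true(all(pt0$eeg > -pi & pt0$eeg <= pi))
  expect_true(all(pt0$gsr > -pi & pt0$gsr <= pi))
})

test_that("recovered phases track the generator's oscillation phase", {
  # clean oscillation: phase RMS error on the valid region below 0.05 rad
  spec <- fast_spec(n_channels = 4, duration = 1500, bands = 0.05,
                    kappa_expert = 1e6, kappa_novice = 1e6, rw_jitter_sd = 0)
  p <- make_participants(spec)
  rec <- generate_recording(spec, p[1, ], 1)$recording
  pt <- preprocess_recording(rec, spec$bands, fs_out = 8, transition = 0.02,
                             apply_csd = FALSE)
  tt <- (seq_len(ncol(rec$eeg)) - 1) / 8
  v <- pt$valid[, 1]
  err <- wrap_pi(pt$gsr[v, 1] - wrap_pi(2 * pi * 0.05 * tt[v]))
  expect_lt(sqrt(mean(err^2)), 0.05)
})
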