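#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. Used for the phase jitter of the
#' synthetic cohort; `kappa = 0` reduces to the circular uniform distribution.
#'
#' @param n number of draws.
#' @param kappa concentration parameter (>= 0).
#' @param mu mean direction in radians.
#' @return `n` angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  if (kappa < 0) isa_stop("isa_invalid_spec", "kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrap_pi(runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) out[(got + 1):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    got <- got + k
  }
  wrap_pi(out + mu)
}

#' Expected resultant length of a von Mises distribution
#'
#' The Bessel-function ratio I1(kappa)/I0(kappa), i.e. the population value the
#' phase synchronization index converges to when phase differences are von
#' Mises distributed.
#'
#' @param kappa concentration (>= 0); vectorized.
#' @return resultant length rho in [0, 1).
#' @export
vm_resultant <- function(kappa) {
  # besselI underflows in scaled form for very large arguments; switch to the
  # asymptotic expansion I1/I0 ~ 1 - 1/(2k) - 1/(8k^2) - 1/(8k^3) there.
  asym <- 1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3)
  exact <- suppressWarnings(
    besselI(kappa, 1, expon.scaled = TRUE) /
      besselI(kappa, 0, expon.scaled = TRUE))
  ifelse(kappa <= 0, 0, ifelse(kappa > 1e4, asym, exact))
}

#' Sample synchronized phase pairs with von Mises jitter
#'
#' Generates `n` time points of a GSR phase (uniform on the circle) and an EEG
#' phase equal to the GSR phase plus a fixed lag `delta` plus i.i.d. von Mises
#' jitter with concentration `kappa`. The expected phase synchronization index
#' of such a pair is the Bessel ratio [vm_resultant()].
#'
#' @param n number of phase samples.
#' @param kappa von Mises concentration of the phase jitter.
#' @param delta fixed phase lag in radians.
#' @param seed optional integer seed (caller RNG state is preserved).
#' @return list with `theta_eeg` and `theta_gsr`, both in (-pi, pi].
#' @export
sample_phase_pairs <- function(n, kappa, delta = 0, seed = NULL) {
  draw <- function() {
    tg <- runif(n, -pi, pi)
    te <- wrap_pi(tg + delta + rvonmises(n, kappa))
    list(theta_eeg = te, theta_gsr = tg)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Spherical Fibonacci montage on the upper hemisphere
#'
#' Deterministic stand-in for a 64-channel EEG cap: channel positions laid out
#' on a spherical Fibonacci lattice restricted to the upper hemisphere (all
#' unit norm, pairwise distinct).
#'
#' @param n_channels number of electrodes (>= 2).
#' @param seed integer controlling a fixed azimuthal rotation of the lattice.
#' @return data.frame with columns `name`, `x`, `y`, `z`.
#' @export
make_montage <- function(n_channels, seed = 0) {
  if (!is.numeric(n_channels) || n_channels < 2)
    isa_stop("isa_invalid_spec", "a montage needs at least 2 channels")
  n <- as.integer(n_channels)
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n            # upper hemisphere: z in (0, 1)
  rad <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))          # golden angle
  offset <- 2 * pi * ((seed * 0.6180339887498949) %% 1)
  az <- i * ga + offset
  data.frame(
    name = sprintf("Ch%02d", i),
    x = rad * cos(az), y = rad * sin(az), z = z,
    stringsAsFactors = FALSE
  )
}

#' Default per-channel phase-lag map with two spatial clusters
#'
#' Channels nearest the vertex (largest z) form an antiphase cluster
#' (delta = pi), the outer ring an in-phase cluster (delta = 0), and a thin
#' transition belt carries intermediate lags (+/- pi/3, +/- 2pi/3). This
#' emulates spatially clustered EEG-GSR phase differences concentrated at 0
#' and pi radians.
#'
#' @param montage montage data.frame from [make_montage()].
#' @return numeric vector of per-channel lags in (-pi, pi].
#' @export
default_lag_map <- function(montage) {
  n <- nrow(montage)
  ord <- order(montage$z, decreasing = TRUE)  # vertex first
  n_pi <- max(1L, round(0.375 * n))
  n_zero <- max(1L, round(0.375 * n))
  lag <- numeric(n)
  lag[ord[seq_len(n_pi)]] <- pi
  lag[ord[(n - n_zero + 1):n]] <- 0
  mid <- ord[setdiff(seq_len(n), c(seq_len(n_pi), (n - n_zero + 1):n))]
  if (length(mid) > 0) {
    belt <- rep(c(2 * pi / 3, -2 * pi / 3, pi / 3, -pi / 3), length.out = length(mid))
    lag[mid] <- belt
  }
  lag
}

#' Specify a synthetic EEG-GSR cohort
#'
#' Collects every ground-truth parameter of the synthetic cohort generator:
#' group sizes, montage size, sampling rate, session structure, analysis
#' bands, von Mises coupling concentrations, the per-channel lag map, noise
#' and drift levels, and the master seed. Defaults emulate the two-group
#' meditation study design: 12 experts (3 female) and 12 novices (10 female),
#' 64 channels at 256 Hz, 45-minute sessions, ten infra-slow bands.
#'
#' @param n_expert,n_novice participants per group.
#' @param n_channels EEG channels (>= 2).
#' @param fs sampling rate in Hz. Use 8 for fast-test mode (skips decimation).
#' @param duration session length in seconds.
#' @param n_sessions sessions per participant (analysis concatenates them).
#' @param bands numeric vector of band lower edges in Hz; band b spans
#'   `[bands[b], bands[b] + band_width]`.
#' @param band_width band width in Hz.
#' @param kappa_expert,kappa_novice von Mises concentration of the EEG-GSR
#'   phase jitter per group (dimensionless; larger = tighter coupling).
#' @param kappa_lag_exponent_expert,kappa_lag_exponent_novice exponent g in the
#'   per-channel concentration kappa_c = kappa_group * |cos(delta_c)|^g. The
#'   expert default 2 concentrates synchronization at in-phase/antiphase
#'   channels; the novice default 0 makes coupling uniform across channels.
#' @param lag_map per-channel lag delta_c in (-pi, pi], or NULL for
#'   [default_lag_map()] on the generated montage.
#' @param noise_sd broadband white-noise SD relative to unit oscillation
#'   amplitude.
#' @param drift_slope maximum magnitude of the per-channel linear drift
#'   (signal units per second; each channel draws a slope uniform in
#'   `[-drift_slope, drift_slope]`).
#' @param jitter_dt epoch length in seconds of the piecewise-constant phase
#'   jitter process (jitter is redrawn i.i.d. each epoch).
#' @param rw_jitter_sd standard deviation (rad/sqrt(s)) of the slow random
#'   walk added to the common oscillation phase.
#' @param amplitudes per-band oscillation amplitudes (default all 1).
#' @param seed master integer seed; all randomness derives from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_expert = 12, n_novice = 12, n_channels = 64,
                        fs = 256, duration = 2700, n_sessions = 2,
                        bands = seq(0.01, 0.10, by = 0.01), band_width = 0.01,
                        kappa_expert = 4, kappa_novice = 1,
                        kappa_lag_exponent_expert = 2,
                        kappa_lag_exponent_novice = 0,
                        lag_map = NULL, noise_sd = 0.5, drift_slope = 0.02,
                        jitter_dt = 90, rw_jitter_sd = 0.01,
                        amplitudes = NULL, seed = 1) {
  if (n_channels < 2) isa_stop("isa_invalid_spec", "n_channels must be >= 2")
  if (kappa_expert < 0 || kappa_novice < 0)
    isa_stop("isa_invalid_spec", "kappa must be >= 0")
  if (fs <= 2 * (max(bands) + band_width))
    isa_stop("isa_invalid_spec", "fs must exceed twice the highest band edge")
  if (n_expert < 1 || n_novice < 1)
    isa_stop("isa_invalid_spec", "each group needs at least one participant")
  montage <- make_montage(n_channels, seed = seed)
  if (is.null(lag_map)) lag_map <- default_lag_map(montage)
  if (length(lag_map) != n_channels)
    isa_stop("isa_invalid_spec", "lag_map must have one lag per channel")
  if (any(lag_map <= -pi - 1e-12 | lag_map > pi + 1e-12))
    isa_stop("isa_invalid_spec", "lags must lie in (-pi, pi]")
  if (is.null(amplitudes)) amplitudes <- rep(1, length(bands))
  structure(list(
    n_expert = n_expert, n_novice = n_novice, n_channels = as.integer(n_channels),
    fs = fs, duration = duration, n_sessions = as.integer(n_sessions),
    bands = bands, band_width = band_width,
    kappa_expert = kappa_expert, kappa_novice = kappa_novice,
    kappa_lag_exponent_expert = kappa_lag_exponent_expert,
    kappa_lag_exponent_novice = kappa_lag_exponent_novice,
    lag_map = lag_map, noise_sd = noise_sd, drift_slope = drift_slope,
    jitter_dt = jitter_dt, rw_jitter_sd = rw_jitter_sd,
    amplitudes = amplitudes, seed = as.integer(seed), montage = montage
  ), class = "cohort_spec")
}

# Per-channel concentration implied by the spec for one group.
channel_kappas <- function(spec, group) {
  if (group == "Expert") {
    spec$kappa_expert * abs(cos(spec$lag_map))^spec$kappa_lag_exponent_expert
  } else {
    spec$kappa_novice * abs(cos(spec$lag_map))^spec$kappa_lag_exponent_novice
  }
}

#' Deterministic participant roster for a cohort spec
#'
#' Demographics reproduce the study's sex imbalance (Expert 3 F, Novice 10 F
#' when group sizes allow) and group age distributions (Expert 39.3 +/- 12.0,
#' Novice 45.0 +/- 14.8 years), drawn deterministically from the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `id`, `index`, `group`, `sex`, `age`.
#' @export
make_participants <- function(spec) {
  with_seed(derive_seed(spec$seed, "participants"), {
    mk <- function(n, grp, n_female, age_mean, age_sd, prefix) {
      sex <- rep("M", n)
      if (n_female > 0) sex[sample.int(n, min(n_female, n))] <- "F"
      age <- round(pmin(70, pmax(20, rnorm(n, age_mean, age_sd))), 1)
      data.frame(
        id = sprintf("%s%02d", prefix, seq_len(n)),
        group = grp, sex = sex, age = age, stringsAsFactors = FALSE
      )
    }
    out <- rbind(
      mk(spec$n_expert, "Expert", round(3 * spec$n_expert / 12), 39.3, 12.0, "E"),
      mk(spec$n_novice, "Novice", round(10 * spec$n_novice / 12), 45.0, 14.8, "N")
    )
    out$index <- seq_len(nrow(out))
    out[, c("id", "index", "group", "sex", "age")]
  })
}

#' Generate one synthetic EEG + GSR recording
#'
#' The GSR is a sum of near-sinusoidal infra-slow oscillations (one per band,
#' each with a slow random-walk phase) plus white noise. Each EEG channel
#' carries the same oscillations shifted by its ground-truth lag `delta_c` and
#' by piecewise-constant i.i.d. von Mises phase jitter whose concentration is
#' set by the participant's group, plus white noise and a linear drift.
#' Deterministic given (spec seed, participant index, session).
#'
#' @param spec a [cohort_spec()].
#' @param participant one row of [make_participants()] (or a list with fields
#'   `id`, `index`, `group`).
#' @param session session index (1-based).
#' @return list with elements `recording` (class `isa_recording`) and
#'   `ground_truth` (data.frame: channel, band, delta, kappa, rho).
#' @export
generate_recording <- function(spec, participant, session = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- as.list(participant)
  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  kap <- channel_kappas(spec, p$group)
  n_epochs <- ceiling(spec$duration / spec$jitter_dt)
  ep_len <- round(spec$jitter_dt * spec$fs)

  res <- with_seed(derive_seed(spec$seed, "recording", p$index, session), {
    nb <- length(spec$bands)
    phi <- matrix(0, n, nb)
    for (b in seq_len(nb)) {
      rw <- cumsum(rnorm(n, 0, spec$rw_jitter_sd / sqrt(spec$fs)))
      phi[, b] <- 2 * pi * spec$bands[b] * tt + rw
    }
    gsr <- as.numeric(cos(phi) %*% spec$amplitudes) +
      spec$noise_sd * rnorm(n)
    eeg <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      sig <- numeric(n)
      for (b in seq_len(nb)) {
        eps <- rvonmises(n_epochs, kap[ch])
        eps_t <- rep(eps, each = ep_len)[seq_len(n)]
        sig <- sig + spec$amplitudes[b] * cos(phi[, b] + spec$lag_map[ch] + eps_t)
      }
      slope <- spec$drift_slope * runif(1, -1, 1)
      eeg[ch, ] <- sig + spec$noise_sd * rnorm(n) + slope * tt
    }
    list(eeg = eeg, gsr = gsr)
  })

  rec <- structure(list(
    eeg = res$eeg, gsr = res$gsr, fs = spec$fs, montage = spec$montage,
    participant = p, session = as.integer(session)
  ), class = "isa_recording")
  gt <- expand.grid(channel = seq_len(spec$n_channels),
                    band = spec$bands, KEEP.OUT.ATTRS = FALSE)
  gt$delta <- spec$lag_map[gt$channel]
  gt$kappa <- kap[gt$channel]
  gt$rho <- vm_resultant(gt$kappa)
  list(recording = rec, ground_truth = gt)
}

#' @export
print.isa_recording <- function(x, ...) {
  cat(sprintf("<isa_recording> %s (%s) session %d: %d EEG channels + GSR, %d samples @ %g Hz\n",
              x$participant$id %||% "?", x$participant$group %||% "?",
              x$session, nrow(x$eeg), ncol(x$eeg), x$fs))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' One recording per participant and session; Expert recordings use
#' `kappa_expert`, Novice recordings `kappa_novice`. Bit-reproducible for a
#' fixed spec.
#'
#' @param spec a [cohort_spec()].
#' @param participants optional roster; defaults to [make_participants()].
#' @return list of `list(recording, ground_truth)` entries, ordered by
#'   participant then session; the roster is attached as attribute
#'   `participants`.
#' @export
generate_cohort <- function(spec, participants = NULL) {
  if (is.null(participants)) participants <- make_participants(spec)
  out <- list()
  for (i in seq_len(nrow(participants))) {
    for (s in seq_len(spec$n_sessions)) {
      out[[length(out) + 1]] <- generate_recording(spec, participants[i, ], s)
    }
  }
  attr(out, "participants") <- participants
  out
}
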