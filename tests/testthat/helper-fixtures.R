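# Shared fixtures, built in code.

# A tiny fast-mode cohort spec (signals generated directly at 8 Hz).
fast_spec <- function(...) {
  args <- utils::modifyList(list(
    n_expert = 1, n_novice = 1, n_channels = 4, fs = 8, duration = 1200,
    n_sessions = 1, bands = 0.03, kappa_expert = 1e6, kappa_novice = 1e6,
    noise_sd = 0, drift_slope = 0, seed = 3
  ), list(...))
  do.call(cohort_spec, args)
}

# Build summarize_cohort() input at the phase level: each participant gets
# per-channel phase pairs with lag `lags[ch]` and concentration `kappas[ch]`,
# T samples, for each band label.
phase_level_cohort <- function(participants, lags, kappas, T, bands, seed = 1) {
  lapply(seq_len(nrow(participants)), function(i) {
    p <- participants[i, ]
    nch <- length(lags)
    nb <- length(bands)
    eeg <- array(NA_real_, c(nch, T, nb))
    gsr <- matrix(NA_real_, T, nb)
    for (b in seq_len(nb)) {
      set.seed(derive_seed_test(seed, i, b))
      tg <- runif(T, -pi, pi)   # common GSR reference phase for the band
      gsr[, b] <- tg
      for (ch in seq_len(nch)) {
        eeg[ch, , b] <- wrap_pi(tg + lags[ch] + rvonmises(T, kappas[ch]))
      }
    }
    list(participant = as.list(p), phases = list(eeg = eeg, gsr = gsr))
  })
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Deterministic small seed for fixtures (independent of package internals).
derive_seed_test <- function(...) {
  v <- unlist(list(...))
  as.integer((sum(v * (31^(seq_along(v) %% 5))) %% 2147483000) + 1)
}
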