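check_phase_pair <- function(theta_eeg, theta_gsr) {
  if (length(theta_eeg) != length(theta_gsr))
    isa_stop("isa_shape", "phase vectors differ in length (%d vs %d)",
             length(theta_eeg), length(theta_gsr))
  if (length(theta_eeg) < 2)
    isa_stop("isa_insufficient_data", "need at least 2 phase samples")
  rng <- range(theta_eeg, theta_gsr)
  if (!all(is.finite(rng)) || rng[1] < -pi - 1e-8 || rng[2] > pi + 1e-8)
    isa_stop("isa_shape", "phases must be finite and lie in (-pi, pi]")
  invisible(TRUE)
}

#' Phase synchronization index and mean phase difference of a phase pair
#'
#' Computes the time-averaged complex exponential of the phase difference,
#' `delta_theta = mean(exp(1i * (theta_eeg - theta_gsr)))`. Its modulus is the
#' phase synchronization index (PSI, 1 = constant phase difference, 0 =
#' uniformly dispersed differences) and its argument the mean phase
#' difference (mPD).
#'
#' @param theta_eeg,theta_gsr phase vectors in (-pi, pi], equal length >= 2.
#' @return object of class `phase_pair_summary`: list with `delta_theta`
#'   (complex), `psi`, `mpd`, `T`.
#' @export
phase_pair_summary <- function(theta_eeg, theta_gsr) {
  check_phase_pair(theta_eeg, theta_gsr)
  z <- mean(exp(1i * (theta_eeg - theta_gsr)))
  structure(list(delta_theta = z, psi = Mod(z), mpd = wrap_pi(Arg(z)),
                 T = length(theta_eeg)),
            class = "phase_pair_summary")
}

#' @export
print.phase_pair_summary <- function(x, ...) {
  cat(sprintf("<phase_pair_summary> PSI = %.4f, mPD = %.4f rad, T = %d\n",
              x$psi, x$mpd, x$T))
  invisible(x)
}

#' Surrogate PSI ensemble by time-shuffling the GSR phase
#'
#' Each surrogate applies an independent uniform random permutation to the
#' time indices of `theta_gsr` and recomputes the PSI, destroying the
#' temporal pairing while preserving both marginal phase distributions.
#'
#' @param theta_eeg,theta_gsr phase vectors in (-pi, pi], equal length >= 2.
#' @param n_surrogates number of surrogates (default 10000).
#' @param seed optional integer seed (caller RNG state preserved).
#' @return object of class `surrogate_ensemble`: list with `surrogate_psis`,
#'   `n_surrogates`, `seed`.
#' @export
surrogate_psis <- function(theta_eeg, theta_gsr, n_surrogates = 10000,
                           seed = NULL) {
  check_phase_pair(theta_eeg, theta_gsr)
  if (n_surrogates < 1)
    isa_stop("isa_invalid_spec", "n_surrogates must be >= 1")
  a <- exp(1i * theta_eeg)
  b <- exp(-1i * theta_gsr)
  n <- length(a)
  draw <- function() vapply(seq_len(n_surrogates),
                            function(i) Mod(mean(a * b[sample.int(n)])),
                            numeric(1))
  psis <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(surrogate_psis = psis, n_surrogates = n_surrogates,
                 seed = seed),
            class = "surrogate_ensemble")
}

#' Permutation significance of an observed PSI
#'
#' Add-one permutation p-value, `p = (1 + #{surrogate >= observed}) /
#' (1 + n_surrogates)`; significance requires the observed PSI to strictly
#' exceed the `1 - alpha` percentile of the surrogate ensemble.
#'
#' @param observed a [phase_pair_summary()].
#' @param ensemble a [surrogate_psis()] ensemble.
#' @param alpha significance level (default 0.05).
#' @return list with `p_value`, `is_significant`, `threshold`.
#' @export
psi_significance <- function(observed, ensemble, alpha = 0.05) {
  sur <- ensemble$surrogate_psis
  if (length(sur) < 1)
    isa_stop("isa_invalid_ensemble", "surrogate ensemble is empty")
  p <- (1 + sum(sur >= observed$psi)) / (1 + length(sur))
  thr <- stats::quantile(sur, 1 - alpha, names = FALSE)
  list(p_value = p, is_significant = observed$psi > thr, threshold = thr)
}

#' Concatenate the valid phase samples of one participant's sessions
#'
#' Drops filter-edge samples (per the valid mask) and joins the remaining
#' phase samples across sessions, per channel and band.
#'
#' @param sessions list of `isa_phase_tensors` from [preprocess_recording()].
#' @return list with `eeg` (channels x valid-samples x bands) and `gsr`
#'   (valid-samples x bands).
#' @export
collect_valid_phases <- function(sessions) {
  stopifnot(length(sessions) > 0)
  nb <- dim(sessions[[1]]$eeg)[3]
  nch <- dim(sessions[[1]]$eeg)[1]
  eeg_parts <- vector("list", length(sessions))
  gsr_parts <- vector("list", length(sessions))
  for (s in seq_along(sessions)) {
    pt <- sessions[[s]]
    keep <- if (nb > 0) pt$valid[, 1] else logical(0)
    eeg_parts[[s]] <- pt$eeg[, keep, , drop = FALSE]
    gsr_parts[[s]] <- pt$gsr[keep, , drop = FALSE]
  }
  eeg <- array(NA_real_, c(nch, sum(vapply(gsr_parts, nrow, 1L)), nb))
  at <- 0
  for (s in seq_along(sessions)) {
    k <- dim(eeg_parts[[s]])[2]
    if (k > 0) eeg[, (at + 1):(at + k), ] <- eeg_parts[[s]]
    at <- at + k
  }
  list(eeg = eeg, gsr = do.call(rbind, gsr_parts))
}

#' Per-(participant, channel, band) PSI/mPD summary table
#'
#' Applies [phase_pair_summary()] to every channel and band of every
#' participant, concatenating valid phase samples across sessions first.
#' Optionally attaches a surrogate permutation p-value per row.
#'
#' @param cohort_phases list with one element per participant:
#'   `list(participant = <roster row>, phases = <collect_valid_phases()
#'   output>)`.
#' @param bands numeric vector of band lower edges (labels for the band
#'   dimension).
#' @param n_surrogates if > 0, compute a permutation p-value per row with this
#'   many surrogates.
#' @param alpha significance level for the per-row test.
#' @param seed master seed for the surrogate streams.
#' @return data.frame with columns participant, group, channel, band, psi,
#'   mpd, T (and p_value, significant when `n_surrogates > 0`).
#' @export
summarize_cohort <- function(cohort_phases, bands, n_surrogates = 0,
                             alpha = 0.05, seed = 1) {
  if (length(cohort_phases) == 0)
    isa_stop("isa_insufficient_data", "no participants supplied")
  rows <- list()
  for (entry in cohort_phases) {
    ph <- entry$phases
    nb <- dim(ph$eeg)[3]
    if (nb != length(bands))
      isa_stop("isa_config", "phase tensor has %d bands but %d band labels given",
               nb, length(bands))
    nch <- dim(ph$eeg)[1]
    for (b in seq_len(nb)) {
      tg <- ph$gsr[, b]
      for (ch in seq_len(nch)) {
        te <- ph$eeg[ch, , b]
        s <- phase_pair_summary(te, tg)
        row <- data.frame(
          participant = entry$participant$id,
          group = entry$participant$group,
          channel = ch, band = bands[b],
          psi = s$psi, mpd = s$mpd, T = s$T,
          stringsAsFactors = FALSE
        )
        if (n_surrogates > 0) {
          ens <- surrogate_psis(te, tg, n_surrogates,
                                seed = derive_seed(seed, "psi-sur",
                                                   entry$participant$index %||% 0,
                                                   ch, round(bands[b] * 1000)))
          sig <- psi_significance(s, ens, alpha)
          row$p_value <- sig$p_value
          row$significant <- sig$is_significant
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
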