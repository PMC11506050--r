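#' Grand-mean phase difference map
#'
#' For each (channel, band), averages the per-participant complex mean phase
#' differences `delta_theta_k = psi_k * exp(1i * mpd_k)` across participants
#' (amplitude-weighted complex mean) and takes its argument as the grand-mean
#' phase difference (gmPD). Channels whose participant vectors cancel
#' (resultant amplitude < 1e-12) are flagged undefined.
#'
#' @param summaries data.frame with columns channel, band, psi, mpd (one row
#'   per participant x channel x band), e.g. one group's subset of
#'   [summarize_cohort()] output.
#' @return data.frame with columns channel, band, gmpd, abs_gmpd,
#'   resultant_amp, K, defined.
#' @export
gmpd_map <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) < 1)
    isa_stop("isa_insufficient_data", "no participant summaries supplied")
  z <- summaries$psi * exp(1i * summaries$mpd)
  sp <- split(seq_len(nrow(summaries)),
              paste(summaries$band, summaries$channel, sep = "|"))
  out <- do.call(rbind, lapply(sp, function(ix) {
    zm <- mean(z[ix])
    amp <- Mod(zm)
    defined <- amp >= 1e-12
    data.frame(
      channel = summaries$channel[ix[1]], band = summaries$band[ix[1]],
      gmpd = if (defined) wrap_pi(Arg(zm)) else NA_real_,
      resultant_amp = amp, K = length(ix), defined = defined,
      stringsAsFactors = FALSE
    )
  }))
  out$abs_gmpd <- abs(out$gmpd)
  out <- out[order(out$band, out$channel), ]
  rownames(out) <- NULL
  out[, c("channel", "band", "gmpd", "abs_gmpd", "resultant_amp", "K", "defined")]
}

#' Non-negative functional connectivity from band-passed signals
#'
#' Pearson correlation between every pair of channels' band-passed signals,
#' with negative correlations clipped to zero and unit diagonal.
#'
#' @param x channels x samples matrix of band-passed EEG (valid samples only).
#' @return channels x channels non-negative symmetric matrix.
#' @export
functional_connectivity <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    isa_stop("isa_invalid_spec", "connectivity needs at least 2 channels")
  if (ncol(x) < 3)
    isa_stop("isa_insufficient_data", "connectivity needs at least 3 samples")
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    isa_stop("isa_undefined_correlation",
             "zero-variance channel(s): %s",
             paste(which(v == 0), collapse = ", "))
  r <- stats::cor(t(x))
  r[r < 0] <- 0
  diag(r) <- 1
  r
}

#' Average connectivity matrices across participants
#'
#' @param mats list of equally sized connectivity matrices.
#' @return element-wise mean matrix.
#' @export
average_connectivity <- function(mats) {
  if (length(mats) == 0)
    isa_stop("isa_insufficient_data", "no connectivity matrices supplied")
  Reduce(`+`, mats) / length(mats)
}

#' Principal gradient by diffusion-map embedding
#'
#' Alpha-normalizes the affinity matrix (`W' = D^-a W D^-a`, a = 0.5 by
#' default), row-normalizes to a Markov operator, eigendecomposes it (through
#' the conjugate symmetric operator), and returns the first non-trivial
#' eigenvector scaled by `lambda / (1 - lambda)` (diffusion time 0). Channels
#' with similar gradient values are more strongly connected. The sign of the
#' gradient is arbitrary.
#'
#' @param w channels x channels symmetric non-negative connectivity matrix
#'   describing a connected graph.
#' @param alpha diffusion normalization exponent (default 0.5).
#' @return object of class `gradient_map`: list with `gradient` (per-channel),
#'   `eigenvalues` (non-trivial Markov spectrum, descending), `scale`.
#' @export
principal_gradient <- function(w, alpha = 0.5) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (n < 2 || ncol(w) != n)
    isa_stop("isa_invalid_spec", "connectivity must be a square matrix of size >= 2")
  if (max(abs(w - t(w))) > 1e-8)
    isa_stop("isa_invalid_spec", "connectivity must be symmetric")
  if (any(w < -1e-12))
    isa_stop("isa_invalid_spec", "connectivity must be non-negative")
  # connectivity check (BFS over the positive-weight graph)
  adj <- w > 0
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen))
    isa_stop("isa_disconnected_components",
             "connectivity graph is disconnected (%d of %d channels reachable)",
             sum(seen), n)
  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  s <- w1 / sqrt(outer(d1, d1))
  e <- eigen(s, symmetric = TRUE)
  lam <- e$values
  psi <- e$vectors / sqrt(d1)      # right eigenvectors of the Markov operator
  psi <- psi / psi[, 1]            # trivial mode normalized to constant 1
  if (n >= 3 && abs(lam[2] - lam[3]) < 1e-9)
    isa_stop("isa_degenerate_spectrum",
             "leading non-trivial eigenvalues are degenerate (gap %.2e)",
             abs(lam[2] - lam[3]))
  if (lam[2] < 1e-9)
    isa_stop("isa_degenerate_spectrum",
             "no non-trivial diffusion mode (lambda_2 = %.2e)", lam[2])
  scale <- lam[2] / (1 - lam[2])
  structure(list(gradient = psi[, 2] * scale,
                 eigenvalues = lam[-1], scale = scale),
            class = "gradient_map")
}

#' Regress |gmPD| on the principal gradient across channels
#'
#' Ordinary least squares of the absolute grand-mean phase difference on the
#' gradient value, channel-wise; the absolute value is used because the
#' gradient is non-circular. Sign flips of the gradient change the slope sign
#' but not R-squared or the p-value.
#'
#' @param abs_gmpd per-channel |gmPD| (radians); NA channels are dropped.
#' @param gradient per-channel gradient values.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_gmpd_on_gradient <- function(abs_gmpd, gradient) {
  if (length(abs_gmpd) != length(gradient))
    isa_stop("isa_shape", "gmPD and gradient must cover the same channel set")
  keep <- is.finite(abs_gmpd) & is.finite(gradient)
  y <- abs_gmpd[keep]; x <- gradient[keep]
  if (length(y) < 3)
    isa_stop("isa_insufficient_data", "need at least 3 defined channels")
  if (stats::var(x) == 0)
    isa_stop("isa_undefined_regression", "gradient is constant across channels")
  fit <- stats::lm(y ~ x)
  # an exactly affine |gmPD| map is legitimate input; silence lm's
  # perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       n = length(y))
}

#' Permutation-null mean R-squared for the gmPD-gradient regression
#'
#' Shuffles the |gmPD| values across channels and refits the regression,
#' returning the mean R-squared over permutations: the spatial-null control
#' against which an observed R-squared is judged.
#'
#' @param abs_gmpd,gradient as in [regress_gmpd_on_gradient()].
#' @param n_perm number of channel permutations (default 100).
#' @param seed optional integer seed.
#' @return mean R-squared across permutations.
#' @export
shuffled_gradient_r2 <- function(abs_gmpd, gradient, n_perm = 100, seed = NULL) {
  keep <- is.finite(abs_gmpd) & is.finite(gradient)
  y <- abs_gmpd[keep]; x <- gradient[keep]
  run <- function() {
    mean(vapply(seq_len(n_perm), function(i) {
      regress_gmpd_on_gradient(y[sample.int(length(y))], x)$r_squared
    }, numeric(1)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
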