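# Spherical-spline surface Laplacian (current source density), Perrin-style.
#
# G and H matrices are Legendre series over the cosine of the inter-electrode
# angle, with spline flexibility m and truncation order n_legendre; the spline
# is fitted with smoothing constant lambda and the sum-to-zero constraint, and
# the Laplacian is read out through H.

# Legendre-series G and H matrices for unit-sphere positions.
csd_gh <- function(pos, m = 4, n_legendre = 50) {
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  g <- matrix(0, nrow(pos), nrow(pos))
  h <- g
  p_prev <- matrix(1, nrow(pos), nrow(pos))  # P_0
  p_cur <- cosang                            # P_1
  for (n in seq_len(n_legendre)) {
    g <- g + (2 * n + 1) / (n * (n + 1))^m * p_cur
    h <- h + (2 * n + 1) / (n * (n + 1))^(m - 1) * p_cur
    p_next <- ((2 * n + 1) * cosang * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  list(G = g / (4 * pi), H = h / (4 * pi))
}

# Linear operator mapping a scalp-potential vector to its surface Laplacian.
csd_operator <- function(montage, m = 4, lambda = 1e-5, n_legendre = 50) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  if (nrow(pos) < 4)
    isa_stop("isa_invalid_spec", "the surface Laplacian needs at least 4 channels")
  nrm <- sqrt(rowSums(pos^2))
  if (any(abs(nrm - 1) > 1e-6))
    isa_stop("isa_invalid_spec", "montage positions must be unit-norm")
  dmat <- as.matrix(stats::dist(pos))
  diag(dmat) <- Inf
  if (min(dmat) < 1e-9)
    isa_stop("isa_singular_montage", "montage contains duplicate electrode positions")
  gh <- csd_gh(pos, m = m, n_legendre = n_legendre)
  G <- gh$G + diag(lambda, nrow(pos))
  Gi <- tryCatch(solve(G), error = function(e)
    isa_stop("isa_singular_montage", "spline system is singular: %s", conditionMessage(e)))
  TC <- rowSums(Gi)
  sgi <- sum(TC)
  gh$H %*% (Gi - outer(TC, TC) / sgi)
}

#' Surface Laplacian (current source density) of multichannel EEG
#'
#' Spherical-spline surface Laplacian after Perrin et al., as implemented in
#' the classic CSD toolbox: Legendre series truncated at order `n_legendre`,
#' spline flexibility `m`, smoothing constant `lambda`, and a sum-to-zero
#' constraint on the spline coefficients. The result is reference-free:
#' adding a common per-sample offset to all channels leaves it unchanged, and
#' a spatially constant field maps to (numerical) zero.
#'
#' @param eeg channels x samples matrix.
#' @param montage data.frame with unit-norm electrode positions (`x`, `y`,
#'   `z`), one row per EEG row.
#' @param m spline flexibility (default 4).
#' @param lambda smoothing constant (default 1e-5).
#' @param n_legendre Legendre truncation order (default 50).
#' @return channels x samples matrix of surface Laplacian estimates.
#' @export
surface_laplacian <- function(eeg, montage, m = 4, lambda = 1e-5,
                              n_legendre = 50) {
  eeg <- as.matrix(eeg)
  if (nrow(montage) != nrow(eeg))
    isa_stop("isa_invalid_spec", "montage has %d positions but EEG has %d channels",
             nrow(montage), nrow(eeg))
  op <- csd_operator(montage, m = m, lambda = lambda, n_legendre = n_legendre)
  op %*% eeg
}
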