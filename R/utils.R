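#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish failure modes.
isa_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "isa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi + .Machine$double.eps * 4 & !is.na(y)] <- pi
  y
}

# Circular distance |a - b| on the circle, in [0, pi].
circ_dist <- function(a, b) abs(Arg(exp(1i * (a - b))))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and a stream label; stays < 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  })))
  h <- 2166136261
  for (p in parts) {
    for (b in c(p %% 256, (p %/% 256) %% 256, (p %/% 65536) %% 256)) {
      h <- bitwXor(as.integer(h %% 2^31), as.integer(abs(b)))
      h <- (as.numeric(h) * 16777619) %% 2^31
    }
  }
  as.integer(h %% 2147483647)
}

# FNV-1a hash of a string, reported as hex; used for config fingerprints.
fnv1a_hex <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
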