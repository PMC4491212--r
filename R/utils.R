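# Internal utilities shared across modules.

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` with the RNG seeded to `seed`, then restores the
#' caller's RNG state, so that library internals (kernel calibration,
#' simulation helpers) never perturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# FNV-1a hash of a serialized R object, returned as a hex string.
# Used for lightweight provenance digests (mesh identity, run configs).
# Long payloads are strided down: this is a provenance fingerprint, not
# a cryptographic digest.
fnv1a <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  # skip the serialization header (encodes R version, not content)
  bytes <- bytes[-seq_len(14L)]
  if (length(bytes) > 65536L) {
    idx <- unique(as.integer(seq(1L, length(bytes), length.out = 65536L)))
    bytes <- c(bytes[idx], length(bytes) %% 256L)
  }
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits; keep h a double
    # (it exceeds .Machine$integer.max) and xor the low byte alone
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b %% 256L)
    # multiply by the FNV prime 16777619 modulo 2^32 without losing
    # double precision: split h into 16-bit halves
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Truncated-normal draws by CDF inversion (vectorised, deterministic
# under the current RNG stream).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-replicate seed stream: replicate k of a run seeded
# with `master` gets its own reproducible seed below 2^31.
replicateSeed <- function(master, counter) {
  as.integer((as.numeric(master) * 7919 + counter * 104729) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
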