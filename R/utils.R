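## internal helpers

# Derived substream seed: one global study seed, one offset per modality,
# kept inside 32-bit integer range.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# FNV-1a 32-bit hash of a character scalar, as hex. Used only to fingerprint
# the configuration actually used for a run (manifest bookkeeping).
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256               # xor touches only the low byte
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopUnless <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
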