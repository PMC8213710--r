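## Package-wide constants (this file collates first).

BASES <- c("A", "C", "G", "T")

## the 12 substitution types, ref>alt
SUBSTITUTION_TYPES <- as.vector(t(outer(BASES, BASES, paste, sep = ">")))[
  as.vector(t(outer(BASES, BASES, "!=")))]

## byte -> base code lookup (A=1, C=2, G=3, T=4; everything else 0)
BASE_CODE <- integer(256L)
BASE_CODE[as.integer(charToRaw(paste(BASES, collapse = ""))) + 1L] <- 1:4
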