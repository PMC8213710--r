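## Shared fixture builders (everything is generated in code).

## minimal single-region configuration for fast tests
tiny_config <- function(..., depth_templates = 60L, seed = 101L) {
  sim_config(panel = data.frame(chrom = "chr1", start = 1000L, end = 1400L),
             depth_templates = depth_templates, seed = seed, ...)
}

## hand-built read-pair table; every argument vectorized over pairs
make_pairs <- function(chrom = "chr1", start, end, strand, umi1, umi2,
                       seq_left, seq_right = seq_left,
                       qname = sprintf("q%d", seq_along(start))) {
  out <- data.frame(qname = qname, chrom = chrom, start = start, end = end,
                    strand = strand, umi1 = umi1, umi2 = umi2,
                    seq_left = seq_left, seq_right = seq_right,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

## a one-site pileup with the given allele counts (named A/C/G/T)
make_pileup <- function(pos = 1500L, ref = "A", counts = c(A = 0L),
                        chrom = "chr1") {
  row <- data.frame(chrom = chrom, pos = pos, ref = ref,
                    A = 0L, C = 0L, G = 0L, T = 0L)
  for (b in names(counts)) row[[b]] <- as.integer(counts[[b]])
  row$depth <- row$A + row$C + row$G + row$T
  class(row) <- c("position_pileup", "data.frame")
  row
}

## stack several make_pileup rows
make_pileups <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("position_pileup", "data.frame")
  out
}
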