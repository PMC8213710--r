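## Per-position allele counting (pileups) over target regions.

## accumulate A/C/G/T counts for sequences anchored at 1-based starts,
## restricted to positions p1..p2; returns 4 x W integer matrix
accumulate_counts <- function(starts, seqs, p1, p2, counts = NULL) {
  w <- p2 - p1 + 1L
  if (is.null(counts)) counts <- matrix(0L, 4L, w)
  if (!length(seqs)) return(counts)
  nc <- nchar(seqs)
  code <- BASE_CODE[as.integer(charToRaw(paste(seqs, collapse = ""))) + 1L]
  pos <- rep.int(starts, nc) + sequence(nc) - 1L
  keep <- code > 0L & pos >= p1 & pos <= p2    # N and "." have code 0
  if (any(keep)) {
    tab <- tabulate(code[keep] + 4L * (pos[keep] - p1), nbins = 4L * w)
    counts <- counts + matrix(tab, nrow = 4L)
  }
  counts
}

#' Per-position allele counts of consensus reads over a target region
#'
#' Counts A/C/G/T support per targeted position. `N` (ambiguous/suppressed)
#' and uncovered positions contribute nothing; depth is the sum of the four
#' allele counts.
#'
#' @param reads a `consensus_reads` data.frame, or a `read_pairs` data.frame
#'   (for the uncollapsed "standard" tier, where each mate's bases are
#'   counted).
#' @param region one-row data.frame with chrom, start, end (BED convention,
#'   0-based half-open).
#' @param reference named character vector of chromosome sequences.
#' @return data.frame of class `position_pileup`: chrom, pos (1-based), ref,
#'   A, C, G, T, depth.
#' @export
position_pileup <- function(reads, region, reference) {
  p1 <- region$start[1L] + 1L
  p2 <- region$end[1L]
  ch <- region$chrom[1L]
  w <- p2 - p1 + 1L
  counts <- matrix(0L, 4L, w)
  r <- reads[reads$chrom == ch, , drop = FALSE]
  if (inherits(reads, "consensus_reads") || !is.null(r$seq)) {
    counts <- accumulate_counts(r$start, r$seq, p1, p2, counts)
  } else {
    counts <- accumulate_counts(r$start, r$seq_left, p1, p2, counts)
    counts <- accumulate_counts(r$end - nchar(r$seq_right) + 1L, r$seq_right,
                                p1, p2, counts)
  }
  refbase <- strsplit(substring(reference[[ch]], p1, p2), "")[[1L]]
  out <- data.frame(chrom = ch, pos = p1:p2, ref = refbase,
                    A = counts[1L, ], C = counts[2L, ],
                    G = counts[3L, ], T = counts[4L, ],
                    depth = colSums(counts),
                    stringsAsFactors = FALSE)
  class(out) <- c("position_pileup", "data.frame")
  out
}

#' Tiered pileups over a whole panel
#'
#' Builds per-position pileups for the duplex, simplex and all-unique
#' consensus tiers, plus the uncollapsed standard tier when the raw pairs are
#' supplied, across all panel regions.
#'
#' @param tiers list from [emit_tiers()].
#' @param panel data.frame of target regions (chrom, start, end; 0-based
#'   half-open).
#' @param reference named character vector of chromosome sequences.
#' @param pairs optional `read_pairs` data.frame for the standard tier.
#' @return named list of `position_pileup` data.frames
#'   (`duplex`, `simplex`, `all_unique`, and `standard` when `pairs` given).
#' @export
pileup_tiers <- function(tiers, panel, reference, pairs = NULL) {
  one <- function(reads) {
    do.call(rbind, lapply(seq_len(nrow(panel)), function(i)
      position_pileup(reads, panel[i, ], reference)))
  }
  out <- list(duplex = one(tiers$duplex),
              simplex = one(tiers$simplex),
              all_unique = one(tiers$all_unique))
  if (!is.null(pairs)) out$standard <- one(pairs)
  for (nm in names(out)) class(out[[nm]]) <- c("position_pileup", "data.frame")
  out
}

## alt fragment count and depth at one site from a pileup
site_counts <- function(pileup, chrom, pos, alt) {
  i <- which(pileup$chrom == chrom & pileup$pos == pos)
  if (!length(i)) return(c(alt = NA_integer_, depth = NA_integer_))
  altc <- if (alt %in% BASES) pileup[[alt]][i[1L]] else 0L
  c(alt = as.integer(altc), depth = as.integer(pileup$depth[i[1L]]))
}
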