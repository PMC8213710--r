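## Consensus collapsing of UMI families into error-suppressed read tiers.
##
## A consensus sequence is represented over the *fragment* coordinates
## (start..end, 1-based inclusive): "." marks positions with no read coverage
## (the interior gap of fragments longer than two read lengths), "N" marks
## positions with no strict-majority base or with duplex strand disagreement.

RAW_DOT <- charToRaw(".")
RAW_N <- charToRaw("N")

## flat base-vote tally for a stack of equal-length sequences: a vector of
## length 4*L laid out base-within-position
vote_tally <- function(seqs, L) {
  code <- BASE_CODE[as.integer(charToRaw(paste(seqs, collapse = ""))) + 1L]
  idx <- rep.int(seq_len(L), length(seqs))
  keep <- code > 0L                 # N and "." carry no vote
  tabulate(code[keep] + 4L * (idx[keep] - 1L), nbins = 4L * L)
}

## strict-majority consensus over fragment columns; returns list(chars, mx,
## n_obs) with chars a character vector of length flen
consensus_core <- function(seq_left, seq_right, flen) {
  l1 <- nchar(seq_left[1L])
  cnt <- integer(4L * flen)
  cnt[seq_len(4L * l1)] <- vote_tally(seq_left, l1)
  if (!is.null(seq_right)) {
    l2 <- nchar(seq_right[1L])
    off <- 4L * (flen - l2)
    cnt[(off + 1L):(4L * flen)] <- cnt[(off + 1L):(4L * flen)] +
      vote_tally(seq_right, l2)
  }
  m <- matrix(cnt, nrow = 4L)
  n_obs <- colSums(m)
  mx <- pmax(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
  called <- 2L * mx > n_obs
  b <- integer(flen)
  for (j in 4:1) b[m[j, ] == mx] <- j
  chars <- rep(".", flen)
  chars[n_obs > 0L] <- "N"
  chars[called] <- BASES[b[called]]
  list(chars = chars, mx = mx, n_obs = n_obs)
}

#' Per-base strand consensus of the read pairs of one strand family
#'
#' Computes the strict-majority base per fragment position from the stacked
#' left and right mates (all pairs of a family share the fragment interval, so
#' mates align column-wise). A base is called only when it holds a strict
#' majority (> half) of the observations at that position; ties and split
#' columns give `N`; positions no mate covers give `.`.
#'
#' @param seq_left character vector of left-mate sequences (equal length).
#' @param seq_right character vector of right-mate sequences (equal length),
#'   parallel to `seq_left`; defaults to `seq_left` spanning the whole
#'   fragment when omitted together with `frag_len`.
#' @param frag_len fragment length in bp (defaults to the left-mate length).
#' @return list with `seq` (consensus string of length `frag_len`), `support`
#'   (integer vector: reads agreeing with the called base) and `n_obs`
#'   (observations per position).
#' @examples
#' strand_consensus(c("ACGT", "ACGT", "ACGA"))$seq   # majority at last column
#' strand_consensus(c("ACGT", "ACGA"))$seq           # tie -> N
#' @export
strand_consensus <- function(seq_left, seq_right = NULL, frag_len = NULL) {
  if (!length(seq_left)) stop_arg("at least one read is required")
  frag_len <- frag_len %||% nchar(seq_left[1L])
  cc <- consensus_core(seq_left, seq_right, frag_len)
  list(seq = paste(cc$chars, collapse = ""),
       support = ifelse(2L * cc$mx > cc$n_obs, cc$mx, 0L),
       n_obs = cc$n_obs)
}

## combine two strand-consensus strings into a duplex consensus:
## agreement keeps the base, disagreement (incl. one-sided N) gives N,
## uncovered positions stay "."
duplex_combine <- function(s1, s2) {
  r1 <- charToRaw(s1)
  r2 <- charToRaw(s2)
  r1[r1 != r2] <- RAW_N
  rawToChar(r1)
}

#' Group aligned UMI-tagged read pairs into families
#'
#' A family is the set of read pairs sharing chromosome, fragment start,
#' fragment end and the canonicalized UMI pair. The UMI pair is read in
#' opposite order on the two strands of one template -- `(a,b)` on the plus
#' strand and `(b,a)` on the minus strand -- so the key swaps minus-strand
#' UMIs, landing both strands of a template in one family.
#'
#' Pairs with a missing/empty UMI are skipped (counted in the `skipped`
#' attribute).
#'
#' @param pairs a `read_pairs` data.frame (see [amplify_and_sequence()] or
#'   [read_sam()]).
#' @param umi_merge_1mm merge families at identical fragment coordinates
#'   whose canonical UMI pairs differ by a single base (tolerates one UMI
#'   sequencing error). Off by default: exact-match grouping.
#' @return the input with a `family` integer column appended; attributes
#'   `families` (per-family summary: chrom, start, end, umi, n_plus, n_minus)
#'   and `skipped` (count of dropped records).
#' @export
group_families <- function(pairs, umi_merge_1mm = FALSE) {
  ok <- !is.na(pairs$umi1) & !is.na(pairs$umi2) &
    nzchar(pairs$umi1) & nzchar(pairs$umi2)
  skipped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  canon <- ifelse(pairs$strand == "+",
                  paste(pairs$umi1, pairs$umi2, sep = "+"),
                  paste(pairs$umi2, pairs$umi1, sep = "+"))
  key <- paste(pairs$chrom, pairs$start, pairs$end, canon, sep = "|")
  if (umi_merge_1mm) {
    coord <- paste(pairs$chrom, pairs$start, pairs$end, sep = "|")
    for (grp in split(seq_along(key), coord)) {
      umis <- unique(canon[grp])
      if (length(umis) < 2L) next
      ## greedy: attach each UMI to the first earlier UMI within 1 mismatch
      canon_map <- umis
      for (i in seq_along(umis)[-1L]) {
        for (j in seq_len(i - 1L)) {
          if (sum(charToRaw(umis[i]) != charToRaw(umis[j])) <= 1L) {
            canon_map[i] <- canon_map[j]
            break
          }
        }
      }
      canon[grp] <- canon_map[match(canon[grp], umis)]
    }
    key <- paste(coord, canon, sep = "|")
  }
  fid <- match(key, unique(key))
  pairs$family <- fid
  first <- !duplicated(fid)
  fam <- data.frame(family = fid[first],
                    chrom = pairs$chrom[first],
                    start = pairs$start[first],
                    end = pairs$end[first],
                    umi = canon[first])
  fam$n_plus <- as.integer(tapply(pairs$strand == "+", fid, sum)[as.character(fam$family)])
  fam$n_minus <- as.integer(tapply(pairs$strand == "-", fid, sum)[as.character(fam$family)])
  attr(pairs, "families") <- fam[order(fam$family), , drop = FALSE]
  attr(pairs, "skipped") <- skipped
  pairs
}

#' Collapse one UMI family into a consensus read
#'
#' If both strands are represented (at `min_duplex_per_strand` read pairs or
#' more each) the two per-strand consensuses are combined position-wise --
#' agreement keeps the base, disagreement gives `N` -- and the read is a
#' *duplex* consensus. Otherwise the tier is set by the single-strand read
#' count: at least `min_simplex_reads` gives *simplex*, exactly 2
#' *sub_simplex*, and 1 a *singleton*.
#'
#' @param fam_pairs data.frame of the read pairs of one family (equal
#'   chrom/start/end).
#' @param min_simplex_reads single-strand reads required for the simplex tier.
#' @param min_duplex_per_strand per-strand read pairs required to treat a
#'   two-strand family as duplex.
#' @return one-row data.frame: chrom, start, end, tier, n_plus, n_minus, seq.
#' @export
collapse_family <- function(fam_pairs, min_simplex_reads = 3L,
                            min_duplex_per_strand = 1L) {
  flen <- fam_pairs$end[1L] - fam_pairs$start[1L] + 1L
  plus <- fam_pairs$strand == "+"
  n_plus <- sum(plus)
  n_minus <- sum(!plus)
  cons_of <- function(rows) {
    strand_consensus(fam_pairs$seq_left[rows], fam_pairs$seq_right[rows], flen)$seq
  }
  if (n_plus >= min_duplex_per_strand && n_minus >= min_duplex_per_strand &&
      n_plus >= 1L && n_minus >= 1L) {
    seq <- duplex_combine(cons_of(which(plus)), cons_of(which(!plus)))
    tier <- "duplex"
  } else {
    seq <- cons_of(seq_len(nrow(fam_pairs)))
    k <- nrow(fam_pairs)
    tier <- if (k >= min_simplex_reads) "simplex" else
      if (k == 2L) "sub_simplex" else "singleton"
  }
  data.frame(chrom = fam_pairs$chrom[1L], start = fam_pairs$start[1L],
             end = fam_pairs$end[1L], tier = tier,
             n_plus = n_plus, n_minus = n_minus, seq = seq,
             stringsAsFactors = FALSE)
}

#' Collapse a read-pair set into consensus reads
#'
#' Driver for the full collapsing step: groups read pairs into UMI families
#' ([group_families()]), collapses every family ([collapse_family()]) and
#' trims the consensus ends ([trim_consensus()]).
#'
#' @inheritParams collapse_family
#' @param pairs a `read_pairs` data.frame.
#' @param trim bases removed from each consensus end (3 by default, matching
#'   the elevated error rate at read ends).
#' @return data.frame of class `consensus_reads`: family, chrom, start, end
#'   (post-trim), tier, n_plus, n_minus, seq; attribute `skipped` counts
#'   dropped inputs (missing UMI or too short to trim).
#' @export
collapse_reads <- function(pairs, trim = 3L, min_simplex_reads = 3L,
                           min_duplex_per_strand = 1L) {
  pairs <- group_families(pairs)
  skipped <- attr(pairs, "skipped")
  n <- nrow(pairs)
  if (!n) {
    out <- data.frame(family = integer(), chrom = character(), start = integer(),
                      end = integer(), tier = character(), n_plus = integer(),
                      n_minus = integer(), seq = character())
    class(out) <- c("consensus_reads", "data.frame")
    attr(out, "skipped") <- skipped
    return(out)
  }
  idx <- split(seq_len(n), pairs$family)
  flen <- pairs$end - pairs$start + 1L
  strand_plus <- pairs$strand == "+"
  sl <- pairs$seq_left
  sr <- pairs$seq_right
  nfam <- length(idx)
  tier <- character(nfam); np <- integer(nfam); nm <- integer(nfam)
  seqv <- character(nfam); row1 <- integer(nfam)
  for (f in seq_len(nfam)) {
    rows <- idx[[f]]
    row1[f] <- rows[1L]
    fl <- flen[rows[1L]]
    plus <- rows[strand_plus[rows]]
    minus <- rows[!strand_plus[rows]]
    np[f] <- length(plus); nm[f] <- length(minus)
    if (np[f] >= min_duplex_per_strand && nm[f] >= min_duplex_per_strand) {
      c1 <- consensus_core(sl[plus], sr[plus], fl)$chars
      c2 <- consensus_core(sl[minus], sr[minus], fl)$chars
      c1[c1 != c2] <- "N"
      seqv[f] <- paste(c1, collapse = "")
      tier[f] <- "duplex"
    } else {
      seqv[f] <- paste(consensus_core(sl[rows], sr[rows], fl)$chars,
                       collapse = "")
      k <- length(rows)
      tier[f] <- if (k >= min_simplex_reads) "simplex" else
        if (k == 2L) "sub_simplex" else "singleton"
    }
  }
  out <- data.frame(family = as.integer(names(idx)),
                    chrom = pairs$chrom[row1],
                    start = pairs$start[row1],
                    end = pairs$end[row1],
                    tier = tier, n_plus = np, n_minus = nm, seq = seqv,
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_reads", "data.frame")
  out <- trim_consensus(out, n_bases = trim)
  attr(out, "skipped") <- skipped
  out
}

#' Trim bases from both ends of consensus reads
#'
#' Removes `n_bases` from each end of every consensus read and shrinks its
#' fragment interval accordingly; reads too short to trim are dropped and
#' counted in the `dropped` attribute. A 167/323-bp fragment mixture trimmed
#' by the default 3 bases per end yields the familiar 161/317-bp cfDNA
#' insert-size peaks.
#'
#' @param cons a `consensus_reads` data.frame.
#' @param n_bases bases to remove from each end.
#' @return the trimmed `consensus_reads` data.frame.
#' @export
trim_consensus <- function(cons, n_bases = 3L) {
  n_bases <- as.integer(n_bases)
  if (n_bases == 0L) return(cons)
  len <- cons$end - cons$start + 1L
  keep <- len > 2L * n_bases
  dropped <- sum(!keep)
  cons <- cons[keep, , drop = FALSE]
  cons$seq <- substring(cons$seq, n_bases + 1L, (len[keep]) - n_bases)
  cons$start <- cons$start + n_bases
  cons$end <- cons$end - n_bases
  rownames(cons) <- NULL
  attr(cons, "dropped") <- dropped
  class(cons) <- c("consensus_reads", "data.frame")
  cons
}

#' Split consensus reads into the output tiers
#'
#' @param cons a `consensus_reads` data.frame.
#' @return named list of `consensus_reads`: `duplex`, `simplex`,
#'   `sub_simplex`, `singleton`, and `all_unique` (the union -- one entry per
#'   sequenced template molecule).
#' @export
emit_tiers <- function(cons) {
  pick <- function(t) {
    out <- cons[cons$tier %in% t, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(duplex = pick("duplex"),
       simplex = pick("simplex"),
       sub_simplex = pick("sub_simplex"),
       singleton = pick("singleton"),
       all_unique = pick(c("duplex", "simplex", "sub_simplex", "singleton")))
}

#' @export
print.consensus_reads <- function(x, ...) {
  cat(sprintf("consensus_reads: %d reads\n", nrow(x)))
  if (nrow(x)) print(table(tier = x$tier))
  invisible(x)
}
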