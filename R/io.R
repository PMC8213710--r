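## Plain-text I/O: SAM read pairs, BED targets, FASTA references, variant
## tables (truth / hotspot / population-AF / panel-of-normals) and a minimal
## fixed-schema VCF. All coordinates follow the field conventions: SAM and
## variant tables are 1-based, BED is 0-based half-open.

#' Write aligned read pairs as coordinate-sorted SAM text
#'
#' Each read pair is emitted as two properly-paired records with standard SAM
#' flags (99/147 for pairs from the plus template strand, 83/163 for the minus
#' strand) and the UMI pair in a tag (`RX:Z:umi1-umi2`, as-read order).
#'
#' @param pairs a `read_pairs` data.frame.
#' @param path output file.
#' @param reference named character vector of chromosome sequences (for `@SQ`
#'   lengths); lengths are inferred from the reads when omitted.
#' @param umi_tag SAM tag carrying the UMI pair.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, path, reference = NULL, umi_tag = "RX") {
  chroms <- unique(pairs$chrom)
  lens <- if (!is.null(reference)) nchar(reference)[chroms] else
    vapply(chroms, function(ch) max(pairs$end[pairs$chrom == ch]) + 1000L, 0L)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(lens)))
  seed <- attr(pairs, "seed")
  if (!is.null(seed)) hdr <- c(hdr, sprintf("@CO\tcfduplex simulation seed=%d", seed))
  l1 <- nchar(pairs$seq_left)
  l2 <- nchar(pairs$seq_right)
  pos_left <- pairs$start
  pos_right <- pairs$end - l2 + 1L
  plus <- pairs$strand == "+"
  tlen <- pairs$end - pairs$start + 1L
  tag <- sprintf("%s:Z:%s-%s", umi_tag, pairs$umi1, pairs$umi2)
  ## R1 is the left (forward) mate for plus-strand pairs, the right (reverse)
  ## mate for minus-strand pairs
  rec <- function(flag, pos, cig_len, seq, mate_pos, tl) {
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*\t%s",
            pairs$qname, flag, pairs$chrom, pos, cig_len, mate_pos, tl, seq, tag)
  }
  fwd_flag <- ifelse(plus, 99L, 163L)    # forward mate: R1 on +, R2 on -
  rev_flag <- ifelse(plus, 147L, 83L)
  lines <- c(rec(fwd_flag, pos_left, l1, pairs$seq_left, pos_right, tlen),
             rec(rev_flag, pos_right, l2, pairs$seq_right, pos_left, -tlen))
  ord <- order(rep(pairs$chrom, 2L), c(pos_left, pos_right))
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}

#' Read SAM text into a read-pair table
#'
#' Accepts the subset of SAM this package writes (proper pairs, simple `xM`
#' CIGARs, UMI tag). Records without a mate or without the UMI tag are skipped
#' and counted in the `skipped` attribute.
#'
#' @param path SAM text file.
#' @param umi_tag SAM tag carrying the UMI pair.
#' @return a `read_pairs` data.frame (see [amplify_and_sequence()]).
#' @export
read_sam <- function(path, umi_tag = "RX") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(qname = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      umi1 = character(), umi2 = character(),
                      seq_left = character(), seq_right = character())
  if (!length(lines)) {
    class(empty) <- c("read_pairs", "data.frame")
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  bad <- nf < 11L
  f <- f[!bad]
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  chrom <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  seqs <- vapply(f, `[[`, "", 10L)
  tag_re <- paste0("^", umi_tag, ":Z:")
  umi <- vapply(f, function(x) {
    hit <- grep(tag_re, x[-(1:11)], value = TRUE)
    if (length(hit)) sub(tag_re, "", hit[1L]) else NA_character_
  }, "")
  first <- bitwAnd(flag, 64L) > 0L
  reverse <- bitwAnd(flag, 16L) > 0L
  paired <- bitwAnd(flag, 1L) > 0L
  ## pair mates by qname
  idx1 <- which(first & paired)
  idx2 <- which(!first & paired)
  m <- match(qname[idx1], qname[idx2])
  ok <- !is.na(m)
  skipped <- sum(bad) + sum(!ok) + (length(idx2) - sum(ok)) + sum(!paired)
  i1 <- idx1[ok]
  i2 <- idx2[m[ok]]
  left_is_1 <- pos[i1] <= pos[i2]
  il <- ifelse(left_is_1, i1, i2)
  ir <- ifelse(left_is_1, i2, i1)
  strand <- ifelse(reverse[i1], "-", "+")     # template strand: R1 orientation
  umi_pair <- umi[i1]
  no_umi <- is.na(umi_pair)
  skipped <- skipped + sum(no_umi)
  keep <- !no_umi
  il <- il[keep]; ir <- ir[keep]; strand <- strand[keep]; umi_pair <- umi_pair[keep]
  usplit <- strsplit(umi_pair, "-", fixed = TRUE)
  out <- data.frame(qname = qname[il],
                    chrom = chrom[il],
                    start = pos[il],
                    end = pos[ir] + nchar(seqs[ir]) - 1L,
                    strand = strand,
                    umi1 = vapply(usplit, `[[`, "", 1L),
                    umi2 = vapply(usplit, function(x) if (length(x) > 1L) x[[2L]] else "", ""),
                    seq_left = seqs[il],
                    seq_right = seqs[ir],
                    stringsAsFactors = FALSE)
  ord <- order(out$chrom, out$start, out$end, out$qname)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Write consensus reads as SAM text (single-end records, tier in a tag)
#' @param cons a `consensus_reads` data.frame.
#' @param path output file.
#' @param reference optional named reference vector for `@SQ` lengths.
#' @return `path`, invisibly.
#' @export
write_consensus_sam <- function(cons, path, reference = NULL) {
  chroms <- unique(cons$chrom)
  lens <- if (!is.null(reference)) nchar(reference)[chroms] else
    vapply(chroms, function(ch) max(cons$end[cons$chrom == ch]) + 1000L, 0L)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(lens)))
  len <- cons$end - cons$start + 1L
  lines <- sprintf("F%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tXT:Z:%s\tXD:i:%d\tXE:i:%d",
                   cons$family, cons$chrom, cons$start, len,
                   gsub(".", "N", cons$seq, fixed = TRUE),
                   cons$tier, cons$n_plus, cons$n_minus)
  ord <- order(cons$chrom, cons$start)
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}

#' Read / write target regions in BED format (0-based half-open)
#' @param path BED file.
#' @return data.frame with chrom, start, end.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  x
}

#' @rdname read_bed
#' @param regions data.frame with chrom, start, end.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write a FASTA reference as a named character vector
#' @param path FASTA file.
#' @param width line width when writing.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop_arg("no FASTA records in ", path)
  nm <- sub("^>([^ \t]+).*$", "\\1", lines[hdr])
  to <- c(hdr[-1L] - 1L, length(lines))
  out <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):to[i]], collapse = "")
  }, "")
  names(out) <- nm
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## generic keyed-variant table reader with per-line validation
read_variant_table <- function(path, extra_cols = character(),
                               extra_classes = character()) {
  cols <- c("chrom", "pos", "ref", "alt", extra_cols)
  classes <- c("character", "integer", "character", "character", extra_classes)
  lines <- readLines(path)
  has_header <- length(lines) && startsWith(lines[1L], "chrom")
  body <- if (has_header) lines[-1L] else lines
  body_no <- seq_along(body) + as.integer(has_header)
  keep <- nzchar(body)
  fields <- strsplit(body[keep], "\t", fixed = TRUE)
  badlen <- lengths(fields) < length(cols)
  if (any(badlen))
    stop_arg(path, ": malformed row at line ",
             paste(body_no[keep][badlen], collapse = ", "),
             " (expected ", length(cols), " tab-delimited fields)")
  out <- utils::read.table(text = body[keep], sep = "\t",
                           col.names = cols, colClasses = classes,
                           stringsAsFactors = FALSE)
  if (any(is.na(out$pos)))
    stop_arg(path, ": non-numeric position at line ",
             paste(body_no[keep][is.na(out$pos)], collapse = ", "))
  out
}

#' Readers for the tab-delimited variant resources
#'
#' Hotspot lists and panel-of-normals tables are keyed by
#' chrom/pos/ref/alt; the population allele-frequency table carries an extra
#' `af` column (emulating a gnomAD extract); truth tables carry the full
#' simulation annotation. Malformed rows raise an error naming the line.
#'
#' @param path tab-delimited file; a `chrom...` header line is optional.
#' @return data.frame.
#' @export
read_hotspots <- function(path) read_variant_table(path)

#' @rdname read_hotspots
#' @export
read_pon <- function(path) read_variant_table(path)

#' @rdname read_hotspots
#' @export
read_popaf <- function(path) {
  out <- read_variant_table(path, "af", "numeric")
  if (any(is.na(out$af) | out$af < 0 | out$af > 1))
    stop_arg(path, ": population AF outside [0, 1]")
  out
}

#' @rdname read_hotspots
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_hotspots
#' @param x data.frame to write.
#' @export
write_truth_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variant calls as a minimal VCF
#'
#' Emits a fixed-schema VCF 4.2 with per-call combined depth (DP), allele
#' depth (AD), allele frequency (VF) and tier-resolved alt counts (DAD duplex,
#' SAD simplex) as FORMAT fields; call mode and hotspot status go to INFO.
#'
#' @param calls data.frame of calls (chrom, pos, ref, alt, duplex_alt,
#'   simplex_alt, AD, DP, VAF, mode, hotspot).
#' @param path output file.
#' @param sample sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cfduplex",
           "##INFO=<ID=MODE,Number=1,Type=String,Description=\"Calling mode: de_novo or genotyped\">",
           "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"Known cancer hotspot site\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Combined duplex+simplex fragment depth\">",
           "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Combined duplex+simplex alt fragments\">",
           "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Variant allele frequency AD/DP\">",
           "##FORMAT=<ID=DAD,Number=1,Type=Integer,Description=\"Duplex alt fragments\">",
           "##FORMAT=<ID=SAD,Number=1,Type=Integer,Description=\"Simplex alt fragments\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  if (nrow(calls)) {
    info <- paste0("MODE=", calls$mode, ifelse(calls$hotspot, ";HOTSPOT", ""))
    gt <- sprintf("%d:%d:%s:%d:%d", calls$DP, calls$AD,
                  formatC(calls$VAF, format = "g", digits = 6),
                  calls$duplex_alt, calls$simplex_alt)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tDP:AD:VF:DAD:SAD\t%s",
                    calls$chrom, calls$pos, calls$ref, calls$alt, info, gt)
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into a call table
#' @param path VCF file.
#' @return data.frame of calls.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), duplex_alt = integer(),
                      simplex_alt = integer(), AD = integer(), DP = integer(),
                      VAF = numeric(), mode = character(), hotspot = logical()))
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(f) < 10L
  if (any(bad))
    stop_arg(path, ": malformed VCF record at line ",
             paste(which(!startsWith(lines, "#"))[bad], collapse = ", "))
  gt <- strsplit(vapply(f, `[[`, "", 10L), ":", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8L)
  data.frame(chrom = vapply(f, `[[`, "", 1L),
             pos = as.integer(vapply(f, `[[`, "", 2L)),
             ref = vapply(f, `[[`, "", 4L),
             alt = vapply(f, `[[`, "", 5L),
             duplex_alt = as.integer(vapply(gt, `[[`, "", 4L)),
             simplex_alt = as.integer(vapply(gt, `[[`, "", 5L)),
             AD = as.integer(vapply(gt, `[[`, "", 2L)),
             DP = as.integer(vapply(gt, `[[`, "", 1L)),
             VAF = as.numeric(vapply(gt, `[[`, "", 3L)),
             mode = sub("^MODE=([^;]+).*$", "\\1", info),
             hotspot = grepl("HOTSPOT", info, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Write / read a generic tab-delimited table with header
#' @param x data.frame.
#' @param path file path.
#' @return the table (readers) or `path` invisibly (writers).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
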