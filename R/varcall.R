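## Threshold-based variant detection from tiered consensus pileups.
##
## Counting is fragment-level: every consensus read represents one original
## template molecule, and overlapping mates were merged during collapsing, so
## a fragment supports the alternate allele at most once (mate disagreement
## at the site yields N, i.e. no support).

#' Combine duplex and simplex allele counts into AD / DP / VAF
#'
#' Reported allele depth (AD), total depth (DP) and allele frequency (VAF)
#' combine the duplex and simplex consensus tiers.
#'
#' @param duplex_counts named vector/list with `alt` and `depth`.
#' @param simplex_counts named vector/list with `alt` and `depth`.
#' @return list with `AD`, `DP`, `VAF` (`VAF` is `NA` and the call must be
#'   suppressed when `DP` is zero).
#' @examples
#' combine_allele_counts(c(alt = 2, depth = 1000), c(alt = 1, depth = 500))
#' @export
combine_allele_counts <- function(duplex_counts, simplex_counts) {
  ad <- as.integer(duplex_counts[["alt"]] + simplex_counts[["alt"]])
  dp <- as.integer(duplex_counts[["depth"]] + simplex_counts[["depth"]])
  if (any(c(duplex_counts[["alt"]], simplex_counts[["alt"]]) < 0) ||
      ad > dp)
    stop_arg("allele counts must be non-negative and AD <= DP")
  list(AD = ad, DP = dp, VAF = if (dp > 0L) ad / dp else NA_real_)
}

#' Genotype a known site (tumor-informed detection)
#'
#' Detection at a site known to be mutated requires at least 1 duplex or 2
#' simplex consensus fragments supporting the alternate allele. AD/DP/VAF
#' combine both tiers.
#'
#' @param duplex_pileup,simplex_pileup `position_pileup` data.frames.
#' @param site one-row data.frame (or list) with chrom, pos, ref, alt.
#' @param min_duplex,min_simplex detection thresholds.
#' @return list: `detected` and `call` (one-row VariantCall data.frame).
#' @export
genotype_site <- function(duplex_pileup, simplex_pileup, site,
                          min_duplex = 1L, min_simplex = 2L) {
  d <- site_counts(duplex_pileup, site$chrom, site$pos, site$alt)
  s <- site_counts(simplex_pileup, site$chrom, site$pos, site$alt)
  if (is.na(d[["depth"]]) && is.na(s[["depth"]]))
    stop_arg("site outside targets: ", site$chrom, ":", site$pos)
  d[is.na(d)] <- 0L
  s[is.na(s)] <- 0L
  detected <- d[["alt"]] >= min_duplex || s[["alt"]] >= min_simplex
  comb <- combine_allele_counts(d, s)
  call <- data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                     alt = site$alt, duplex_alt = d[["alt"]],
                     simplex_alt = s[["alt"]], AD = comb$AD, DP = comb$DP,
                     VAF = comb$VAF, mode = "genotyped",
                     hotspot = isTRUE(site$hotspot),
                     stringsAsFactors = FALSE)
  if (!is.na(comb$VAF) || !detected) {
    list(detected = detected, call = call)
  } else {
    list(detected = FALSE, call = call)     # DP == 0: call suppressed
  }
}

#' Genotype a list of known sites
#'
#' @inheritParams genotype_site
#' @param known data.frame of prior-knowledge sites (chrom, pos, ref, alt,
#'   optional hotspot).
#' @return VariantCall data.frame with a `detected` column.
#' @export
genotype_variants <- function(duplex_pileup, simplex_pileup, known,
                              min_duplex = 1L, min_simplex = 2L) {
  rows <- lapply(seq_len(nrow(known)), function(i) {
    g <- genotype_site(duplex_pileup, simplex_pileup, known[i, ],
                       min_duplex = min_duplex, min_simplex = min_simplex)
    cbind(g$call, detected = g$detected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' De novo variant calling from the duplex tier
#'
#' Scans the duplex pileup for non-reference alleles and emits a call when
#' the duplex alt fragment count reaches the hotspot-dependent minimum: 3
#' duplex consensus fragments at a known cancer hotspot, 5 otherwise.
#' Reported AD/DP/VAF combine the duplex and simplex tiers. Each alternate
#' allele of a multi-allelic site is evaluated independently.
#'
#' @param duplex_pileup,simplex_pileup `position_pileup` data.frames.
#' @param hotspots data.frame of hotspot sites (chrom, pos, ref, alt); may be
#'   `NULL` or empty.
#' @param min_hotspot,min_non_hotspot duplex alt-fragment minima.
#' @return VariantCall data.frame (possibly zero rows).
#' @export
call_de_novo <- function(duplex_pileup, simplex_pileup = NULL, hotspots = NULL,
                         min_hotspot = 3L, min_non_hotspot = 5L) {
  pu <- duplex_pileup[duplex_pileup$depth > 0L, , drop = FALSE]
  if (!nrow(pu)) return(empty_calls())
  cand <- position_error_rates(pu, max_af = 1)    # all non-ref allele counts
  cand <- cand[cand$count > 0L, , drop = FALSE]
  if (!nrow(cand)) return(empty_calls())
  hot_keys <- if (is.null(hotspots) || !nrow(hotspots)) character() else
    variant_key(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt)
  is_hot <- variant_key(cand$chrom, cand$pos, cand$ref, cand$alt) %in% hot_keys
  called <- cand$count >= ifelse(is_hot, min_hotspot, min_non_hotspot)
  cand <- cand[called, , drop = FALSE]
  is_hot <- is_hot[called]
  if (!nrow(cand)) return(empty_calls())
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    d <- c(alt = cand$count[i],
           depth = site_counts(duplex_pileup, cand$chrom[i], cand$pos[i],
                               cand$alt[i])[["depth"]])
    s <- if (is.null(simplex_pileup)) c(alt = 0L, depth = 0L) else {
      sc <- site_counts(simplex_pileup, cand$chrom[i], cand$pos[i], cand$alt[i])
      sc[is.na(sc)] <- 0L
      sc
    }
    comb <- combine_allele_counts(d, s)
    data.frame(chrom = cand$chrom[i], pos = cand$pos[i], ref = cand$ref[i],
               alt = cand$alt[i], duplex_alt = as.integer(d[["alt"]]),
               simplex_alt = as.integer(s[["alt"]]), AD = comb$AD,
               DP = comb$DP, VAF = comb$VAF, mode = "de_novo",
               hotspot = is_hot[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), duplex_alt = integer(), simplex_alt = integer(),
             AD = integer(), DP = integer(), VAF = numeric(),
             mode = character(), hotspot = logical(), stringsAsFactors = FALSE)
}

#' Structural-variant read-support rule
#'
#' An SV is called with a minimum of 3 fusion-spanning reads when seen de
#' novo, or 1 fusion-spanning read when the SV was previously identified in
#' that patient. Junction discovery itself is upstream; only the support rule
#' is applied.
#'
#' @param junction_read_count fusion-spanning read count (>= 0).
#' @param previously_identified logical.
#' @param min_de_novo,min_known thresholds.
#' @return logical: called or not (vectorized).
#' @examples
#' sv_support_rule(c(2, 3), previously_identified = FALSE)
#' @export
sv_support_rule <- function(junction_read_count, previously_identified,
                            min_de_novo = 3L, min_known = 1L) {
  if (any(junction_read_count < 0)) stop_arg("junction read count must be >= 0")
  junction_read_count >= ifelse(previously_identified, min_known, min_de_novo)
}
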