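## Matched-WBC (buffy coat) classification of plasma variant calls into
## somatic / germline / clonal-hematopoiesis compartments, population-database
## filtering, the unmatched-mode heuristic, and fingerprint-SNP identity
## checks.

BOX_LEVELS <- c("I_somatic_cfDNA_only", "II_tumor_with_trace_WBC",
                "III_germline", "IV_CH")

#' Classify a plasma call against its matched-WBC evidence (boxes I-IV)
#'
#' Compartments follow the VAF geometry of matched plasma/WBC calling:
#' \describe{
#'   \item{III (germline)}{both VAFs in the presumed heterozygous germline
#'     range, 0.35--0.65 (inclusive).}
#'   \item{IV (CH)}{WBC-supported and both VAFs below 0.10 -- clonal
#'     hematopoiesis present at equivalent low frequency in both
#'     compartments.}
#'   \item{I (somatic, cfDNA-only)}{no WBC support.}
#'   \item{II (tumor with trace WBC)}{everything else: present in cfDNA at
#'     higher VAF with limited WBC evidence.}
#' }
#' Precedence is III, IV, I, II: germline evidence is strongest, CH requires
#' WBC support. The boundaries are inclusive at 0.35 and 0.65 and exclusive
#' at 0.10. Vectorized; every (plasma, wbc, support) triple maps to exactly
#' one box.
#'
#' @param plasma_vaf,wbc_vaf VAFs in `[0, 1]` (WBC VAF is 0 when absent).
#' @param wbc_supported logical: does the WBC sample show the allele at the
#'   supporting-fragment minimum (2 consensus fragments by default upstream)?
#' @param germline_range inclusive germline VAF range.
#' @param ch_max exclusive upper VAF bound of the CH box.
#' @return character vector of box labels.
#' @examples
#' classify_compartment(0.50, 0.48, TRUE)      # III_germline
#' classify_compartment(0.0044, 0.0031, TRUE)  # IV_CH
#' classify_compartment(0.12, 0, FALSE)        # I_somatic_cfDNA_only
#' @export
classify_compartment <- function(plasma_vaf, wbc_vaf, wbc_supported,
                                 germline_range = c(0.35, 0.65),
                                 ch_max = 0.10) {
  if (any(plasma_vaf < 0 | plasma_vaf > 1 | wbc_vaf < 0 | wbc_vaf > 1,
          na.rm = TRUE))
    stop_arg("VAFs must lie in [0, 1]")
  n <- max(length(plasma_vaf), length(wbc_vaf), length(wbc_supported))
  p <- rep_len(plasma_vaf, n)
  w <- rep_len(wbc_vaf, n)
  s <- rep_len(wbc_supported, n)
  germ <- p >= germline_range[1] & p <= germline_range[2] &
    w >= germline_range[1] & w <= germline_range[2]
  ch <- !germ & s & p < ch_max & w < ch_max & w > 0
  box1 <- !germ & !ch & !s
  out <- rep(BOX_LEVELS[2L], n)
  out[box1] <- BOX_LEVELS[1L]
  out[ch] <- BOX_LEVELS[4L]
  out[germ] <- BOX_LEVELS[3L]
  out
}

#' Population-database filtering (panel of normals + population AF)
#'
#' A variant is removed when it is present in the curated panel of normals or
#' when its population allele frequency reaches `af_threshold` (0.5% by
#' default, emulating the gnomAD common-variant rule). Removal reasons are
#' recorded per variant.
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @param panel_of_normals data.frame with chrom, pos, ref, alt (or `NULL`).
#' @param population_af data.frame with chrom, pos, ref, alt, af (or `NULL`).
#' @param af_threshold population-AF removal threshold, in (0, 1).
#' @return list: `retained`, `removed` (with a `reason` column).
#' @export
population_filter <- function(variants, panel_of_normals = NULL,
                              population_af = NULL, af_threshold = 0.005) {
  if (af_threshold <= 0 || af_threshold >= 1)
    stop_arg("af_threshold must lie in (0, 1)")
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  in_pon <- if (is.null(panel_of_normals) || !nrow(panel_of_normals))
    rep(FALSE, nrow(variants)) else
      key %in% variant_key(panel_of_normals$chrom, panel_of_normals$pos,
                           panel_of_normals$ref, panel_of_normals$alt)
  af <- rep(0, nrow(variants))
  if (!is.null(population_af) && nrow(population_af)) {
    m <- match(key, variant_key(population_af$chrom, population_af$pos,
                                population_af$ref, population_af$alt))
    af[!is.na(m)] <- population_af$af[m[!is.na(m)]]
  }
  common <- af >= af_threshold
  removed <- in_pon | common
  reason <- ifelse(in_pon & common, "pon+population_af",
            ifelse(in_pon, "pon",
            ifelse(common, "population_af", NA)))
  ret <- variants[!removed, , drop = FALSE]
  rem <- variants[removed, , drop = FALSE]
  if (nrow(rem)) rem$reason <- reason[removed]
  rownames(ret) <- rownames(rem) <- NULL
  list(retained = ret, removed = rem)
}

#' Unmatched-mode filtering and its cost in lost somatic variants
#'
#' Emulates filtering without a matched WBC sample: the population filter
#' plus the germline-range VAF heuristic (plasma VAF within 0.35--0.65
#' removed as presumed germline). When truth labels are available (synthetic
#' runs), somatic-truth variants removed by the heuristic are reported as
#' improperly removed -- the loss the matched design avoids.
#'
#' @inheritParams population_filter
#' @param variants data.frame with chrom, pos, ref, alt and a `VAF` column.
#' @param germline_range VAF heuristic range applied without WBC data.
#' @param truth optional truth table with chrom, pos, ref, alt, compartment.
#' @return list: `retained`, `removed` (with reasons), `improperly_removed`
#'   (somatic-truth variants removed; empty data.frame when truth is absent).
#' @export
unmatched_mode_filter <- function(variants, panel_of_normals = NULL,
                                  population_af = NULL, af_threshold = 0.005,
                                  germline_range = c(0.35, 0.65),
                                  truth = NULL) {
  pf <- population_filter(variants, panel_of_normals, population_af,
                          af_threshold)
  heur <- pf$retained$VAF >= germline_range[1] & pf$retained$VAF <= germline_range[2]
  rem2 <- pf$retained[heur, , drop = FALSE]
  if (nrow(rem2)) rem2$reason <- "germline_vaf_heuristic"
  retained <- pf$retained[!heur, , drop = FALSE]
  removed <- rbind(pf$removed, rem2)
  improper <- removed[0, , drop = FALSE]
  if (!is.null(truth) && nrow(removed)) {
    tkey <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
    rkey <- variant_key(removed$chrom, removed$pos, removed$ref, removed$alt)
    m <- match(rkey, tkey)
    somatic <- !is.na(m) & truth$compartment[m] == "somatic_tumor"
    improper <- removed[somatic, , drop = FALSE]
  }
  rownames(retained) <- rownames(removed) <- rownames(improper) <- NULL
  list(retained = retained, removed = removed, improperly_removed = improper)
}

#' Fingerprint-SNP concordance between plasma and WBC samples
#'
#' Verifies that the plasma and WBC libraries come from the same donor.
#' VAFs at fingerprint SNP sites are discretized to genotypes (hom-ref below
#' `cuts[1]`, hom-alt above `cuts[2]`, het in between); concordance is the
#' fraction of informative sites (adequate depth in both samples) with
#' identical genotypes. The verdict is `"match"` at or above
#' `match_threshold`, `"mismatch"` below, and `"indeterminate"` with fewer
#' than `min_sites` informative sites.
#'
#' @param plasma_vaf,wbc_vaf VAF vectors over the same fingerprint sites.
#' @param plasma_depth,wbc_depth optional depth vectors; sites below
#'   `min_depth` in either sample are not informative.
#' @param cuts genotype discretization cuts (hom-ref/het and het/hom-alt).
#' @param min_sites minimum informative sites for a verdict.
#' @param min_depth minimum depth for a site to be informative.
#' @param match_threshold concordance required to declare a match.
#' @return list: `concordance`, `n_informative`, `verdict`.
#' @export
fingerprint_concordance <- function(plasma_vaf, wbc_vaf,
                                    plasma_depth = NULL, wbc_depth = NULL,
                                    cuts = c(0.1, 0.9), min_sites = 20L,
                                    min_depth = 20L, match_threshold = 0.9) {
  stopifnot(length(plasma_vaf) == length(wbc_vaf))
  informative <- !is.na(plasma_vaf) & !is.na(wbc_vaf)
  if (!is.null(plasma_depth)) informative <- informative & plasma_depth >= min_depth
  if (!is.null(wbc_depth)) informative <- informative & wbc_depth >= min_depth
  gt <- function(v) findInterval(v, cuts)      # 0 hom-ref, 1 het, 2 hom-alt
  n <- sum(informative)
  if (n < min_sites)
    return(list(concordance = NA_real_, n_informative = n,
                verdict = "indeterminate"))
  conc <- mean(gt(plasma_vaf[informative]) == gt(wbc_vaf[informative]))
  list(concordance = conc, n_informative = n,
       verdict = if (conc >= match_threshold) "match" else "mismatch")
}
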