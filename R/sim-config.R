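#' Simulation configuration for synthetic UMI-tagged cfDNA read sets
#'
#' Bundles the generative parameters of the synthetic sequencing model:
#' a bimodal (mono-/di-nucleosomal) fragment-length mixture, per-template PCR
#' strand families, per-base substitution error, and target panel geometry.
#'
#' Fragment-length peaks are *pre-trim* template lengths. The downstream
#' consensus step trims 3 bases from each read end, so the defaults of 167 and
#' 323 bp reproduce the characteristic post-trim cfDNA insert-size peaks at
#' 161 and 317 bp.
#'
#' @param panel data.frame of target regions with columns `chrom`, `start`,
#'   `end` (BED convention: 0-based half-open).
#' @param mono_peak_bp mode of the mononucleosomal fragment-length component
#'   (bp, pre-trim).
#' @param di_peak_bp mode of the dinucleosomal component (bp, pre-trim).
#' @param mono_weight mixture weight of the mononucleosomal component, in
#'   `[0, 1]`.
#' @param length_sd_bp standard deviation of each mixture component (bp).
#' @param tumor_fraction_short_shift_bp non-negative shortening (bp) applied to
#'   tumor-derived fragments, emulating the shorter ctDNA length profile.
#' @param seq_error_rate per-base substitution probability during sequencing.
#' @param family_size_mean mean per-strand PCR duplicate count; family sizes
#'   follow `1 + Poisson(family_size_mean - 1)` so every sequenced strand
#'   yields at least one read.
#' @param duplex_capture_prob probability that the second strand of a template
#'   is sequenced at all (the first strand always is).
#' @param depth_templates unique template molecules covering a target position.
#' @param read_len read length (bp) of each mate.
#' @param umi_len length of each UMI of the dual-UMI pair.
#' @param min_fragment_bp floor on simulated fragment length (bp).
#' @param umi_tag SAM tag name used to carry the UMI pair.
#' @param seed integer master seed; all stage seeds are derived from it.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(depth_templates = 50, seed = 7)
#' cfg$mono_peak_bp
#' @export
sim_config <- function(panel = data.frame(chrom = "chr1",
                                          start = c(1000L, 5000L),
                                          end = c(1600L, 5600L)),
                       mono_peak_bp = 167L,
                       di_peak_bp = 323L,
                       mono_weight = 0.85,
                       length_sd_bp = 15,
                       tumor_fraction_short_shift_bp = 15L,
                       seq_error_rate = 1e-3,
                       family_size_mean = 3,
                       duplex_capture_prob = 0.5,
                       depth_templates = 800L,
                       read_len = 100L,
                       umi_len = 3L,
                       min_fragment_bp = 50L,
                       umi_tag = "RX",
                       seed = 1L) {
  cfg <- list(panel = panel,
              mono_peak_bp = as.integer(mono_peak_bp),
              di_peak_bp = as.integer(di_peak_bp),
              mono_weight = mono_weight,
              length_sd_bp = length_sd_bp,
              tumor_fraction_short_shift_bp = as.integer(tumor_fraction_short_shift_bp),
              seq_error_rate = seq_error_rate,
              family_size_mean = family_size_mean,
              duplex_capture_prob = duplex_capture_prob,
              depth_templates = as.integer(depth_templates),
              read_len = as.integer(read_len),
              umi_len = as.integer(umi_len),
              min_fragment_bp = as.integer(min_fragment_bp),
              umi_tag = umi_tag,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$panel),
            all(c("chrom", "start", "end") %in% names(cfg$panel)))
  if (any(cfg$panel$end <= cfg$panel$start))
    stop_arg("panel regions must satisfy start < end (0-based half-open)")
  probs <- c(cfg$mono_weight, cfg$seq_error_rate, cfg$duplex_capture_prob)
  if (any(probs < 0 | probs > 1))
    stop_arg("mono_weight, seq_error_rate and duplex_capture_prob must lie in [0, 1]")
  if (cfg$mono_peak_bp <= 0 || cfg$di_peak_bp <= 0 || cfg$depth_templates <= 0)
    stop_arg("fragment peaks and depth_templates must be positive")
  if (cfg$length_sd_bp < 0) stop_arg("length_sd_bp must be non-negative")
  if (cfg$tumor_fraction_short_shift_bp < 0)
    stop_arg("tumor_fraction_short_shift_bp must be non-negative")
  if (cfg$family_size_mean < 1)
    stop_arg("family_size_mean must be >= 1 (every strand yields at least one read)")
  if (cfg$read_len < 20) stop_arg("read_len must be at least 20")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("cfDNA read-set simulation configuration\n")
  cat(sprintf("  panel: %d region(s), %d targeted bp\n",
              nrow(x$panel), sum(x$panel$end - x$panel$start)))
  cat(sprintf("  fragment length: %d/%d bp peaks (weights %.2f/%.2f, sd %.1f)\n",
              x$mono_peak_bp, x$di_peak_bp, x$mono_weight, 1 - x$mono_weight,
              x$length_sd_bp))
  cat(sprintf("  tumor fragment shortening: %d bp\n", x$tumor_fraction_short_shift_bp))
  cat(sprintf("  seq error %.2g/base; family size 1+Pois(%.2g); duplex capture %.2f\n",
              x$seq_error_rate, x$family_size_mean - 1, x$duplex_capture_prob))
  cat(sprintf("  depth %d templates/site; reads 2 x %d bp; UMI %d+%d; seed %d\n",
              x$depth_templates, x$read_len, x$umi_len, x$umi_len, x$seed))
  invisible(x)
}

#' Build a truth table of injected variants
#'
#' Places somatic, germline and clonal-hematopoiesis (CH) truth variants at
#' random positions inside the configured panel, together with population
#' allele frequencies (germline variants are common population SNPs; somatic
#' and CH variants are absent from the population table) and optional
#' fingerprint SNP sites shared between the plasma and WBC compartments of the
#' simulated donor.
#'
#' Compartment VAF conventions: germline truth has both plasma and WBC VAF
#' near 0.5 (heterozygous); CH truth has equal low VAF in both compartments;
#' somatic truth has WBC VAF 0, or a small trace value for variants meant to
#' exercise the "tumor with trace WBC support" compartment.
#'
#' @param config a [sim_config()].
#' @param n_somatic somatic variants with no WBC support (expected box I).
#' @param n_somatic_trace somatic variants with trace WBC support (box II).
#' @param n_germline heterozygous germline variants (box III).
#' @param n_ch clonal hematopoiesis variants (box IV).
#' @param n_fingerprint fingerprint SNP sites (donor genotypes drawn from
#'   Hardy-Weinberg at allele frequency 0.5; identical in plasma and WBC).
#' @param somatic_vaf_range range of somatic plasma VAFs.
#' @param trace_plasma_vaf_range plasma VAF range of trace-WBC somatic variants.
#' @param trace_wbc_vaf WBC VAF of trace-WBC somatic variants.
#' @param ch_vaf_range VAF range (both compartments) of CH variants.
#' @param hotspot_fraction fraction of somatic variants flagged as hotspots.
#' @param seed integer seed (defaults to a stream derived from `config$seed`).
#' @return data.frame with columns chrom, pos, ref, alt, compartment,
#'   plasma_vaf, wbc_vaf, hotspot, pop_af, true_box.
#' @export
sim_truth <- function(config,
                      n_somatic = 5L, n_somatic_trace = 5L,
                      n_germline = 5L, n_ch = 5L,
                      n_fingerprint = 25L,
                      somatic_vaf_range = c(0.03, 0.30),
                      trace_plasma_vaf_range = c(0.12, 0.30),
                      trace_wbc_vaf = 0.015,
                      ch_vaf_range = c(0.02, 0.06),
                      hotspot_fraction = 0.4,
                      seed = NULL) {
  seed <- seed %||% key_seed(config$seed, "truth")
  ref <- sim_reference(config)
  n_total <- n_somatic + n_somatic_trace + n_germline + n_ch + n_fingerprint
  with_seed(seed, {
    ## candidate positions: interior of each panel region (1-based), away from
    ## region edges so full-depth coverage is available at every truth site
    cand <- do.call(rbind, lapply(seq_len(nrow(config$panel)), function(i) {
      r <- config$panel[i, ]
      margin <- 25L
      pos <- (r$start + 1L + margin):(r$end - margin)
      data.frame(chrom = r$chrom, pos = pos)
    }))
    if (n_total > nrow(cand))
      stop_arg("panel too small for the requested number of truth variants")
    pick <- cand[sample.int(nrow(cand), n_total), ]
    refb <- substring(ref[pick$chrom], pick$pos, pick$pos)
    altb <- vapply(refb, function(b) sample(other_bases(b), 1L), "")
    comp <- rep(c("somatic_tumor", "somatic_tumor", "germline", "CH", "fingerprint"),
                c(n_somatic, n_somatic_trace, n_germline, n_ch, n_fingerprint))
    plasma <- numeric(n_total)
    wbc <- numeric(n_total)
    i1 <- seq_len(n_somatic)
    i2 <- n_somatic + seq_len(n_somatic_trace)
    i3 <- n_somatic + n_somatic_trace + seq_len(n_germline)
    i4 <- n_somatic + n_somatic_trace + n_germline + seq_len(n_ch)
    i5 <- n_somatic + n_somatic_trace + n_germline + n_ch + seq_len(n_fingerprint)
    plasma[i1] <- runif(n_somatic, somatic_vaf_range[1], somatic_vaf_range[2])
    plasma[i2] <- runif(n_somatic_trace, trace_plasma_vaf_range[1], trace_plasma_vaf_range[2])
    wbc[i2] <- trace_wbc_vaf
    plasma[i3] <- 0.5; wbc[i3] <- 0.5
    vch <- runif(n_ch, ch_vaf_range[1], ch_vaf_range[2])
    plasma[i4] <- vch; wbc[i4] <- vch
    gt <- sample(c(0, 0.5, 1), n_fingerprint, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    plasma[i5] <- gt; wbc[i5] <- gt
    hot <- rep(FALSE, n_total)
    som_idx <- c(i1, i2)
    if (length(som_idx))
      hot[som_idx] <- runif(length(som_idx)) < hotspot_fraction
    pop_af <- numeric(n_total)
    pop_af[i3] <- runif(n_germline, 0.01, 0.5)
    pop_af[i5] <- 0.5
    truth <- data.frame(chrom = pick$chrom, pos = pick$pos,
                        ref = refb, alt = altb, compartment = comp,
                        plasma_vaf = plasma, wbc_vaf = wbc,
                        hotspot = hot, pop_af = pop_af,
                        stringsAsFactors = FALSE, row.names = NULL)
    truth$true_box <- truth_box(truth)
    ## drop fingerprint hom-ref genotype rows from the variant truth? no:
    ## keep them -- genotype 0 sites are informative for concordance.
    truth[order(truth$chrom, truth$pos), , drop = FALSE]
  })
}

## Expected WBC-matched compartment (box) of each truth variant.
truth_box <- function(truth) {
  ifelse(truth$compartment == "germline", "III_germline",
  ifelse(truth$compartment == "CH", "IV_CH",
  ifelse(truth$compartment == "somatic_tumor" & truth$wbc_vaf > 0,
         "II_tumor_with_trace_WBC",
  ifelse(truth$compartment == "somatic_tumor", "I_somatic_cfDNA_only", NA))))
}
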