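## Background substitution-error profiling across consensus tiers.
##
## The error rate of a substitution type (e.g. A>G) is the fraction of
## sequenced bases supporting that non-reference allele. Non-reference
## alleles above the allele-frequency cap (2% by default) are treated as real
## variants and excluded from the error tally.

#' Per-position, per-substitution background error rates
#'
#' For every pileup position and each of the three non-reference bases, the
#' rate is `count / depth` when the allele frequency is at or below `max_af`;
#' alleles above the cap are excluded from the error tally (flagged, rate
#' `NA`) since they represent real variants rather than background error.
#' Zero-depth positions are skipped.
#'
#' @param pileup a `position_pileup` data.frame.
#' @param max_af allele-frequency cap for the error analysis.
#' @param exclude optional data.frame of regions (chrom, start, end; 0-based
#'   half-open) removed from the analysis -- e.g. known SNP or repeat tracks.
#' @return data.frame: chrom, pos, ref, alt, type (e.g. `"A>G"`), count,
#'   depth, rate, excluded.
#' @export
position_error_rates <- function(pileup, max_af = 0.02, exclude = NULL) {
  pu <- pileup[pileup$depth > 0L & pileup$ref %in% BASES, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- rep(FALSE, nrow(pu))
    for (i in seq_len(nrow(exclude)))
      drop <- drop | (pu$chrom == exclude$chrom[i] &
                        pu$pos > exclude$start[i] & pu$pos <= exclude$end[i])
    pu <- pu[!drop, , drop = FALSE]
  }
  n <- nrow(pu)
  alt1 <- vapply(pu$ref, function(b) other_bases(b), character(3L))
  out <- data.frame(chrom = rep(pu$chrom, each = 3L),
                    pos = rep(pu$pos, each = 3L),
                    ref = rep(pu$ref, each = 3L),
                    alt = as.vector(alt1),
                    stringsAsFactors = FALSE)
  cnt_mat <- t(as.matrix(pu[, BASES]))
  idx <- match(out$alt, BASES) + 4L * (rep(seq_len(n), each = 3L) - 1L)
  out$type <- paste(out$ref, out$alt, sep = ">")
  out$count <- as.integer(cnt_mat[idx])
  out$depth <- rep(pu$depth, each = 3L)
  af <- out$count / out$depth
  out$excluded <- af > max_af
  out$rate <- ifelse(out$excluded, NA_real_, af)
  out
}

#' Median background error over error-containing positions
#'
#' Summarizes one sample/tier by the median of per-position total error rates
#' restricted to positions that have non-zero non-reference support (the
#' all-zero majority of positions is excluded from the median, as in the
#' per-position view of deep-panel error). If no position carries an error
#' the summary is flagged undefined (`NA`), not zero.
#'
#' @param pileup a `position_pileup` data.frame.
#' @param max_af allele-frequency cap (see [position_error_rates()]).
#' @return list: `median` (NA when undefined), `n_sites`, `n_error_sites`,
#'   `defined`.
#' @export
sample_error_summary <- function(pileup, max_af = 0.02) {
  if (!nrow(pileup)) stop_arg("empty pileup")
  rates <- position_error_rates(pileup, max_af = max_af)
  ok <- !rates$excluded
  per_site <- tapply(rates$count[ok], list(rates$pos[ok], rates$chrom[ok]), sum)
  per_depth <- tapply(rates$depth[ok], list(rates$pos[ok], rates$chrom[ok]),
                      function(d) d[1L])
  r <- as.vector(per_site / per_depth)
  r <- r[!is.na(r)]
  err <- r[r > 0]
  list(median = if (length(err)) stats::median(err) else NA_real_,
       n_sites = length(r), n_error_sites = length(err),
       defined = length(err) > 0L)
}

#' Aggregate (per-tier) error rates
#'
#' The tier-level background error rate: total non-reference bases (after the
#' allele-frequency cap) divided by total sequenced bases across all targeted
#' positions. `substitution_error_rates()` resolves the same aggregate by the
#' 12 substitution types.
#'
#' @inheritParams sample_error_summary
#' @return `tier_error_rate`: a single rate. `substitution_error_rates`: a
#'   data.frame with type, count, depth, rate.
#' @export
tier_error_rate <- function(pileup, max_af = 0.02) {
  rates <- position_error_rates(pileup, max_af = max_af)
  ok <- !rates$excluded
  tot_depth <- sum(pileup$depth[pileup$depth > 0L])
  if (tot_depth == 0L) return(NA_real_)
  sum(rates$count[ok]) / tot_depth
}

#' @rdname tier_error_rate
#' @export
substitution_error_rates <- function(pileup, max_af = 0.02) {
  rates <- position_error_rates(pileup, max_af = max_af)
  ok <- !rates$excluded
  cnt <- tapply(rates$count[ok], rates$type[ok], sum)
  dep <- tapply(rates$depth[ok], rates$type[ok], sum)
  types <- SUBSTITUTION_TYPES
  out <- data.frame(type = types,
                    count = as.integer(cnt[types]),
                    depth = as.numeric(dep[types]))
  out$count[is.na(out$count)] <- 0L
  out$depth[is.na(out$depth)] <- 0
  out$rate <- ifelse(out$depth > 0, out$count / out$depth, NA_real_)
  out
}

#' Nearest-rank percentile
#'
#' The q-th percentile of `x` as the order statistic of rank
#' `ceiling(q * n)` -- no interpolation, so a single outlier among many zeros
#' does not lift the summary until it reaches the rank.
#'
#' @param x numeric vector.
#' @param q percentile in (0, 1].
#' @return the nearest-rank percentile.
#' @export
percentile_nearest_rank <- function(x, q = 0.95) {
  if (!length(x)) stop_arg("empty vector")
  if (q <= 0 || q > 1) stop_arg("q must lie in (0, 1]")
  sort(x)[ceiling(q * length(x))]
}

#' Cohort-level per-site error summary
#'
#' Given per-sample per-position error tables (from
#' [position_error_rates()], all over the same site set), computes for every
#' site and substitution type the cohort percentile (95th by default,
#' nearest-rank), summarizes the site by the maximum across its substitution
#' types (a conservative site-level rate), and reports the fraction of sites
#' whose summarized rate is zero.
#'
#' @param per_sample_rates list of data.frames from [position_error_rates()].
#' @param q cohort percentile.
#' @return list: `site_rates` (chrom, pos, rate), `zero_fraction`.
#' @export
cohort_site_summary <- function(per_sample_rates, q = 0.95) {
  if (!length(per_sample_rates)) stop_arg("no samples")
  keys <- lapply(per_sample_rates, function(r) paste(r$chrom, r$pos, r$alt))
  ref_key <- keys[[1L]]
  for (i in seq_along(keys)) {
    if (!identical(sort(keys[[i]]), sort(ref_key))) {
      missing <- setdiff(ref_key, keys[[i]])
      extra <- setdiff(keys[[i]], ref_key)
      stop_arg("ragged site sets across samples; differing entries: ",
               paste(utils::head(c(missing, extra), 5L), collapse = ", "))
    }
  }
  ord <- order(ref_key)
  mat <- vapply(per_sample_rates, function(r) {
    r <- r[order(paste(r$chrom, r$pos, r$alt)), ]
    ifelse(r$excluded, NA_real_, r$rate)
  }, numeric(length(ref_key)))
  mat[is.na(mat)] <- 0        # capped alleles: no contribution to error
  per_allele <- apply(mat, 1L, percentile_nearest_rank, q = q)
  base <- per_sample_rates[[1L]][order(paste(per_sample_rates[[1L]]$chrom,
                                             per_sample_rates[[1L]]$pos,
                                             per_sample_rates[[1L]]$alt)), ]
  site_key <- paste(base$chrom, base$pos)
  site_rate <- tapply(per_allele, site_key, max)
  first <- !duplicated(site_key)
  sk <- site_key[first]
  out <- data.frame(chrom = base$chrom[first], pos = base$pos[first],
                    rate = as.numeric(site_rate[sk]))
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  list(site_rates = out, zero_fraction = mean(out$rate == 0))
}

#' Simulation study of per-tier error suppression
#'
#' Simulates a variant-free targeted panel region by region (so memory stays
#' bounded), collapses reads, and accumulates per-tier error and depth
#' totals plus per-site zero-error bookkeeping. Used to demonstrate the
#' ordering standard > simplex > duplex of background error and the
#' corresponding ordering of zero-error site fractions.
#'
#' @param n_regions number of independent 1-region panels simulated.
#' @param region_bp width of each region.
#' @param depth_templates unique templates per position.
#' @param seq_error_rate per-base substitution error.
#' @param seed integer seed.
#' @param config_args extra arguments passed to [sim_config()].
#' @param max_af allele-frequency cap in the error tally.
#' @return list with `rates` (named per-tier aggregate error rates),
#'   `errors`, `bases` (per-tier totals), `zero_fraction` (per-tier fraction
#'   of targeted sites without any non-reference observation), `n_sites`,
#'   `n_templates`.
#' @export
error_suppression_study <- function(n_regions = 40L, region_bp = 1000L,
                                    depth_templates = 1200L,
                                    seq_error_rate = 1e-3, seed = 1L,
                                    config_args = list(), max_af = 0.02) {
  tiers_tracked <- c("standard", "all_unique", "simplex", "duplex")
  errors <- stats::setNames(numeric(4L), tiers_tracked)
  bases <- stats::setNames(numeric(4L), tiers_tracked)
  zero_sites <- stats::setNames(numeric(4L), tiers_tracked)
  n_sites <- 0L
  n_templates <- 0L
  for (r in seq_len(n_regions)) {
    panel <- data.frame(chrom = "chr1", start = 1000L, end = 1000L + region_bp)
    cfg <- do.call(sim_config, c(list(panel = panel,
                                      depth_templates = depth_templates,
                                      seq_error_rate = seq_error_rate,
                                      seed = key_seed(seed, c("region", r))),
                                 config_args))
    sim <- simulate_reads(cfg, truth = NULL, sample = "plasma")
    cons <- collapse_reads(sim$pairs)
    tiers <- emit_tiers(cons)
    pus <- pileup_tiers(tiers, cfg$panel, sim$reference, pairs = sim$pairs)
    for (tname in tiers_tracked) {
      pu <- pus[[tname]]
      pr <- position_error_rates(pu, max_af = max_af)
      ok <- !pr$excluded
      errors[tname] <- errors[tname] + sum(pr$count[ok])
      bases[tname] <- bases[tname] + sum(pu$depth)
      err_per_site <- tapply(pr$count[ok], pr$pos[ok], sum)
      covered <- pu$pos[pu$depth > 0L]
      zero_sites[tname] <- zero_sites[tname] +
        sum(err_per_site[as.character(covered)] == 0, na.rm = TRUE) +
        sum(!as.character(covered) %in% names(err_per_site))
    }
    n_sites <- n_sites + sum(pus$standard$depth > 0L)
    n_templates <- n_templates + attr(sim$pairs, "n_templates")
  }
  list(rates = errors / bases, errors = errors, bases = bases,
       zero_fraction = zero_sites / n_sites,
       n_sites = n_sites, n_templates = n_templates)
}
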