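#' Deterministic synthetic reference for a simulation configuration
#'
#' Generates a random but seed-reproducible reference sequence for every
#' chromosome named in the panel, long enough to contain all panel regions
#' plus a margin for fragments extending past region edges.
#'
#' @param config a [sim_config()].
#' @param margin extra bases kept on each side of the outermost regions.
#' @return named character vector, one sequence per chromosome.
#' @export
sim_reference <- function(config, margin = 1000L) {
  chroms <- unique(config$panel$chrom)
  with_seed(key_seed(config$seed, "reference"), {
    out <- vapply(chroms, function(ch) {
      len <- max(config$panel$end[config$panel$chrom == ch]) + margin
      paste(sample(BASES, len, replace = TRUE), collapse = "")
    }, "")
    names(out) <- chroms
    out
  })
}

#' Draw cfDNA fragment lengths from the bimodal mixture
#'
#' Lengths are drawn from a two-component normal mixture with modes at the
#' configured mono- and di-nucleosomal peaks, rounded to integers and floored
#' at `config$min_fragment_bp`. Tumor-compartment draws are shortened by
#' `config$tumor_fraction_short_shift_bp`, emulating the shorter ctDNA
#' fragment profile.
#'
#' @param config a [sim_config()].
#' @param n number of lengths to draw (>= 1).
#' @param compartment `"normal"` or `"tumor"`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers inside a seeded block stay reproducible).
#' @return integer vector of `n` fragment lengths.
#' @examples
#' cfg <- sim_config(seed = 1)
#' summary(sample_fragment_lengths(cfg, 1000, seed = 1))
#' @export
sample_fragment_lengths <- function(config, n, compartment = c("normal", "tumor"),
                                    seed = NULL) {
  compartment <- match.arg(compartment)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_arg("n must be a positive count")
  n <- as.integer(n)
  draw <- function() {
    mono <- runif(n) < config$mono_weight
    mu <- ifelse(mono, config$mono_peak_bp, config$di_peak_bp)
    len <- round(rnorm(n, mean = mu, sd = config$length_sd_bp))
    if (compartment == "tumor")
      len <- len - config$tumor_fraction_short_shift_bp
    pmax(as.integer(len), config$min_fragment_bp)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate unique template molecules over the target panel
#'
#' Places template fragments (uniform start positions, mixture lengths) over
#' each panel region at the configured per-position depth, assigns a dual UMI
#' to each template, and lets every template covering a truth site carry the
#' alternate allele with probability equal to the compartment VAF
#' (`plasma_vaf` or `wbc_vaf` depending on `sample`). Plasma templates that
#' carry a somatic alternate allele are shortened by the configured tumor
#' fragment shift (the carried site remains covered).
#'
#' @param config a [sim_config()].
#' @param truth truth table from [sim_truth()] (may have zero rows).
#' @param sample `"plasma"` or `"wbc"` -- selects which truth VAF column and
#'   whether tumor shortening applies.
#' @param seed integer seed.
#' @return list of class `sim_templates` with elements `templates`
#'   (template_id, chrom, start, end, umi1, umi2, somatic_carrier), `alts`
#'   (template_id, chrom, pos, alt), plus the `config`, `sample` and `seed`.
#' @export
simulate_templates <- function(config, truth = NULL,
                               sample = c("plasma", "wbc"), seed = NULL) {
  sample <- match.arg(sample)
  seed <- seed %||% key_seed(config$seed, c("templates", sample))
  if (is.null(truth))
    truth <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), compartment = character(),
                        plasma_vaf = numeric(), wbc_vaf = numeric())
  ## every truth site must fall inside a panel region
  if (nrow(truth)) {
    inside <- vapply(seq_len(nrow(truth)), function(i) {
      any(config$panel$chrom == truth$chrom[i] &
            config$panel$start < truth$pos[i] &
            config$panel$end >= truth$pos[i])
    }, TRUE)
    if (any(!inside))
      stop_arg("truth site(s) outside panel: ",
               paste(truth$chrom[!inside], truth$pos[!inside],
                     sep = ":", collapse = ", "))
  }
  vaf_col <- if (sample == "plasma") "plasma_vaf" else "wbc_vaf"
  lbar <- config$mono_weight * config$mono_peak_bp +
    (1 - config$mono_weight) * config$di_peak_bp
  with_seed(seed, {
    tlist <- vector("list", nrow(config$panel))
    alist <- list()
    next_id <- 0L
    for (i in seq_len(nrow(config$panel))) {
      r <- config$panel[i, ]
      w <- r$end - r$start                       # targeted width
      n_tpl <- as.integer(round(config$depth_templates * (w + lbar - 1) / lbar))
      len <- sample_fragment_lengths(config, n_tpl, "normal")
      rs <- r$start + 1L                          # first 1-based position
      start <- rs - len + 1L +
        floor(runif(n_tpl) * (r$end - (rs - len + 1L) + 1L))
      start <- as.integer(start)
      end <- start + len - 1L
      tpl <- data.frame(template_id = next_id + seq_len(n_tpl),
                        chrom = r$chrom, start = start, end = end)
      ## allele assignment per covered truth site
      tr <- truth[truth$chrom == r$chrom &
                    truth$pos > r$start & truth$pos <= r$end, , drop = FALSE]
      som <- rep(FALSE, n_tpl)
      if (nrow(tr)) {
        for (j in seq_len(nrow(tr))) {
          cov <- which(tpl$start <= tr$pos[j] & tpl$end >= tr$pos[j])
          if (!length(cov)) next
          carry <- cov[runif(length(cov)) < tr[[vaf_col]][j]]
          if (!length(carry)) next
          alist[[length(alist) + 1L]] <-
            data.frame(template_id = tpl$template_id[carry],
                       chrom = r$chrom, pos = tr$pos[j], alt = tr$alt[j])
          if (tr$compartment[j] == "somatic_tumor" && sample == "plasma")
            som[carry] <- TRUE
        }
      }
      tpl$somatic_carrier <- som
      tlist[[i]] <- tpl
      next_id <- next_id + n_tpl
    }
    templates <- do.call(rbind, tlist)
    alts <- if (length(alist)) do.call(rbind, alist) else
      data.frame(template_id = integer(), chrom = character(),
                 pos = integer(), alt = character())
    ## shorten plasma templates that carry a somatic allele, keeping carried
    ## sites covered
    shift <- config$tumor_fraction_short_shift_bp
    if (sample == "plasma" && shift > 0 && any(templates$somatic_carrier)) {
      idx <- which(templates$somatic_carrier)
      for (k in idx) {
        len <- templates$end[k] - templates$start[k] + 1L
        new_len <- max(config$min_fragment_bp, len - shift)
        ns <- templates$start[k] + ((len - new_len) %/% 2L)
        sites <- alts$pos[alts$template_id == templates$template_id[k]]
        if (length(sites)) {
          ns <- min(ns, min(sites))
          ns <- max(ns, max(sites) - new_len + 1L)
        }
        templates$start[k] <- as.integer(ns)
        templates$end[k] <- as.integer(ns + new_len - 1L)
      }
    }
    ## dual UMIs from the fixed short alphabet pool
    n_all <- nrow(templates)
    rand_umi <- function(n) {
      m <- matrix(sample(BASES, n * config$umi_len, replace = TRUE), nrow = n)
      apply(m, 1L, paste, collapse = "")
    }
    templates$umi1 <- rand_umi(n_all)
    templates$umi2 <- rand_umi(n_all)
    structure(list(templates = templates, alts = alts, config = config,
                   sample = sample, seed = seed),
              class = "sim_templates")
  })
}

#' Fraction of templates covering a site that carry the alternate allele
#'
#' Bookkeeping helper used to check truth-VAF recovery of the generator.
#' @param sim a `sim_templates` object.
#' @param chrom,pos site coordinates (1-based).
#' @return list with `covered`, `alt` counts and `fraction`.
#' @export
alt_template_fraction <- function(sim, chrom, pos) {
  tpl <- sim$templates
  cov <- tpl$chrom == chrom & tpl$start <= pos & tpl$end >= pos
  alt <- sim$alts$template_id[sim$alts$chrom == chrom & sim$alts$pos == pos]
  n_alt <- sum(tpl$template_id[cov] %in% alt)
  list(covered = sum(cov), alt = n_alt,
       fraction = if (sum(cov)) n_alt / sum(cov) else NA_real_)
}

#' PCR-amplify and sequence simulated templates into aligned read pairs
#'
#' For each template the first strand is always sequenced with
#' `1 + Poisson(family_size_mean - 1)` read pairs; the opposite strand is
#' captured with probability `duplex_capture_prob` and, when captured, gets an
#' independent family-size draw. Each read pair consists of two
#' `read_len`-long mates anchored at the fragment ends (truncated for short
#' fragments). Every emitted base is substituted by a uniformly chosen other
#' base with probability `seq_error_rate`.
#'
#' @param sim a `sim_templates` object from [simulate_templates()].
#' @param seed integer seed.
#' @param reference optional reference from [sim_reference()] (rebuilt from
#'   the config when omitted).
#' @return data.frame of class `read_pairs`: one row per read pair with
#'   columns qname, chrom, start, end (fragment, 1-based inclusive), strand
#'   (originating template strand), umi1/umi2 (in as-read order: swapped on the
#'   minus strand), seq_left, seq_right. Attributes: `tier_truth` (expected
#'   consensus tier per template), `template_seq` (error-free template
#'   sequences), `umi_tag`, `n_templates`, `seed`.
#' @export
amplify_and_sequence <- function(sim, seed = NULL, reference = NULL) {
  config <- sim$config
  seed <- seed %||% key_seed(sim$seed, "amplify")
  reference <- reference %||% sim_reference(config)
  tpl <- sim$templates
  n_tpl <- nrow(tpl)
  ## error-free template sequences: reference substring + carried alts
  tseq <- unname(substring(reference[tpl$chrom], tpl$start, tpl$end))
  if (nrow(sim$alts)) {
    idx <- match(sim$alts$template_id, tpl$template_id)
    off <- sim$alts$pos - tpl$start[idx] + 1L
    keep <- off >= 1L & off <= (tpl$end[idx] - tpl$start[idx] + 1L)
    for (k in which(keep))
      substr(tseq[idx[k]], off[k], off[k]) <- sim$alts$alt[k]
  }
  with_seed(seed, {
    n1 <- 1L + rpois(n_tpl, config$family_size_mean - 1)
    second <- runif(n_tpl) < config$duplex_capture_prob
    n2 <- ifelse(second, 1L + rpois(n_tpl, config$family_size_mean - 1), 0L)
    first_strand <- ifelse(runif(n_tpl) < 0.5, "+", "-")
    tier <- ifelse(n2 >= 1L, "duplex",
            ifelse(n1 >= 3L, "simplex",
            ifelse(n1 == 2L, "sub_simplex", "singleton")))
    tpl_idx <- c(rep(seq_len(n_tpl), n1), rep(seq_len(n_tpl), n2))
    strand <- c(rep(first_strand, n1),
                rep(ifelse(first_strand == "+", "-", "+"), n2))
    dup <- c(sequence(n1), sequence(n2))
    half <- rep(c(1L, 2L), c(sum(n1), sum(n2)))
    flen <- tpl$end[tpl_idx] - tpl$start[tpl_idx] + 1L
    rl <- pmin(config$read_len, flen)
    seq_left <- inject_errors(substring(tseq[tpl_idx], 1L, rl),
                              config$seq_error_rate)
    seq_right <- inject_errors(substring(tseq[tpl_idx], flen - rl + 1L, flen),
                               config$seq_error_rate)
    pairs <- data.frame(
      qname = paste0("T", tpl$template_id[tpl_idx], ".", half, ".", dup),
      chrom = tpl$chrom[tpl_idx],
      start = tpl$start[tpl_idx],
      end = tpl$end[tpl_idx],
      strand = strand,
      umi1 = ifelse(strand == "+", tpl$umi1[tpl_idx], tpl$umi2[tpl_idx]),
      umi2 = ifelse(strand == "+", tpl$umi2[tpl_idx], tpl$umi1[tpl_idx]),
      seq_left = seq_left,
      seq_right = seq_right,
      stringsAsFactors = FALSE)
    ord <- order(pairs$chrom, pairs$start, pairs$end, pairs$qname)
    pairs <- pairs[ord, , drop = FALSE]
    rownames(pairs) <- NULL
    structure(pairs,
              class = c("read_pairs", "data.frame"),
              tier_truth = tier,
              template_seq = tseq,
              template_id = tpl$template_id,
              umi_tag = config$umi_tag,
              n_templates = n_tpl,
              seed = seed)
  })
}

## Substitute each base with probability `rate` (uniform over the other 3).
## Operates on the current RNG stream.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  nc <- nchar(seqs)
  k <- rbinom(length(seqs), nc, rate)
  hit <- which(k > 0L)
  for (i in hit) {
    pos <- sample.int(nc[i], k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(other_bases(cur), 1L)
    }
  }
  seqs
}

#' One-call simulation of an aligned, UMI-tagged read set
#'
#' Convenience wrapper: [simulate_templates()] followed by
#' [amplify_and_sequence()].
#'
#' @inheritParams simulate_templates
#' @return list with elements `pairs` (the `read_pairs` data.frame),
#'   `templates`, `alts`, `reference`, `config`, `sample`.
#' @export
simulate_reads <- function(config, truth = NULL,
                           sample = c("plasma", "wbc"), seed = NULL) {
  sample <- match.arg(sample)
  seed <- seed %||% key_seed(config$seed, c("reads", sample))
  reference <- sim_reference(config)
  sim <- simulate_templates(config, truth, sample, seed = seed)
  pairs <- amplify_and_sequence(sim, seed = key_seed(seed, "amplify"),
                                reference = reference)
  list(pairs = pairs, templates = sim$templates, alts = sim$alts,
       reference = reference, config = config, sample = sample)
}
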