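## End-to-end driver: simulate a scene to files, run the full analysis
## (collapse -> pileup -> call -> matched-normal classification ->
## fragment-size adjudication -> QC) from files, persist every intermediate.

#' Write a complete synthetic plasma/WBC scene to a directory
#'
#' Simulates a plasma and a matched WBC read set for one donor under a shared
#' truth table and persists every pipeline input as plain text: SAM reads,
#' FASTA reference, BED targets, and tab-delimited truth/hotspot/population
#' AF/panel-of-normals/fingerprint/prior-knowledge tables.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param truth truth table from [sim_truth()]; generated with defaults when
#'   omitted.
#' @return a [pipeline_config()] pointing at the written files.
#' @export
simulate_scene <- function(config, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- truth %||% sim_truth(config)
  p <- function(f) file.path(dir, f)
  plasma <- simulate_reads(config, truth, "plasma")
  wbc <- simulate_reads(config, truth, "wbc")
  write_fasta(plasma$reference, p("reference.fa"))
  write_bed(config$panel, p("targets.bed"))
  write_sam(plasma$pairs, p("plasma.sam"), plasma$reference, config$umi_tag)
  write_sam(wbc$pairs, p("wbc.sam"), wbc$reference, config$umi_tag)
  write_truth_table(truth, p("truth.tsv"))
  vcols <- c("chrom", "pos", "ref", "alt")
  hot <- truth[truth$hotspot, vcols, drop = FALSE]
  write_truth_table(hot, p("hotspots.tsv"))
  pop <- truth[truth$pop_af > 0, c(vcols, "pop_af"), drop = FALSE]
  names(pop)[5L] <- "af"
  write_truth_table(pop, p("popaf.tsv"))
  write_truth_table(truth[0, vcols, drop = FALSE], p("pon.tsv"))
  fp <- truth[truth$compartment == "fingerprint", , drop = FALSE]
  write_bed(data.frame(chrom = fp$chrom, start = fp$pos - 1L, end = fp$pos),
            p("fingerprint.bed"))
  known <- truth[truth$compartment != "fingerprint",
                 c(vcols, "hotspot"), drop = FALSE]
  write_truth_table(known, p("known.tsv"))
  pipeline_config(plasma = p("plasma.sam"), wbc = p("wbc.sam"),
                  reference = p("reference.fa"), targets = p("targets.bed"),
                  hotspots = p("hotspots.tsv"), popaf = p("popaf.tsv"),
                  pon = p("pon.tsv"), fingerprint_snps = p("fingerprint.bed"),
                  known = p("known.tsv"), truth = p("truth.tsv"),
                  out_dir = p("out"), umi_tag = config$umi_tag,
                  seed = config$seed)
}

#' Pipeline configuration
#'
#' Paths to all pipeline inputs plus the calling/filtering thresholds. All
#' provided paths must exist at construction time; optional resources may be
#' `NULL`. All randomness downstream (the fragment-size bootstrap) flows from
#' `seed`.
#'
#' @param plasma,reference,targets required input files (SAM/FASTA/BED).
#' @param wbc,hotspots,popaf,pon,fingerprint_snps,known,truth optional inputs.
#' @param out_dir directory for persisted intermediates (`NULL` to skip).
#' @param umi_tag SAM tag carrying the UMI.
#' @param trim consensus end-trim (bases per end).
#' @param min_simplex_reads single-strand reads for the simplex tier.
#' @param min_genotype_duplex,min_genotype_simplex genotyping thresholds.
#' @param min_hotspot_duplex,min_de_novo_duplex de novo thresholds.
#' @param min_wbc_fragments WBC fragments establishing "presence in WBC".
#' @param af_threshold population-AF removal threshold.
#' @param fragsize_min_vaf VAF floor of the fragment-size test.
#' @param fragsize_B bootstrap replicates per variant.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(plasma, reference, targets, wbc = NULL,
                            hotspots = NULL, popaf = NULL, pon = NULL,
                            fingerprint_snps = NULL, known = NULL,
                            truth = NULL, out_dir = NULL, umi_tag = "RX",
                            trim = 3L, min_simplex_reads = 3L,
                            min_genotype_duplex = 1L, min_genotype_simplex = 2L,
                            min_hotspot_duplex = 3L, min_de_novo_duplex = 5L,
                            min_wbc_fragments = 2L, af_threshold = 0.005,
                            fragsize_min_vaf = 5e-4, fragsize_B = 10000L,
                            seed = 1L) {
  if (missing(plasma) || missing(reference) || missing(targets))
    stop_arg("plasma, reference and targets are required")
  cfg <- as.list(environment())
  paths <- c("plasma", "reference", "targets", "wbc", "hotspots", "popaf",
             "pon", "fingerprint_snps", "known", "truth")
  for (nm in paths) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop_arg("input file for '", nm, "' does not exist: ", cfg[[nm]])
  }
  stopifnot(cfg$trim >= 0, cfg$min_simplex_reads >= 1,
            cfg$af_threshold > 0, cfg$af_threshold < 1,
            cfg$fragsize_B >= 100)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from flat key=value text
#'
#' Lines of the form `key = value` (one per line, `#` comments allowed),
#' with keys matching the arguments of [pipeline_config()]. Arguments given
#' directly through `...` override the file -- the file format mirrors the
#' CLI flags, and every flag stays overridable.
#'
#' @param path configuration file.
#' @param ... overrides passed straight to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  numeric_keys <- c("trim", "min_simplex_reads", "min_genotype_duplex",
                    "min_genotype_simplex", "min_hotspot_duplex",
                    "min_de_novo_duplex", "min_wbc_fragments", "af_threshold",
                    "fragsize_min_vaf", "fragsize_B", "seed")
  for (k in intersect(names(args), numeric_keys))
    args[[k]] <- as.numeric(args[[k]])
  bad <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(bad))
    stop_arg(path, ": unknown configuration key(s): ", paste(bad, collapse = ", "))
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes collapse -> pileup -> calling (genotyping of known sites plus de
#' novo calling) -> matched-WBC compartment classification (boxes I-IV) ->
#' population-database annotation -> fragment-size adjudication ->
#' fingerprint and coverage QC, persisting every intermediate to
#' `config$out_dir` when set. Deterministic under a fixed config seed.
#'
#' An empty plasma input aborts cleanly: the returned object has status
#' `"aborted_empty_input"` and a coverage-zero QC block.
#'
#' @param config a [pipeline_config()].
#' @return object of class `cfduplex_run`: `calls` (annotated call table),
#'   `fragsize` (per-variant size test table), `fingerprint`, `qc`,
#'   `unmatched` (unmatched-mode report when truth is available), `status`,
#'   `log`.
#' @export
run_pipeline <- function(config) {
  log <- new_log()
  targets <- run_stage("load_targets", read_bed(config$targets))
  reference <- run_stage("load_reference", read_fasta(config$reference))
  plasma_pairs <- run_stage("load_plasma", read_sam(config$plasma, config$umi_tag))
  log_count(log, "plasma_read_pairs_in", nrow(plasma_pairs))
  if (!nrow(plasma_pairs)) {
    qc <- list(plasma_mean_coverage = c(standard = 0, all_unique = 0,
                                        simplex = 0, duplex = 0),
               coverage_ordering_ok = TRUE,
               fraction_fragments_le_500 = NA_real_,
               fingerprint = list(verdict = "indeterminate"))
    return(structure(list(calls = empty_calls(), fragsize = NULL,
                          fingerprint = qc$fingerprint, qc = qc,
                          unmatched = NULL,
                          status = "aborted_empty_input",
                          log = log_as_list(log)),
                     class = "cfduplex_run"))
  }
  hotspots <- if (!is.null(config$hotspots)) read_hotspots(config$hotspots)
  popaf <- if (!is.null(config$popaf)) read_popaf(config$popaf)
  pon <- if (!is.null(config$pon)) read_pon(config$pon)
  known <- if (!is.null(config$known)) read_truth_table(config$known)
  truth <- if (!is.null(config$truth)) read_truth_table(config$truth)

  ## collapse
  plasma_cons <- run_stage("collapse_plasma",
                           collapse_reads(plasma_pairs, trim = config$trim,
                                          min_simplex_reads = config$min_simplex_reads))
  plasma_tiers <- emit_tiers(plasma_cons)
  log_count(log, "plasma_consensus_reads", nrow(plasma_cons))
  wbc_pairs <- NULL; wbc_tiers <- NULL
  if (!is.null(config$wbc)) {
    wbc_pairs <- run_stage("load_wbc", read_sam(config$wbc, config$umi_tag))
    wbc_cons <- run_stage("collapse_wbc",
                          collapse_reads(wbc_pairs, trim = config$trim,
                                         min_simplex_reads = config$min_simplex_reads))
    wbc_tiers <- emit_tiers(wbc_cons)
    log_count(log, "wbc_read_pairs_in", nrow(wbc_pairs))
  }

  ## pileups
  ppu <- run_stage("pileup_plasma",
                   pileup_tiers(plasma_tiers, targets, reference, plasma_pairs))
  wpu <- if (!is.null(wbc_tiers))
    run_stage("pileup_wbc", pileup_tiers(wbc_tiers, targets, reference, wbc_pairs))

  ## calling
  calls <- run_stage("call", {
    dn <- call_de_novo(ppu$duplex, ppu$simplex, hotspots,
                       min_hotspot = config$min_hotspot_duplex,
                       min_non_hotspot = config$min_de_novo_duplex)
    out <- dn
    if (!is.null(known) && nrow(known)) {
      gt <- genotype_variants(ppu$duplex, ppu$simplex, known,
                              min_duplex = config$min_genotype_duplex,
                              min_simplex = config$min_genotype_simplex)
      gt <- gt[gt$detected, names(gt) != "detected", drop = FALSE]
      new <- !variant_key(gt$chrom, gt$pos, gt$ref, gt$alt) %in%
        variant_key(dn$chrom, dn$pos, dn$ref, dn$alt)
      out <- rbind(dn, gt[new, , drop = FALSE])
    }
    out <- out[!is.na(out$VAF), , drop = FALSE]
    out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  })
  log_count(log, "calls", nrow(calls))

  ## matched-WBC annotation and compartments
  calls <- run_stage("normal_filter", {
    if (!is.null(wpu) && nrow(calls)) {
      wd <- t(vapply(seq_len(nrow(calls)), function(i) {
        d <- site_counts(wpu$duplex, calls$chrom[i], calls$pos[i], calls$alt[i])
        s <- site_counts(wpu$simplex, calls$chrom[i], calls$pos[i], calls$alt[i])
        d[is.na(d)] <- 0L; s[is.na(s)] <- 0L
        c(alt = d[["alt"]] + s[["alt"]], depth = d[["depth"]] + s[["depth"]])
      }, c(alt = 0, depth = 0)))
      calls$wbc_alt <- as.integer(wd[, "alt"])
      calls$wbc_dp <- as.integer(wd[, "depth"])
      calls$wbc_vaf <- ifelse(calls$wbc_dp > 0, calls$wbc_alt / calls$wbc_dp, 0)
      calls$wbc_supported <- calls$wbc_alt >= config$min_wbc_fragments
    } else if (nrow(calls)) {
      calls$wbc_alt <- 0L; calls$wbc_dp <- 0L
      calls$wbc_vaf <- 0; calls$wbc_supported <- FALSE
    }
    if (nrow(calls))
      calls$box <- classify_compartment(calls$VAF, calls$wbc_vaf,
                                        calls$wbc_supported)
    calls
  })

  ## population-database annotation
  calls <- run_stage("population_filter", {
    if (nrow(calls)) {
      pf <- population_filter(calls, pon, popaf, config$af_threshold)
      key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
      rkey <- variant_key(pf$removed$chrom, pf$removed$pos, pf$removed$ref,
                          pf$removed$alt)
      m <- match(key, rkey)
      calls$population_filter <- ifelse(is.na(m), "retained",
                                        pf$removed$reason[m])
    }
    calls
  })

  ## unmatched-mode report (synthetic runs with truth)
  unmatched <- if (!is.null(truth) && nrow(calls))
    run_stage("unmatched_mode",
              unmatched_mode_filter(calls, pon, popaf, config$af_threshold,
                                    truth = truth))

  ## fragment-size adjudication
  fragsize <- run_stage("fragsize", {
    if (!nrow(calls)) NULL else {
      rows <- lapply(seq_len(nrow(calls)), function(i) {
        v <- calls[i, ]
        as_ <- allele_fragment_sizes(plasma_tiers$all_unique, v,
                                     min_vaf = config$fragsize_min_vaf)
        if (as_$status != "ok" || !length(as_$alt_sizes) ||
            !length(as_$ref_sizes)) {
          return(data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                            alt = v$alt, mu_ref = NA_real_, mu_alt = NA_real_,
                            delta = NA_real_, p_value = NA_real_,
                            status = if (as_$status != "ok") as_$status else
                              "insufficient_fragments"))
        }
        ft <- bootstrap_mean_test(as_$ref_sizes, as_$alt_sizes,
                                  B = config$fragsize_B, seed = config$seed,
                                  variant_id = variant_key(v$chrom, v$pos,
                                                           v$ref, v$alt))
        data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                   mu_ref = ft$mu_ref, mu_alt = ft$mu_alt, delta = ft$delta,
                   p_value = ft$p_value, status = "ok")
      })
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    }
  })

  ## fingerprint identity check
  fingerprint <- run_stage("fingerprint", {
    if (is.null(config$fingerprint_snps) || is.null(wpu))
      list(concordance = NA_real_, n_informative = 0L,
           verdict = "indeterminate")
    else {
      fpsites <- read_bed(config$fingerprint_snps)
      gvaf <- function(pu) {
        vapply(seq_len(nrow(fpsites)), function(i) {
          j <- which(pu$chrom == fpsites$chrom[i] & pu$pos == fpsites$end[i])
          if (!length(j) || pu$depth[j[1L]] == 0L) return(NA_real_)
          1 - pu[[pu$ref[j[1L]]]][j[1L]] / pu$depth[j[1L]]
        }, 0)
      }
      gdp <- function(pu) {
        vapply(seq_len(nrow(fpsites)), function(i) {
          j <- which(pu$chrom == fpsites$chrom[i] & pu$pos == fpsites$end[i])
          if (!length(j)) 0L else as.integer(pu$depth[j[1L]])
        }, 0L)
      }
      fingerprint_concordance(gvaf(ppu$all_unique), gvaf(wpu$all_unique),
                              gdp(ppu$all_unique), gdp(wpu$all_unique))
    }
  })

  ## QC
  qc <- run_stage("qc", {
    meancov <- function(pus) vapply(pus, function(p) mean(p$depth), 0)
    ordering <- all(ppu$duplex$depth <= ppu$all_unique$depth) &&
      all(ppu$all_unique$depth <= ppu$standard$depth)
    fam <- plasma_cons$n_plus + plasma_cons$n_minus
    sizes <- fragment_sizes(plasma_tiers$all_unique, targets, max_size = .Machine$integer.max)
    list(plasma_mean_coverage = meancov(ppu),
         wbc_mean_coverage = if (!is.null(wpu)) meancov(wpu),
         coverage_ordering_ok = ordering,
         family_size_hist = table(fam),
         fraction_fragments_le_500 = mean(sizes <= 500),
         tier_counts = table(plasma_cons$tier),
         fingerprint = fingerprint)
  })

  run <- structure(list(calls = calls, fragsize = fragsize,
                        fingerprint = fingerprint, qc = qc,
                        unmatched = unmatched, status = "ok",
                        log = log_as_list(log)),
                   class = "cfduplex_run")

  ## persist intermediates
  if (!is.null(config$out_dir)) run_stage("persist", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$out_dir, f)
    write_tsv(calls, o("calls.tsv"))
    write_vcf(calls, o("calls.vcf"), sample = "PLASMA")
    if (!is.null(fragsize)) write_tsv(fragsize, o("fragsize.tsv"))
    sz <- fragment_sizes(plasma_tiers$all_unique, targets)
    szt <- as.data.frame(table(size = sz), stringsAsFactors = FALSE)
    names(szt) <- c("size", "count")
    write_tsv(szt, o("fragment_size_hist.tsv"))
    for (t in c("duplex", "simplex", "all_unique"))
      write_consensus_sam(plasma_tiers[[t]], o(paste0("plasma_", t, ".sam")),
                          reference)
    qct <- data.frame(key = c(paste0("plasma_mean_coverage.",
                                     names(qc$plasma_mean_coverage)),
                              "coverage_ordering_ok",
                              "fraction_fragments_le_500",
                              "fingerprint_concordance",
                              "fingerprint_verdict"),
                      value = c(sprintf("%.4f", qc$plasma_mean_coverage),
                                as.character(qc$coverage_ordering_ok),
                                sprintf("%.6f", qc$fraction_fragments_le_500),
                                sprintf("%.6f", fingerprint$concordance),
                                fingerprint$verdict))
    write_tsv(qct, o("qc.tsv"))
  })
  run
}

#' @export
print.cfduplex_run <- function(x, ...) {
  cat("cfduplex pipeline run --", x$status, "\n")
  if (x$status != "ok") return(invisible(x))
  cat(sprintf("  %d call(s); plasma coverage (mean): %s\n", nrow(x$calls),
              paste(sprintf("%s %.0fx", names(x$qc$plasma_mean_coverage),
                            x$qc$plasma_mean_coverage), collapse = ", ")))
  if (nrow(x$calls)) print(table(box = x$calls$box))
  cat(sprintf("  fingerprint: %s (concordance %.3f over %d sites)\n",
              x$fingerprint$verdict, x$fingerprint$concordance,
              x$fingerprint$n_informative))
  invisible(x)
}
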