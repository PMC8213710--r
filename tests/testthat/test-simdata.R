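test_that("fragment-length mixture reproduces the configured bimodal peaks", {
  cfg <- sim_config(mono_weight = 0.85, length_sd_bp = 15, seed = 1)
  len <- sample_fragment_lengths(cfg, 1e5, "normal", seed = 1)
  mode_in <- function(x, lo, hi, bw = 2) {
    d <- stats::density(x[x >= lo & x <= hi], bw = bw)
    d$x[which.max(d$y)]
  }
  expect_lt(abs(mode_in(len, 100, 250) - 167), 2)
  expect_lt(abs(mode_in(len, 250, 450) - 323), 4)
  ## mixture weight recovered
  expect_equal(mean(len < 245), 0.85, tolerance = 0.01)
})

test_that("tumor-compartment fragments are shorter by the configured shift", {
  cfg <- sim_config(tumor_fraction_short_shift_bp = 10L, seed = 2)
  nrm <- sample_fragment_lengths(cfg, 1e5, "normal", seed = 10)
  tum <- sample_fragment_lengths(cfg, 1e5, "tumor", seed = 11)
  ## difference of means vs configured shift, within Monte-Carlo error
  se <- sqrt(var(nrm) / 1e5 + var(tum) / 1e5)
  expect_lt(abs((mean(tum) - mean(nrm)) + 10), 4 * se + 0.1)
})

test_that("degenerate mixture and argument validation behave", {
  cfg <- sim_config(mono_weight = 1, length_sd_bp = 0, seed = 3)
  expect_true(all(sample_fragment_lengths(cfg, 50, seed = 1) == 167L))
  expect_error(sample_fragment_lengths(cfg, 0), "positive")
  expect_error(sample_fragment_lengths(cfg, -3), "positive")
})

test_that("alt-template fraction converges to the truth VAF", {
  cfg <- sim_config(panel = data.frame(chrom = "chr1", start = 1000L, end = 1200L),
                    depth_templates = 10000L, seed = 4)
  ref <- sim_reference(cfg)
  pos <- 1100L
  refb <- substr(ref["chr1"], pos, pos)
  truth <- data.frame(chrom = "chr1", pos = pos, ref = refb,
                      alt = setdiff(c("A", "C", "G", "T"), refb)[1],
                      compartment = "germline", plasma_vaf = 0.5, wbc_vaf = 0.5)
  sim <- simulate_templates(cfg, truth, "plasma", seed = 4)
  fr <- alt_template_fraction(sim, "chr1", pos)
  expect_gt(fr$covered, 9000)
  expect_gt(fr$fraction, 0.48)
  expect_lt(fr$fraction, 0.52)

  ## zero VAF everywhere -> zero alt templates
  truth$plasma_vaf <- 0
  sim0 <- simulate_templates(cfg, truth, "plasma", seed = 5)
  expect_identical(nrow(sim0$alts), 0L)

  ## low-VAF somatic: alt count within the exact binomial 99% interval
  cfg2 <- sim_config(panel = cfg$panel, depth_templates = 2000L, seed = 6)
  truth$plasma_vaf <- 0.005
  truth$compartment <- "somatic_tumor"
  sim2 <- simulate_templates(cfg2, truth, "plasma", seed = 6)
  fr2 <- alt_template_fraction(sim2, "chr1", pos)
  ci <- stats::qbinom(c(0.005, 0.995), fr2$covered, 0.005)
  expect_gte(fr2$alt, ci[1])
  expect_lte(fr2$alt, ci[2])
})

test_that("truth sites outside the panel are rejected by name", {
  cfg <- tiny_config()
  truth <- data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "C",
                      compartment = "germline", plasma_vaf = 0.5, wbc_vaf = 0.5)
  expect_error(simulate_templates(cfg, truth, "plasma"), "chr1:5")
})

test_that("error-free sequencing reproduces template bases exactly", {
  cfg <- tiny_config(seq_error_rate = 0)
  sim <- simulate_reads(cfg, NULL, "plasma")
  pairs <- sim$pairs
  tid <- as.integer(sub("^T(\\d+)\\..*$", "\\1", pairs$qname))
  tseq <- attr(pairs, "template_seq")[match(tid, attr(pairs, "template_id"))]
  flen <- pairs$end - pairs$start + 1L
  expect_identical(pairs$seq_left,
                   substring(tseq, 1L, nchar(pairs$seq_left)))
  expect_identical(pairs$seq_right,
                   substring(tseq, flen - nchar(pairs$seq_right) + 1L, flen))
})

test_that("observed mismatch fraction matches the configured error rate", {
  cfg <- sim_config(panel = data.frame(chrom = "chr1", start = 1000L, end = 1500L),
                    depth_templates = 200L, seq_error_rate = 1e-3, seed = 7)
  sim <- simulate_reads(cfg, NULL, "plasma")
  pairs <- sim$pairs
  tid <- as.integer(sub("^T(\\d+)\\..*$", "\\1", pairs$qname))
  tseq <- attr(pairs, "template_seq")[match(tid, attr(pairs, "template_id"))]
  flen <- pairs$end - pairs$start + 1L
  truth_left <- substring(tseq, 1L, nchar(pairs$seq_left))
  truth_right <- substring(tseq, flen - nchar(pairs$seq_right) + 1L, flen)
  mism <- function(a, b) {
    sum(vapply(seq_along(a), function(i)
      sum(charToRaw(a[i]) != charToRaw(b[i])), 0L))
  }
  n_bases <- sum(nchar(pairs$seq_left)) + sum(nchar(pairs$seq_right))
  n_err <- mism(pairs$seq_left, truth_left) + mism(pairs$seq_right, truth_right)
  expect_gt(n_bases, 5e5)
  sigma <- sqrt(n_bases * 1e-3)
  expect_lt(abs(n_err - n_bases * 1e-3), 3 * sigma)
})

test_that("identical seed and config give byte-identical read sets", {
  cfg <- tiny_config()
  a <- simulate_reads(cfg, NULL, "plasma")
  b <- simulate_reads(cfg, NULL, "plasma")
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$templates, b$templates)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(a$pairs, f1, a$reference)
  write_sam(b$pairs, f2, b$reference)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("forced duplex construction yields only duplex families", {
  cfg <- tiny_config(duplex_capture_prob = 1, family_size_mean = 3)
  sim <- simulate_reads(cfg, NULL, "plasma")
  expect_true(all(attr(sim$pairs, "tier_truth") == "duplex"))
  cons <- collapse_reads(sim$pairs)
  expect_true(all(cons$tier == "duplex"))
})
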