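test_that("fragment sizes are counted once and capped at 500 bp", {
  cons <- data.frame(family = 1:3, chrom = "chr1",
                     start = c(1000L, 1000L, 1000L),
                     end = c(1160L, 1599L, 1316L),
                     tier = "duplex", n_plus = 1L, n_minus = 1L, seq = "A")
  class(cons) <- c("consensus_reads", "data.frame")
  expect_setequal(fragment_sizes(cons), c(161L, 317L))   # 600-bp fragment excluded
  expect_identical(fragment_sizes(cons[1, ]), 161L)
  ## target restriction
  tg <- data.frame(chrom = "chr1", start = 2000L, end = 2100L)
  expect_identical(length(fragment_sizes(cons, tg)), 0L)
})

test_that("allele-specific sizes partition fragments by their consensus base", {
  cfg <- sim_config(panel = data.frame(chrom = "chr1", start = 1000L, end = 1200L),
                    depth_templates = 400L, seq_error_rate = 0, seed = 51L)
  ref <- sim_reference(cfg)
  pos <- 1100L
  refb <- substr(ref["chr1"], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  truth <- data.frame(chrom = "chr1", pos = pos, ref = refb, alt = alt,
                      compartment = "somatic_tumor", plasma_vaf = 0.05,
                      wbc_vaf = 0)
  sim <- simulate_reads(cfg, truth, "plasma")
  cons <- emit_tiers(collapse_reads(sim$pairs))$all_unique
  as_ <- allele_fragment_sizes(cons, truth)
  ## with error-free reads every injected alt template whose reads cover the
  ## site is recovered as exactly one alt fragment; expectation computed from
  ## the generator's own template/allele bookkeeping (reads are 100 bp and
  ## trimming removes 3 bp per fragment end)
  tpl <- sim$templates[sim$templates$template_id %in% sim$alts$template_id, ]
  read_covered <- function(tpl, p) {
    ## reads span the untrimmed fragment ends (100 bp each); trimming then
    ## removes 3 bp from each fragment end
    (p >= tpl$start + 3L & p <= tpl$start + 99L) |
      (p >= tpl$end - 99L & p <= tpl$end - 3L)
  }
  expect_identical(length(as_$alt_sizes), sum(read_covered(tpl, pos)))
  expect_gt(length(as_$alt_sizes), 0L)
  expect_identical(as_$status, "ok")

  ## wild-type-only locus: empty alt list, ref list equals read-level coverage
  wt_pos <- 1150L
  wt <- list(chrom = "chr1", pos = wt_pos,
             ref = substr(ref["chr1"], wt_pos, wt_pos),
             alt = setdiff(c("A", "C", "G", "T"),
                           substr(ref["chr1"], wt_pos, wt_pos))[1])
  as_wt <- allele_fragment_sizes(cons, wt, min_vaf = 0)
  expect_identical(length(as_wt$alt_sizes), 0L)
  expect_identical(length(as_wt$ref_sizes),
                   sum(read_covered(sim$templates, wt_pos) &
                         (sim$templates$end - sim$templates$start + 1L - 6L) <= 500L))
})

test_that("variants below the 0.05% VAF floor are refused, not emptied", {
  cons <- data.frame(family = 1:1000, chrom = "chr1", start = 1000L,
                     end = 1160L, tier = "duplex", n_plus = 1L, n_minus = 1L,
                     seq = strrep("C", 161), stringsAsFactors = FALSE)
  class(cons) <- c("consensus_reads", "data.frame")
  v <- list(chrom = "chr1", pos = 1080L, ref = "C", alt = "T")
  out <- allele_fragment_sizes(cons, v, min_vaf = 5e-4)
  expect_identical(out$status, "excluded_low_vaf")
  expect_match(out$reason, "below floor")
})

test_that("the bootstrap p-value is near 0.5 for identical groups", {
  x <- sample_fragment_lengths(sim_config(seed = 1), 500, seed = 61)
  ft <- bootstrap_mean_test(x, x, B = 4000, seed = 2)
  expect_equal(ft$delta, 0)
  ## within 3 sigma of Binomial(B, 0.5)/B
  expect_lt(abs(ft$p_value - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("a 15-bp shortening of 200 alt fragments is highly significant", {
  cfg <- sim_config(tumor_fraction_short_shift_bp = 15L, seed = 3)
  refs <- sample_fragment_lengths(cfg, 2000, "normal", seed = 62)
  alts <- sample_fragment_lengths(cfg, 200, "tumor", seed = 63)
  ft <- bootstrap_mean_test(refs, alts, B = 10000, seed = 4)
  expect_gt(ft$delta, 5)
  expect_lt(ft$p_value, 0.001)
  ## the permutation null agrees
  ftp <- bootstrap_mean_test(refs, alts, B = 2000, seed = 4,
                             null = "label_permutation")
  expect_lt(ftp$p_value, 0.001)
})

test_that("two-sided p is invariant to label swap with sign flip", {
  set.seed(64)
  a <- round(rnorm(80, 180, 25)); b <- round(rnorm(50, 172, 25))
  f1 <- bootstrap_mean_test(a, b, B = 3000, seed = 5, alternative = "two.sided")
  f2 <- bootstrap_mean_test(b, a, B = 3000, seed = 5, alternative = "two.sided")
  expect_equal(f1$delta, -f2$delta)
  expect_equal(f1$p_value, f2$p_value, tolerance = 0.05)
})

test_that("under the null the p-value distribution is approximately uniform", {
  set.seed(65)
  base <- sample_fragment_lengths(sim_config(seed = 1), 5000, seed = 66)
  ps <- vapply(1:400, function(i) {
    g <- sample(base, 90)
    bootstrap_mean_test(g[1:60], g[61:90], B = 200, seed = i)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("degenerate inputs are rejected or warned about", {
  expect_error(bootstrap_mean_test(integer(), 1:5), "non-empty")
  expect_warning(bootstrap_mean_test(1:50, 1:50, B = 50, seed = 1), "coarse")
})
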