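test_that("genotyping detection flips at 1 duplex / 2 simplex fragments", {
  site <- list(chrom = "chr1", pos = 1500L, ref = "A", alt = "G")
  gt <- function(d_alt, s_alt) {
    genotype_site(make_pileup(counts = c(A = 1000L - d_alt, G = d_alt)),
                  make_pileup(counts = c(A = 500L - s_alt, G = s_alt)),
                  site)$detected
  }
  expect_true(gt(1L, 0L))      # at least 1 duplex
  expect_false(gt(0L, 1L))     # 1 simplex is not enough
  expect_true(gt(0L, 2L))      # or 2 simplex
  expect_false(gt(0L, 0L))
  expect_error(genotype_site(make_pileup(counts = c(A = 10L)),
                             make_pileup(counts = c(A = 10L)),
                             list(chrom = "chr2", pos = 9L, ref = "A", alt = "G")),
               "outside targets")
})

test_that("de novo calling flips at 3 (hotspot) and 5 (non-hotspot) duplex reads", {
  hot <- data.frame(chrom = "chr1", pos = 1500L, ref = "A", alt = "G")
  dn <- function(d_alt, hotspots) {
    nrow(call_de_novo(make_pileup(counts = c(A = 1000L - d_alt, G = d_alt)),
                      make_pileup(counts = c(A = 500L)), hotspots))
  }
  expect_identical(dn(2L, hot), 0L)
  expect_identical(dn(3L, hot), 1L)
  expect_identical(dn(4L, NULL), 0L)
  expect_identical(dn(5L, NULL), 1L)
  ## hotspot flag carried on the call
  call <- call_de_novo(make_pileup(counts = c(A = 997L, G = 3L)),
                       make_pileup(counts = c(A = 500L)), hot)
  expect_true(call$hotspot)
  expect_identical(call$mode, "de_novo")
})

test_that("SV support rule flips at 3 de novo / 1 previously identified", {
  expect_false(sv_support_rule(2, FALSE))
  expect_true(sv_support_rule(3, FALSE))
  expect_true(sv_support_rule(1, TRUE))
  expect_false(sv_support_rule(0, TRUE))
  expect_error(sv_support_rule(-1, FALSE))
})

test_that("AD/DP/VAF combine duplex and simplex counts", {
  cc <- combine_allele_counts(c(alt = 2, depth = 1000), c(alt = 1, depth = 500))
  expect_identical(cc$AD, 3L)
  expect_identical(cc$DP, 1500L)
  expect_equal(cc$VAF, 0.002)
  ## empty simplex: VAF equals the duplex VAF
  cc2 <- combine_allele_counts(c(alt = 5, depth = 1000), c(alt = 0, depth = 0))
  expect_equal(cc2$VAF, 0.005)
  ## zero total depth: VAF undefined
  expect_true(is.na(combine_allele_counts(c(alt = 0, depth = 0),
                                          c(alt = 0, depth = 0))$VAF))
})

test_that("genotyped detection nests de novo detection", {
  ## any duplex alt count that satisfies de novo also satisfies genotyping
  for (d_alt in c(3L, 5L, 8L)) {
    dpu <- make_pileup(counts = c(A = 1000L - d_alt, G = d_alt))
    spu <- make_pileup(counts = c(A = 500L))
    dn <- call_de_novo(dpu, spu, NULL, min_hotspot = 3L, min_non_hotspot = 5L)
    gt <- genotype_site(dpu, spu, list(chrom = "chr1", pos = 1500L,
                                       ref = "A", alt = "G"))
    if (nrow(dn) > 0) expect_true(gt$detected)
  }
})

test_that("measured VAF of a simulated low-frequency variant is binomially consistent", {
  cfg <- sim_config(panel = data.frame(chrom = "chr1", start = 1000L, end = 1100L),
                    depth_templates = 2000L, seed = 31L)
  ref <- sim_reference(cfg)
  pos <- 1050L
  refb <- substr(ref["chr1"], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  truth <- data.frame(chrom = "chr1", pos = pos, ref = refb, alt = alt,
                      compartment = "somatic_tumor", plasma_vaf = 0.01,
                      wbc_vaf = 0, hotspot = TRUE)
  sim <- simulate_reads(cfg, truth, "plasma")
  tiers <- emit_tiers(collapse_reads(sim$pairs))
  pus <- pileup_tiers(tiers, cfg$panel, sim$reference)
  g <- genotype_site(pus$duplex, pus$simplex,
                     list(chrom = "chr1", pos = pos, ref = refb, alt = alt))
  expect_true(g$detected)
  dp <- g$call$DP
  ci <- stats::qbinom(c(0.005, 0.995), dp, 0.01) / dp
  expect_gte(g$call$VAF, ci[1])
  expect_lte(g$call$VAF, ci[2])
})

test_that("overlapping-mate disagreement removes fragment support for the alt", {
  ## single read pair fully overlapping; left mate carries the alt,
  ## right mate the reference at the same position
  ref20 <- strrep("C", 20)
  alt20 <- paste0(strrep("C", 10), "A", strrep("C", 9))
  p <- make_pairs(start = 3000L, end = 3019L, strand = "+",
                  umi1 = "AAA", umi2 = "TTT",
                  seq_left = alt20, seq_right = ref20)
  cons <- collapse_reads(p, trim = 0L)
  expect_identical(substr(cons$seq, 11, 11), "N")
})
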