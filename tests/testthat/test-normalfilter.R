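test_that("compartment classification reproduces the box geometry", {
  expect_identical(classify_compartment(0.50, 0.48, TRUE), "III_germline")
  ## low equal frequencies in both compartments: clonal hematopoiesis
  expect_identical(classify_compartment(0.0044, 0.0031, TRUE), "IV_CH")
  expect_identical(classify_compartment(0.12, 0, FALSE), "I_somatic_cfDNA_only")
  expect_identical(classify_compartment(0.25, 0.01, TRUE),
                   "II_tumor_with_trace_WBC")
  expect_error(classify_compartment(1.2, 0, FALSE), "VAF")
})

test_that("box boundaries follow the documented inclusivity", {
  ## 0.35 and 0.65 are inside the germline box
  expect_identical(classify_compartment(0.35, 0.35, TRUE), "III_germline")
  expect_identical(classify_compartment(0.65, 0.65, TRUE), "III_germline")
  expect_identical(classify_compartment(0.3499, 0.5, TRUE),
                   "II_tumor_with_trace_WBC")
  ## 0.10 exactly is outside the CH box
  expect_identical(classify_compartment(0.05, 0.10, TRUE),
                   "II_tumor_with_trace_WBC")
  expect_identical(classify_compartment(0.0999, 0.0999, TRUE), "IV_CH")
})

test_that("box assignment is a total function over the VAF grid", {
  grid <- expand.grid(p = seq(0, 1, by = 0.05), w = seq(0, 1, by = 0.05),
                      s = c(TRUE, FALSE))
  out <- classify_compartment(grid$p, grid$w, grid$s)
  expect_identical(length(out), nrow(grid))
  expect_true(all(out %in% c("I_somatic_cfDNA_only", "II_tumor_with_trace_WBC",
                             "III_germline", "IV_CH")))
  ## no WBC support can never yield boxes that require WBC evidence
  expect_false(any(out[!grid$s] %in% "IV_CH"))
})

test_that("population filter removes PoN members and common variants", {
  v <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  pon <- v[3, ]
  popaf <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "G",
                      af = c(0.006, 0.004))
  pf <- population_filter(v, pon, popaf, af_threshold = 0.005)
  expect_identical(pf$removed$pos, c(1L, 3L))     # AF 0.006 and PoN
  expect_identical(pf$retained$pos, c(2L, 4L))    # AF 0.004 is below 0.5%
  expect_setequal(pf$removed$reason, c("population_af", "pon"))
  expect_error(population_filter(v, NULL, NULL, af_threshold = 0), "threshold")

  ## exact accounting on a marked synthetic callset
  set.seed(77)
  v2 <- data.frame(chrom = "chr1", pos = 1:100, ref = "A", alt = "G")
  common <- sort(sample(100, 40))
  popaf2 <- data.frame(chrom = "chr1", pos = common, ref = "A", alt = "G",
                       af = runif(40, 0.005, 0.5))
  pf2 <- population_filter(v2, NULL, popaf2)
  expect_identical(nrow(pf2$removed), 40L)
})

test_that("unmatched-mode filtering loses germline-range somatic truth", {
  v <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                  VAF = c(0.49, 0.42, 0.05, 0.50), stringsAsFactors = FALSE)
  truth <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                      compartment = c("germline", "somatic_tumor",
                                      "somatic_tumor", "germline"))
  um <- unmatched_mode_filter(v, truth = truth)
  ## the two germline and the 0.42 somatic fall in the heuristic range
  expect_identical(sort(um$removed$pos), c(1L, 2L, 4L))
  expect_identical(um$improperly_removed$pos, 2L)
  expect_identical(um$retained$pos, 3L)
  ## without truth the improper report is empty, filtering unchanged
  um2 <- unmatched_mode_filter(v)
  expect_identical(nrow(um2$improperly_removed), 0L)
  expect_identical(sort(um2$removed$pos), c(1L, 2L, 4L))
})

test_that("matched filtering retains strictly more somatic truth than unmatched", {
  ## synthetic callset with known composition
  set.seed(13)
  calls <- data.frame(chrom = "chr1", pos = 1:30, ref = "A", alt = "G",
                      VAF = c(runif(10, 0.35, 0.65),      # germline
                              runif(5, 0.01, 0.08),       # CH
                              runif(10, 0.01, 0.30),      # somatic low
                              runif(5, 0.36, 0.60)),      # somatic in range
                      wbc_vaf = c(runif(10, 0.4, 0.6), runif(5, 0.01, 0.08),
                                  rep(0, 15)),
                      wbc_supported = c(rep(TRUE, 15), rep(FALSE, 15)))
  truth <- data.frame(chrom = "chr1", pos = 1:30, ref = "A", alt = "G",
                      compartment = rep(c("germline", "CH", "somatic_tumor",
                                          "somatic_tumor"), c(10, 5, 10, 5)))
  box <- classify_compartment(calls$VAF, calls$wbc_vaf, calls$wbc_supported)
  matched_kept <- calls[box %in% c("I_somatic_cfDNA_only",
                                   "II_tumor_with_trace_WBC"), ]
  um <- unmatched_mode_filter(calls, truth = truth)
  somatic_pos <- truth$pos[truth$compartment == "somatic_tumor"]
  expect_true(all(somatic_pos %in% matched_kept$pos))        # no somatic lost
  expect_false(any(truth$pos[truth$compartment != "somatic_tumor"] %in%
                     matched_kept$pos))                      # all germline/CH removed
  expect_gt(sum(matched_kept$pos %in% somatic_pos),
            sum(um$retained$pos %in% somatic_pos))           # strictly more
  expect_gt(nrow(um$improperly_removed), 0L)
})

test_that("fingerprint concordance discriminates same-donor from random pairs", {
  ## identical genotype vectors
  v <- c(rep(0.01, 10), rep(0.5, 20), rep(0.99, 10))
  fc <- fingerprint_concordance(v, v)
  expect_equal(fc$concordance, 1)
  expect_identical(fc$verdict, "match")

  ## independent random genotypes: expected concordance is
  ## 0.25^2 + 0.5^2 + 0.25^2 = 0.375 under Hardy-Weinberg at AF 0.5
  set.seed(99)
  draws <- replicate(200, {
    g1 <- sample(c(0, 0.5, 1), 50, TRUE, prob = c(0.25, 0.5, 0.25))
    g2 <- sample(c(0, 0.5, 1), 50, TRUE, prob = c(0.25, 0.5, 0.25))
    fingerprint_concordance(g1, g2)$concordance
  })
  expect_equal(mean(draws), 0.375, tolerance = 0.03)
  expect_identical(fingerprint_concordance(
    sample(c(0, 0.5, 1), 50, TRUE, prob = c(0.25, 0.5, 0.25)),
    sample(c(0, 0.5, 1), 50, TRUE, prob = c(0.25, 0.5, 0.25)))$verdict,
    "mismatch")

  ## too few informative sites -> indeterminate
  fc2 <- fingerprint_concordance(v[1:10], v[1:10])
  expect_identical(fc2$verdict, "indeterminate")
  expect_true(is.na(fc2$concordance))
  ## depth gating drops shallow sites
  fc3 <- fingerprint_concordance(v, v, plasma_depth = rep(5L, 40),
                                 wbc_depth = rep(100L, 40))
  expect_identical(fc3$verdict, "indeterminate")
})
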