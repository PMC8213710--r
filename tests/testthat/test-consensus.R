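test_that("UMI canonicalization joins the two strands of one template", {
  sq <- strrep("A", 60)
  pairs <- make_pairs(start = 2000L, end = 2059L,
                      strand = c("+", "+", "-", "-"),
                      umi1 = c("ACT", "ACT", "GGA", "GGA"),
                      umi2 = c("GGA", "GGA", "ACT", "ACT"),
                      seq_left = sq)
  g <- group_families(pairs)
  fam <- attr(g, "families")
  expect_identical(nrow(fam), 1L)
  expect_identical(fam$n_plus, 2L)
  expect_identical(fam$n_minus, 2L)

  ## distinct UMI pairs at the same coordinates -> distinct families
  pairs2 <- make_pairs(start = 2000L, end = 2059L,
                       strand = c("+", "+"),
                       umi1 = c("ACT", "TTT"), umi2 = c("GGA", "CCC"),
                       seq_left = sq)
  expect_identical(nrow(attr(group_families(pairs2), "families")), 2L)

  ## missing UMI -> record skipped with a count
  pairs3 <- pairs
  pairs3$umi1[1] <- ""
  g3 <- group_families(pairs3)
  expect_identical(attr(g3, "skipped"), 1L)
  expect_identical(nrow(g3), 3L)
})

test_that("strand consensus applies the strict-majority rule with N on ties", {
  ## three identical reads: consensus equals the read, support 3 everywhere
  r <- strand_consensus(rep("ACGTACGT", 3))
  expect_identical(r$seq, "ACGTACGT")
  expect_true(all(r$support == 3L))
  ## majority column {A,A,G} -> A; tie {A,G} -> N
  expect_identical(strand_consensus(c("A", "A", "G"))$seq, "A")
  expect_identical(strand_consensus(c("A", "G"))$seq, "N")
  expect_identical(strand_consensus(c("AC", "AG", "AT"))$seq, "AN")
})

test_that("family collapse assigns tiers and the duplex agreement rule", {
  sq_alt <- paste0(strrep("C", 10), "A", strrep("C", 9))   # alt A at offset 11
  p <- make_pairs(start = 3000L, end = 3019L,
                  strand = c(rep("+", 5), "-"),
                  umi1 = c(rep("AAA", 5), "CCC"),
                  umi2 = c(rep("CCC", 5), "AAA"),
                  seq_left = sq_alt, seq_right = sq_alt)
  cc <- collapse_family(p)
  expect_identical(cc$tier, "duplex")
  expect_identical(substr(cc$seq, 11, 11), "A")
  expect_identical(c(cc$n_plus, cc$n_minus), c(5L, 1L))

  ## one strand only, 3 reads -> simplex
  cs <- collapse_family(p[1:3, ])
  expect_identical(cs$tier, "simplex")
  expect_identical(collapse_family(p[1:2, ])$tier, "sub_simplex")
  expect_identical(collapse_family(p[1, ])$tier, "singleton")

  ## strand disagreement at one column -> N in the duplex consensus
  p2 <- p[c(1, 6), ]
  ref <- strrep("C", 20)
  p2$seq_left[2] <- ref; p2$seq_right[2] <- ref
  cd <- collapse_family(p2)
  expect_identical(cd$tier, "duplex")
  expect_identical(substr(cd$seq, 11, 11), "N")
  expect_identical(substr(cd$seq, 1, 10), strrep("C", 10))
})

test_that("trimming removes 3 bases per end and adjusts the interval", {
  cons <- data.frame(family = 1L, chrom = "chr1", start = 501L, end = 600L,
                     tier = "duplex", n_plus = 1L, n_minus = 1L,
                     seq = paste(rep("A", 100), collapse = ""))
  class(cons) <- c("consensus_reads", "data.frame")
  tr <- trim_consensus(cons, 3L)
  expect_identical(nchar(tr$seq), 94L)
  expect_identical(c(tr$start, tr$end), c(504L, 597L))
  ## n_bases = 0 is the identity
  expect_identical(trim_consensus(cons, 0L)$seq, cons$seq)
  ## a 167-bp fragment reports a 161-bp insert after trimming
  cons$end <- 667L; cons$seq <- strrep("A", 167)
  tr2 <- trim_consensus(cons, 3L)
  expect_identical(tr2$end - tr2$start + 1L, 161L)
  ## too-short reads are dropped and counted
  short <- cons; short$end <- 505L; short$seq <- strrep("A", 5)
  tr3 <- trim_consensus(short, 3L)
  expect_identical(nrow(tr3), 0L)
  expect_identical(attr(tr3, "dropped"), 1L)
})

test_that("tier emission partitions the consensus set", {
  cfg <- tiny_config(depth_templates = 120L, seed = 42L)
  sim <- simulate_reads(cfg, NULL, "plasma")
  cons <- collapse_reads(sim$pairs)
  tiers <- emit_tiers(cons)
  expect_identical(nrow(tiers$all_unique),
                   nrow(tiers$duplex) + nrow(tiers$simplex) +
                     nrow(tiers$sub_simplex) + nrow(tiers$singleton))
  ## tier counts match the generator's bookkeeping
  expect_identical(as.vector(table(cons$tier)[sort(unique(cons$tier))]),
                   as.vector(table(attr(sim$pairs, "tier_truth"))[sort(unique(cons$tier))]))
  ## family count equals the number of sequenced templates
  expect_identical(nrow(cons), attr(sim$pairs, "n_templates"))

  ## no second strands -> no duplex reads
  cfg0 <- tiny_config(duplex_capture_prob = 0)
  cons0 <- collapse_reads(simulate_reads(cfg0, NULL, "plasma")$pairs)
  expect_identical(sum(cons0$tier == "duplex"), 0L)
})

test_that("collapsing an already-collapsed duplex read leaves its sequence unchanged", {
  cfg <- tiny_config(seq_error_rate = 0)
  sim <- simulate_reads(cfg, NULL, "plasma")
  cons <- collapse_reads(sim$pairs, trim = 0L)
  dup <- cons[cons$tier == "duplex", ][1:10, ]
  again <- make_pairs(start = dup$start, end = dup$end, strand = "+",
                      umi1 = sprintf("U%d", seq_len(10)), umi2 = "AAA",
                      seq_left = dup$seq, seq_right = dup$seq)
  re <- collapse_reads(again, trim = 0L)
  re <- re[order(re$start, re$end), ]
  dup <- dup[order(dup$start, dup$end), ]
  expect_identical(re$seq, dup$seq)
})

test_that("the optional 1-mismatch UMI merge joins near-identical families", {
  sq <- strrep("G", 40)
  pairs <- make_pairs(start = 2000L, end = 2039L,
                      strand = c("+", "+", "+"),
                      umi1 = c("ACT", "ACT", "ACT"),
                      umi2 = c("GGA", "GGA", "GGT"),   # one UMI base off
                      seq_left = sq)
  exact <- group_families(pairs)
  expect_identical(nrow(attr(exact, "families")), 2L)
  merged <- group_families(pairs, umi_merge_1mm = TRUE)
  expect_identical(nrow(attr(merged, "families")), 1L)
  ## two mismatches stay separate even with the merge on
  pairs$umi2[3] <- "TTA"
  merged2 <- group_families(pairs, umi_merge_1mm = TRUE)
  expect_identical(nrow(attr(merged2, "families")), 2L)
})

test_that("consensus tiers suppress sequencing error in the expected order", {
  ## elevated error rate so all tiers show measurable error at small scale
  st <- error_suppression_study(n_regions = 2L, region_bp = 600L,
                                depth_templates = 500L,
                                seq_error_rate = 0.05, seed = 9L)
  r <- st$rates
  expect_gt(r[["standard"]], 10 * r[["simplex"]])
  expect_gt(r[["simplex"]], 10 * r[["duplex"]])
  expect_gt(r[["duplex"]], 0)      # observable, not merely absent
})
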