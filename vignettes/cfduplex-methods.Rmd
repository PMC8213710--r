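---
title: "Duplex consensus calling for cfDNA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling for cfDNA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cfduplex)
```

# The problem

Circulating cell-free DNA (cfDNA) carries tumor-derived fragments (ctDNA) at
allele fractions that routinely sit below the raw error rate of short-read
sequencing (~10^-3 per base). Three ideas make variant calling possible down
to ~0.1% VAF and below:

1. **Duplex UMI consensus.** Every original double-stranded template is
   tagged with a dual unique molecular identifier (UMI) before PCR. Reads are
   grouped back into families per template *strand*; a base is trusted most
   when the consensus of the two strands agrees (a *duplex* consensus),
   because polymerase and sequencer errors on opposite strands are
   independent.
2. **Matched white-blood-cell (WBC) sequencing.** Most cfDNA is of
   hematopoietic origin, so germline variants and clonal hematopoiesis (CH)
   appear in both plasma and WBC DNA. Sequencing the buffy coat of the same
   blood tube lets both be removed without discarding genuine somatic
   variants — including somatic variants whose VAF happens to fall in the
   heterozygous germline range, which a VAF-based heuristic would throw away.
3. **Fragmentomics.** ctDNA fragments are a little shorter than
   hematopoietically derived cfDNA. At a variant locus, comparing the
   fragment lengths of alternate-allele and reference-allele molecules gives
   an orthogonal read on the variant's compartment of origin.

The package implements the full computational chain — synthetic read
generation, consensus collapsing, background-error profiling, threshold
calling, WBC classification, fragment-size testing and validation
statistics — so each claim above is demonstrable end to end on data with
known truth.

# The synthetic data generator

`sim_config()` fixes the generative model; these defaults are the study
conditions for every test in the package and are not tuned per experiment.

| parameter | default | units | rationale |
|---|---|---|---|
| `mono_peak_bp`, `di_peak_bp` | 167, 323 | bp | pre-trim template peaks; after the pipeline's 3-bp-per-end trim they reproduce the canonical cfDNA insert modes at 161 and 317 bp (mono- and di-nucleosomal protection) |
| `mono_weight` | 0.85 | — | mononucleosomal fragments dominate cfDNA |
| `length_sd_bp` | 15 | bp | spread of each mixture component |
| `tumor_fraction_short_shift_bp` | 15 | bp | ctDNA fragments are shorter; 10–20 bp mean shifts are typical of plasma studies |
| `seq_error_rate` | 1e-3 | /base | raw substitution error of short-read sequencing |
| `family_size_mean` | 3 | reads/strand | PCR duplicates per sequenced strand follow `1 + Poisson(mean − 1)`, guaranteeing ≥ 1 read per strand |
| `duplex_capture_prob` | 0.5 | — | probability the second strand of a template is sequenced at all |
| `depth_templates` | 800 | templates/site | unique-molecule depth of a deep targeted panel |
| `read_len` | 100 | bp | each mate |
| `umi_len` | 3 | bp | dual 3+3 UMI |

Two of these deserve justification because the family-size law is not
observable from published summaries directly. With `family_size_mean = 3`
and `duplex_capture_prob = 0.5`, the expected fraction of templates that
yield a duplex consensus is 0.50 and the fraction yielding a simplex
consensus (single strand, ≥ 3 reads) is
`0.5 × P(1 + Pois(2) ≥ 3) = 0.297`, i.e. a duplex:simplex consensus coverage
ratio of 1.68 — matching the ratio of published tier coverages of deep
cfDNA panels (≈ 1100×:660× after collapsing). The corresponding
raw-to-duplex coverage multiple of the simulator (~11×) is *lower* than a
real hybrid-capture run (~17×): we deliberately spend fewer redundant raw
reads per template, which leaves all consensus-level statistics unchanged
while keeping simulations tractable. The same two parameters also keep
consensus errors *observable*: with large PCR families, simplex consensus
errors (which require two identical errors among three reads, probability
≈ e² at the 3-read family size) would become too rare to measure by
simulation at any feasible scale.

What the generator does **not** emulate: quality-score structure (no
per-cycle error profile beyond the end-trim rationale), indel sequencing
errors, GC-coverage bias, UMI collisions/errors (exact-match grouping is the
default, a 1-mismatch merge flag exists but is off), or contamination.
Passing tests therefore demonstrate the *logic* of the pipeline under its
stated error model, not robustness to every artifact of real libraries.

Truth tables from `sim_truth()` encode the compartment conventions:
germline variants at VAF 0.5 in both compartments and common in the
population table; CH variants at one low VAF (2–6%) shared by both
compartments; somatic variants only in plasma (WBC VAF 0), with an optional
trace-WBC class (WBC VAF 1.5%) representing tumor variants with limited
buffy-coat evidence; fingerprint SNPs drawn from Hardy–Weinberg at allele
frequency 0.5, identical in both samples of a donor.

# Consensus collapsing

Read pairs sharing chromosome, fragment start, fragment end and the
*canonicalized* UMI pair form one family: the dual UMI reads `(a,b)` from one
strand and `(b,a)` from the other, so minus-strand keys are swapped before
matching. The fragment *end* is part of the key on purpose — fragment length
is identity-bearing in cfDNA (and needed downstream by fragmentomics), so
two templates with equal start but different length must not merge.

Within a strand, the consensus base at a position is the strict majority
(> 50%) of all read observations covering it; ties and split columns give
`N`. Overlapping mates of one pair contribute two observations each, so a
within-pair disagreement at a site also yields `N` — one fragment can never
support an allele twice, and a mate conflict removes its support entirely.
A duplex consensus requires ≥ 1 read pair on *each* strand (the literal
"both strands" rule; the per-strand minimum is configurable); the two strand
consensuses are compared column-wise and any disagreement gives `N`.
Single-strand families are tiered by read count: ≥ 3 simplex, 2 sub-simplex,
1 singleton. Three bases are trimmed from each consensus end (read ends
carry elevated error), shrinking a 167-bp fragment to the familiar 161-bp
insert. Consensus base qualities are a fixed per-tier label rather than an
arithmetic combination — downstream code consumes allele counts, not
qualities.

The four output collections are: `duplex`, `simplex`, `all_unique`
(duplex + simplex + sub-simplex + singleton; one entry per sequenced
template) and the uncollapsed `standard` reads.

# Error profiling

The error rate of a substitution type at a position is the fraction of
sequenced bases supporting that non-reference allele. Alleles above a 2%
allele-frequency cap are treated as real variants and excluded from the
error tally (the cap excludes the *allele*, not the whole position — a site
with a genuine heterozygous SNP can still measure background error on the
other two alternates). Three summaries are provided:

* `sample_error_summary()` — the median over *error-containing* positions
  only, matching the per-position view in which all-zero positions are
  uninformative. With no error-containing position the summary is flagged
  undefined, never reported as zero.
* `tier_error_rate()` / `substitution_error_rates()` — the aggregate
  fraction of non-reference bases across all targeted positions, overall or
  by the 12 substitution types. The aggregate is the quantity the
  suppression mechanism acts on, and the one used for tier-ordering checks:
  at realistic simulation scales most substitution types see zero consensus
  errors, so medians of per-type or per-error-site rates are degenerate for
  the consensus tiers (a single error at low tier depth produces a *large*
  per-site rate, inverting the apparent ordering).
* `cohort_site_summary()` — per site and substitution type, the
  nearest-rank 95th percentile across samples (so rank 45 of 47: one or two
  outlier samples do not lift a site), summarized per site by the maximum
  across types (conservative), plus the fraction of sites whose summarized
  rate is zero.

**Expected suppression, and the scale chosen for the study.** With raw error
e = 10^-3: the standard tier measures ≈ e; a 3-read simplex family passes an
error only when 2 of 3 reads agree on the same wrong base (≈ e²), and larger
families are stricter, so the simplex rate is ≈ P(family = 3 | simplex) · e²
≈ 4 × 10^-7; a duplex error needs the same wrong base on both strands
(≈ e²/3 when both strands have one read, ≈ 2% of duplex families), ≈ 6 ×
10^-9. `error_suppression_study()` defaults to 40 independent 1-kb regions
at 1200 templates/site (~300,000 templates, ~1.2 × 10^7 simplex bases): the
expected simplex error count (~5) makes the ordering
standard > simplex > duplex empirically decidable, while duplex errors
remain, as they should, essentially unobservable. These sizes were fixed by
this power computation before the tests were run.

# Variant calling

Counting is fragment-level throughout (a consensus read is one original
molecule). Two modes:

* **Genotyping (tumor-informed):** at a site known to be mutated, detection
  requires ≥ 1 duplex *or* ≥ 2 simplex alt fragments.
* **De novo:** a call requires ≥ 3 duplex alt fragments at a known cancer
  hotspot, ≥ 5 otherwise; de novo evidence is duplex-only.

Reported AD/DP/VAF always combine the duplex and simplex tiers; a zero
combined depth suppresses the call. Multi-allelic sites evaluate each
alternate independently; indels are keyed by left-aligned anchor position
with the same thresholds. Because duplex alt fragments at true VAF v and
duplex depth D are Binomial(D, v) by construction, the de novo hotspot
sensitivity has the closed form P(X ≥ 3 | D, v) — at D = 1100 and
v = 0.5%, 0.912 — which the simulation-based test verifies. The
structural-variant support rule is a thin threshold on externally supplied
fusion-spanning read counts: ≥ 3 de novo, ≥ 1 for a previously identified
event.

# Matched-WBC classification (boxes I–IV)

Every plasma call is compared with the WBC pileup at its site. "Presence in
WBC" is operationalized as ≥ 2 supporting WBC consensus fragments (the
qualitative notion of "limited supporting evidence" needs a number; 1
fragment is within duplex-tier noise of a deep run). Classification is a
total function with precedence III → IV → I → II:

| box | rule | interpretation |
|---|---|---|
| III | both VAFs in [0.35, 0.65] (inclusive) | heterozygous germline |
| IV | WBC-supported, both VAFs < 0.10, WBC VAF > 0 | clonal hematopoiesis |
| I | no WBC support | somatic, cfDNA-only |
| II | everything else | tumor variant with trace WBC evidence |

Germline evidence is strongest, hence first; CH requires WBC support by
definition; the remaining split is purely on WBC support. The boundaries are
inclusive at 0.35/0.65 and exclusive at 0.10, and boundary cases are pinned
by tests. `unmatched_mode_filter()` simulates the no-WBC alternative
(population filter plus the 35–65% VAF heuristic) and, when truth is known,
reports somatic variants the heuristic wrongly removes — the quantitative
argument for matched sequencing. The population filter removes a variant
present in the panel of normals or at ≥ 0.5% population allele frequency.
Plasma–WBC sample identity is verified by fingerprint SNP concordance:
VAFs discretized at 0.1/0.9 into genotypes, ≥ 20 informative sites required
(below that the verdict is indeterminate), match declared at ≥ 0.9
concordance. Unrelated samples concentrate near the Hardy–Weinberg chance
agreement of 0.375, so the 0.9 cut separates the two regimes by a wide
margin.

# Fragment-size bootstrap test

At a variant locus, `all_unique` consensus fragments covering the site are
partitioned by their consensus base into reference and alternate groups
(`N`/uncovered excluded); sizes are capped at 500 bp and variants below
0.05% fragment-level VAF are refused outright. The test statistic is
Δ = mean(ref) − mean(alt), positive when mutant fragments are shorter. The
null (equal means) is modeled by resampling with replacement from the
pooled, *mean-centered* sizes at the original group sizes; a group-label
permutation null is available behind a flag (both are implemented because
the choice is genuinely open; pooled-centered is the default as the more
literal "bootstrap" reading). The p-value is the fraction of B = 10,000
null statistics ≥ the observed Δ (one-sided; a two-sided option compares
|Δ*|), with a +1/+1 continuity correction so the smallest reportable value
is 1/(B+1) rather than 0. Per-variant RNG streams are derived from
(seed, variant key), making results independent of evaluation order.

A power note that matters for interpreting single-variant results: cfDNA
fragment lengths are bimodal, so the pooled standard deviation is ~58 bp,
an order of magnitude larger than the within-peak spread. A 15-bp
shortening with 200 alternate and 2000 reference fragments therefore gives
z ≈ 3.5 — usually but not always significant at the 10^-3 level. The
package's calibration tests assert strict significance at the pooled
cohort scale (~1,500 mutant fragments, z ≈ 10) and detection (p < 0.05) at
the single-variant scale, alongside a 2,000-repetition type-I-error check
(rejection rate 0.05 ± 0.02 at B = 1,000) and a KS uniformity check of the
null p-value distribution.

# Validation statistics

"Exact" intervals are Clopper–Pearson, computed from the inverse
incomplete-beta relations (`qbeta(α/2, k, n−k+1)`;
`qbeta(1−α/2, k+1, n−k)`), with the k = 0 and k = n ends pinned to 0 and 1;
values are held at full precision and rounded only for display.
Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPA = TP/(TP+FP),
NPA = TN/(TN+FN), each with its exact interval on the (numerator,
denominator) pair; zero denominators yield NA, never 0. The coefficient of
variation uses the sample (n−1) standard deviation over the mean.

# Numerical and I/O conventions

* SAM records and variant tables are 1-based; BED is 0-based half-open
  (interval [100, 200) holds 1-based positions 101..200). Round-trip
  fidelity of every format is tested.
* Consensus sequences are strings over fragment coordinates with `.` for
  positions no read covers (the interior gap of fragments longer than two
  read lengths) and `N` for suppressed/ambiguous calls; neither contributes
  to pileup counts or depth.
* All randomness flows from a single seed; stage seeds are derived by a
  deterministic hash, and identical seed + configuration gives
  byte-identical persisted outputs (no timestamps in any output).
* Degenerate inputs: empty plasma input aborts the pipeline cleanly with a
  coverage-zero QC block; reads too short to trim are dropped and counted;
  zero-depth positions are skipped, not zero-filled; an all-zero error
  summary is "undefined", not 0.

# Known limitations

* The simulator emits reads pre-aligned at their true coordinates;
  alignment, realignment and mapping artifacts are upstream concerns and
  entirely out of scope.
* Indel truth variants are injected error-free and located by anchor
  position; indel-specific alignment pathology is not modeled.
* No copy-number, structural-variant discovery, or microsatellite logic:
  the SV module is only the read-support threshold applied to supplied
  junction counts.
* Published cohort-level error-rate values from real donor panels depend on
  real library artifacts (OxoG-type damage, mapping error, trinucleotide
  context) that the generator deliberately does not model; the package
  asserts orderings and mechanisms, not those cohort constants.
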