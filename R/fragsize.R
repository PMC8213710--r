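## cfDNA fragment-length analysis: size distributions, allele-specific
## fragment sizes at variant loci, and the bootstrap test of equal mean
## fragment length between reference- and alternate-allele fragments.

#' Fragment sizes of consensus fragments or read pairs over target regions
#'
#' Returns the template length of every fragment overlapping the targets,
#' each fragment counted once, restricted to `max_size` (500 bp by default:
#' the size window that holds the overwhelming majority of cfDNA fragments).
#'
#' @param reads a `consensus_reads` or `read_pairs` data.frame (both carry
#'   fragment start/end per row).
#' @param targets optional data.frame of target regions (chrom, start, end;
#'   0-based half-open); fragments overlapping any target are kept.
#' @param max_size maximum fragment size retained (bp).
#' @return integer vector of fragment sizes.
#' @export
fragment_sizes <- function(reads, targets = NULL, max_size = 500L) {
  size <- reads$end - reads$start + 1L
  keep <- size <= max_size & size >= 1L
  if (!is.null(targets) && nrow(targets)) {
    on_target <- rep(FALSE, nrow(reads))
    for (i in seq_len(nrow(targets))) {
      on_target <- on_target |
        (reads$chrom == targets$chrom[i] &
           reads$start <= targets$end[i] &
           reads$end >= targets$start[i] + 1L)
    }
    keep <- keep & on_target
  }
  as.integer(size[keep])
}

#' Allele-specific fragment sizes at a variant locus
#'
#' Partitions consensus fragments covering the site by the allele their
#' consensus base supports: reference-allele fragments vs alternate-allele
#' fragments. Fragments with `N` or no coverage at the site are excluded.
#' Variants with a fragment-level VAF below `min_vaf` (0.05% by default) are
#' refused -- at such frequencies the alternate size sample is too small and
#' contamination-prone to size-type.
#'
#' @param reads a `consensus_reads` data.frame (typically the all-unique
#'   tier, one row per template molecule).
#' @param variant one-row data.frame/list with chrom, pos, ref, alt.
#' @param min_vaf minimum fragment-level VAF for inclusion.
#' @param max_size maximum fragment size retained (bp).
#' @return list of class `allele_sizes`: `ref_sizes`, `alt_sizes`, `vaf`,
#'   `status` (`"ok"` or `"excluded_low_vaf"`), `reason`.
#' @export
allele_fragment_sizes <- function(reads, variant, min_vaf = 5e-4,
                                  max_size = 500L) {
  r <- reads[reads$chrom == variant$chrom &
               reads$start <= variant$pos & reads$end >= variant$pos, ,
             drop = FALSE]
  size <- r$end - r$start + 1L
  base <- substr(r$seq, variant$pos - r$start + 1L, variant$pos - r$start + 1L)
  is_ref <- base == variant$ref
  is_alt <- base == variant$alt
  n_ref <- sum(is_ref)
  n_alt <- sum(is_alt)
  vaf <- if (n_ref + n_alt > 0L) n_alt / (n_ref + n_alt) else NA_real_
  if (is.na(vaf) || vaf < min_vaf) {
    return(structure(list(ref_sizes = integer(), alt_sizes = integer(),
                          vaf = vaf, status = "excluded_low_vaf",
                          reason = sprintf(
                            "fragment-level VAF %s below floor %g",
                            format(vaf), min_vaf)),
                     class = "allele_sizes"))
  }
  structure(list(ref_sizes = as.integer(size[is_ref & size <= max_size]),
                 alt_sizes = as.integer(size[is_alt & size <= max_size]),
                 vaf = vaf, status = "ok", reason = NA_character_),
            class = "allele_sizes")
}

#' Bootstrap test of equal mean fragment size (H0: mu_REF = mu_ALT)
#'
#' The test statistic is `Delta = mean(ref) - mean(alt)`: positive when
#' alternate-allele fragments are shorter, as expected for tumor-derived
#' cfDNA. The null is modeled by resampling with replacement from the
#' pooled, mean-centered sizes at the original group sizes
#' (`null = "pooled_centered"`, the default) or by resampling group labels
#' without replacement (`null = "label_permutation"`). The p-value is the
#' fraction of null replicates with a statistic at least as large as the
#' observed one (one-sided, `alternative = "greater"`); a two-sided option
#' compares `|Delta*|` to `|Delta|`. The +1/+1 continuity correction keeps
#' the smallest reportable p-value at `1/(B+1)` rather than 0.
#'
#' @param ref_sizes,alt_sizes integer vectors of fragment sizes (non-empty).
#' @param B bootstrap replicates (10,000 by default).
#' @param seed integer seed; combined with `variant_id` so per-variant tests
#'   are reproducible independently of evaluation order.
#' @param variant_id optional character key identifying the variant.
#' @param null null-model resampling scheme.
#' @param alternative one- or two-sided comparison.
#' @return object of class `fragsize_test`: mu_ref, mu_alt, delta, p_value,
#'   B, n_ref, n_alt, null, alternative, seed.
#' @examples
#' x <- rnorm(200, 166, 20); y <- rnorm(60, 151, 20)
#' bootstrap_mean_test(x, y, B = 2000, seed = 1)
#' @export
bootstrap_mean_test <- function(ref_sizes, alt_sizes, B = 10000L, seed = 1L,
                                variant_id = NULL,
                                null = c("pooled_centered", "label_permutation"),
                                alternative = c("greater", "two.sided")) {
  null <- match.arg(null)
  alternative <- match.arg(alternative)
  if (!length(ref_sizes) || !length(alt_sizes))
    stop_arg("both size groups must be non-empty")
  if (B < 100L) warning("B < 100 gives a very coarse p-value")
  n1 <- length(ref_sizes)
  n2 <- length(alt_sizes)
  mu_ref <- mean(ref_sizes)
  mu_alt <- mean(alt_sizes)
  delta <- mu_ref - mu_alt
  use_seed <- if (is.null(variant_id)) as.integer(seed) else
    key_seed(seed, variant_id)
  pool <- c(ref_sizes, alt_sizes)
  stat <- with_seed(use_seed, {
    if (null == "pooled_centered") {
      src <- pool - mean(pool)
      draw_delta_star(src, n1, n2, B, replace = TRUE)
    } else {
      draw_delta_star(pool, n1, n2, B, replace = FALSE)
    }
  })
  exceed <- if (alternative == "greater") sum(stat >= delta) else
    sum(abs(stat) >= abs(delta))
  p <- (exceed + 1) / (B + 1)
  structure(list(mu_ref = mu_ref, mu_alt = mu_alt, delta = delta,
                 p_value = p, B = as.integer(B), n_ref = n1, n_alt = n2,
                 null = null, alternative = alternative, seed = use_seed),
            class = "fragsize_test")
}

## Delta* for B null replicates, chunked to bound memory.
## replace = TRUE: both groups resampled independently from src.
## replace = FALSE: labels permuted within the pool each replicate.
draw_delta_star <- function(src, n1, n2, B, replace) {
  out <- numeric(B)
  chunk <- max(1L, as.integer(2e6 %/% (n1 + n2)))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    if (replace) {
      m1 <- matrix(src[sample.int(length(src), b * n1, replace = TRUE)], nrow = b)
      m2 <- matrix(src[sample.int(length(src), b * n2, replace = TRUE)], nrow = b)
      out[done + seq_len(b)] <- rowMeans(m1) - rowMeans(m2)
    } else {
      for (j in seq_len(b)) {
        idx <- sample.int(n1 + n2, n1)
        out[done + j] <- mean(src[idx]) - mean(src[-idx])
      }
    }
    done <- done + b
  }
  out
}

#' @export
print.fragsize_test <- function(x, ...) {
  cat("Bootstrap test of equal mean fragment size\n")
  cat(sprintf("  mu_ref = %.2f bp (n=%d), mu_alt = %.2f bp (n=%d)\n",
              x$mu_ref, x$n_ref, x$mu_alt, x$n_alt))
  cat(sprintf("  Delta = %.2f bp, p %s %.3g  (B = %d, %s, %s null)\n",
              x$delta, if (x$p_value <= 1 / x$B) "<" else "=",
              x$p_value, x$B, x$alternative, x$null))
  invisible(x)
}
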