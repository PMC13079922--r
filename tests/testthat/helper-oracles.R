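# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the package's own code paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# maximal-run oracle via a single regex over the whole sequence
regex_scan_oracle <- function(seq, unit = "GGAA") {
  m <- gregexpr(sprintf("(?:%s)+", unit), toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer(),
                      unit_count = integer()))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len,
             unit_count = as.integer(len / nchar(unit)))
}

# O(n^2) interval merge oracle (0-based half-open, gap < dist merges)
naive_merge_oracle <- function(df, dist = 0L) {
  df <- df[order(df$chrom, df$start), ]
  out <- NULL
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is.null(out) && out$chrom[nrow(out)] == r$chrom &&
        r$start - out$end[nrow(out)] < dist) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], r$end)
    } else {
      out <- rbind(out, data.frame(chrom = r$chrom, start = r$start,
                                   end = r$end))
    }
  }
  out
}

# all-pairs overlap oracle
naive_intersect_oracle <- function(a, b, min_overlap = 1L) {
  hits <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap) hits <- rbind(hits, data.frame(a_idx = i, b_idx = j))
  }
  hits
}

# two-sided Fisher p by exhaustive hypergeometric enumeration (lchoose
# arithmetic, independent of stats::fisher.test / dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- a + b + c + d
  lo <- max(0L, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  lp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(N, k)
  p_obs <- lp[xs == a]
  sum(exp(lp[lp <= p_obs + log(1 + 1e-7)]))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000L,
                             max_len = 300L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE))
}

# independent hand enumeration of the single-sample GSEA running sum
ssgsea_oracle_one <- function(x, set, alpha) {
  ord <- names(sort(x, decreasing = TRUE))
  r <- rank(x)[ord]
  inset <- ord %in% set
  p_in <- 0; p_out <- 0; total <- 0
  sum_w <- sum(r[inset]^alpha)
  n_out <- sum(!inset)
  for (i in seq_along(ord)) {
    if (inset[i]) p_in <- p_in + r[[i]]^alpha / sum_w
    else p_out <- p_out + 1 / n_out
    total <- total + as.numeric(p_in - p_out)
  }
  total
}

# small hand-built scenario for signature-rule tests: two genes with
# promoter peaks, one enhancer-gene loop
tiny_peak_scenario <- function() {
  genes <- data.frame(gene = c("gA", "gB", "gC"),
                      chrom = "chr1", strand = "+",
                      tss = c(10000L, 30000L, 50000L))
  peaks_bed <- data.frame(
    chrom = "chr1",
    start = c(9000L, 29000L, 40000L),
    end = c(9400L, 29400L, 40400L),
    name = c("pk1", "pk2", "pk3"))
  peak_table <- data.frame(
    peak = c("pk1", "pk2", "pk3"),
    log2fc = c(1.2, -1.6, 0.9),
    max_run = c(12L, 1L, 11L),
    repeat_class = c(">=10x", "1x", ">=10x"))
  list(genes = genes, peaks_bed = peaks_bed, peak_table = peak_table)
}
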