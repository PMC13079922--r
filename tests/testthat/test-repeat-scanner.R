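# Maximal GGAA-run scanning and per-peak repeat profiling.

test_that("scan_sequence finds maximal runs on both strands", {
  b <- scan_sequence("GGAAGGAAGGAA")
  expect_equal(b$start, 0L)
  expect_equal(b$end, 12L)
  expect_equal(b$unit_count, 3L)

  expect_equal(nrow(scan_sequence("TTCCTTCC", "plus_only")), 0L)
  mb <- scan_sequence("TTCCTTCC", "both")
  expect_equal(mb$strand, "-")
  expect_equal(mb$unit_count, 2L)

  two <- scan_sequence("GGAAGGAACGGAAGGAAGGAAGGAAGGAA")
  expect_equal(two$unit_count, c(2L, 5L))
  expect_equal(two$start, c(0L, 9L))

  expect_identical(scan_sequence("ggaaGGaa"), scan_sequence("GGAAGGAA"))
  expect_equal(nrow(scan_sequence("GGANGGAA"))[1], 1L)
  expect_error(scan_sequence("GGAAZ"), "position 5")
})

test_that("scan_sequence equals the maximal-regex oracle on random sequence", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(200:5000, 1)
    # spike extra GGAA/TTCC content so runs are frequent
    s <- random_dna(n)
    s <- gsub("ACGT", "GGAA", s, fixed = TRUE)
    got <- scan_sequence(s, "both")
    plus <- regex_scan_oracle(s, "GGAA")
    minus <- regex_scan_oracle(s, "TTCC")
    expect_equal(got[got$strand == "+", c("start", "end", "unit_count")],
                 plus, ignore_attr = TRUE)
    expect_equal(got[got$strand == "-", c("start", "end", "unit_count")],
                 minus, ignore_attr = TRUE)
  }
})

test_that("reported blocks are maximal and strand-symmetric", {
  set.seed(7)
  s <- gsub("CT", "GGAAGGAA", random_dna(4000))
  b <- scan_sequence(s, "both")
  expect_true(all(b$end - b$start == 4L * b$unit_count))
  for (i in seq_len(nrow(b))) {
    unit <- if (b$strand[i] == "+") "GGAA" else "TTCC"
    left <- substr(s, b$start[i] - 3L, b$start[i])
    right <- substr(s, b$end[i] + 1L, b$end[i] + 4L)
    expect_false(identical(left, unit))
    expect_false(identical(right, unit))
  }
  # both-strand scan == plus scan of seq plus remapped plus scan of revcomp
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  fromrc <- scan_sequence(rc, "plus_only")
  remap <- data.frame(start = nchar(s) - fromrc$end,
                      end = nchar(s) - fromrc$start,
                      unit_count = fromrc$unit_count)
  minus <- b[b$strand == "-", c("start", "end", "unit_count")]
  expect_equal(minus[order(minus$start), ],
               remap[order(remap$start), ], ignore_attr = TRUE)
})

test_that("scan_fasta recovers planted repeats and tolerates empty records", {
  fa <- tempfile(fileext = ".fa")
  plan <- data.frame(chrom = "chrT",
                     start = c(1000L, 2000L, 3000L, 4000L, 5000L),
                     unit_count = c(1L, 4L, 5L, 10L, 15L),
                     strand = "+")
  generate_genome(c(chrT = 10000L), plan, seed = 11L, fa)
  blocks <- scan_fasta(fa)
  planted <- blocks[blocks$unit_count >= 2 | blocks$start %in% plan$start, ]
  expect_true(all(plan$start %in% blocks$start))
  got <- blocks[match(plan$start, blocks$start), ]
  expect_equal(got$unit_count, plan$unit_count)
  # chance background blocks are single units only
  expect_true(all(blocks$unit_count[!blocks$start %in% plan$start] <= 1))

  # empty record and soft-masked sequence
  writeLines(c(">empty", "", ">c2", "ggaaggaa"), fa)
  b2 <- scan_fasta(fa)
  expect_equal(b2$chrom, "c2")
  expect_equal(b2$unit_count, 2L)
  expect_error(scan_fasta(fa, chrom_subset = "missing"), "missing")
})

test_that("profile_intervals matches a brute-force per-peak rescan", {
  fa <- tempfile(fileext = ".fa")
  plan <- data.frame(chrom = "chrT",
                     start = c(1200L, 1300L, 3000L, 6000L),
                     unit_count = c(13L, 9L, 2L, 7L),
                     strand = "+")
  generate_genome(c(chrT = 10000L), plan, seed = 3L, fa)
  blocks <- scan_fasta(fa)

  # peak covering the 13x and 9x blocks (a two-block multimeric element);
  # the window sits inside the scrubbed flanks so no chance blocks intrude
  pk <- data.frame(chrom = "chrT", start = 1150L, end = 1386L, name = "p1")
  pr <- profile_intervals(pk, blocks)
  expect_equal(pr$max_run, 13L)
  expect_equal(pr$n_blocks_ge_5, 2L)
  expect_equal(pr$total_units, 22L)
  expect_equal(pr$repeat_class, ">=10x")

  none <- profile_intervals(
    data.frame(chrom = "chrT", start = 8000L, end = 8050L), blocks)
  expect_equal(none$max_run, 0L)
  expect_equal(none$repeat_class, "0x")

  # random peaks: profile equals a rescan of the underlying subsequence
  seqs <- as.character(Biostrings::readDNAStringSet(fa))
  set.seed(5)
  for (i in 1:20) {
    st <- sample(100:9000, 1); en <- st + sample(100:500, 1)
    p <- profile_intervals(data.frame(chrom = "chrT", start = st, end = en),
                           blocks)
    sub <- substr(seqs[["chrT"]], st + 1 - 60, en + 60)
    local_blocks <- regex_scan_oracle(sub)
    loc <- local_blocks[local_blocks$start + (st - 60) < en &
                          local_blocks$end + (st - 60) > st, ]
    expect_equal(p$max_run, if (nrow(loc)) max(loc$unit_count) else 0L)
    expect_equal(p$n_blocks_total, nrow(loc))
  }

  expect_error(profile_intervals(pk, blocks, window_mode = "center_window"),
               "center_halfwidth")
})

test_that("repeat classes follow the published bins", {
  expect_equal(classify_repeat_class(c(0L, 1L, 4L, 5L, 9L, 10L, 25L)),
               c("0x", "1-4x", "1-4x", "5-9x", "5-9x", ">=10x", ">=10x"))
  sch <- repeat_class_scheme("extremes")
  expect_equal(classify_repeat_class(c(1L, 3L, 12L), sch$bin_edges,
                                     sch$labels),
               c("1x", "2-9x", "10x"))
  expect_equal(classify_repeat_class(1L, bin_edges = c(1L, 2L),
                                     labels = c("lo", "hi")), "lo")
  expect_error(classify_repeat_class(1L, bin_edges = c(5L, 2L)))
})
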