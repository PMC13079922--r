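# Generator contracts: determinism, planted-truth consistency, noiseless
# limits and null calibration of the synthetic study.

test_that("generate_genome is byte-deterministic and validates the plan", {
  spec <- c(chrA = 5000L)
  plan <- data.frame(chrom = "chrA", start = c(1000L, 2000L),
                     unit_count = c(3L, 10L), strand = c("+", "-"))
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  generate_genome(spec, plan, seed = 7L, f1)
  generate_genome(spec, plan, seed = 7L, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  generate_genome(spec, plan, seed = 8L, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  # planted coordinates identical across seeds
  b1 <- scan_fasta(f1, "both"); b3 <- scan_fasta(f3, "both")
  expect_equal(b1[b1$unit_count >= 3, c("start", "unit_count", "strand")],
               b3[b3$unit_count >= 3, c("start", "unit_count", "strand")],
               ignore_attr = TRUE)
  expect_equal(b1$strand[b1$start == 2000], "-")

  overlapping <- data.frame(chrom = "chrA", start = c(1000L, 1008L),
                            unit_count = c(5L, 2L), strand = "+")
  expect_error(generate_genome(spec, overlapping, 1L, tempfile()),
               "overlapping")
  outside <- data.frame(chrom = "chrA", start = 4990L, unit_count = 5L,
                        strand = "+")
  expect_error(generate_genome(spec, outside, 1L, tempfile()), "bounds")
})

test_that("empty repeat plan leaves only chance single-unit runs near windows", {
  f <- tempfile()
  generate_genome(c(chrA = 20000L),
                  data.frame(chrom = character(), start = integer(),
                             unit_count = integer(), strand = character()),
                  seed = 9L, f)
  b <- scan_fasta(f)
  # chance runs of >= 3 units are vanishingly rare in 20 kb of uniform DNA
  expect_true(all(b$unit_count <= 2))
})

test_that("peak experiment respects planted folds in the noiseless limit", {
  plan <- default_study_plan(2L)
  expect_error(generate_peak_experiment(plan, dispersion = 0),
               "dispersion")
  expect_error(generate_peak_experiment(plan, depth_a = -1), "depths")

  quiet <- generate_peak_experiment(plan, dispersion = 1e-6,
                                    base_mean = 2e5, seed = 2L)
  lib <- setNames(quiet$samples$lib_size, quiet$samples$sample)
  norm <- normalize_signal(quiet$counts, lib)
  lfc <- peak_log2fc(norm, c("A_1", "A_2"), c("B_1", "B_2"))
  expect_lt(max(abs(lfc - quiet$truth$lfc)), 0.05)
})

test_that("depth normalization cancels a planted depth confound", {
  plan <- default_study_plan(3L)
  plan$peak_plan$lfc <- 0   # null effects, condition B sequenced 2x deeper
  exp_ <- generate_peak_experiment(plan, dispersion = 0.01,
                                   depth_a = 8e6, depth_b = 16e6, seed = 3L)
  lib <- setNames(exp_$samples$lib_size, exp_$samples$sample)
  norm <- normalize_signal(exp_$counts, lib)
  lfc <- peak_log2fc(norm, c("A_1", "A_2"), c("B_1", "B_2"))
  expect_lt(abs(mean(lfc)), 0.05)
  raw_lfc <- peak_log2fc(exp_$counts, c("A_1", "A_2"), c("B_1", "B_2"))
  expect_gt(abs(mean(raw_lfc)), 0.5)   # confound visible without normalization
})

test_that("cohort generator validates inputs and plants null correctly", {
  plan <- default_study_plan(4L)
  expect_error(generate_expression_and_survival(plan, n_samples = 5),
               ">= 8")
  null <- generate_expression_and_survival(plan, n_samples = 60,
                                           effect_log2 = 0, hazard_beta = 0,
                                           seed = 4L)
  sig <- plan$signature_truth$`10x_promoter`
  sc <- ssgsea_score(null$expression, sig)
  u <- null$samples$latent
  hi <- u > median(u)
  expect_lt(abs(mean(sc[hi]) - mean(sc[!hi])), 0.25)
  # censoring rate close to target under defaults
  withc <- generate_expression_and_survival(plan, n_samples = 400,
                                            censor_rate = 0.25, seed = 5L)
  expect_lt(abs(mean(1 - withc$survival$event) - 0.25), 0.1)
})

test_that("manifest identifiers resolve in the generated artifacts", {
  st <- simulate_study(seed = 6L, n_samples = 40)
  mf <- st$manifest
  expect_true(all(mf$planted_peaks$peak %in% st$peaks$name))
  expect_true(all(mf$planted_loops$peak %in% st$peaks$name))
  expect_true(all(mf$planted_loops$gene %in% st$plan$genes$gene))
  expect_true(all(unlist(mf$signature_truth) %in%
                    c(rownames(st$cohort$expression))))
  fasta_chroms <- sub("\\s.*$", "", Biostrings::fasta.index(st$fasta)$desc)
  expect_true(all(names(mf$genome_spec) %in% fasta_chroms))
  # every planted repeat is recovered by the scanner at its exact position
  blocks <- scan_fasta(st$fasta)
  key_b <- paste(blocks$chrom, blocks$start, blocks$unit_count)
  key_p <- with(mf$planted_repeats, paste(chrom, start, unit_count))
  expect_true(all(key_p %in% key_b))
})

test_that("simulate_study writes a complete file bundle deterministically", {
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_study(seed = 8L, dir = d1, n_samples = 30)
  s2 <- simulate_study(seed = 8L, dir = d2, n_samples = 30)
  for (f in c("genome.fa", "peaks.bed", "peak_counts.tsv",
              "loops_rep1.tsv", "survival.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  lp <- read_loops(file.path(d1, "loops_rep1.tsv"))
  expect_gt(nrow(lp), 0)
})
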