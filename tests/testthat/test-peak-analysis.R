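# Signal normalization, fold-changes, status partition, stratification,
# profile matrices and the surrogate DE test.

test_that("normalize_signal rescales to the target depth", {
  m <- matrix(c(100, 50), nrow = 1, dimnames = list("p1", c("s1", "s2")))
  n <- normalize_signal(m, c(s1 = 8e6, s2 = 16e6), 16e6)
  expect_equal(unname(n[1, ]), c(200, 50))
  same <- normalize_signal(m, c(s1 = 16e6, s2 = 16e6))
  expect_equal(same, m)
  expect_error(normalize_signal(m, c(s1 = 0, s2 = 1)), "positive")
})

test_that("peak_log2fc uses pseudocounted group means", {
  m <- matrix(c(7, 7, 31, 31), nrow = 1,
              dimnames = list("p", c("c1", "c2", "t1", "t2")))
  expect_equal(unname(peak_log2fc(m, c("c1", "c2"), c("t1", "t2"))), 2)
  expect_equal(unname(peak_log2fc(m, c("c1", "c2"), c("c1", "c2"))), 0)
})

test_that("status partition is exhaustive, exclusive and preset-driven", {
  m <- matrix(c(700, 700, 10, 10, 10, 10, 700, 700, 100, 100, 100, 100),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("c1", "c2", "t1", "t2")))
  d <- differential_peaks(m, c("c1", "c2"), c("t1", "t2"),
                          fc_thresholds("figure"))
  expect_setequal(d$status, c("lost", "gained", "retained"))
  expect_true(all(table(d$peak) == 1))
  dm <- differential_peaks(m, c("c1", "c2"), c("t1", "t2"),
                           fc_thresholds("methods"))
  expect_equal(dm$status[dm$peak == "a"], "lost")
  expect_true(all(dm$status %in% c("lost", "retained", "gained")))
})

test_that("venn_partition mirrors counts and detects planted dropout", {
  a <- data.frame(chrom = "c", start = (0:99) * 1000L,
                  end = (0:99) * 1000L + 200L)
  set.seed(21)
  lostidx <- sample(100, 40)
  b <- a[-lostidx, ]
  v <- venn_partition(a, b)
  expect_equal(unname(v$counts["a_only"]), 40)
  expect_equal(unname(v$counts["b_only"]), 0)
  expect_equal(unname(v$fractions["lost_fraction"]), 0.4)
  vr <- venn_partition(b, a)
  expect_equal(unname(vr$counts["b_only"]), 40)

  expect_equal(unname(venn_partition(a, a)$counts[c("a_only", "b_only")]),
               c(0, 0))
  far <- a; far$chrom <- "other"
  expect_equal(unname(venn_partition(a, far)$counts["shared_a"]), 0)
})

test_that("stratify_by_class summarizes and tests between classes", {
  set.seed(4)
  d <- data.frame(peak = sprintf("p%03d", 1:120),
                  log2fc = c(rnorm(60, -1), rnorm(60, 1)),
                  status = "retained",
                  repeat_class = rep(c("1-4x", ">=10x"), each = 60))
  s <- stratify_by_class(d, test_classes = c("1-4x", ">=10x"))
  expect_lt(s$class_stats$mean_log2fc[s$class_stats$repeat_class == "1-4x"], 0)
  expect_lt(s$test$p_value, 1e-6)
  # permuted labels: between-class difference centred at zero
  ps <- replicate(50, {
    d2 <- d; d2$repeat_class <- sample(d2$repeat_class)
    st <- stratify_by_class(d2)$class_stats
    diff(st$mean_log2fc)
  })
  expect_lt(abs(mean(ps)), 0.15)
  # single class: no test, no failure
  expect_null(stratify_by_class(d[d$repeat_class == "1-4x", ])$test)
})

test_that("signal_profile_matrix handles constant, empty and edge tracks", {
  anchors <- data.frame(chrom = "c", start = c(5000L, 100L),
                        end = c(5400L, 140L))
  tr <- data.frame(chrom = "c", start = 0L, end = 20000L, value = 3)
  p <- signal_profile_matrix(tr, anchors, half_width = 1000L, bin = 100L)
  expect_true(all(p$matrix[1, ] == 3))
  expect_true(all(is.na(p$matrix[2, ])))   # window crosses the edge
  empty <- signal_profile_matrix(
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = numeric()),
    anchors[1, ], half_width = 1000L, bin = 100L)
  expect_true(all(is.na(empty$matrix)))
})

test_that("fc_correlation reports exact r on degenerate inputs", {
  x <- setNames(rnorm(50), paste0("p", 1:50))
  expect_equal(fc_correlation(x, x)$r, 1)
  expect_equal(fc_correlation(x, -x)$r, -1)
  expect_error(fc_correlation(x, setNames(rep(1, 50), names(x))), "variance")
})

test_that("surrogate_de has power on planted folds and controls the FDR", {
  set.seed(12)
  n_genes <- 400; n_true <- 80
  grp <- setNames(rep(c("a", "b"), each = 10), paste0("s", 1:20))
  mu <- matrix(200, n_genes, 20)
  mu[seq_len(n_true), grp == "b"] <- 800   # planted 2-fold (log2) genes
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 10), n_genes,
                dimnames = list(sprintf("g%03d", 1:n_genes), names(grp)))
  de <- surrogate_de(cnt, grp)
  found <- de$gene[de$adj_p < 0.05 & de$log2FC > 0]
  expect_gte(mean(sprintf("g%03d", 1:n_true) %in% found), 0.9)
  false_pos <- sum(!found %in% sprintf("g%03d", 1:n_true))
  expect_lte(false_pos / max(1, length(found)), 0.08)

  mirror <- cnt[, 1:10]
  mirror[, 6:10] <- mirror[, 1:5]   # group b duplicates group a exactly
  same <- surrogate_de(mirror, setNames(rep(c("a", "b"), each = 5),
                                        colnames(mirror)))
  expect_true(all(same$log2FC == 0))
  expect_error(surrogate_de(cnt[, 1:3], setNames(c("a", "a", "b"),
                                                 colnames(cnt)[1:3])),
               ">=2")
})
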