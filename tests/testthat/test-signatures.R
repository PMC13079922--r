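# Signature-derivation rules, the Cox screen and prognostic refinement.

test_that("10x promoter rule selects genes by promoter overlap and fold", {
  sc <- tiny_peak_scenario()
  sig <- build_10x_promoter(sc$peak_table, sc$peaks_bed, sc$genes)
  expect_s3_class(sig, "gene_signature")
  expect_equal(sig$genes, "gA")   # pk1 is multimeric+up and sits in gA promoter
  expect_equal(sig$direction, "up")

  none <- build_10x_promoter(sc$peak_table, sc$peaks_bed, sc$genes,
                             fc_gt = Inf)
  expect_length(none$genes, 0L)

  # one peak under two promoters includes both genes
  g2 <- rbind(sc$genes,
              data.frame(gene = "gA2", chrom = "chr1", strand = "+",
                         tss = 9300L))
  both <- build_10x_promoter(sc$peak_table, sc$peaks_bed, g2)
  expect_setequal(both$genes, c("gA", "gA2"))
})

test_that("1x promoter rule applies the FLI1-knockdown filter", {
  sc <- tiny_peak_scenario()
  de <- data.frame(gene = c("gA", "gB", "gC"),
                   log2FC = c(-2, -2, 2), adj_p = c(0.001, 0.001, 0.001))
  sig <- build_1x_promoter(sc$peak_table, sc$peaks_bed, sc$genes, de)
  expect_equal(sig$genes, "gB")
  # peak qualifies but gene is up under siFLI1 -> excluded
  de_up <- transform(de, log2FC = c(-2, 2, 2))
  expect_length(build_1x_promoter(sc$peak_table, sc$peaks_bed, sc$genes,
                                  de_up)$genes, 0L)
  none <- transform(de, adj_p = 0.5)
  expect_length(build_1x_promoter(sc$peak_table, sc$peaks_bed, sc$genes,
                                  none)$genes, 0L)
  expect_error(build_1x_promoter(sc$peak_table, sc$peaks_bed, sc$genes,
                                 de[, c("gene", "log2FC")]), "adj_p")
})

test_that("fold thresholds act monotonically on signature membership", {
  sc <- tiny_peak_scenario()
  sizes <- vapply(c(2, 1, 0.5, 0.1), function(thr)
    length(build_10x_promoter(sc$peak_table, sc$peaks_bed, sc$genes,
                              fc_gt = thr)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("cox_screen recovers a planted binary log-hazard ratio", {
  set.seed(31)
  n <- 200
  x <- rep(c(0, 1), each = n / 2)
  tt <- rexp(n, rate = 0.02 * exp(1 * x))
  expr <- matrix(c(x, rep(1, n)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("planted", "flat"), sprintf("s%d", 1:n)))
  surv <- data.frame(sample = colnames(expr), time = tt, event = 1L)
  res <- cox_screen(expr, surv)
  # coefficient on z-scored x equals beta * sd(x)
  expect_equal(res$coef[res$gene == "planted"] / sd(x), 1, tolerance = 0.35)
  expect_false(res$converged[res$gene == "flat"])
  expect_error(cox_screen(expr, transform(surv, event = 0L)), "events")
})

test_that("null genes split coefficient signs evenly", {
  set.seed(32)
  n <- 100
  expr <- matrix(rnorm(50 * n), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:n)))
  surv <- data.frame(sample = colnames(expr), time = rexp(n, 0.02),
                     event = 1L)
  res <- cox_screen(expr, surv)
  expect_gt(mean(res$coef > 0), 0.3)
  expect_lt(mean(res$coef > 0), 0.7)
})

test_that("prognostic refinement keeps positive-coefficient genes only", {
  sig <- gene_signature("10x_combined", c("a", "b", "c"), "up")
  cox <- data.frame(gene = c("a", "b"), coef = c(0.5, -0.5),
                    se = 0.1, z = 1, p_value = 0.1, score_chisq = 1,
                    converged = TRUE)
  expect_warning(ref <- refine_prognostic(sig, cox), "dropped")
  expect_equal(ref$genes, "a")
  allneg <- transform(cox, coef = -abs(coef))
  expect_warning(none <- refine_prognostic(sig, allneg))
  expect_length(none$genes, 0L)
})

test_that("activity signature requires concordant significance in all systems", {
  t1 <- data.frame(gene = c("u", "d", "x", "y"),
                   log2FC = c(2, -2, 1, 1), adj_p = c(0.01, 0.01, 0.01, 0.5))
  t2 <- data.frame(gene = c("u", "d", "x", "y"),
                   log2FC = c(1, -1, -1, 1), adj_p = c(0.01, 0.01, 0.01, 0.01))
  act <- build_activity_signature(list(a = t1, b = t2))
  expect_equal(act$up$genes, "u")
  expect_equal(act$down$genes, "d")    # x discordant, y not significant in t1
  expect_error(build_activity_signature(list(t1)), ">= 2")
  empty <- t1[0, ]
  act0 <- build_activity_signature(list(a = t1, b = empty))
  expect_length(act0$up$genes, 0L)
})

test_that("signatures re-derive identically with matching provenance", {
  sc <- tiny_peak_scenario()
  s1 <- build_10x_promoter(sc$peak_table, sc$peaks_bed, sc$genes)
  s2 <- build_10x_promoter(sc$peak_table, sc$peaks_bed, sc$genes)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$provenance$input_digests, s2$provenance$input_digests)
})

test_that("GMT files round-trip signatures", {
  sigs <- list(one = gene_signature("one", c("a", "b"), "up"),
               two = gene_signature("two", c("c"), "down"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sigs, f)
  back <- read_gmt(f)
  expect_equal(back$one, c("a", "b"))
  expect_equal(back$two, "c")
})
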